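## The three gene-classification rules at the heart of the dormancy
## analysis: the low-expression filter, the consensus differential-
## expression rule across paired models, and the dormancy-persistence call.
## All are inclusive threshold rules — no p-values, no correction.

#' Low-expression filter with per-model either-stage evaluation
#'
#' A gene counts as *expressed in a model* when, in at least one of that
#' model's two samples (its own active/dormant pair), TPM and raw counts
#' both clear the thresholds (`TPM >= tpm_min` AND `count >= count_min`).
#' A gene is *retained* when it is expressed in at least
#' `min_models_expressed` models.
#'
#' @param experiment A [count_experiment()].
#' @param config A [filter_config()].
#' @param tpm_table Optional precomputed [tpm()] tibble.
#' @return A list: `genes` — character vector of retained genes; `summary` —
#'   tibble `gene`, `n_models_expressed`, `retained`; `flags` — long tibble
#'   `gene`, `model`, `expressed`.
#' @examples
#' sim <- simulate_counts(count_sim_config(n_genes = 100, seed = 5))
#' ef <- expression_filter(sim$experiment, filter_config())
#' head(ef$summary)
#' @export
expression_filter <- function(experiment, config = filter_config(),
                              tpm_table = NULL) {
  stopifnot(inherits(experiment, "count_experiment"),
            inherits(config, "filter_config"))
  meta <- experiment$sample_meta
  n_models <- length(unique(meta$model))
  if (config$min_models_expressed > n_models) {
    abort(sprintf(
      "`min_models_expressed` (%d) exceeds the number of models (%d).",
      config$min_models_expressed, n_models),
      class = "dormantx_config_error")
  }
  tpm_table <- tpm_table %||% tpm(experiment)
  cmat <- counts_matrix(experiment)
  tmat <- as.matrix(tpm_table[meta$sample])
  pass <- tmat >= config$tpm_min & cmat >= config$count_min

  models <- unique(meta$model)
  flags <- purrr::map_dfr(models, function(m) {
    cols <- meta$sample[meta$model == m]
    tibble(gene = experiment$counts$gene, model = m,
           expressed = rowSums(pass[, cols, drop = FALSE]) > 0)
  })
  summary <- flags |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_models_expressed = sum(.data$expressed),
                     .groups = "drop") |>
    dplyr::mutate(retained =
                    .data$n_models_expressed >= config$min_models_expressed) |>
    dplyr::arrange(match(.data$gene, experiment$counts$gene))
  list(genes = summary$gene[summary$retained], summary = summary,
       flags = flags)
}

#' Consensus differential-expression calls across paired models
#'
#' A gene is called differentially expressed when its per-model
#' dormant/active fold change clears the threshold in the same direction in
#' enough models: up-support is the number of models with
#' `fc >= fc_threshold`, down-support the number with
#' `fc <= 1/fc_threshold`; the call is `up` (or `down`) when the respective
#' support reaches `min_models_de`, else `none`. If both directions qualify
#' (possible only when `min_models_de <= n_models/2`) the gene is called
#' `none` with a warning — a consensus call must point one way.
#'
#' @param fc_table Long tibble `gene`, `model`, `fc` from
#'   [model_fold_changes()].
#' @param config A [filter_config()].
#' @return Tibble `gene`, `direction` (`"up"`/`"down"`/`"none"`),
#'   `support` (models backing the called direction, 0 for `none`),
#'   `up_support`, `down_support`.
#' @examples
#' fc <- tibble::tibble(gene = "g", model = paste0("M", 1:5),
#'                      fc = c(2.1, 2.5, 3.0, 1.2, 0.8))
#' consensus_de(fc, filter_config())
#' @export
consensus_de <- function(fc_table, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  calls <- fc_table |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      up_support = sum(.data$fc >= config$fc_threshold),
      down_support = sum(.data$fc <= 1 / config$fc_threshold),
      .groups = "drop") |>
    dplyr::mutate(
      up_ok = .data$up_support >= config$min_models_de,
      down_ok = .data$down_support >= config$min_models_de,
      direction = dplyr::case_when(
        .data$up_ok & .data$down_ok ~ "none",
        .data$up_ok ~ "up",
        .data$down_ok ~ "down",
        TRUE ~ "none"),
      support = dplyr::case_when(
        direction == "up" ~ .data$up_support,
        direction == "down" ~ .data$down_support,
        TRUE ~ 0L))
  conflicted <- calls$gene[calls$up_ok & calls$down_ok]
  if (length(conflicted) > 0) {
    warn(sprintf(
      "Gene(s) qualified in both directions, called 'none': %s.",
      paste(conflicted, collapse = ", ")))
  }
  dplyr::select(calls, "gene", "direction", "support",
                "up_support", "down_support")
}

#' Dormancy-persistent gene calls
#'
#' A gene is dormancy-persistent when its mean normalized count is at or
#' above `persistence_floor` (default 1024 = 2^10) in the active stage AND
#' in the dormant stage — highly expressed regardless of dormancy. The
#' default scope averages across models per stage; `scope = "per_model"`
#' instead requires every model's own stage values to clear the floor.
#' `use_normalized = FALSE` applies the rule to raw counts.
#'
#' @param experiment A [count_experiment()].
#' @param config A [filter_config()].
#' @param scope `"across_models"` (stage mean over all models) or
#'   `"per_model"`.
#' @param use_normalized Apply the floor to median-of-ratios-normalized
#'   counts (default) or raw counts.
#' @param normalized Optional precomputed [normalize_counts()] tibble.
#' @return Tibble `gene`, `mean_active`, `mean_dormant`, `persistent`.
#' @examples
#' sim <- simulate_counts(count_sim_config(n_genes = 100, seed = 8))
#' dplyr::filter(persistent_genes(sim$experiment), persistent)
#' @export
persistent_genes <- function(experiment, config = filter_config(),
                             scope = c("across_models", "per_model"),
                             use_normalized = TRUE, normalized = NULL) {
  stopifnot(inherits(experiment, "count_experiment"),
            inherits(config, "filter_config"))
  scope <- match.arg(scope)
  tab <- if (use_normalized) {
    resolve_normalized(experiment, normalized)
  } else experiment$counts
  meta <- experiment$sample_meta
  act <- as.matrix(tab[meta$sample[meta$stage == "active"]])
  dor <- as.matrix(tab[meta$sample[meta$stage == "dormant"]])
  floor <- config$persistence_floor
  out <- tibble(gene = tab$gene,
                mean_active = rowMeans(act),
                mean_dormant = rowMeans(dor))
  out$persistent <- if (scope == "across_models") {
    out$mean_active >= floor & out$mean_dormant >= floor
  } else {
    rowSums(act >= floor) == ncol(act) & rowSums(dor >= floor) == ncol(dor)
  }
  out
}
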