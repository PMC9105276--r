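## Synthetic data: dual-species read sets and paired-model count experiments
## with planted ground truth, for validating the analysis end to end.

DEFAULT_MODELS <- c("LTL313B", "LTL313H", "LTL412", "LTL471", "LTL556")

model_ids <- function(n_models) {
  if (n_models == 5L) DEFAULT_MODELS else sprintf("M%d", seq_len(n_models))
}

#' Simulate xenograft reads aligned to a combined human+mouse reference
#'
#' Draws a read population mimicking a PDX RNA-seq library mapped against a
#' joint human+mouse reference: each read is either unmapped, ambiguous
#' (alignments in both genomes), or uniquely mapped, and uniquely mapped
#' reads are human with probability `human_fraction`, mouse otherwise.
#' Human-unique and mouse-unique reads carry a single alignment to one gene
#' of their species; ambiguous reads carry one alignment per species with
#' independent scores.
#'
#' @param config A [read_sim_config()].
#' @param n_target_genes Number of gene targets per species to draw hits
#'   from.
#' @return A list with `alignments` — a tibble of per-hit records
#'   (`read_id`, `species`, `target_id`, `score`; unmapped reads appear once
#'   with `NA` species/target and score 0) — and `truth`, a tibble mapping
#'   `read_id` to its planted species label
#'   (`"human"`, `"mouse"`, `"both"`, `"none"`).
#' @examples
#' sim <- simulate_reads(read_sim_config(n_reads = 100, seed = 7))
#' dplyr::count(sim$truth, species)
#' @export
simulate_reads <- function(config, n_target_genes = 50) {
  stopifnot(inherits(config, "read_sim_config"))
  with_seed(config$seed, {
    n <- config$n_reads
    read_id <- sprintf("read%06d", seq_len(n))
    a <- config$ambiguous_fraction
    u <- config$unmapped_fraction
    category <- sample(c("unique", "both", "none"), n, replace = TRUE,
                       prob = c(1 - a - u, a, u))
    species <- ifelse(
      category == "unique",
      sample(c("human", "mouse"), n, replace = TRUE,
             prob = c(config$human_fraction, 1 - config$human_fraction)),
      category)
    truth <- tibble(read_id = read_id, species = species)

    human_pool <- sprintf("HG%03d", seq_len(n_target_genes))
    mouse_pool <- sprintf("MG%03d", seq_len(n_target_genes))
    pick <- function(pool, k) sample(pool, k, replace = TRUE)
    score <- function(k) round(runif(k, 40, 60), 1)

    is_h <- species == "human"
    is_m <- species == "mouse"
    is_b <- species == "both"
    is_n <- species == "none"
    alignments <- dplyr::bind_rows(
      tibble(read_id = read_id[is_h], species = "human",
             target_id = pick(human_pool, sum(is_h)),
             score = score(sum(is_h))),
      tibble(read_id = read_id[is_m], species = "mouse",
             target_id = pick(mouse_pool, sum(is_m)),
             score = score(sum(is_m))),
      tibble(read_id = rep(read_id[is_b], each = 2L),
             species = rep(c("human", "mouse"), sum(is_b)),
             target_id = as.vector(rbind(pick(human_pool, sum(is_b)),
                                         pick(mouse_pool, sum(is_b)))),
             score = score(2L * sum(is_b))),
      tibble(read_id = read_id[is_n], species = NA_character_,
             target_id = NA_character_, score = 0))
    alignments <- dplyr::arrange(alignments, .data$read_id, .data$species)
    list(alignments = alignments, truth = truth)
  })
}

#' Simulate a paired active/dormant count experiment with planted truth
#'
#' Generates negative-binomial counts for `n_genes` genes across paired
#' active/dormant samples of `n_models` PDX models. Per-gene baseline
#' expected counts are drawn log-normally around `baseline_mean_log2`.
#' Planted classes:
#'
#' * **DE genes** — the dormant-stage mean is multiplied (up) or divided
#'   (down) by `de_fold`, in `de_models_planted` of the models.
#' * **Persistent genes** — both stage means are set to
#'   `persistent_floor_margin * filter_config$persistence_floor`.
#' * **Signature genes** — genes named in `signature_sets` (default: the
#'   packaged placeholder proliferation and androgen-responsive sets) are
#'   added with their dormant-stage mean reduced by
#'   `signature_reduction_log2` log2 units in every model, emulating the
#'   shutdown of proliferation and androgen-receptor signaling after
#'   castration.
#'
#' Effective lengths are drawn log-uniformly in \[300, 10000\] nt.
#'
#' @param config A [count_sim_config()].
#' @param filter_config A [filter_config()]; supplies the persistence floor
#'   at which persistent genes are planted.
#' @param signature_sets Named list of character vectors of gene symbols to
#'   embed as signature genes, or `NULL` to plant none.
#' @param immune_genes Gene symbols to scatter across the simulated genes
#'   (inheriting whatever planted class sits at their position), so that the
#'   annotation and discriminative stages see a realistic immune complement.
#'   `NULL` (default) embeds the packaged immune groups, capped at 25% of
#'   `n_genes`; `character(0)` embeds none.
#' @return A list with `experiment` (a [count_experiment()]) and `truth`, a
#'   per-gene tibble with columns `gene`, `de_direction`
#'   (`"up"`/`"down"`/`"none"`), `persistent` (logical), `signature`
#'   (set name or `NA`), and `base_mean` (the planted active-stage mean).
#' @examples
#' sim <- simulate_counts(count_sim_config(n_genes = 200, seed = 42))
#' dplyr::count(sim$truth, de_direction)
#' @export
simulate_counts <- function(config, filter_config = dormantx::filter_config(),
                            signature_sets = default_signature_sets(),
                            immune_genes = NULL) {
  stopifnot(inherits(config, "count_sim_config"),
            inherits(filter_config, "filter_config"))
  with_seed(config$seed, {
    n_genes <- config$n_genes
    n_models <- config$n_models
    models <- model_ids(n_models)

    n_up <- round(config$frac_de_up * n_genes)
    n_down <- round(config$frac_de_down * n_genes)
    n_pers <- round(config$frac_persistent * n_genes)

    sig_genes <- unlist(lapply(names(signature_sets %||% list()),
                               function(s) {
                                 setNames(signature_sets[[s]],
                                          rep(s, length(signature_sets[[s]])))
                               }))
    n_sig <- length(sig_genes)
    if (n_up + n_down + n_pers + n_sig > n_genes) {
      abort("Planted classes exceed `n_genes`; increase `n_genes`.",
            class = "dormantx_config_error")
    }

    gene <- sprintf("GENE%05d", seq_len(n_genes))
    de_direction <- rep("none", n_genes)
    de_direction[seq_len(n_up)] <- "up"
    de_direction[n_up + seq_len(n_down)] <- "down"
    persistent <- rep(FALSE, n_genes)
    persistent[n_up + n_down + seq_len(n_pers)] <- TRUE
    signature <- rep(NA_character_, n_genes)
    sig_idx <- integer(0)
    if (n_sig > 0) {
      sig_idx <- n_up + n_down + n_pers + seq_len(n_sig)
      gene[sig_idx] <- unname(sig_genes)
      signature[sig_idx] <- names(sig_genes)
    }

    ## scatter immune symbols over non-signature positions; they inherit the
    ## planted class (DE / persistent / null) at their landing spot
    free <- setdiff(seq_len(n_genes), sig_idx)
    if (is.null(immune_genes)) {
      pool <- names(immune_gene_groups()$group_of)
      immune_genes <- head(pool, min(floor(0.25 * n_genes), length(free)))
    }
    immune_genes <- setdiff(immune_genes, gene)
    if (length(immune_genes) > 0) {
      if (length(immune_genes) > length(free)) {
        abort("Too many `immune_genes` for `n_genes`.",
              class = "dormantx_config_error")
      }
      spots <- sample(free, length(immune_genes))
      gene[spots] <- immune_genes
    }

    base_mean <- 2^stats::rnorm(n_genes, config$baseline_mean_log2, 1.5)
    base_mean[persistent] <-
      filter_config$persistence_floor * config$persistent_floor_margin

    ## stage means per gene x model
    de_models <- models[seq_len(config$de_models_planted)]
    mu_active <- matrix(base_mean, n_genes, n_models,
                        dimnames = list(gene, models))
    mu_dormant <- mu_active
    fold <- rep(1, n_genes)
    fold[de_direction == "up"] <- config$de_fold
    fold[de_direction == "down"] <- 1 / config$de_fold
    mu_dormant[, de_models] <- mu_dormant[, de_models] * fold
    sig_shrink <- ifelse(is.na(signature), 1,
                         2^(-config$signature_reduction_log2))
    mu_dormant <- mu_dormant * sig_shrink

    size <- 1 / config$nb_dispersion
    draw <- function(mu) {
      matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
             nrow = nrow(mu), dimnames = dimnames(mu))
    }
    active_counts <- draw(mu_active)
    dormant_counts <- draw(mu_dormant)

    sample_meta <- tibble(
      sample = as.vector(rbind(paste0(models, "_active"),
                               paste0(models, "_dormant"))),
      model = rep(models, each = 2L),
      stage = rep(c("active", "dormant"), n_models))
    counts <- tibble(gene = gene)
    for (i in seq_len(n_models)) {
      counts[[paste0(models[i], "_active")]] <- active_counts[, i]
      counts[[paste0(models[i], "_dormant")]] <- dormant_counts[, i]
    }
    eff_length <- tibble(gene = gene,
                         eff_length = round(exp(runif(n_genes, log(300),
                                                      log(10000)))))
    truth <- tibble(gene = gene, de_direction = de_direction,
                    persistent = persistent, signature = signature,
                    base_mean = base_mean)
    list(experiment = count_experiment(counts, sample_meta, eff_length),
         truth = truth)
  })
}

#' Packaged placeholder signature gene sets
#'
#' Small stand-in proliferation and androgen-responsive signatures used by
#' the simulator and examples. These are well-known marker genes, not the
#' curated signatures a production analysis would supply via GMT files.
#'
#' @return Named list of two character vectors
#'   (`proliferation`, `androgen_response`).
#' @export
default_signature_sets <- function() {
  sets <- read_gmt(system.file("extdata", "signatures_synthetic.gmt",
                               package = "dormantx"))
  sets[c("proliferation", "androgen_response")]
}
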