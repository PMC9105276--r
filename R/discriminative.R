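## Random-forest selection of the immune genes that best separate active
## from dormant samples. With 5 paired models there are only 10 samples, so
## the forest is trained on all of them (no held-out split) and the contract
## is procedural: deterministic ranking under a fixed seed.

#' Select discriminative genes by random-forest feature importance
#'
#' Trains a random-forest classifier of stage (active vs dormant) on
#' `log2(normalized count + 1)` values of the given genes and ranks genes by
#' feature importance, normalized to sum 1. Selection is either the top
#' `rule_value` genes (`"top_k"`, default 54 — the size of the published
#' discriminative set) or all genes with normalized importance at or above
#' `rule_value` (`"importance_threshold"`). Ties are broken lexicographically
#' by symbol, making the ranking fully deterministic under a fixed seed.
#'
#' Impurity importance is the default; permutation importance is available
#' because impurity importance is biased in the presence of correlated
#' features (negative permutation importances are clamped to 0 before
#' normalization).
#'
#' @param experiment A [count_experiment()].
#' @param genes Genes to rank (default: genes annotated to an immune group
#'   by `collection`). At least 2 must be present in the experiment.
#' @param collection [gene_set_collection()] used when `genes` is `NULL`.
#' @param n_trees Number of trees (default 1000; stability matters more than
#'   speed at 10 samples).
#' @param seed Integer seed for the forest.
#' @param selection_rule `"top_k"` or `"importance_threshold"`.
#' @param rule_value Number of genes (top_k) or importance cutoff.
#' @param importance `"impurity"` or `"permutation"`.
#' @param normalized Optional precomputed [normalize_counts()] tibble.
#' @return A `feature_ranking` object; `tidy()` it for the per-gene table
#'   (`gene`, `importance`, `rank`, `selected`), `glance()` for run
#'   metadata.
#' @examples
#' sim <- simulate_counts(count_sim_config(n_genes = 100, seed = 11))
#' fr <- select_discriminative_features(
#'   sim$experiment, genes = sim$experiment$counts$gene[1:30],
#'   seed = 1, rule_value = 5)
#' tidy(fr)
#' @export
select_discriminative_features <- function(experiment, genes = NULL,
                                           collection = immune_gene_groups(),
                                           n_trees = 1000, seed = 1L,
                                           selection_rule = c("top_k",
                                                              "importance_threshold"),
                                           rule_value = 54,
                                           importance = c("impurity",
                                                          "permutation"),
                                           normalized = NULL) {
  stopifnot(inherits(experiment, "count_experiment"))
  selection_rule <- match.arg(selection_rule)
  importance <- match.arg(importance)
  assert_positive(n_trees, "n_trees", integer = TRUE)

  if (is.null(genes)) {
    ann <- annotate_genes(experiment$counts$gene, collection)
    genes <- ann$gene[ann$group != "unannotated"]
  }
  norm <- resolve_normalized(experiment, normalized)
  genes <- intersect(genes, norm$gene)
  if (length(genes) < 2) {
    abort("Need at least 2 candidate genes present in the experiment.",
          class = "dormantx_input_error")
  }
  meta <- experiment$sample_meta
  if (length(unique(meta$stage)) < 2) {
    abort("Both stages must be present to train the classifier.",
          class = "dormantx_label_error")
  }
  sub <- norm[match(genes, norm$gene), ]
  x <- t(log2(as.matrix(sub[meta$sample]) + 1))
  colnames(x) <- genes
  dat <- as.data.frame(x)
  ## ranger rejects non-syntactic names (e.g. HLA-A); train on safe names
  safe <- make.names(genes)
  names(dat) <- safe
  dat$.stage <- factor(meta$stage, levels = c("active", "dormant"))

  fit <- ranger::ranger(
    dependent.variable.name = ".stage", data = dat,
    num.trees = n_trees, importance = importance,
    seed = seed, num.threads = 1)
  imp <- pmax(fit$variable.importance[safe], 0)
  total <- sum(imp)
  imp_norm <- if (total > 0) imp / total else rep(1 / length(imp), length(imp))

  ranking <- tibble(gene = genes, importance = unname(imp_norm)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
  ranking$selected <- switch(
    selection_rule,
    top_k = ranking$rank <= rule_value,
    importance_threshold = ranking$importance >= rule_value)

  structure(
    list(ranking = ranking, selection_rule = selection_rule,
         rule_value = rule_value, importance = importance,
         n_trees = as.integer(n_trees), seed = as.integer(seed),
         oob_error = fit$prediction.error),
    class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf(
    "<feature_ranking> %d genes, %d selected (%s = %g), %s importance, %d trees, seed %d\n",
    nrow(x$ranking), sum(x$ranking$selected), x$selection_rule,
    x$rule_value, x$importance, x$n_trees, x$seed))
  print(head(x$ranking, 5))
  invisible(x)
}

#' @describeIn select_discriminative_features Per-gene ranking as a tibble.
#' @param x A `feature_ranking`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.feature_ranking <- function(x, ...) x$ranking

#' @describeIn select_discriminative_features One-row run metadata
#'   (selection rule, importance mode, trees, seed, out-of-bag error).
#' @exportS3Method generics::glance
glance.feature_ranking <- function(x, ...) {
  tibble(n_genes = nrow(x$ranking), n_selected = sum(x$ranking$selected),
         selection_rule = x$selection_rule, rule_value = x$rule_value,
         importance = x$importance, n_trees = x$n_trees, seed = x$seed,
         oob_error = x$oob_error)
}
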