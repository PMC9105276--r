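## Gene-set I/O, immune-group annotation, and signature-level comparison of
## active vs dormant stages.

#' Read / write gene sets in GMT format
#'
#' `read_gmt()` parses a tab-separated GMT file (set name, description,
#' member symbols) into a named list of character vectors;
#' `write_gmt()` is the inverse.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled `""` when absent).
#' @return `read_gmt()`: named list of character vectors. `write_gmt()`:
#'   `path`, invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GMT file not found: %s", path),
          class = "dormantx_geneset_error")
  }
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a validated gene-set collection
#'
#' Wraps a named list of gene groups (e.g. the 20 immune gene families) into
#' a collection with a gene -> group lookup. Within-set duplicates are
#' dropped; a gene appearing in two different groups is a curation error and
#' aborts, listing the offending genes.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @return A `gene_set_collection`: list with `sets` (the deduplicated list)
#'   and `group_of` (named character vector, gene -> group).
#' @examples
#' col <- gene_set_collection(list(A = c("TP53", "MYC"), B = "EGFR"))
#' col$group_of[["MYC"]]
#' @export
gene_set_collection <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  sets <- lapply(sets, unique)
  all_genes <- unlist(sets, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup) > 0) {
    abort(sprintf("Gene(s) assigned to more than one group: %s.",
                  paste(dup, collapse = ", ")),
          class = "dormantx_curation_error")
  }
  group_of <- setNames(rep(names(sets), lengths(sets)), all_genes)
  structure(list(sets = sets, group_of = group_of),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d groups, %d genes\n",
              length(x$sets), length(x$group_of)))
  invisible(x)
}

#' The packaged immune gene-group collection
#'
#' Loads the 20 immune gene groups shipped with the package (chemokines and
#' their receptors, interferons and their receptors, interleukins and their
#' receptors, TNF superfamily ligands and receptors, B7 family, BMPs and
#' their receptors, MHC and related molecules, complement components and
#' regulators, mucins, colony-stimulating factors, toll-like receptors,
#' TGF-beta receptors, and prostaglandin E2 metabolism). The membership is a
#' working list assembled from well-known family members — configurable by
#' supplying your own GMT via [read_gmt()] + [gene_set_collection()].
#'
#' @return A [gene_set_collection()].
#' @export
immune_gene_groups <- function() {
  gene_set_collection(
    read_gmt(system.file("extdata", "immune_groups.gmt",
                         package = "dormantx")))
}

#' Annotate genes with their immune group
#'
#' Assigns each input gene its group label by exact symbol match against a
#' [gene_set_collection()]; genes absent from the collection are labeled
#' `"unannotated"`. Total and idempotent on its input.
#'
#' @param genes Character vector of gene symbols, or a data frame with a
#'   `gene` column.
#' @param collection A [gene_set_collection()]; defaults to the packaged
#'   immune groups.
#' @return A tibble with columns `gene`, `group`.
#' @examples
#' annotate_genes(c("VTCN1", "CD46", "NOT_A_GENE"))
#' @export
annotate_genes <- function(genes, collection = immune_gene_groups()) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.data.frame(genes)) genes <- genes$gene
  group <- unname(collection$group_of[genes])
  tibble(gene = genes,
         group = dplyr::coalesce(group, "unannotated"))
}

## normalized counts for an experiment (gene + sample columns), reused by the
## signature / filter / clustering layers
resolve_normalized <- function(experiment, normalized = NULL) {
  normalized %||% normalize_counts(experiment)
}

#' Summarize a gene signature across paired samples
#'
#' Computes per-sample distribution summaries (median and quartiles of
#' `log2(normalized + 1)` over the signature genes — the numbers behind a
#' violin plot) and, per model, the paired signature shift: the median over
#' signature genes of `log2(dormant + 1) - log2(active + 1)` on normalized
#' counts. Negative shifts mean the signature is reduced in dormancy; for a
#' proliferation or androgen-responsive signature after castration this is
#' the expected sign.
#'
#' @param experiment A [count_experiment()].
#' @param gene_set Character vector of signature gene symbols.
#' @param normalized Optional precomputed [normalize_counts()] tibble.
#' @return A list of two tibbles: `sample_summary` (`sample`, `model`,
#'   `stage`, `n_genes`, `q25`, `median`, `q75`) and `model_shift` (`model`,
#'   `shift_log2`).
#' @examples
#' sim <- simulate_counts(count_sim_config(n_genes = 300, seed = 3))
#' sig <- default_signature_sets()$proliferation
#' signature_summary(sim$experiment, sig)$model_shift
#' @export
signature_summary <- function(experiment, gene_set, normalized = NULL) {
  norm <- resolve_normalized(experiment, normalized)
  present <- intersect(gene_set, norm$gene)
  if (length(present) < 2) {
    abort(sprintf(
      "Signature has %d gene(s) in the experiment; need at least 2.",
      length(present)), class = "dormantx_geneset_error")
  }
  meta <- experiment$sample_meta
  sub <- norm[norm$gene %in% present, ]
  logm <- log2(as.matrix(sub[meta$sample]) + 1)

  sample_summary <- tibble(
    sample = meta$sample, model = meta$model, stage = meta$stage,
    n_genes = length(present),
    q25 = apply(logm, 2, quantile, 0.25, names = FALSE),
    median = apply(logm, 2, median),
    q75 = apply(logm, 2, quantile, 0.75, names = FALSE))

  models <- unique(meta$model)
  shift <- vapply(models, function(m) {
    act <- meta$sample[meta$model == m & meta$stage == "active"]
    dor <- meta$sample[meta$model == m & meta$stage == "dormant"]
    median(logm[, dor] - logm[, act])
  }, numeric(1))
  list(sample_summary = sample_summary,
       model_shift = tibble(model = models, shift_log2 = unname(shift)))
}

#' Paired signed-rank test of a signature within one model
#'
#' Two-sided Wilcoxon signed-rank test across signature genes between the
#' active and dormant sample of one model, on `log2(normalized + 1)` values.
#' This is an interpretive add-on for quantifying a signature shift; the
#' headline gene filters are threshold rules, not tests. When every paired
#' difference is exactly zero (identical columns) the test degenerates and
#' the no-shift convention `statistic = 0, p_value = 1` is returned.
#'
#' @inheritParams signature_summary
#' @param model Model identifier present in the experiment.
#' @return A one-row tibble: `model`, `n_genes`, `statistic`, `p_value`.
#' @export
compare_paired_signature <- function(experiment, gene_set, model,
                                     normalized = NULL) {
  norm <- resolve_normalized(experiment, normalized)
  meta <- experiment$sample_meta
  if (!model %in% meta$model) {
    abort(sprintf("Unknown model '%s'.", model),
          class = "dormantx_input_error")
  }
  present <- intersect(gene_set, norm$gene)
  if (length(present) < 10) {
    abort(sprintf(
      "Signature has %d gene(s) in the experiment; need at least 10 for the signed-rank test.",
      length(present)), class = "dormantx_insufficient_data_error")
  }
  sub <- norm[norm$gene %in% present, ]
  act <- log2(sub[[meta$sample[meta$model == model & meta$stage == "active"]]] + 1)
  dor <- log2(sub[[meta$sample[meta$model == model & meta$stage == "dormant"]]] + 1)
  if (all(dor == act)) {
    return(tibble(model = model, n_genes = length(present),
                  statistic = 0, p_value = 1))
  }
  wt <- suppressWarnings(wilcox.test(dor, act, paired = TRUE))
  tibble(model = model, n_genes = length(present),
         statistic = unname(wt$statistic), p_value = wt$p.value)
}
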