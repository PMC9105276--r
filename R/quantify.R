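## Gene-level quantification: read aggregation, TPM, median-of-ratios size
## factors, and per-model dormant/active fold changes. These re-express the
## standard counting/normalization stages as explicit formulas so every
## downstream threshold is auditable.

#' Aggregate retained reads into gene counts
#'
#' Counts, per gene, the retained human reads whose human hits name exactly
#' one gene; a read hitting more than one distinct human gene is ambiguous
#' and contributes to none (unique-assignment counting).
#'
#' @param reads Tibble of human alignment rows (`read_id`, `target_id`, ...)
#'   as returned in `partition_reads()$reads`.
#' @param genes Optional character vector of gene ids fixing the output
#'   universe (genes with no reads get count 0).
#' @return Tibble `gene`, `count`, sorted by gene.
#' @examples
#' reads <- tibble::tibble(
#'   read_id = c("r1", "r2", "r3", "r3"),
#'   target_id = c("A", "A", "A", "B"))
#' aggregate_counts(reads)  # r3 is ambiguous between A and B
#' @export
aggregate_counts <- function(reads, genes = NULL) {
  reads <- as_tibble(reads)
  counted <- if (nrow(reads) == 0) {
    tibble(gene = character(), count = integer())
  } else {
    reads |>
      dplyr::distinct(.data$read_id, .data$target_id) |>
      dplyr::group_by(.data$read_id) |>
      dplyr::filter(dplyr::n() == 1L) |>
      dplyr::ungroup() |>
      dplyr::count(gene = .data$target_id, name = "count")
  }
  if (!is.null(genes)) {
    counted <- tibble(gene = genes) |>
      dplyr::left_join(counted, by = "gene") |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  }
  dplyr::arrange(counted, .data$gene)
}

tpm_vector <- function(counts, eff_length) {
  if (any(eff_length <= 0)) {
    abort("Effective lengths must be positive.",
          class = "dormantx_validation_error")
  }
  rate <- counts / eff_length
  denom <- sum(rate)
  if (denom == 0) return(rep(0, length(counts)))  # all-zero convention
  rate / denom * 1e6
}

#' Transcripts per million
#'
#' `tpm_g = (count_g / length_g) / sum_h(count_h / length_h) * 1e6`, per
#' sample. Columns of an all-zero sample are returned as all-zero TPM.
#'
#' @param experiment A [count_experiment()] (lengths taken from
#'   `eff_length`).
#' @return Tibble `gene` plus one TPM column per sample; each nonzero
#'   column sums to 1e6.
#' @export
tpm <- function(experiment) {
  stopifnot(inherits(experiment, "count_experiment"))
  mat <- counts_matrix(experiment)
  len <- experiment$eff_length$eff_length
  rate <- mat / len
  denom <- colSums(rate)
  out <- sweep(rate, 2, ifelse(denom == 0, 1, denom), "/") * 1e6
  dplyr::bind_cols(tibble(gene = experiment$counts$gene),
                   as_tibble(out, .name_repair = "minimal"))
}

#' Median-of-ratios size factors
#'
#' The per-sample size factor is the median, over genes with all-positive
#' counts, of that sample's count divided by the gene's across-sample
#' geometric mean, rescaled so the factors' own geometric mean is 1 (the
#' scale of normalized counts is only identified up to a constant; this
#' convention makes re-normalizing an already-normalized matrix yield
#' factors of exactly 1). Normalized counts are raw counts divided by the
#' sample's factor. With no all-positive gene the reference is undefined;
#' pass `pseudocount` to compute factors on `counts + pseudocount` instead.
#'
#' @param counts Gene x sample data frame (with a `gene` column), matrix, or
#'   [count_experiment()].
#' @param pseudocount Optional positive offset applied before computing the
#'   factors (fallback for sparse toy matrices).
#' @return Tibble `sample`, `size_factor`.
#' @examples
#' m <- tibble::tibble(gene = c("a", "b"), s1 = c(10, 20), s2 = c(20, 40))
#' size_factors(m)  # (1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts, pseudocount = NULL) {
  mat <- if (inherits(counts, "count_experiment")) {
    counts_matrix(counts)
  } else if (is.data.frame(counts)) {
    m <- as.matrix(counts[setdiff(names(counts), "gene")])
    rownames(m) <- counts$gene %||% NULL
    m
  } else as.matrix(counts)
  if (!is.null(pseudocount)) {
    assert_positive(pseudocount, "pseudocount")
    mat <- mat + pseudocount
  }
  ref <- rowSums(mat > 0) == ncol(mat)
  if (!any(ref)) {
    abort(paste0("No gene has positive counts in every sample; ",
                 "supply `pseudocount` (e.g. 0.5) to compute factors."),
          class = "dormantx_normalization_error")
  }
  logm <- log(mat[ref, , drop = FALSE])
  geo <- rowMeans(logm)
  sf <- apply(exp(logm - geo), 2, median)
  sf <- sf / exp(mean(log(sf)))  # geometric-mean-1 convention
  tibble(sample = colnames(mat) %||% sprintf("S%d", seq_len(ncol(mat))),
         size_factor = unname(sf))
}

#' Normalized counts
#'
#' Divides each sample's counts by its median-of-ratios size factor.
#'
#' @inheritParams tpm
#' @param pseudocount Passed to [size_factors()] as a fallback for matrices
#'   with no all-positive gene.
#' @return Tibble `gene` plus one normalized-count column per sample.
#' @export
normalize_counts <- function(experiment, pseudocount = NULL) {
  stopifnot(inherits(experiment, "count_experiment"))
  mat <- counts_matrix(experiment)
  sf <- size_factors(experiment, pseudocount = pseudocount)
  norm <- sweep(mat, 2, sf$size_factor[match(colnames(mat), sf$sample)], "/")
  dplyr::bind_cols(tibble(gene = experiment$counts$gene), as_tibble(norm))
}

#' Per-model dormant/active fold changes
#'
#' For each gene and model, `fc = (normalized dormant + pseudocount) /
#' (normalized active + pseudocount)`. With one sample per stage per model
#' this plain ratio (not a shrunken estimate) is the fold change the
#' consensus DE rule consumes; the pseudocount keeps it finite and equal to
#' 1 when both stages are zero.
#'
#' @inheritParams tpm
#' @param pseudocount Positive offset (default 1).
#' @param normalized Optional precomputed [normalize_counts()] tibble.
#' @return Long tibble `gene`, `model`, `fc` (always positive).
#' @examples
#' sim <- simulate_counts(count_sim_config(n_genes = 100, seed = 2))
#' model_fold_changes(sim$experiment)
#' @export
model_fold_changes <- function(experiment, pseudocount = 1,
                               normalized = NULL) {
  stopifnot(inherits(experiment, "count_experiment"))
  assert_positive(pseudocount, "pseudocount")
  norm <- resolve_normalized(experiment, normalized)
  meta <- experiment$sample_meta
  models <- unique(meta$model)
  purrr::map_dfr(models, function(m) {
    act <- meta$sample[meta$model == m & meta$stage == "active"]
    dor <- meta$sample[meta$model == m & meta$stage == "dormant"]
    if (length(act) != 1L || length(dor) != 1L) {
      abort(sprintf("Model '%s' is missing a stage pair.", m),
            class = "dormantx_pairing_error")
    }
    tibble(gene = norm$gene, model = m,
           fc = (norm[[dor]] + pseudocount) / (norm[[act]] + pseudocount))
  })
}
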