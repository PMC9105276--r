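#' Paired-model count experiment
#'
#' Container for a gene x sample RNA-seq count matrix with paired samples:
#' every PDX model contributes exactly one active (pre-castration) and one
#' dormant (post-castration) sample. Per-gene effective lengths (nt) are
#' carried for TPM computation.
#'
#' @param counts A data frame with a `gene` column followed by one
#'   non-negative integer column per sample.
#' @param sample_meta A data frame with columns `sample`, `model`, `stage`
#'   (`stage` in `"active"`/`"dormant"`), one row per count column.
#' @param eff_length A data frame with columns `gene`, `eff_length`
#'   (positive, nucleotides), one row per gene.
#' @return A `count_experiment` object (list of the three validated tibbles).
#' @examples
#' sim <- simulate_counts(count_sim_config(n_genes = 50, seed = 1))
#' sim$experiment
#' @export
count_experiment <- function(counts, sample_meta, eff_length) {
  counts <- as_tibble(counts)
  sample_meta <- as_tibble(sample_meta)
  eff_length <- as_tibble(eff_length)

  if (!"gene" %in% names(counts)) {
    abort("`counts` must have a `gene` column.", class = "dormantx_input_error")
  }
  if (anyDuplicated(counts$gene)) {
    abort("Gene identifiers in `counts` must be unique.",
          class = "dormantx_input_error")
  }
  samples <- setdiff(names(counts), "gene")
  if (!setequal(samples, sample_meta$sample)) {
    abort("Count columns and `sample_meta$sample` must match.",
          class = "dormantx_input_error")
  }
  if (!all(sample_meta$stage %in% c("active", "dormant"))) {
    abort("`stage` must be 'active' or 'dormant'.",
          class = "dormantx_input_error")
  }
  pairing <- table(sample_meta$model, sample_meta$stage)
  if (!all(pairing == 1L)) {
    bad <- rownames(pairing)[rowSums(pairing != 1L) > 0]
    abort(sprintf(
      "Every model needs exactly one active and one dormant sample; check: %s.",
      paste(bad, collapse = ", ")), class = "dormantx_pairing_error")
  }
  mat <- as.matrix(counts[samples])
  if (any(mat < 0) || any(is.na(mat))) {
    abort("Counts must be non-negative and complete.",
          class = "dormantx_input_error")
  }
  if (!setequal(eff_length$gene, counts$gene) ||
      any(eff_length$eff_length <= 0)) {
    abort("`eff_length` must cover every gene with a positive length.",
          class = "dormantx_input_error")
  }
  ## order metadata model-then-stage for stable downstream column order
  sample_meta <- dplyr::arrange(sample_meta, .data$model,
                                match(.data$stage, c("active", "dormant")))
  counts <- counts[c("gene", sample_meta$sample)]
  eff_length <- eff_length[match(counts$gene, eff_length$gene), ]
  structure(list(counts = counts, sample_meta = sample_meta,
                 eff_length = eff_length),
            class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat(sprintf("<count_experiment> %d genes x %d samples (%d paired models)\n",
              nrow(x$counts), nrow(x$sample_meta),
              length(unique(x$sample_meta$model))))
  print(head(x$counts, 5))
  invisible(x)
}

## gene x sample numeric matrix with gene rownames
counts_matrix <- function(experiment) {
  m <- as.matrix(experiment$counts[experiment$sample_meta$sample])
  rownames(m) <- experiment$counts$gene
  m
}

## column vector of samples for one stage, ordered by model
stage_samples <- function(experiment, stage) {
  meta <- experiment$sample_meta
  meta$sample[meta$stage == stage][order(meta$model[meta$stage == stage])]
}
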