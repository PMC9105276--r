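#' Gene-filter thresholds
#'
#' Bundles the thresholds used by the three gene-classification rules:
#' the expression filter (a gene is expressed in a model when TPM and raw
#' counts clear `tpm_min` / `count_min` in at least one of the two stages of
#' that model's pair, and is retained when expressed in at least
#' `min_models_expressed` models), the consensus differential-expression rule
#' (at least `fc_threshold`-fold change in the same direction in at least
#' `min_models_de` models), and the dormancy-persistence rule (stage-mean
#' normalized counts at or above `persistence_floor` in both the active and
#' the dormant stage).
#'
#' Defaults are the thresholds used throughout the dormant-PDX analysis:
#' TPM >= 1, counts >= 10, 3 of 5 models, 2-fold, and a persistence floor of
#' 1024 (2^10) normalized counts. All comparisons are inclusive.
#'
#' @param tpm_min Minimum TPM for a gene to count as expressed in a sample.
#' @param count_min Minimum raw read count for the same call.
#' @param min_models_expressed Models in which a gene must be expressed to be
#'   retained.
#' @param fc_threshold Fold-change threshold for the consensus DE rule
#'   (applied as `fc >= fc_threshold` for up, `fc <= 1/fc_threshold` for down).
#' @param min_models_de Models that must clear the fold-change threshold in
#'   the same direction.
#' @param persistence_floor Stage-mean normalized count floor for a gene to be
#'   called dormancy-persistent.
#' @return A `filter_config` list.
#' @examples
#' filter_config()
#' filter_config(fc_threshold = 4)
#' @export
filter_config <- function(tpm_min = 1, count_min = 10,
                          min_models_expressed = 3,
                          fc_threshold = 2, min_models_de = 3,
                          persistence_floor = 1024) {
  assert_positive(tpm_min, "tpm_min")
  assert_positive(count_min, "count_min", integer = TRUE)
  assert_positive(min_models_expressed, "min_models_expressed", integer = TRUE)
  assert_positive(fc_threshold, "fc_threshold")
  assert_positive(min_models_de, "min_models_de", integer = TRUE)
  assert_positive(persistence_floor, "persistence_floor")
  structure(
    list(tpm_min = tpm_min, count_min = count_min,
         min_models_expressed = min_models_expressed,
         fc_threshold = fc_threshold, min_models_de = min_models_de,
         persistence_floor = persistence_floor),
    class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Configuration for the dual-species read simulator
#'
#' Describes the read population of a xenograft RNA-seq library aligned to a
#' combined human+mouse reference: a fraction of reads mapping ambiguously to
#' both genomes, a fraction failing to map, and — among uniquely mapping
#' reads — a human (tumor) versus mouse (stroma) split.
#'
#' @param n_reads Number of reads to simulate.
#' @param human_fraction Proportion of reads originating from the human
#'   (tumor) compartment.
#' @param ambiguous_fraction Proportion of reads aligning to both genomes.
#' @param unmapped_fraction Proportion of reads with no alignment.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `read_sim_config` list.
#' @seealso [simulate_reads()]
#' @export
read_sim_config <- function(n_reads = 10000, human_fraction = 0.7,
                            ambiguous_fraction = 0.1,
                            unmapped_fraction = 0.05, seed = 1L) {
  assert_positive(n_reads, "n_reads", integer = TRUE)
  assert_proportion(human_fraction, "human_fraction")
  assert_proportion(ambiguous_fraction, "ambiguous_fraction")
  assert_proportion(unmapped_fraction, "unmapped_fraction")
  if (ambiguous_fraction + unmapped_fraction > 1) {
    abort(paste0("`ambiguous_fraction` + `unmapped_fraction` must be <= 1 ",
                 "(got ", ambiguous_fraction, " + ", unmapped_fraction, ")."),
          class = "dormantx_config_error")
  }
  structure(
    list(n_reads = as.integer(n_reads), human_fraction = human_fraction,
         ambiguous_fraction = ambiguous_fraction,
         unmapped_fraction = unmapped_fraction, seed = as.integer(seed)),
    class = "read_sim_config")
}

#' Configuration for the paired-model count simulator
#'
#' Describes a negative-binomial gene x sample count experiment with one
#' active (pre-castration) and one dormant (post-castration) sample per PDX
#' model, with planted gene classes: consensus-DE genes (dormant-stage mean
#' multiplied or divided by `de_fold`), dormancy-persistent genes (both stage
#' means planted at `persistent_floor_margin` times the downstream persistence
#' floor), and signature genes (proliferation / androgen-responsive sets)
#' whose dormant-stage mean is reduced by `signature_reduction_log2` log2
#' units.
#'
#' @param n_models Number of paired PDX models (default 5).
#' @param n_genes Number of simulated genes.
#' @param nb_dispersion Negative-binomial dispersion shared across genes
#'   (variance = mu + dispersion * mu^2).
#' @param baseline_mean_log2 Mean of the log2 baseline expected count across
#'   genes (baselines are drawn log-normally around this).
#' @param frac_de_up,frac_de_down Proportions of genes planted up- or
#'   down-regulated in dormancy.
#' @param de_fold Planted fold change (>= 2) for DE genes.
#' @param de_models_planted Number of models (out of `n_models`) in which the
#'   DE effect is planted; default all, lower values probe the consensus
#'   rule's boundary.
#' @param frac_persistent Proportion of genes planted as dormancy-persistent.
#' @param persistent_floor_margin Multiple (> 1) of the persistence floor at
#'   which persistent genes' stage means are planted.
#' @param signature_reduction_log2 Planted post-castration log2 reduction for
#'   signature genes.
#' @param seed Integer seed.
#' @return A `count_sim_config` list.
#' @seealso [simulate_counts()]
#' @export
count_sim_config <- function(n_models = 5, n_genes = 2000,
                             nb_dispersion = 0.05,
                             baseline_mean_log2 = 6,
                             frac_de_up = 0.05, frac_de_down = 0.05,
                             de_fold = 4, de_models_planted = n_models,
                             frac_persistent = 0.02,
                             persistent_floor_margin = 2,
                             signature_reduction_log2 = 2,
                             seed = 1L) {
  assert_positive(n_models, "n_models", integer = TRUE)
  assert_positive(n_genes, "n_genes", integer = TRUE)
  assert_positive(nb_dispersion, "nb_dispersion")
  assert_proportion(frac_de_up, "frac_de_up")
  assert_proportion(frac_de_down, "frac_de_down")
  assert_proportion(frac_persistent, "frac_persistent")
  if (frac_de_up + frac_de_down + frac_persistent > 1) {
    abort("`frac_de_up` + `frac_de_down` + `frac_persistent` must be <= 1.",
          class = "dormantx_config_error")
  }
  if (de_fold < 2) {
    abort("`de_fold` must be >= 2 so planted genes clear the consensus rule.",
          class = "dormantx_config_error")
  }
  assert_positive(de_models_planted, "de_models_planted", integer = TRUE)
  if (de_models_planted > n_models) {
    abort("`de_models_planted` cannot exceed `n_models`.",
          class = "dormantx_config_error")
  }
  if (persistent_floor_margin <= 1) {
    abort("`persistent_floor_margin` must be > 1.",
          class = "dormantx_config_error")
  }
  structure(
    list(n_models = as.integer(n_models), n_genes = as.integer(n_genes),
         nb_dispersion = nb_dispersion,
         baseline_mean_log2 = baseline_mean_log2,
         frac_de_up = frac_de_up, frac_de_down = frac_de_down,
         de_fold = de_fold, de_models_planted = as.integer(de_models_planted),
         frac_persistent = frac_persistent,
         persistent_floor_margin = persistent_floor_margin,
         signature_reduction_log2 = signature_reduction_log2,
         seed = as.integer(seed)),
    class = "count_sim_config")
}
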