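test_that("config invariants are enforced with informative errors", {
  expect_error(read_sim_config(ambiguous_fraction = 0.6,
                               unmapped_fraction = 0.6),
               class = "dormantx_config_error")
  expect_error(read_sim_config(human_fraction = 1.2),
               "human_fraction", class = "dormantx_config_error")
  expect_error(count_sim_config(frac_de_up = 0.5, frac_de_down = 0.5,
                                frac_persistent = 0.1),
               class = "dormantx_config_error")
  expect_error(count_sim_config(de_fold = 1.5),
               class = "dormantx_config_error")
  expect_error(count_sim_config(de_models_planted = 7, n_models = 5),
               class = "dormantx_config_error")
})

test_that("degenerate fractions give an all-human single-hit population", {
  sim <- simulate_reads(read_sim_config(n_reads = 1000, human_fraction = 1,
                                        ambiguous_fraction = 0,
                                        unmapped_fraction = 0, seed = 2))
  expect_equal(nrow(sim$truth), 1000)
  expect_true(all(sim$truth$species == "human"))
  expect_true(all(sim$alignments$species == "human"))
  expect_equal(dplyr::n_distinct(sim$alignments$read_id), 1000)
})

test_that("simulators are bit-identical under a fixed seed", {
  cfg <- read_sim_config(n_reads = 500, seed = 99)
  expect_identical(simulate_reads(cfg), simulate_reads(cfg))
  ccfg <- count_sim_config(n_genes = 150, seed = 99)
  expect_identical(simulate_counts(ccfg), simulate_counts(ccfg))
})

test_that("realized read-species proportions track configured fractions", {
  cfg <- read_sim_config(n_reads = 10000, human_fraction = 0.7,
                         ambiguous_fraction = 0.1, unmapped_fraction = 0.05,
                         seed = 7)
  counts <- table(simulate_reads(cfg)$truth$species)
  n <- cfg$n_reads
  expected <- c(human = 0.7 * 0.85, mouse = 0.3 * 0.85, both = 0.1,
                none = 0.05)
  for (sp in names(expected)) {
    p <- expected[[sp]]
    expect_lt(abs(counts[[sp]] / n - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("planted class labels are counted exactly", {
  sim <- simulate_counts(count_sim_config(n_genes = 1000, frac_de_up = 0.05,
                                          frac_de_down = 0.03,
                                          frac_persistent = 0.02, seed = 4),
                         signature_sets = NULL)
  expect_equal(sum(sim$truth$de_direction == "up"), 50)
  expect_equal(sum(sim$truth$de_direction == "down"), 30)
  expect_equal(sum(sim$truth$persistent), 20)
  expect_equal(nrow(sim$experiment$counts), 1000)
  expect_equal(nrow(sim$experiment$sample_meta), 10)
})

test_that("counts concentrate on the planted negative-binomial means", {
  # near-Poisson limit: per-gene sample means across replicates stay within
  # 2% of the planted mean
  ratios <- vapply(1:200, function(s) {
    sim <- simulate_counts(
      count_sim_config(n_genes = 20, nb_dispersion = 1e-4, frac_de_up = 0,
                       frac_de_down = 0, frac_persistent = 0, seed = s),
      signature_sets = NULL, immune_genes = character(0))
    cm <- as.matrix(sim$experiment$counts[-1])
    mean(rowMeans(cm) / sim$truth$base_mean)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.02)
})

test_that("persistent genes clear the floor in both stages almost surely", {
  # planted at margin 2 (mean 2048 vs floor 1024), normalized stage means
  hits <- unlist(lapply(1:100, function(s) {
    sim <- simulate_counts(
      count_sim_config(n_genes = 200, frac_persistent = 0.02,
                       persistent_floor_margin = 2, seed = s),
      signature_sets = NULL, immune_genes = character(0))
    pg <- persistent_genes(sim$experiment)
    pg$persistent[pg$gene %in% sim$truth$gene[sim$truth$persistent]]
  }))
  expect_gte(mean(hits), 0.95)
})

test_that("planted fold change is recovered from raw stage means", {
  cfg <- count_sim_config(n_genes = 300, nb_dispersion = 0.05, de_fold = 4)
  ratios <- vapply(1:10, function(s) {
    cfg$seed <- s
    sim <- simulate_counts(cfg, signature_sets = NULL,
                           immune_genes = character(0))
    up <- sim$truth$gene[sim$truth$de_direction == "up"]
    cm <- counts <- sim$experiment$counts
    meta <- sim$experiment$sample_meta
    act <- rowMeans(as.matrix(cm[cm$gene %in% up,
                                 meta$sample[meta$stage == "active"]]))
    dor <- rowMeans(as.matrix(cm[cm$gene %in% up,
                                 meta$sample[meta$stage == "dormant"]]))
    mean(dor / act)
  }, numeric(1))
  expect_lt(abs(mean(ratios) / 4 - 1), 0.05)
})

test_that("DE planted in only k models is confined to those models", {
  sim <- simulate_counts(count_sim_config(n_genes = 200, de_models_planted = 2,
                                          nb_dispersion = 0.01, seed = 12),
                         signature_sets = NULL, immune_genes = character(0))
  fc <- model_fold_changes(sim$experiment)
  up <- sim$truth$gene[sim$truth$de_direction == "up"]
  planted_models <- unique(sim$experiment$sample_meta$model)[1:2]
  by_model <- fc |>
    dplyr::filter(.data$gene %in% up) |>
    dplyr::group_by(model) |>
    dplyr::summarise(m = exp(mean(log(fc))))
  expect_true(all(by_model$m[by_model$model %in% planted_models] > 3))
  expect_true(all(by_model$m[!by_model$model %in% planted_models] < 1.5))
})
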