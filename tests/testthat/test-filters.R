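test_that("expression rule: both thresholds, either stage, within model", {
  # gene passes in the active stage of models 1-3 only
  active <- cbind(c(1000, 8), c(1000, 8), c(1000, 8), c(2, 8), c(2, 8))
  dormant <- cbind(c(2, 8), c(2, 8), c(2, 8), c(2, 8), c(2, 8))
  rownames(active) <- rownames(dormant) <- c("hit", "lowcount")
  exp1 <- build_experiment(active, dormant)
  ef <- expression_filter(exp1, filter_config())
  expect_true("hit" %in% ef$genes)
  s <- ef$summary
  expect_equal(s$n_models_expressed[s$gene == "hit"], 3)
  # counts below 10 everywhere: never expressed even with high TPM
  expect_equal(s$n_models_expressed[s$gene == "lowcount"], 0)
})

test_that("a gene expressed in only 2 of 5 models is dropped", {
  active <- cbind(c(1000), c(1000), c(2), c(2), c(2))
  dormant <- cbind(c(2), c(2), c(2), c(2), c(2))
  rownames(active) <- rownames(dormant) <- "g"
  ef <- expression_filter(build_experiment(active, dormant), filter_config())
  expect_length(ef$genes, 0)
  expect_error(
    expression_filter(build_experiment(active, dormant),
                      filter_config(min_models_expressed = 6)),
    class = "dormantx_config_error")
})

test_that("consensus DE calls follow the 2-fold / 3-model rule", {
  fc <- function(v) tibble::tibble(gene = "g", model = paste0("M", 1:5),
                                   fc = v)
  call <- function(v) consensus_de(fc(v), filter_config())
  up <- call(c(2.1, 2.5, 3.0, 1.2, 0.8))
  expect_equal(up$direction, "up")
  expect_equal(up$support, 3L)
  down <- call(c(0.4, 0.45, 0.3, 0.9, 2.2))
  expect_equal(down$direction, "down")
  expect_equal(down$support, 3L)
  all5 <- call(c(2, 4, 8, 2.5, 3))  # threshold inclusive at exactly 2
  expect_equal(all5$direction, "up")
  expect_equal(all5$support, 5L)
  expect_equal(call(c(2.1, 2.5, 1.9, 1.2, 0.8))$direction, "none")
})

test_that("a gene qualifying both ways is called none with a warning", {
  fc <- tibble::tibble(gene = "g", model = paste0("M", 1:4),
                       fc = c(4, 4, 0.2, 0.2))
  expect_warning(out <- consensus_de(fc, filter_config(min_models_de = 2)),
                 "both directions")
  expect_equal(out$direction, "none")
})

test_that("persistence requires the floor in both stages, inclusively", {
  active <- cbind(c(2000, 5000, 1024), c(2000, 5000, 1024),
                  c(2000, 5000, 1024), c(2000, 5000, 1024),
                  c(2000, 5000, 1024))
  dormant <- cbind(c(1500, 900, 1024), c(1500, 900, 1024),
                   c(1500, 900, 1024), c(1500, 900, 1024),
                   c(1500, 900, 1024))
  rownames(active) <- rownames(dormant) <- c("both_high", "dormant_low",
                                             "exactly_floor")
  exp1 <- build_experiment(active, dormant)
  # rule applied to the given (already normalized) values
  pg <- persistent_genes(exp1, filter_config(), normalized = exp1$counts)
  expect_equal(setNames(pg$persistent, pg$gene),
               c(both_high = TRUE, dormant_low = FALSE,
                 exactly_floor = TRUE))
  # raw-count mode and per-model scope agree here (constant across models)
  expect_equal(persistent_genes(exp1, use_normalized = FALSE)$persistent,
               pg$persistent)
  expect_equal(persistent_genes(exp1, scope = "per_model",
                                normalized = exp1$counts)$persistent,
               pg$persistent)
})

test_that("raising thresholds never adds calls (monotonicity)", {
  sim <- simulate_counts(count_sim_config(n_genes = 300, seed = 31))
  fc <- model_fold_changes(sim$experiment)
  base <- consensus_de(fc, filter_config())
  stricter_fc <- consensus_de(fc, filter_config(fc_threshold = 3))
  stricter_k <- consensus_de(fc, filter_config(min_models_de = 4))
  called <- function(x) x$gene[x$direction != "none"]
  expect_true(all(called(stricter_fc) %in% called(base)))
  expect_true(all(called(stricter_k) %in% called(base)))

  pg <- persistent_genes(sim$experiment, filter_config())
  pg_hi <- persistent_genes(sim$experiment,
                            filter_config(persistence_floor = 4096))
  expect_true(all(pg$gene[pg_hi$persistent] %in% pg$gene[pg$persistent]))
})

test_that("filters match the brute-force oracle on random instances", {
  cfg <- filter_config()
  for (s in 1:25) {
    set.seed(s)
    active <- matrix(rnbinom(20 * 5, mu = sample(c(3, 30, 2000), 20 * 5,
                                                 replace = TRUE),
                             size = 5), 20, 5)
    dormant <- matrix(rnbinom(20 * 5, mu = sample(c(3, 30, 2000), 20 * 5,
                                                  replace = TRUE),
                              size = 5), 20, 5)
    rownames(active) <- rownames(dormant) <- sprintf("g%02d", 1:20)
    lens <- sample(300:5000, 20)
    exp1 <- build_experiment(active, dormant, eff_length = lens)
    meta <- exp1$sample_meta

    # expression filter vs loop oracle (oracle computes TPM from scratch)
    cm <- as.matrix(exp1$counts[-1]); rownames(cm) <- exp1$counts$gene
    tpms <- apply(cm, 2, function(cl) {
      r <- cl / lens
      if (sum(r) == 0) r else r / sum(r) * 1e6
    })
    ef <- expression_filter(exp1, cfg)
    orc <- oracle_expression(cm, tpms, meta, cfg)
    expect_setequal(ef$genes, orc$retained)
    expect_equal(setNames(ef$summary$n_models_expressed, ef$summary$gene),
                 orc$n_expr[ef$summary$gene])

    # consensus DE vs loop oracle on the same fold changes
    fc <- model_fold_changes(exp1, pseudocount = 1)
    fc_by_gene <- split(fc$fc, fc$gene)
    de <- consensus_de(fc, cfg)
    expect_equal(setNames(de$direction, de$gene),
                 oracle_de(fc_by_gene, cfg)[de$gene])

    # persistence vs loop oracle on normalized counts
    norm <- normalize_counts(exp1, pseudocount = 0.5)
    nm <- as.matrix(norm[-1]); rownames(nm) <- norm$gene
    pg <- persistent_genes(exp1, cfg, normalized = norm)
    expect_equal(setNames(pg$persistent, pg$gene),
                 oracle_persistent(nm, meta, cfg)[pg$gene])
  }
})
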