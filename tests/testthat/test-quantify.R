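test_that("reads aggregate to unique-gene counts, ambiguous reads dropped", {
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4", "r5", "r6", "r6"),
    target_id = c("A", "A", "B", "A", "B", "A", "B"))
  got <- aggregate_counts(reads)
  expect_equal(got, tibble::tibble(gene = c("A", "B"), count = c(3L, 2L)))
  # fixed universe fills zeros; empty input is all-zero
  expect_equal(aggregate_counts(reads[0, ], genes = c("A", "C"))$count,
               c(0L, 0L))
})

test_that("aggregated counts match the simulator's read allocation", {
  sim <- simulate_reads(read_sim_config(n_reads = 3000, seed = 6))
  res <- partition_reads(sim$alignments)
  counts <- aggregate_counts(res$reads)
  # every retained read hits exactly one human gene here, so totals match
  expect_equal(sum(counts$count), res$report$n_retained)
  manual <- table(res$reads$target_id)
  expect_equal(setNames(counts$count, counts$gene),
               setNames(as.integer(manual), names(manual)))
})

test_that("TPM follows the length-normalized formula and sums to 1e6", {
  # equal rates: counts (10, 30) over lengths (100, 300) split evenly
  exp1 <- build_experiment(active = cbind(c(10, 30)),
                           dormant = cbind(c(10, 30)),
                           eff_length = c(100, 300))
  t1 <- tpm(exp1)
  expect_equal(t1$M1_active, c(5e5, 5e5))
  expect_equal(t1$M1_dormant, c(5e5, 5e5))

  sim <- simulate_counts(count_sim_config(n_genes = 80, seed = 13))
  tt <- tpm(sim$experiment)
  expect_equal(unname(colSums(as.matrix(tt[-1]))), rep(1e6, 10),
               tolerance = 1e-6)

  # invariant to rescaling all counts of a sample
  doubled <- sim$experiment
  doubled$counts[-1] <- doubled$counts[-1] * 2
  expect_equal(tpm(doubled), tt)
})

test_that("size factors implement median-of-ratios", {
  m <- tibble::tibble(gene = c("a", "b", "c"),
                      s1 = c(10, 20, 5), s2 = c(10, 20, 5))
  expect_equal(size_factors(m)$size_factor, c(1, 1))

  m2 <- tibble::tibble(gene = c("a", "b", "c"),
                       s1 = c(10, 20, 5), s2 = c(20, 40, 10))
  expect_equal(size_factors(m2)$size_factor, c(1 / sqrt(2), sqrt(2)))

  # rescaling every count by a common constant leaves the factors alone:
  # the ratio to the geometric mean cancels the constant
  m3 <- m2
  m3[-1] <- m3[-1] * 7
  expect_equal(size_factors(m3)$size_factor, size_factors(m2)$size_factor)

  # no all-positive gene: error points at the pseudocount fallback
  sparse <- tibble::tibble(gene = c("a", "b"), s1 = c(0, 5), s2 = c(5, 0))
  expect_error(size_factors(sparse), "pseudocount",
               class = "dormantx_normalization_error")
  expect_length(size_factors(sparse, pseudocount = 0.5)$size_factor, 2)
})

test_that("size factors agree with DESeq2's median-of-ratios", {
  sim <- simulate_counts(count_sim_config(n_genes = 300, seed = 17))
  mine <- size_factors(sim$experiment)$size_factor
  cm <- as.matrix(sim$experiment$counts[-1])
  ref <- DESeq2::estimateSizeFactorsForMatrix(cm)
  # same median-of-ratios up to the geometric-mean-1 convention
  expect_equal(mine, unname(ref / exp(mean(log(ref)))), tolerance = 1e-10)
})

test_that("normalization is idempotent to tolerance", {
  sim <- simulate_counts(count_sim_config(n_genes = 120, seed = 19))
  norm <- normalize_counts(sim$experiment)
  renorm <- size_factors(norm)
  expect_equal(renorm$size_factor, rep(1, 10), tolerance = 1e-10)
})

test_that("fold changes are pseudocounted normalized ratios", {
  # on given normalized counts: active 100, dormant 50 -> (50+1)/(100+1)
  exp1 <- build_experiment(active = cbind(c(100, 10, 0)),
                           dormant = cbind(c(50, 10, 0)))
  norm <- function(a, d) {
    tibble::tibble(gene = exp1$counts$gene, M1_active = a, M1_dormant = d)
  }
  fc <- model_fold_changes(exp1, normalized = norm(c(100, 10, 0),
                                                   c(50, 10, 0)))
  expect_equal(fc$fc, c(51 / 101, 1, 1))
  expect_true(all(fc$fc > 0))

  # monotone in dormant, antitone in active
  fc_up <- model_fold_changes(exp1, normalized = norm(c(100, 10, 0),
                                                      c(60, 10, 0)))
  expect_gt(fc_up$fc[1], fc$fc[1])
  fc_dn <- model_fold_changes(exp1, normalized = norm(c(120, 10, 0),
                                                      c(50, 10, 0)))
  expect_lt(fc_dn$fc[1], fc$fc[1])
})

test_that("experiment construction rejects broken pairings", {
  counts <- tibble::tibble(gene = "g", a = 1, b = 2)
  meta_bad <- tibble::tibble(sample = c("a", "b"), model = c("M1", "M2"),
                             stage = c("active", "dormant"))
  el <- tibble::tibble(gene = "g", eff_length = 500)
  expect_error(count_experiment(counts, meta_bad, el),
               class = "dormantx_pairing_error")
  meta_ok <- tibble::tibble(sample = c("a", "b"), model = "M1",
                            stage = c("active", "dormant"))
  expect_s3_class(count_experiment(counts, meta_ok, el), "count_experiment")
  expect_error(count_experiment(counts, meta_ok,
                                tibble::tibble(gene = "g", eff_length = -1)),
               class = "dormantx_input_error")
})
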