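test_that("genome-wide filter keeps strictly significant records", {
  ow <- overweight_instruments()
  kept <- select_genome_wide(ow, 5e-8)
  expect_equal(n_records(kept), 14L)  # all published p-values pass
  d <- ow$data
  d$pval[1L] <- 6e-8   # above threshold
  d$pval[2L] <- 2.10e-10
  ds <- summary_dataset(d, "x")
  kept2 <- select_genome_wide(ds, 5e-8)
  expect_false(d$snp_id[1L] %in% kept2$data$snp_id)
  expect_true(d$snp_id[2L] %in% kept2$data$snp_id)
  # all-null dataset empties out
  d$pval <- 0.5
  expect_equal(n_records(select_genome_wide(summary_dataset(d, "x"))), 0L)
})

test_that("genome-wide filter equals a brute-force row scan (property)", {
  for (seed in 1:3) {
    ds <- random_dataset(200L, seed)
    thr <- 10^runif(1, -9, -1)
    got <- select_genome_wide(ds, thr)$data$snp_id
    want <- ds$data$snp_id[sapply(seq_len(200L),
                                  function(i) ds$data$pval[i] < thr)]
    expect_identical(got, want)
  }
})

test_that("distance pruning keeps the strongest association per window", {
  ds <- summary_dataset(data.frame(
    snp_id = c("a", "b", "c"), chrom = "1",
    pos = c(1e6, 1.5e6, 5e6),
    effect_allele = "A", other_allele = "C", eaf = 0.3,
    beta = 0.1, se = 0.01,
    pval = c(1e-20, 1e-9, 1e-12), n = 1e5), "x")
  res <- prune_instruments(ds, prune_config(window_bp = 1e6))
  expect_identical(res$retained$data$snp_id, c("a", "c"))
  expect_identical(res$removals$removed_id, "b")
  expect_identical(res$removals$kept_id, "a")
  # single record unchanged
  one <- mrsummary:::subset_dataset(ds, 1L)
  expect_equal(prune_instruments(one)$retained$data$snp_id, "a")
})

test_that("LD pruning removes the weaker of a correlated pair", {
  ds <- summary_dataset(data.frame(
    snp_id = c("a", "b"), chrom = c("1", "2"), pos = c(1e6, 1e6),
    effect_allele = "A", other_allele = "C", eaf = 0.3, beta = 0.1,
    se = 0.01, pval = c(1e-30, 1e-10), n = 1e5), "x")
  ld <- matrix(c(1, 0.002, 0.002, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  res <- prune_instruments(ds, prune_config(ld_matrix = ld))
  expect_identical(res$retained$data$snp_id, "a")
  expect_identical(res$removals$reason, "ld")
  # r2 exactly at the cutoff is kept (strict >)
  ld[1, 2] <- ld[2, 1] <- 0.001
  res2 <- prune_instruments(ds, prune_config(ld_matrix = ld))
  expect_equal(n_records(res2$retained), 2L)
  # missing id in the matrix is a configuration error
  expect_error(prune_instruments(ds, prune_config(ld_matrix = ld[1, 1, drop = FALSE])),
               "lacks snp_id")
})

test_that("pruning is independent of input record order (property)", {
  ds <- random_dataset(60L, 7L)
  res1 <- prune_instruments(ds, prune_config(window_bp = 5e6))
  for (seed in 1:3) {
    set.seed(seed)
    shuf <- mrsummary:::subset_dataset(ds, sample.int(60L))
    res2 <- prune_instruments(shuf, prune_config(window_bp = 5e6))
    expect_setequal(res2$retained$data$snp_id, res1$retained$data$snp_id)
  }
})

test_that("R-squared matches the published per-SNP values", {
  # unrounded value then the 4-decimal display convention
  expect_equal(compute_r2(0.140, 0.45), 0.009702)
  expect_equal(display_r2(compute_r2(0.140, 0.45)), 0.0097)
  expect_equal(display_r2(compute_r2(-0.079, 0.06)), 0.0007)
  expect_equal(display_r2(compute_r2(0.057, 0.50)), 0.0016)
  expect_equal(display_r2(compute_r2(0.099, 0.29)), 0.0040)
  expect_equal(compute_r2(0, 0.3), 0)
  # frequency symmetry
  expect_equal(compute_r2(0.08, 0.2), compute_r2(0.08, 0.8))
  expect_error(compute_r2(0.1, NA), "eaf missing")
})

test_that("F-statistic formula and domain", {
  expect_equal(compute_f(compute_r2(-0.079, 0.06), 158945, 14), 7.99737,
               tolerance = 1e-6)
  expect_equal(compute_f(0, 1000, 3), 0)
  expect_equal(compute_f(0.5, 103, 1), 101)
  expect_error(compute_f(0.1, 10, 9), "n > k")
  # strictly increasing in r2 (property)
  r2 <- sort(runif(20, 0, 0.9))
  expect_true(all(diff(compute_f(r2, 1e4, 10)) > 0))
})

test_that("weak-instrument filter reproduces the published exclusion", {
  ow <- overweight_instruments()
  res <- filter_weak(ow, n = 158945, f_min = 10)
  expect_identical(res$excluded$data$snp_id, "rs12444979")
  expect_equal(n_records(res$retained), 13L)
  expect_equal(attr(res$diagnostics, "k_used"), 14L)
  d <- res$diagnostics
  expect_equal(d$f_stat[d$snp_id == "rs12444979"], 7.99737, tolerance = 1e-5)
  expect_identical(d$weak, d$f_stat < 10)
  # empty dataset passes through
  empty <- mrsummary:::subset_dataset(ow, FALSE)
  expect_equal(n_records(filter_weak(empty, n = 100)$retained), 0L)
})

test_that("F exactly at the cutoff is retained (strict inequality)", {
  ds <- summary_dataset(data.frame(
    snp_id = "rs1", chrom = "1", pos = 100, effect_allele = "A",
    other_allele = "C", eaf = 0.3, beta = 0.1, se = 0.01, pval = 1e-9,
    n = 1000), "x")
  f <- compute_f(compute_r2(0.1, 0.3), 1000, 1)
  expect_equal(n_records(filter_weak(ds, n = 1000, f_min = f)$retained), 1L)
  expect_equal(n_records(filter_weak(ds, n = 1000,
                                     f_min = f * (1 + 1e-12))$retained), 0L)
})

test_that("weak filter equals a brute-force per-record scan (property)", {
  for (seed in 4:6) {
    ds <- random_dataset(100L, seed)
    res <- filter_weak(ds, n = 2e5, f_min = 10)
    f <- sapply(seq_len(100L), function(i) {
      r2 <- 2 * ds$data$beta[i]^2 * ds$data$eaf[i] * (1 - ds$data$eaf[i])
      r2 / (1 - r2) * (2e5 - 100 - 1) / 100
    })
    expect_identical(res$retained$data$snp_id, ds$data$snp_id[f >= 10])
  }
})

test_that("full selection chain reproduces the 13-instrument set", {
  sel <- select_instruments(overweight_instruments())
  expect_equal(n_records(sel$instruments), 13L)
  expect_identical(sel$excluded$snp_id, "rs12444979")
  expect_identical(sel$excluded$stage, "weak_filter")
  expect_equal(sel$audit$n_out, c(14L, 14L, 14L, 13L))
  # audit consistency: candidates = retained + excluded at every stage
  expect_true(all(sel$audit$n_in - sel$audit$n_out ==
                    c(0L, table(factor(sel$excluded$stage,
                                       c("significance", "prune",
                                         "weak_filter"))))))
})
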