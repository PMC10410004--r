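test_that("multivariable IVW: nesting, exact recovery, WLS oracle", {
  # M = 1 reduces exactly to univariable IVW (beta) and IVW-MRE (se)
  set.seed(17)
  gamma <- rnorm(9, 0.3, 0.1)
  big <- 0.25 * gamma + rnorm(9, 0, 0.02)
  se_b <- runif(9, 0.01, 0.05)
  h <- harmonized_set(gamma = gamma, se_gamma = rep(0.01, 9),
                      big_gamma = big, se_big_gamma = se_b)
  uni <- mvmr_ivw(mvmr_input(matrix(gamma, ncol = 1), big, se_b))[[1L]]
  expect_equal(uni$beta, mr_ivw(h, "fixed")$beta, tolerance = 1e-10)
  expect_equal(uni$se, mr_ivw(h, "multiplicative_random")$se,
               tolerance = 1e-10)
  # noise-free two-exposure recovery
  set.seed(18)
  g2 <- matrix(rnorm(16, 0.1, 0.05), 8, 2,
               dimnames = list(NULL, c("bmi", "smoking")))
  big2 <- 0.3 * g2[, 1] - 0.2 * g2[, 2]
  est2 <- mvmr_ivw(mvmr_input(g2, big2, rep(0.01, 8)))
  expect_equal(est2$bmi$beta, 0.3)
  expect_equal(est2$smoking$beta, -0.2)
  # random instance vs normal-equations oracle
  big3 <- big2 + rnorm(8, 0, 0.05)
  w3 <- runif(8, 0.01, 0.05)^-2
  est3 <- mvmr_ivw(mvmr_input(g2, big3, w3^-0.5))
  oracle <- oracle_wls(g2, big3, w3)
  expect_equal(c(est3$bmi$beta, est3$smoking$beta), unname(oracle),
               tolerance = 1e-8)
  # rank deficiency and J <= M are errors
  gg <- cbind(a = g2[, 1], b = 2 * g2[, 1])
  expect_error(mvmr_ivw(mvmr_input(gg, big2, rep(0.01, 8))), "collinear")
  expect_error(mvmr_input(matrix(1:4, 2, 2), c(0.1, 0.2), c(0.1, 0.1)),
               "more SNPs than exposures")
})

test_that("bonferroni threshold", {
  expect_equal(bonferroni_threshold(1, 2), 0.025)
  expect_equal(bonferroni_threshold(1, 1), 0.05)
  expect_equal(bonferroni_threshold(2, 5), 0.005)
  expect_equal(bonferroni_threshold(4, 3), 0.05 / 12)
  expect_error(bonferroni_threshold(0, 3), "positive")
})

test_that("mediation arithmetic and the delta-method SE", {
  res <- two_step_mediation(0.5, 0.01, 0.5, 0.01, 0.2, 0.01, alpha = 0.05)
  expect_equal(res$mediated_effect, 0.10)
  expect_equal(res$proportion, 0.20)
  expect_identical(res$classification, "partial_mediation")
  # delta-method oracle
  b1 <- 0.37; s1 <- 0.04; b2 <- -0.21; s2 <- 0.09
  r <- two_step_mediation(0.3, 0.01, b1, s1, b2, s2, alpha = 0.05)
  expect_equal(r$mediated_se, sqrt(b1^2 * s2^2 + b2^2 * s1^2))
  # condition (ii): insignificant total effect, significant paths
  r2 <- two_step_mediation(0.05, 0.5, 0.5, 0.01, 0.2, 0.01, alpha = 0.05)
  expect_identical(r2$classification, "complete_mediation")
  expect_true(is.na(r2$proportion))
  # condition (iii): significant total effect, a null path
  r3 <- two_step_mediation(0.5, 0.01, 0.5, 0.01, 0.01, 0.5, alpha = 0.05)
  expect_identical(r3$classification, "no_mediation")
})

test_that("classification is a total function over all 8 patterns", {
  sig <- list(yes = c(1, 0.01), no = c(0.01, 1))  # (beta, se)
  want <- function(s0, s1, s2) {
    if (s0 && s1 && s2) "partial_mediation"
    else if (!s0 && s1 && s2) "complete_mediation"
    else if (s0) "no_mediation"
    else "no_causal_effect"
  }
  for (s0 in c(TRUE, FALSE)) for (s1 in c(TRUE, FALSE)) {
    for (s2 in c(TRUE, FALSE)) {
      a <- sig[[if (s0) "yes" else "no"]]
      b <- sig[[if (s1) "yes" else "no"]]
      c_ <- sig[[if (s2) "yes" else "no"]]
      res <- two_step_mediation(a[1], a[2], b[1], b[2], c_[1], c_[2],
                                alpha = 0.05)
      expect_identical(res$classification, want(s0, s1, s2),
                       label = sprintf("pattern (%d,%d,%d)", s0, s1, s2))
      expect_identical(is.na(res$proportion), !s0)
    }
  }
})

test_that("run_mediation recovers the generating decomposition", {
  ms <- simulate_mediation_study(
    simulation_config(seed = 42, n_snps = 40, n_exposure = 5e5,
                      n_outcome = 5e5),
    b1 = 0.5, b2 = 0.3, c_direct = 0.45, n_mediator = 5e5)
  expect_equal(ms$truth$proportion, 0.25)
  res <- run_mediation(ms$exposure, ms$mediator, ms$outcome, alpha = 0.05)
  expect_identical(res$classification, "partial_mediation")
  expect_lt(abs(res$beta1 - 0.5), 0.05)
  expect_lt(abs(res$beta2 - 0.3), 0.05)
  expect_lt(abs(res$proportion - 0.25), 0.1)
  legs <- attr(res, "legs")
  # mediator-leg instruments exclude the exposure's instruments
  expect_length(intersect(legs$mediator_outcome$instrument_ids,
                          legs$exposure_mediator$instrument_ids), 0L)
  # deterministic given the config seed
  res2 <- run_mediation(ms$exposure, ms$mediator, ms$outcome, alpha = 0.05)
  expect_equal(res, res2)
})

test_that("fully mediated model: proportion converges to 1 (property)", {
  # direct effect 0: the paper-style classifier still sees a significant
  # total effect (b1*b2 != 0), so the proportion converges to 1
  props <- vapply(1:50, function(s) {
    ms <- simulate_mediation_study(
      simulation_config(seed = s, n_snps = 30, n_exposure = 5e5,
                        n_outcome = 5e5),
      b1 = 0.5, b2 = 0.3, c_direct = 0, n_mediator = 5e5)
    run_mediation(ms$exposure, ms$mediator, ms$outcome,
                  alpha = 0.05)$proportion
  }, numeric(1L))
  expect_lt(abs(mean(props) - 1), 0.07)
})

test_that("independent mediator path yields no mediation (property)", {
  cls <- vapply(1:50, function(s) {
    ms <- simulate_mediation_study(
      simulation_config(seed = s, n_snps = 30, n_exposure = 5e5,
                        n_outcome = 5e5),
      b1 = 0, b2 = 0.3, c_direct = 0.45, n_mediator = 5e5)
    run_mediation(ms$exposure, ms$mediator, ms$outcome,
                  alpha = 0.05)$classification
  }, character(1L))
  expect_gte(mean(cls == "no_mediation"), 0.9)
})
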