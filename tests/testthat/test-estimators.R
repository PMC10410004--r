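test_that("Wald ratios: arithmetic, sign, and elementwise oracle", {
  h <- harmonized_set(gamma = c(0.5, -0.5), se_gamma = c(0.01, 0.01),
                      big_gamma = c(0.25, 0.25), se_big_gamma = c(0.1, 0.1))
  r <- wald_ratios(h)
  expect_equal(r$theta, c(0.5, -0.5))
  expect_equal(r$sigma, c(0.2, 0.2))
  expect_equal(r$weight, r$sigma^-2)
  # batch equals the per-record loop oracle
  set.seed(31)
  h2 <- harmonized_set(gamma = rnorm(100, 0.2, 0.1) + 0.5,
                       se_gamma = runif(100, 0.01, 0.05),
                       big_gamma = rnorm(100), se_big_gamma = runif(100, 0.01, 0.2))
  r2 <- wald_ratios(h2)
  for (i in c(1L, 37L, 100L)) {
    expect_equal(r2$theta[i], h2$records$big_gamma[i] / h2$records$gamma[i])
    expect_equal(r2$sigma[i],
                 h2$records$se_big_gamma[i] / abs(h2$records$gamma[i]))
  }
  # zero gamma is an error naming the SNP
  h3 <- harmonized_set(gamma = c(0.5, 0), se_gamma = c(0.01, 0.01),
                       big_gamma = c(0.1, 0.1), se_big_gamma = c(0.1, 0.1))
  expect_error(wald_ratios(h3), "snp2")
})

test_that("IVW matches two independent oracles on the 3-instrument toy", {
  h <- toy_from_ratios(c(0.1, 0.3, 0.2), c(0.1, 0.2, 0.1))
  est <- mr_ivw(h, "fixed")
  # oracle 1: explicit weighted mean
  w <- c(0.1, 0.2, 0.1)^-2
  expect_equal(est$beta, sum(w * c(0.1, 0.3, 0.2)) / sum(w))
  expect_equal(est$beta, 37.5 / 225)      # hand-computed
  expect_equal(est$se, sum(w)^-0.5)
  # oracle 2: zero-intercept weighted regression on the same records
  r <- h$records
  slope <- oracle_wls(matrix(r$gamma), r$big_gamma, r$se_big_gamma^-2)
  expect_equal(est$beta, unname(slope), tolerance = 1e-10)
})

test_that("IVW degenerate cases", {
  h1 <- toy_from_ratios(0.42, 0.1)
  e1 <- mr_ivw(h1, "fixed")
  expect_equal(e1$beta, 0.42)
  expect_equal(e1$se, 0.1)
  expect_error(mr_ivw(h1, "multiplicative_random"), "at least 2")
  # homogeneous ratios: Q = 0, FE and MRE coincide
  h2 <- toy_from_ratios(rep(0.25, 5), rep(0.1, 5))
  fe <- mr_ivw(h2, "fixed"); mre <- mr_ivw(h2, "multiplicative_random")
  expect_equal(fe$beta, 0.25)
  expect_equal(cochran_q(h2)$q, 0)
  expect_equal(mre$se, fe$se)
})

test_that("IVW is invariant to order and to paired sign flips (property)", {
  set.seed(19)
  for (rep in 1:3) {
    gamma <- rnorm(12, 0.3, 0.05)
    h <- harmonized_set(gamma = gamma, se_gamma = runif(12, 0.005, 0.02),
                        big_gamma = 0.2 * gamma + rnorm(12, 0, 0.01),
                        se_big_gamma = runif(12, 0.005, 0.05))
    ref <- mr_ivw(h, "fixed")
    perm <- sample.int(12)
    hp <- h; hp$records <- h$records[perm, ]
    expect_equal(mr_ivw(hp, "fixed")$beta, ref$beta)
    flip <- runif(12) < 0.5
    hf <- h
    hf$records$gamma[flip] <- -hf$records$gamma[flip]
    hf$records$big_gamma[flip] <- -hf$records$big_gamma[flip]
    expect_equal(mr_ivw(hf, "fixed")$beta, ref$beta)
    # ratio-mean and regression forms agree to 1e-10
    reg <- oracle_wls(matrix(h$records$gamma), h$records$big_gamma,
                      h$records$se_big_gamma^-2)
    expect_equal(ref$beta, unname(reg), tolerance = 1e-10)
  }
})

test_that("Egger recovers exact lines and matches the WLS oracle", {
  gamma <- seq(0.1, 0.5, length.out = 5)
  h <- harmonized_set(gamma = gamma, se_gamma = rep(0.01, 5),
                      big_gamma = 0.1 + 0.3 * gamma,
                      se_big_gamma = rep(0.05, 5))
  e <- mr_egger(h)
  expect_equal(e$intercept, 0.1)
  expect_equal(e$slope$beta, 0.3)
  # zero intercept on exact data: Egger slope equals IVW
  h0 <- harmonized_set(gamma = gamma, se_gamma = rep(0.01, 5),
                       big_gamma = 0.3 * gamma, se_big_gamma = rep(0.05, 5))
  expect_equal(mr_egger(h0)$slope$beta, mr_ivw(h0, "fixed")$beta)
  # random 10-instrument set vs normal-equations oracle
  set.seed(4)
  hr <- harmonized_set(gamma = rnorm(10, 0.3, 0.1),
                       se_gamma = runif(10, 0.005, 0.02),
                       big_gamma = rnorm(10, 0.1, 0.05),
                       se_big_gamma = runif(10, 0.01, 0.08))
  er <- mr_egger(hr)
  sgn <- sign(hr$records$gamma)
  coefs <- oracle_wls(cbind(1, abs(hr$records$gamma)),
                      hr$records$big_gamma * sgn,
                      hr$records$se_big_gamma^-2)
  expect_equal(er$intercept, coefs[1L], tolerance = 1e-10)
  expect_equal(er$slope$beta, coefs[2L], tolerance = 1e-10)
  expect_error(mr_egger(toy_from_ratios(c(0.1, 0.2), c(0.1, 0.1))),
               "at least 3")
})

test_that("median estimators: interpolation and bootstrap behavior", {
  h <- toy_from_ratios(c(0.1, 0.2, 0.9), rep(0.1, 3))
  est <- mr_median(h, "simple", n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.2)   # s-grid {1/6, 3/6, 5/6} interpolated at 0.5
  expect_identical(est$method, "simple_median")
  # weighted median equals the independent cumulative-weight oracle
  set.seed(12)
  for (rep in 1:5) {
    theta <- rnorm(5); sigma <- runif(5, 0.05, 0.3)
    hw <- toy_from_ratios(theta, sigma)
    est_w <- mr_median(hw, "weighted", n_boot = 100, seed = 2)
    expect_equal(est_w$beta, oracle_weighted_median(theta, sigma^-2))
  }
  # same seed -> identical SE; different seeds agree within 20% at n_boot 2000
  h5 <- toy_from_ratios(c(0.1, 0.15, 0.2, 0.3, 0.5), rep(0.1, 5))
  a <- mr_median(h5, "weighted", n_boot = 2000, seed = 7)
  b <- mr_median(h5, "weighted", n_boot = 2000, seed = 7)
  c_ <- mr_median(h5, "weighted", n_boot = 2000, seed = 8)
  expect_identical(a$se, b$se)
  expect_lt(abs(a$se - c_$se) / a$se, 0.2)
  expect_warning(mr_median(h5, "weighted", n_boot = 50, seed = 1), "n_boot")
})

test_that("mode estimators: dominant cluster, grid oracle, bandwidth range", {
  h <- toy_from_ratios(c(0.2, 0.2, 0.2, 5.0), rep(0.2, 4))
  est <- mr_mode(h, "simple", n_boot = 100, seed = 3)
  expect_lt(abs(est$beta - 0.2), 0.1)  # outlier-resistant
  # argmax equals an independent dense-grid scan (within one grid step)
  set.seed(9)
  theta <- rnorm(8, 0.3, 0.2); sigma <- runif(8, 0.05, 0.2)
  hr <- toy_from_ratios(theta, sigma)
  est_r <- mr_mode(hr, "weighted", n_boot = 100, seed = 5)
  s <- min(sd(theta), mad(theta))
  bw <- 0.9 * s * 8^(-1 / 5)
  oracle <- oracle_mode(theta, sigma^-2, bw)
  step <- diff(range(theta)) / 1023
  expect_lt(abs(est_r$beta - oracle), step + 1e-12)
  # doubling the bandwidth keeps the estimate inside [min, max] theta
  for (bf in c(0.5, 1, 2, 4)) {
    eb <- mr_mode(hr, "weighted", bandwidth_factor = bf, n_boot = 100,
                  seed = 5)
    expect_gte(eb$beta, min(theta))
    expect_lte(eb$beta, max(theta))
  }
})

test_that("estimator battery is approximately unbiased without pleiotropy", {
  # stated world: theta = 0.3, 50 instruments, large samples; mean estimate
  # across seeds within 0.02 of the truth for every estimator
  seeds <- 1:100
  res <- sapply(seeds, function(s) {
    st <- simulate_study(simulation_config(seed = s, theta = 0.3))
    h <- align_alleles(st$exposure, st$outcome)
    c(ivw = mr_ivw(h, "fixed")$beta,
      egger = mr_egger(h)$slope$beta,
      smed = mr_median(h, "simple", n_boot = 100, seed = s)$beta,
      wmed = mr_median(h, "weighted", n_boot = 100, seed = s)$beta,
      smode = mr_mode(h, "simple", n_boot = 100, seed = s)$beta,
      wmode = mr_mode(h, "weighted", n_boot = 100, seed = s)$beta)
  })
  bias <- abs(rowMeans(res) - 0.3)
  expect_true(all(bias < 0.02), info = paste(names(bias), round(bias, 4),
                                             collapse = "; "))
})

test_that("directional pleiotropy biases IVW more than Egger (property)", {
  seeds <- 1:60
  res <- sapply(seeds, function(s) {
    st <- simulate_study(simulation_config(seed = s, theta = 0.3,
                                           pleiotropy = "directional"))
    h <- align_alleles(st$exposure, st$outcome)
    c(ivw = mr_ivw(h, "fixed")$beta, egger = mr_egger(h)$slope$beta)
  })
  expect_gt(abs(mean(res["ivw", ]) - 0.3), abs(mean(res["egger", ]) - 0.3))
})
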