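#' Per-SNP Wald ratio estimates
#'
#' For each harmonized instrument, the ratio estimate
#' `theta_j = big_gamma_j / gamma_j` with first-order (delta-method) standard
#' error `sigma_j = se_big_gamma_j / |gamma_j|` — the standard default which
#' ignores the exposure-side uncertainty; `second_order = TRUE` adds the
#' exposure-SE term `sqrt(se_G^2/gamma^2 + G^2 se_g^2/gamma^4)`.
#'
#' @param h a `harmonized_set`.
#' @param second_order use the second-order SE (default `FALSE`).
#' @return data.frame with `snp_id`, `theta`, `sigma`, `weight`
#'   (`weight = sigma^-2` exactly).
#' @export
wald_ratios <- function(h, second_order = FALSE) {
  check_harmonized(h, 1L, "wald_ratios")
  r <- h$records
  zero <- r$snp_id[r$gamma == 0]
  if (length(zero)) {
    stop("wald_ratios: zero exposure effect for ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  theta <- r$big_gamma / r$gamma
  sigma <- if (second_order) {
    sqrt(r$se_big_gamma^2 / r$gamma^2 +
           r$big_gamma^2 * r$se_gamma^2 / r$gamma^4)
  } else {
    r$se_big_gamma / abs(r$gamma)
  }
  data.frame(snp_id = r$snp_id, theta = theta, sigma = sigma,
             weight = sigma^-2, stringsAsFactors = FALSE)
}

# inverse-variance weighted mean of ratio estimates; core of IVW and Q
ivw_core <- function(theta, weight) {
  est <- sum(weight * theta) / sum(weight)
  list(est = est, se_fe = sum(weight)^-0.5,
       q = sum(weight * (theta - est)^2))
}

#' Inverse-variance weighted estimator
#'
#' Precision-weighted average of the Wald ratios,
#' `theta = sum(w_j theta_j) / sum(w_j)` with `w_j = sigma_j^-2` —
#' algebraically identical to the zero-intercept weighted regression of the
#' outcome effects on the exposure effects with weights `se_big_gamma^-2`.
#' The fixed-effects SE is `(sum w_j)^-1/2`; the multiplicative
#' random-effects variant inflates it by `sqrt(max(1, Q/(J-1)))` where Q is
#' Cochran's Q (the floor at 1 prevents under-dispersion shrinking SEs).
#' CIs are normal (`+/- 1.96 SE`), p-values from the standard normal.
#'
#' @param h a `harmonized_set`.
#' @param variant `"fixed"` (>= 1 instrument) or `"multiplicative_random"`
#'   (>= 2 instruments, needs Q).
#' @return an [mr_estimate] with method `ivw_fe` or `ivw_mre`.
#' @export
mr_ivw <- function(h, variant = c("fixed", "multiplicative_random")) {
  variant <- match.arg(variant)
  check_harmonized(h, if (variant == "fixed") 1L else 2L, "mr_ivw")
  r <- wald_ratios(h)
  core <- ivw_core(r$theta, r$weight)
  j <- nrow(r)
  if (variant == "fixed") {
    normal_estimate("ivw_fe", core$est, core$se_fe, j)
  } else {
    se <- core$se_fe * sqrt(max(1, core$q / (j - 1)))
    normal_estimate("ivw_mre", core$est, se, j)
  }
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' *with* a free intercept, weights `se_big_gamma^-2`. Records are first
#' re-signed so every exposure effect is non-negative (the estimator's
#' identifiability convention). Coefficient variances are multiplied by the
#' residual overdispersion factor `max(1, RSS_w/(J-2))`; slope and intercept
#' p-values and the slope CI use the t distribution with `J - 2` df. A
#' non-zero intercept indicates directional pleiotropy (the Egger intercept
#' test).
#'
#' @param h a `harmonized_set` with >= 3 instruments.
#' @return list of class `egger_result`: `slope` (an [mr_estimate], method
#'   `egger`), `intercept`, `intercept_se`, `intercept_p`, `df`.
#' @export
mr_egger <- function(h) {
  check_harmonized(h, 3L, "mr_egger")
  r <- h$records
  sgn <- ifelse(r$gamma < 0, -1, 1)
  x <- r$gamma * sgn
  y <- r$big_gamma * sgn
  w <- r$se_big_gamma^-2
  j <- length(x)
  fit <- stats::lm.wfit(cbind(intercept = 1, slope = x), y, w)
  rss <- sum(w * fit$residuals^2)
  phi <- max(1, rss / (j - 2))
  xtwx_inv <- chol2inv(chol(crossprod(cbind(1, x) * sqrt(w))))
  ses <- sqrt(phi * diag(xtwx_inv))
  slope <- unname(fit$coefficients["slope"])
  intercept <- unname(fit$coefficients["intercept"])
  tcrit <- stats::qt(0.975, j - 2)
  pt2 <- function(est, se) {
    max(2 * stats::pt(-abs(est / se), j - 2), .Machine$double.xmin)
  }
  slope_est <- mr_estimate("egger", slope, ses[2L],
                           slope - tcrit * ses[2L], slope + tcrit * ses[2L],
                           pt2(slope, ses[2L]), j)
  structure(list(slope = slope_est, intercept = intercept,
                 intercept_se = ses[1L],
                 intercept_p = pt2(intercept, ses[1L]), df = j - 2L),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g [pleiotropy test, t df = %d]\n",
              x$intercept, x$intercept_se, x$intercept_p, x$df))
  invisible(x)
}

# interpolated weighted median of theta at cumulative weight 0.5
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]
  wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (0.5 <= s[1L]) return(th[1L])
  if (0.5 >= s[length(s)]) return(th[length(th)])
  stats::approx(s, th, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(theta, sigma, n_boot, seed, point_fun) {
  set.seed(seed)
  j <- length(theta)
  reps <- vapply(seq_len(n_boot), function(b) {
    point_fun(stats::rnorm(j, theta, sigma))
  }, numeric(1L))
  stats::sd(reps)
}

check_boot <- function(n_boot) {
  if (n_boot < 100) {
    warning("n_boot < 100 gives unstable bootstrap SEs", call. = FALSE)
  }
}

#' Median-based estimators
#'
#' Orders the Wald ratios and linearly interpolates the (weighted) cumulative
#' distribution `s_j = sum_{i<=j} w_i - w_j/2` at 0.5. `simple` uses equal
#' weights `1/J`; `weighted` uses normalized inverse-variance weights. The SE
#' comes from a seeded parametric bootstrap (each `theta_j` resampled from
#' `Normal(theta_j, sigma_j)`, the median recomputed `n_boot` times); CI and
#' p-value are normal-based. Consistent when instruments carrying at least
#' half the weight are valid.
#'
#' @param h a `harmonized_set` with >= 3 instruments.
#' @param weighting `"simple"` or `"weighted"`.
#' @param n_boot bootstrap replicates (default 1000; < 100 warns).
#' @param seed integer seed for the bootstrap (required).
#' @return an [mr_estimate] with method `simple_median` or `weighted_median`.
#' @export
mr_median <- function(h, weighting = c("weighted", "simple"), n_boot = 1000,
                      seed) {
  weighting <- match.arg(weighting)
  check_harmonized(h, 3L, "mr_median")
  check_boot(n_boot)
  r <- wald_ratios(h)
  w <- if (weighting == "simple") rep(1 / nrow(r), nrow(r)) else r$weight
  est <- weighted_median_point(r$theta, w)
  se <- boot_se(r$theta, r$sigma, n_boot, seed,
                function(th) weighted_median_point(th, w))
  method <- if (weighting == "simple") "simple_median" else "weighted_median"
  normal_estimate(method, est, se, nrow(r))
}

# argmax of the weighted normal-kernel density of theta on a fine grid
mode_point <- function(theta, w, bandwidth_factor, n_grid = 1024L) {
  s <- min(stats::sd(theta), stats::mad(theta))
  if (!is.finite(s) || s <= 0) s <- max(stats::sd(theta), 1e-8)
  bw <- bandwidth_factor * 0.9 * s * length(theta)^(-1 / 5)
  grid <- seq(min(theta), max(theta), length.out = n_grid)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, theta, bw)),
                 numeric(1L))
  grid[which.max(dens)]
}

#' Mode-based estimators
#'
#' Estimate = the argmax of a normal-kernel-smoothed density of the Wald
#' ratios on a fine grid spanning their range; the bandwidth is
#' `bandwidth_factor` times the modified Silverman rule
#' `0.9 min(sd, mad) J^(-1/5)`. `weighted` weights each kernel by the ratio's
#' inverse variance. SE by the same seeded parametric bootstrap as
#' [mr_median]. Consistent when the largest group of instruments sharing a
#' ratio value is valid (outlier-resistant).
#'
#' @inheritParams mr_median
#' @param bandwidth_factor multiplier on the Silverman bandwidth (> 0,
#'   default 1).
#' @return an [mr_estimate] with method `simple_mode` or `weighted_mode`.
#' @export
mr_mode <- function(h, weighting = c("weighted", "simple"),
                    bandwidth_factor = 1, n_boot = 1000, seed) {
  weighting <- match.arg(weighting)
  check_harmonized(h, 3L, "mr_mode")
  stopifnot(bandwidth_factor > 0)
  check_boot(n_boot)
  r <- wald_ratios(h)
  w <- if (weighting == "simple") rep(1 / nrow(r), nrow(r)) else r$weight
  est <- mode_point(r$theta, w, bandwidth_factor)
  se <- boot_se(r$theta, r$sigma, n_boot, seed,
                function(th) mode_point(th, w, bandwidth_factor))
  method <- if (weighting == "simple") "simple_mode" else "weighted_mode"
  normal_estimate(method, est, se, nrow(r))
}

#' Tidy table of estimates
#'
#' Binds any number of [mr_estimate]s (or `egger_result`s, whose slope is
#' taken) into the tidy results layout used across the package.
#'
#' @param estimates list of [mr_estimate] / `egger_result` objects.
#' @param exposure,outcome trait labels stamped on every row.
#' @return data.frame with columns `exposure`, `outcome`, `method`, `nsnp`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pval`.
#' @export
estimates_table <- function(estimates, exposure = NA_character_,
                            outcome = NA_character_) {
  rows <- lapply(estimates, function(e) {
    if (inherits(e, "egger_result")) e <- e$slope
    as.data.frame(e)
  })
  tab <- do.call(rbind, rows)
  cbind(data.frame(exposure = exposure, outcome = outcome,
                   stringsAsFactors = FALSE), tab)
}
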