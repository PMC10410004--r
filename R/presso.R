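# leave-one-out slopes of the zero-intercept weighted regression of
# big_gamma on gamma, and the per-SNP weighted residual contributions.
# gamma/big_gamma may be matrices (replicates in rows) for vectorized use.
presso_residuals <- function(gamma, big_gamma, w) {
  if (is.null(dim(gamma))) {
    gamma <- matrix(gamma, nrow = 1L)
    big_gamma <- matrix(big_gamma, nrow = 1L)
  }
  wg <- sweep(gamma * big_gamma, 2L, w, `*`)     # w_j * g_j * G_j
  wgg <- sweep(gamma^2, 2L, w, `*`)              # w_j * g_j^2
  a <- rowSums(wg); b <- rowSums(wgg)
  theta_loo <- (a - wg) / (b - wgg)              # slope without SNP j
  res <- sweep((big_gamma - gamma * theta_loo)^2, 2L, w, `*`)
  list(contrib = res, rss = rowSums(res))
}

#' MR-PRESSO: global, outlier and distortion tests
#'
#' The pleiotropy residual sum and outlier procedure. (1) *Global test*: the
#' observed residual sum of squares `RSS_obs` accumulates, over instruments,
#' each SNP's weighted squared residual about the leave-that-SNP-out IVW
#' regression; its null distribution is built by parametric resampling
#' (`gamma* ~ N(gamma, se_gamma)`, `big_gamma* ~ N(gamma * theta_loo,
#' se_big_gamma)`), and `global_p = (1 + #\{RSS* >= RSS_obs\}) / (1 + n_sim)`
#' (add-one form; never zero). (2) *Outlier test*: each SNP's observed
#' residual contribution is compared with its own simulated distribution;
#' the empirical p-values are Bonferroni-adjusted over the J instruments and
#' SNPs below `outlier_alpha` are declared outliers. (3) *Distortion test*:
#' when outliers exist, the IVW estimate is recomputed without them and the
#' distortion coefficient `100 (theta_corrected - theta_raw) /
#' |theta_corrected|` (percent) is compared with distortions from removing
#' random outlier-sized subsets. All randomness derives from the single
#' `seed`; identical inputs and seed give an identical result.
#'
#' @param h a `harmonized_set` with >= 4 instruments (the leave-one-out
#'   regression needs at least 3 remaining).
#' @param n_sim simulation replicates (>= 100; default 1000).
#' @param outlier_alpha significance level for the Bonferroni-adjusted
#'   per-SNP outlier test (default 0.05).
#' @param seed integer seed (required).
#' @return list of class `presso_result`: `rss_obs`, `global_p`, `outliers`
#'   (data.frame `snp_id`, `outlier_p` of flagged SNPs), `outlier_pvals`
#'   (all J adjusted p-values), `raw_estimate`, `corrected_estimate`,
#'   `distortion_coefficient`, `distortion_p` (the latter three `NULL` when
#'   no outlier is found), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed) {
  check_harmonized(h, 4L, "mr_presso")
  if (n_sim < 100) stop("mr_presso needs n_sim >= 100", call. = FALSE)
  r <- h$records
  j <- nrow(r)
  w <- r$se_big_gamma^-2
  obs <- presso_residuals(r$gamma, r$big_gamma, w)
  theta_loo <- drop((sum(w * r$gamma * r$big_gamma) -
                       w * r$gamma * r$big_gamma) /
                      (sum(w * r$gamma^2) - w * r$gamma^2))
  set.seed(seed)
  gamma_sim <- matrix(stats::rnorm(n_sim * j, mean = rep(r$gamma, each = n_sim),
                                   sd = rep(r$se_gamma, each = n_sim)),
                      nrow = n_sim)
  big_sim <- matrix(stats::rnorm(n_sim * j,
                                 mean = rep(r$gamma * theta_loo, each = n_sim),
                                 sd = rep(r$se_big_gamma, each = n_sim)),
                    nrow = n_sim)
  sim <- presso_residuals(gamma_sim, big_sim, w)
  rss_obs <- obs$rss
  global_p <- (1 + sum(sim$rss >= rss_obs)) / (1 + n_sim)
  outlier_raw_p <- (1 + colSums(sim$contrib >=
                                  matrix(obs$contrib, n_sim, j, byrow = TRUE))) /
    (1 + n_sim)
  outlier_adj_p <- pmin(1, outlier_raw_p * j)
  is_outlier <- outlier_adj_p < outlier_alpha
  outlier_pvals <- data.frame(snp_id = r$snp_id, outlier_p = outlier_adj_p,
                              outlier = is_outlier, stringsAsFactors = FALSE)
  raw <- mr_ivw(h, "fixed")
  raw$method <- "presso_raw"
  corrected <- NULL; distortion <- NULL; distortion_p <- NULL
  if (any(is_outlier) && sum(!is_outlier) >= 2L) {
    sub <- h
    sub$records <- r[!is_outlier, , drop = FALSE]
    corrected <- mr_ivw(sub, "fixed")
    corrected$method <- "presso_outlier_corrected"
    distortion <- 100 * (corrected$beta - raw$beta) / abs(corrected$beta)
    n_out <- sum(is_outlier)
    wgG <- w * r$gamma * r$big_gamma
    wgg <- w * r$gamma^2
    a <- sum(wgG); b_tot <- sum(wgg)
    dist_sim <- vapply(seq_len(n_sim), function(b) {
      drop_idx <- sample.int(j, n_out)
      est_b <- (a - sum(wgG[drop_idx])) / (b_tot - sum(wgg[drop_idx]))
      100 * (est_b - raw$beta) / abs(est_b)
    }, numeric(1L))
    distortion_p <- (1 + sum(abs(dist_sim) >= abs(distortion))) / (1 + n_sim)
  }
  structure(list(rss_obs = rss_obs, global_p = global_p,
                 outliers = outlier_pvals[is_outlier,
                                          c("snp_id", "outlier_p"),
                                          drop = FALSE],
                 outlier_pvals = outlier_pvals,
                 raw_estimate = raw, corrected_estimate = corrected,
                 distortion_coefficient = distortion,
                 distortion_p = distortion_p,
                 n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS_obs = %.4f, global p = %.4g (n_sim = %d)\n",
              x$rss_obs, x$global_p, x$n_sim))
  if (nrow(x$outliers)) {
    cat("  outliers:", paste(x$outliers$snp_id, collapse = ", "), "\n")
    cat(sprintf("  distortion = %.3f%%, p = %.3g\n",
                x$distortion_coefficient, x$distortion_p))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}
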