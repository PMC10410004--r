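#' Multivariable MR input container
#'
#' Per-SNP outcome effects plus a J x M matrix of exposure effects, all
#' harmonized to a common effect allele per SNP.
#'
#' @param gamma_matrix numeric J x M matrix of exposure effects (one column
#'   per exposure; column names = exposure labels).
#' @param big_gamma,se_big_gamma outcome effects and SEs (length J).
#' @param snp_id optional identifiers.
#' @return object of class `mvmr_input`.
#' @export
mvmr_input <- function(gamma_matrix, big_gamma, se_big_gamma, snp_id = NULL) {
  gamma_matrix <- as.matrix(gamma_matrix)
  j <- nrow(gamma_matrix); m <- ncol(gamma_matrix)
  stopifnot(length(big_gamma) == j, length(se_big_gamma) == j,
            all(se_big_gamma > 0), !anyNA(gamma_matrix), !anyNA(big_gamma))
  if (j <= m) stop("multivariable MR needs more SNPs than exposures",
                   call. = FALSE)
  if (is.null(colnames(gamma_matrix))) {
    colnames(gamma_matrix) <- paste0("exposure", seq_len(m))
  }
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(j))
  structure(list(gamma_matrix = gamma_matrix, big_gamma = big_gamma,
                 se_big_gamma = se_big_gamma, snp_id = as.character(snp_id)),
            class = "mvmr_input")
}

#' Multivariable IVW estimator
#'
#' Weighted least squares of the outcome effects on the M exposure-effect
#' columns with no intercept and weights `se_big_gamma^-2`; coefficient
#' variances carry the multiplicative overdispersion factor
#' `max(1, RSS_w / (J - M))`; CIs and p-values are normal-based. With M = 1
#' this reduces exactly to univariable IVW (regression form).
#'
#' @param input an [mvmr_input].
#' @return list of [mr_estimate]s (method `mvmr_ivw`), one per exposure,
#'   named by exposure label.
#' @export
mvmr_ivw <- function(input) {
  stopifnot(inherits(input, "mvmr_input"))
  x <- input$gamma_matrix
  j <- nrow(x); m <- ncol(x)
  w <- input$se_big_gamma^-2
  xw <- x * sqrt(w)
  qrx <- qr(xw)
  if (qrx$rank < m) {
    bad <- colnames(x)[qrx$pivot[seq.int(qrx$rank + 1L, m)]]
    stop("mvmr_ivw: rank-deficient design; collinear exposure(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.wfit(x, input$big_gamma, w)
  rss <- sum(w * fit$residuals^2)
  phi <- max(1, rss / (j - m))
  cov_unscaled <- chol2inv(chol(crossprod(xw)))
  ses <- sqrt(phi * diag(cov_unscaled))
  out <- lapply(seq_len(m), function(mm) {
    normal_estimate("mvmr_ivw", unname(fit$coefficients[mm]), ses[mm], j)
  })
  names(out) <- colnames(x)
  out
}

#' Bonferroni threshold for an exposure-outcome matrix
#'
#' `p = 0.05 / (E * C)` where `E` and `C` are the numbers of exposures and
#' outcomes under test.
#'
#' @param n_exposures,n_outcomes positive integers.
#' @return the corrected significance threshold.
#' @export
bonferroni_threshold <- function(n_exposures, n_outcomes) {
  if (n_exposures < 1 || n_outcomes < 1) {
    stop("bonferroni_threshold needs positive counts", call. = FALSE)
  }
  0.05 / n_exposures / n_outcomes
}

#' Two-step mediation decomposition and classification
#'
#' Given the total effect `beta0` (exposure -> outcome), the exposure ->
#' mediator effect `beta1` and the mediator -> outcome effect `beta2` (each
#' with SE), tests each by a two-sided Wald z at `alpha` and classifies:
#'
#' * all three significant -> `partial_mediation`;
#' * `beta0` not significant but `beta1` and `beta2` significant ->
#'   `complete_mediation`;
#' * `beta0` significant but `beta1` or `beta2` not -> `no_mediation`;
#' * `beta0` and at least one path coefficient non-significant ->
#'   `no_causal_effect`.
#'
#' The mediated effect is `beta1 * beta2` with first-order delta-method SE
#' `sqrt(beta1^2 se2^2 + beta2^2 se1^2)`; the mediated proportion
#' `beta1 * beta2 / beta0` is emitted only when `beta0` is significant.
#'
#' @param beta0,se0 total effect and SE.
#' @param beta1,se1 exposure -> mediator effect and SE.
#' @param beta2,se2 mediator -> outcome effect and SE.
#' @param alpha two-sided significance level (required; no silent default in
#'   pipeline use).
#' @return list of class `mediation_result`: the six inputs, `mediated_effect`,
#'   `mediated_se`, `proportion` (`NA` unless `beta0` significant),
#'   `classification`, `alpha_used`.
#' @export
two_step_mediation <- function(beta0, se0, beta1, se1, beta2, se2,
                               alpha = 0.05) {
  stopifnot(se0 > 0, se1 > 0, se2 > 0, alpha > 0, alpha < 1)
  zcrit <- stats::qnorm(1 - alpha / 2)
  sig <- function(b, s) abs(b / s) > zcrit
  s0 <- sig(beta0, se0); s1 <- sig(beta1, se1); s2 <- sig(beta2, se2)
  classification <- if (s0 && s1 && s2) "partial_mediation"
  else if (!s0 && s1 && s2) "complete_mediation"
  else if (s0) "no_mediation"
  else "no_causal_effect"
  mediated <- beta1 * beta2
  mediated_se <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  proportion <- NA_real_
  if (s0) {
    if (beta0 == 0) stop("mediated proportion undefined: beta0 = 0",
                         call. = FALSE)
    proportion <- mediated / beta0
  }
  structure(list(beta0 = beta0, se0 = se0, beta1 = beta1, se1 = se1,
                 beta2 = beta2, se2 = se2, mediated_effect = mediated,
                 mediated_se = mediated_se, proportion = proportion,
                 classification = classification, alpha_used = alpha),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Two-step mediation: beta0 = %.4g, beta1 = %.4g, beta2 = %.4g\n",
              x$beta0, x$beta1, x$beta2))
  cat(sprintf("  mediated effect = %.4g (se %.4g)%s -> %s (alpha = %g)\n",
              x$mediated_effect, x$mediated_se,
              if (is.na(x$proportion)) "" else
                sprintf(", proportion = %.3f", x$proportion),
              x$classification, x$alpha_used))
  invisible(x)
}

#' Run a full two-step mediation MR analysis
#'
#' Estimates the three legs — `beta0`: exposure -> outcome, `beta1`:
#' exposure -> mediator, `beta2`: mediator -> outcome — each via the complete
#' pipeline (significance filter -> pruning -> weak-instrument filter ->
#' harmonization -> primary IVW estimate with the heterogeneity-triggered
#' fixed/random switch), then composes [two_step_mediation]. By default the
#' mediator leg's instruments exclude SNPs that served as exposure
#' instruments, so the mediator pathway is instrumented independently of the
#' exposure.
#'
#' @param exposure,mediator,outcome valid [summary_dataset]s.
#' @param alpha significance level for the mediation classification
#'   (required).
#' @param config a [prune_config] applied to every leg.
#' @param f_min weak-instrument cutoff (default 10).
#' @param het_alpha heterogeneity-switch level (default 0.05).
#' @param exclude_exposure_instruments drop exposure-instrument ids from the
#'   mediator leg (default `TRUE`).
#' @param palindrome_window passed to [align_alleles].
#' @return a `mediation_result`; attribute `"legs"` carries the three
#'   per-leg [mr_estimate]s and instrument counts.
#' @export
run_mediation <- function(exposure, mediator, outcome, alpha,
                          config = prune_config(), f_min = 10,
                          het_alpha = 0.05,
                          exclude_exposure_instruments = TRUE,
                          palindrome_window = 0.08) {
  leg <- function(exp_ds, out_ds, name, drop_ids = character()) {
    sel <- select_instruments(exp_ds, config, f_min = f_min)
    inst <- sel$instruments
    if (length(drop_ids)) {
      inst <- subset_dataset(inst, !(inst$data$snp_id %in% drop_ids))
    }
    if (n_records(inst) < 2L) {
      stop("mediation leg '", name, "' has fewer than 2 instruments",
           call. = FALSE)
    }
    h <- align_alleles(inst, out_ds, palindrome_window = palindrome_window)
    check_harmonized(h, 2L, paste0("mediation leg '", name, "'"))
    het <- cochran_q(h)
    method <- select_primary_method(het, het_alpha)
    est <- mr_ivw(h, if (method == "ivw_mre") "multiplicative_random" else "fixed")
    list(est = est, n_instruments = nrow(h$records),
         instrument_ids = h$records$snp_id)
  }
  leg0 <- leg(exposure, outcome, "exposure->outcome")
  leg1 <- leg(exposure, mediator, "exposure->mediator")
  drop_ids <- if (exclude_exposure_instruments) leg1$instrument_ids else
    character()
  leg2 <- leg(mediator, outcome, "mediator->outcome", drop_ids = drop_ids)
  res <- two_step_mediation(leg0$est$beta, leg0$est$se,
                            leg1$est$beta, leg1$est$se,
                            leg2$est$beta, leg2$est$se, alpha = alpha)
  attr(res, "legs") <- list(total = leg0, exposure_mediator = leg1,
                            mediator_outcome = leg2)
  res
}
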