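#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (theta_j - theta_FE)^2` over the Wald ratios with the same
#' first-order weights as IVW (coherence between test and estimator), with p
#' from the upper tail of the chi-square distribution on `J - 1` df. Large Q
#' signals that the per-SNP ratios disagree beyond sampling noise
#' (heterogeneity, e.g. from pleiotropy).
#'
#' @param ratios data.frame from [wald_ratios] (columns `theta`, `weight`),
#'   or a `harmonized_set` (ratios computed internally).
#' @return list of class `heterogeneity_result`: `q`, `df` (= J - 1),
#'   `pval`.
#' @export
cochran_q <- function(ratios) {
  if (inherits(ratios, "harmonized_set")) ratios <- wald_ratios(ratios)
  j <- nrow(ratios)
  if (j < 2L) stop("cochran_q needs at least 2 instruments", call. = FALSE)
  core <- ivw_core(ratios$theta, ratios$weight)
  structure(list(q = core$q, df = j - 1L,
                 pval = stats::pchisq(core$q, j - 1L, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4f on %d df, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

#' Heterogeneity-triggered choice of the primary IVW variant
#'
#' The primary causal estimate is IVW fixed-effects unless heterogeneity is
#' identified (Q-test `p < alpha`, strict), in which case the multiplicative
#' random-effects variant is used.
#'
#' @param het a `heterogeneity_result` from [cochran_q].
#' @param alpha heterogeneity significance level (default 0.05).
#' @return `"ivw_mre"` if `het$pval < alpha`, else `"ivw_fe"`.
#' @export
select_primary_method <- function(het, alpha = 0.05) {
  stopifnot(inherits(het, "heterogeneity_result"), alpha > 0, alpha < 1)
  if (het$pval < alpha) "ivw_mre" else "ivw_fe"
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate J times, each time excluding one instrument,
#' and flags exclusions after which the estimate changes sign relative to the
#' all-instrument reference or the 95% CI's zero-crossing status changes —
#' an operational definition of a "less robust" association driven by a
#' single variant.
#'
#' @param h a `harmonized_set` with >= 3 instruments.
#' @param variant IVW variant used throughout (`"fixed"` or
#'   `"multiplicative_random"`).
#' @return list of class `loo_result`: `reference` (an [mr_estimate]),
#'   `results` (data.frame `excluded_id`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `pval`, `flagged`), `any_flagged`.
#' @export
leave_one_out <- function(h, variant = c("fixed", "multiplicative_random")) {
  variant <- match.arg(variant)
  check_harmonized(h, 3L, "leave_one_out")
  reference <- mr_ivw(h, variant)
  ids <- h$records$snp_id
  crosses_zero <- function(e) e$ci_low <= 0 && e$ci_high >= 0
  rows <- lapply(seq_along(ids), function(jj) {
    sub <- h
    sub$records <- h$records[-jj, , drop = FALSE]
    e <- mr_ivw(sub, variant)
    flagged <- sign(e$beta) != sign(reference$beta) ||
      crosses_zero(e) != crosses_zero(reference)
    data.frame(excluded_id = ids[jj], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  structure(list(reference = reference, results = results,
                 any_flagged = any(results$flagged)),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("Leave-one-out over %d instruments (reference beta = %.4g): %s\n",
              nrow(x$results), x$reference$beta,
              if (x$any_flagged) {
                paste0("flagged after excluding ",
                       paste(x$results$excluded_id[x$results$flagged],
                             collapse = ", "))
              } else "no influential exclusion"))
  invisible(x)
}

#' Tidy sensitivity table
#'
#' Collects heterogeneity and pleiotropy diagnostics into one table (test
#' name, statistic, df, p), mirroring the usual published layout.
#'
#' @param het `heterogeneity_result` or `NULL`.
#' @param egger `egger_result` or `NULL` (contributes the intercept test).
#' @param presso `presso_result` or `NULL` (contributes the global and
#'   distortion tests).
#' @return data.frame with columns `test`, `statistic`, `df`, `pval`.
#' @export
sensitivity_table <- function(het = NULL, egger = NULL, presso = NULL) {
  rows <- list()
  if (!is.null(het)) {
    rows[[length(rows) + 1L]] <- data.frame(
      test = "cochran_q", statistic = het$q, df = het$df, pval = het$pval)
  }
  if (!is.null(egger)) {
    rows[[length(rows) + 1L]] <- data.frame(
      test = "egger_intercept", statistic = egger$intercept,
      df = egger$df, pval = egger$intercept_p)
  }
  if (!is.null(presso)) {
    rows[[length(rows) + 1L]] <- data.frame(
      test = "presso_global", statistic = presso$rss_obs, df = NA_integer_,
      pval = presso$global_p)
    if (!is.null(presso$distortion_coefficient)) {
      rows[[length(rows) + 1L]] <- data.frame(
        test = "presso_distortion", statistic = presso$distortion_coefficient,
        df = NA_integer_, pval = presso$distortion_p)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(test = character(), statistic = numeric(), df = integer(),
               pval = numeric())
  rownames(out) <- NULL
  out
}
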