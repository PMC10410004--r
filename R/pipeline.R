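mrs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mrsummary_error")))
}

# accepts a summary_dataset or a file spec list(path, column_map, ...)
resolve_dataset <- function(x, what = "dataset") {
  if (inherits(x, "summary_dataset")) return(x)
  if (is.list(x) && !is.null(x$path)) {
    cm <- if (is.null(x$column_map)) canonical_column_map() else
      unlist(x$column_map)
    return(read_summary_stats(
      x$path, cm, default_n = x$default_n,
      trait_label = if (is.null(x$trait_label)) basename(x$path) else x$trait_label,
      trait_type = if (is.null(x$trait_type)) "continuous" else x$trait_type))
  }
  mrs_error(paste0(what, " must be a summary_dataset or a list with $path"),
            "mrsummary_config_error")
}

#' Analysis configuration for one exposure-outcome pair
#'
#' Bundles every tunable of the single-pair pipeline: input datasets (or file
#' specs with column maps), pruning settings, the weak-instrument cutoff
#' (default F < 10), the palindrome window, the estimator list (default: the
#' standard seven — IVW-FE, IVW-MRE, MR-Egger, simple/weighted median,
#' simple/weighted mode — plus MR-PRESSO), the heterogeneity-switch level,
#' bootstrap and PRESSO simulation sizes, and the master seed (required
#' because median/mode/PRESSO are stochastic; there is no hidden default).
#'
#' @param exposure,outcome [summary_dataset]s or file specs
#'   (`list(path=, column_map=, default_n=, trait_label=, trait_type=)`).
#' @param prune a [prune_config].
#' @param f_min weak-instrument F cutoff (default 10).
#' @param n_exposure sample size override for the F-statistic (default: from
#'   the exposure dataset).
#' @param palindrome_window see [align_alleles].
#' @param estimators character vector of estimator names among `ivw_fe`,
#'   `ivw_mre`, `egger`, `simple_median`, `weighted_median`, `simple_mode`,
#'   `weighted_mode`, `presso`.
#' @param het_alpha heterogeneity-switch level (default 0.05).
#' @param n_boot bootstrap replicates for median/mode SEs (default 1000).
#' @param presso_n_sim MR-PRESSO replicates (default 1000).
#' @param seed master integer seed (required).
#' @param reverse swap exposure and outcome roles before analysis
#'   (reverse-causality run).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(exposure, outcome, prune = prune_config(),
                            f_min = 10, n_exposure = NULL,
                            palindrome_window = 0.08,
                            estimators = c("ivw_fe", "ivw_mre", "egger",
                                           "simple_median", "weighted_median",
                                           "simple_mode", "weighted_mode",
                                           "presso"),
                            het_alpha = 0.05, n_boot = 1000,
                            presso_n_sim = 1000, seed, reverse = FALSE) {
  known <- c("ivw_fe", "ivw_mre", "egger", "simple_median", "weighted_median",
             "simple_mode", "weighted_mode", "presso")
  bad <- setdiff(estimators, known)
  if (length(bad)) {
    mrs_error(paste0("unknown estimator(s): ", paste(bad, collapse = ", ")),
              "mrsummary_config_error")
  }
  if (missing(seed) || is.null(seed)) {
    mrs_error("analysis_config: seed is required (stochastic estimators enabled)",
              "mrsummary_config_error")
  }
  structure(list(exposure = exposure, outcome = outcome, prune = prune,
                 f_min = f_min, n_exposure = n_exposure,
                 palindrome_window = palindrome_window,
                 estimators = estimators, het_alpha = het_alpha,
                 n_boot = n_boot, presso_n_sim = presso_n_sim,
                 seed = as.integer(seed), reverse = isTRUE(reverse)),
            class = "analysis_config")
}

#' Run the full MR pipeline for one exposure-outcome pair
#'
#' Executes significance selection, LD/distance pruning, weak-instrument
#' filtering, harmonization, every configured estimator, the sensitivity
#' battery (Cochran's Q, Egger intercept, leave-one-out, MR-PRESSO), the
#' heterogeneity-triggered choice between IVW-FE and IVW-MRE, and assembles a
#' report: the instrument audit (counts at each stage, excluded ids with
#' reasons), the tidy estimate table, the sensitivity table, and the selected
#' primary estimate. All stochastic components draw from streams derived from
#' the one master seed, so identical config implies an identical report.
#'
#' @param config an [analysis_config].
#' @return object of class `mr_report`.
#' @export
run_pair <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  exposure <- resolve_dataset(config$exposure, "exposure")
  outcome <- resolve_dataset(config$outcome, "outcome")
  if (config$reverse) { tmp <- exposure; exposure <- outcome; outcome <- tmp }
  sel <- select_instruments(exposure, config$prune, n = config$n_exposure,
                            f_min = config$f_min)
  h <- align_alleles(sel$instruments, outcome,
                     palindrome_window = config$palindrome_window)
  if (nrow(h$records) < 2L) {
    mrs_error(sprintf(
      "fewer than 2 instruments survive (selection left %d, harmonization left %d)",
      n_records(sel$instruments), nrow(h$records)),
      "mrsummary_estimation_error")
  }
  het <- cochran_q(h)
  primary_method <- select_primary_method(het, config$het_alpha)
  notes <- character()
  egger_res <- NULL; presso_res <- NULL
  estimates <- list()
  for (est in config$estimators) {
    res <- tryCatch(switch(
      est,
      ivw_fe = mr_ivw(h, "fixed"),
      ivw_mre = mr_ivw(h, "multiplicative_random"),
      egger = mr_egger(h),
      simple_median = mr_median(h, "simple", config$n_boot,
                                seed = derive_seed(config$seed, 101L)),
      weighted_median = mr_median(h, "weighted", config$n_boot,
                                  seed = derive_seed(config$seed, 102L)),
      simple_mode = mr_mode(h, "simple", n_boot = config$n_boot,
                            seed = derive_seed(config$seed, 103L)),
      weighted_mode = mr_mode(h, "weighted", n_boot = config$n_boot,
                              seed = derive_seed(config$seed, 104L)),
      presso = mr_presso(h, config$presso_n_sim,
                         seed = derive_seed(config$seed, 105L))),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      notes <- c(notes, sprintf("%s skipped: %s", est, res))
    } else if (inherits(res, "egger_result")) {
      egger_res <- res
      estimates[[est]] <- res$slope
    } else if (inherits(res, "presso_result")) {
      presso_res <- res
      estimates[[est]] <- res$raw_estimate
      if (!is.null(res$corrected_estimate)) {
        estimates[["presso_corrected"]] <- res$corrected_estimate
      }
    } else {
      estimates[[est]] <- res
    }
  }
  loo <- tryCatch(leave_one_out(h), error = function(e) NULL)
  if (is.null(loo)) notes <- c(notes, "leave-one-out skipped (< 3 instruments)")
  primary <- mr_ivw(h, if (primary_method == "ivw_mre")
    "multiplicative_random" else "fixed")
  est_tab <- estimates_table(estimates, exposure$trait_label,
                             outcome$trait_label)
  structure(list(
    exposure_label = exposure$trait_label, outcome_label = outcome$trait_label,
    audit = sel$audit, excluded = sel$excluded,
    instrument_diagnostics = sel$diagnostics,
    harmonization_dropped = h$dropped, n_instruments = nrow(h$records),
    estimates = est_tab, raw_estimates = estimates,
    heterogeneity = het, egger = egger_res, presso = presso_res, loo = loo,
    sensitivity = sensitivity_table(het, egger_res, presso_res),
    primary_method = primary_method, primary = primary, notes = notes,
    seed = config$seed, reverse = config$reverse,
    package_version = as.character(utils::packageVersion("mrsummary"))),
    class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("== MR report: %s -> %s (mrsummary %s, seed %d) ==\n",
              x$exposure_label, x$outcome_label, x$package_version, x$seed))
  cat("Instrument audit:\n"); print(x$audit)
  if (nrow(x$excluded)) {
    cat("Excluded:", paste(sprintf("%s (%s)", x$excluded$snp_id,
                                   x$excluded$stage), collapse = ", "), "\n")
  }
  if (nrow(x$harmonization_dropped)) {
    cat("Dropped at harmonization:\n"); print(x$harmonization_dropped)
  }
  cat(sprintf("Primary method (heterogeneity p = %.3g): %s\n",
              x$heterogeneity$pval, x$primary_method))
  print(x$primary)
  cat("Estimates:\n"); print(x$estimates, digits = 4)
  cat("Sensitivity:\n"); print(x$sensitivity, digits = 4)
  if (length(x$notes)) cat("Notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Run a matrix of exposure-outcome analyses
#'
#' Applies [run_pair] to each configuration, isolating per-pair failures
#' (reported, not fatal to the batch), concatenates the tidy estimate tables,
#' and flags significance against the Bonferroni threshold
#' `0.05 / E / C` computed from the matrix dimensions via
#' [bonferroni_threshold] (overridable).
#'
#' @param configs non-empty list of [analysis_config]s.
#' @param n_exposures,n_outcomes matrix dimensions for the Bonferroni rule;
#'   default: counts of distinct exposure/outcome labels among successful
#'   runs.
#' @return object of class `mr_matrix_report`: `reports` (per-pair
#'   `mr_report`s or error messages), `estimates` (combined tidy table with
#'   `bonferroni_significant` on every row), `threshold`, `failures`.
#' @export
run_matrix <- function(configs, n_exposures = NULL, n_outcomes = NULL) {
  if (!length(configs)) {
    mrs_error("run_matrix: empty config list", "mrsummary_config_error")
  }
  reports <- lapply(configs, function(cfg) {
    tryCatch(run_pair(cfg), error = function(e) conditionMessage(e))
  })
  ok <- vapply(reports, inherits, logical(1L), "mr_report")
  failures <- unlist(reports[!ok])
  tabs <- lapply(reports[ok], `[[`, "estimates")
  estimates <- if (length(tabs)) do.call(rbind, tabs) else NULL
  if (is.null(n_exposures)) {
    n_exposures <- max(1L, length(unique(vapply(
      reports[ok], `[[`, "", "exposure_label"))))
  }
  if (is.null(n_outcomes)) {
    n_outcomes <- max(1L, length(unique(vapply(
      reports[ok], `[[`, "", "outcome_label"))))
  }
  threshold <- bonferroni_threshold(n_exposures, n_outcomes)
  if (!is.null(estimates)) {
    estimates$bonferroni_significant <- estimates$pval < threshold
  }
  structure(list(reports = reports, estimates = estimates,
                 threshold = threshold, failures = failures),
            class = "mr_matrix_report")
}

#' @export
print.mr_matrix_report <- function(x, ...) {
  cat(sprintf("== MR matrix report: %d analyses, Bonferroni threshold %.4g ==\n",
              length(x$reports), x$threshold))
  if (!is.null(x$estimates)) print(x$estimates, digits = 4)
  if (length(x$failures)) {
    cat("Failures:\n"); for (f in x$failures) cat(" -", f, "\n")
  }
  invisible(x)
}

#' Serialize an MR report to plain-text tables
#'
#' Writes the tidy estimate table, the sensitivity table, the instrument
#' audit and a human-readable summary under `dir`.
#'
#' @param report an `mr_report`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(estimates = file.path(dir, "estimates.tsv"),
             sensitivity = file.path(dir, "sensitivity.tsv"),
             audit = file.path(dir, "instrument_audit.tsv"),
             summary = file.path(dir, "report.txt"))
  data.table::fwrite(report$estimates, paths[["estimates"]], sep = "\t")
  data.table::fwrite(report$sensitivity, paths[["sensitivity"]], sep = "\t")
  data.table::fwrite(report$audit, paths[["audit"]], sep = "\t")
  con <- file(paths[["summary"]], "w")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(paths)
}
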