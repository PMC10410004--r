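# derived per-block RNG seed: one stream per SNP block so that adding SNPs
# never perturbs earlier draws; always < 2^31
derive_seed <- function(seed, block) {
  ((as.numeric(seed) %% 1000003) * 2039 + block * 7919 + 1) %% 2147483629
}

wald_p <- function(beta, se) {
  pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
}

# single-SNP regression approximation to the summary-statistic SE
approx_se <- function(n, eaf) 1 / sqrt(2 * n * eaf * (1 - eaf))

NONPAL_PAIRS <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
PAL_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulation configuration
#'
#' The stated world of the generator: a linear causal model
#' `big_gamma_j = theta * gamma_j + alpha_j` over independent biallelic SNPs
#' (post-pruning assumption: no LD), with per-SNP standard errors from the
#' single-SNP regression approximation `se = 1/sqrt(2 n eaf (1 - eaf))` and
#' observed effects drawn around the truth. Defaults emulate a GIANT-scale
#' binary-exposure GWAS instrumenting a UK-Biobank-scale continuous outcome:
#' 50 instruments, exposure n = 158,945, outcome n = 472,174, effect-allele
#' frequencies uniform on (0.05, 0.95), exposure effect magnitudes
#' `|gamma| ~ N(0.08, 0.02)` with random sign (the scale of published
#' overweight instruments, beta 0.05-0.14).
#'
#' @param n_snps number of instruments (>= 2; default 50).
#' @param theta true causal effect (default 0.3).
#' @param n_exposure,n_outcome simulated GWAS sample sizes (>= 100).
#' @param eaf_range interval inside (0, 1) for uniform frequency draws.
#' @param gamma_mean,gamma_sd mean and SD of the exposure effect magnitudes.
#' @param pleiotropy `"none"`, `"balanced"` (direct effects centered on 0) or
#'   `"directional"` (centered on `alpha_mean` in the exposure-increasing
#'   allele orientation, i.e. multiplied by `sign(gamma_j)`).
#' @param alpha_mean,alpha_sd mean and SD of the per-SNP direct (pleiotropic)
#'   effects; `alpha_mean` is forced to 0 for `"balanced"`.
#' @param inside_violation correlate direct effects with instrument strength
#'   (adds `0.1 * gamma_j` to `alpha_j`), violating InSIDE.
#' @param outlier_fraction fraction of SNPs whose outcome effect is shifted
#'   (in \[0, 0.5\]; default 0).
#' @param outlier_shift shift size in units of the outcome SE (default 10).
#' @param palindromic_fraction,swap_fraction fractions of SNPs given an A/T
#'   or C/G allele pair, and whose outcome record is stored on the opposite
#'   effect/other-allele orientation, to exercise harmonization.
#' @param seed master integer seed (required).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 50, theta = 0.3,
                              n_exposure = 158945, n_outcome = 472174,
                              eaf_range = c(0.05, 0.95),
                              gamma_mean = 0.08, gamma_sd = 0.02,
                              pleiotropy = c("none", "balanced", "directional"),
                              alpha_mean = 0.002, alpha_sd = 0.002,
                              inside_violation = FALSE,
                              outlier_fraction = 0, outlier_shift = 10,
                              palindromic_fraction = 0.2,
                              swap_fraction = 0.3, seed) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(n_snps >= 2, n_exposure >= 100, n_outcome >= 100,
            length(eaf_range) == 2L, eaf_range[1L] > 0, eaf_range[2L] < 1,
            eaf_range[1L] < eaf_range[2L], gamma_sd >= 0, alpha_sd >= 0,
            outlier_fraction >= 0, outlier_fraction <= 0.5,
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            swap_fraction >= 0, swap_fraction <= 1)
  if (missing(seed)) stop("simulation_config: seed is required", call. = FALSE)
  if (pleiotropy == "balanced") alpha_mean <- 0
  structure(list(n_snps = as.integer(n_snps), theta = theta,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 eaf_range = eaf_range, gamma_mean = gamma_mean,
                 gamma_sd = gamma_sd, pleiotropy = pleiotropy,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 inside_violation = inside_violation,
                 outlier_fraction = outlier_fraction,
                 outlier_shift = outlier_shift,
                 palindromic_fraction = palindromic_fraction,
                 swap_fraction = swap_fraction, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a two-sample GWAS summary-statistic study
#'
#' Generates paired exposure/outcome [summary_dataset]s under the linear
#' causal model of [simulation_config], together with the generating truth.
#' For each SNP: frequency drawn uniform on `eaf_range`; true exposure effect
#' from the magnitude distribution with random sign; true outcome effect
#' `theta * gamma_j + alpha_j`, plus `outlier_shift` outcome SEs for planted
#' outliers; observed effects `Normal(truth, se)` with
#' `se = 1/sqrt(2 n eaf (1 - eaf))`; p-values from the Wald z. Alleles are
#' assigned at random with configurable palindromic and swapped-orientation
#' fractions. One derived RNG stream per SNP: adding SNPs does not perturb
#' earlier draws; identical config implies an identical study.
#'
#' @param config a [simulation_config].
#' @return object of class `simulated_study`: `exposure`, `outcome`
#'   (valid [summary_dataset]s) and `truth` (list: `theta`, `gamma`, `alpha`,
#'   `big_gamma`, `outlier_ids`, `eaf`, `se_exposure`, `se_outcome`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  j <- config$n_snps
  set.seed(derive_seed(config$seed, 0L))
  n_out <- round(config$outlier_fraction * j)
  outlier_idx <- if (n_out > 0) sort(sample.int(j, n_out)) else integer()
  snp_id <- sprintf("rs%07d", seq_len(j))
  gamma <- alpha <- big_gamma <- eaf <- se_x <- se_y <- numeric(j)
  bx <- by <- numeric(j)
  ea <- oa <- character(j)
  swap <- logical(j)
  for (jj in seq_len(j)) {
    set.seed(derive_seed(config$seed, jj))
    eaf[jj] <- stats::runif(1L, config$eaf_range[1L], config$eaf_range[2L])
    mag <- abs(stats::rnorm(1L, config$gamma_mean, config$gamma_sd))
    sgn <- sample(c(-1, 1), 1L)
    gamma[jj] <- sgn * mag
    az <- stats::rnorm(1L)
    # directional effects are directional in the exposure-increasing allele
    # orientation (sign(gamma)); otherwise a random-sign gamma would make any
    # constant alpha balanced in ratio space
    alpha[jj] <- switch(config$pleiotropy,
                        none = 0,
                        balanced = config$alpha_sd * az,
                        directional = sgn * (config$alpha_mean +
                                               config$alpha_sd * az))
    if (config$inside_violation && config$pleiotropy != "none") {
      alpha[jj] <- alpha[jj] + 0.1 * gamma[jj]
    }
    pal <- stats::runif(1L) < config$palindromic_fraction
    pair <- if (pal) PAL_PAIRS[[sample.int(4L, 1L)]] else
      NONPAL_PAIRS[[sample.int(4L, 1L)]]
    ea[jj] <- pair[1L]; oa[jj] <- pair[2L]
    swap[jj] <- stats::runif(1L) < config$swap_fraction
    se_x[jj] <- approx_se(config$n_exposure, eaf[jj])
    se_y[jj] <- approx_se(config$n_outcome, eaf[jj])
    big_gamma[jj] <- config$theta * gamma[jj] + alpha[jj] +
      if (jj %in% outlier_idx) config$outlier_shift * se_y[jj] else 0
    bx[jj] <- stats::rnorm(1L, gamma[jj], se_x[jj])
    by[jj] <- stats::rnorm(1L, big_gamma[jj], se_y[jj])
  }
  chrom <- as.character(1L + (seq_len(j) - 1L) %% 22L)
  pos <- 1e6 * seq_len(j)
  exposure <- summary_dataset(
    data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
               effect_allele = ea, other_allele = oa, eaf = eaf, beta = bx,
               se = se_x, pval = wald_p(bx, se_x), n = config$n_exposure,
               stringsAsFactors = FALSE),
    "sim_exposure", default_n = config$n_exposure)
  outcome <- summary_dataset(
    data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
               effect_allele = ifelse(swap, oa, ea),
               other_allele = ifelse(swap, ea, oa),
               eaf = ifelse(swap, 1 - eaf, eaf),
               beta = ifelse(swap, -by, by), se = se_y,
               pval = wald_p(by, se_y), n = config$n_outcome,
               stringsAsFactors = FALSE),
    "sim_outcome", default_n = config$n_outcome)
  structure(list(exposure = exposure, outcome = outcome,
                 truth = list(theta = config$theta, gamma = gamma,
                              alpha = alpha, big_gamma = big_gamma,
                              outlier_ids = snp_id[outlier_idx], eaf = eaf,
                              se_exposure = se_x, se_outcome = se_y),
                 config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %d SNPs, theta = %g, pleiotropy = %s, %d outliers\n",
              x$config$n_snps, x$truth$theta, x$config$pleiotropy,
              length(x$truth$outlier_ids)))
  invisible(x)
}

#' Simulate a three-trait mediation study
#'
#' Generates exposure (X), mediator (M) and outcome (Y) summary statistics
#' under the DAG `X -> M -> Y` with direct path `X -> Y`: `b1` (X on M),
#' `b2` (M on Y) and direct effect `c_direct`, so the true total effect is
#' `beta0 = c_direct + b1 * b2` and the true mediated proportion
#' `b1 * b2 / beta0` (flagged undefined when `beta0 = 0`). Two disjoint
#' instrument sets are generated — `n_snps` SNPs instrumenting X (effects on
#' M: `b1 * gamma`; on Y: `beta0 * gamma`) and `n_snps_mediator` SNPs
#' instrumenting M only (effects on X: 0; on Y: `b2 * delta`) — matching the
#' independence the two-step procedure assumes. All three datasets carry all
#' SNPs.
#'
#' @param config a [simulation_config] (theta is ignored; pleiotropy/outlier
#'   settings apply to none of the legs in v1).
#' @param b1 effect of exposure on mediator.
#' @param b2 effect of mediator on outcome.
#' @param c_direct direct exposure -> outcome effect.
#' @param n_snps_mediator instruments for the mediator (default
#'   `config$n_snps`).
#' @param n_mediator mediator GWAS sample size (default `config$n_outcome`).
#' @return list of class `simulated_mediation_study`: `exposure`, `mediator`,
#'   `outcome` ([summary_dataset]s) and `truth` (list: `b1`, `b2`,
#'   `c_direct`, `beta0`, `mediated_effect`, `proportion`,
#'   `proportion_defined`, per-set SNP ids).
#' @export
simulate_mediation_study <- function(config, b1 = 0.5, b2 = 0.3,
                                     c_direct = 0.45,
                                     n_snps_mediator = config$n_snps,
                                     n_mediator = config$n_outcome) {
  stopifnot(inherits(config, "simulation_config"), n_snps_mediator >= 2)
  beta0 <- c_direct + b1 * b2
  j_x <- config$n_snps
  j_m <- n_snps_mediator
  total <- j_x + j_m
  snp_id <- sprintf("rs%07d", seq_len(total))
  is_x_set <- seq_len(total) <= j_x
  ns <- c(x = config$n_exposure, m = n_mediator, y = config$n_outcome)
  gamma <- eafs <- numeric(total)
  ea <- oa <- character(total)
  cols <- lapply(ns, function(...) {
    list(beta = numeric(total), se = numeric(total), swap = logical(total))
  })
  for (jj in seq_len(total)) {
    set.seed(derive_seed(config$seed, jj))
    eaf <- stats::runif(1L, config$eaf_range[1L], config$eaf_range[2L])
    eafs[jj] <- eaf
    mag <- abs(stats::rnorm(1L, config$gamma_mean, config$gamma_sd))
    g <- sample(c(-1, 1), 1L) * mag
    gamma[jj] <- g
    pal <- stats::runif(1L) < config$palindromic_fraction
    pair <- if (pal) PAL_PAIRS[[sample.int(4L, 1L)]] else
      NONPAL_PAIRS[[sample.int(4L, 1L)]]
    ea[jj] <- pair[1L]; oa[jj] <- pair[2L]
    # true effects of this SNP on the three traits
    eff <- if (is_x_set[jj]) c(x = g, m = b1 * g, y = beta0 * g) else
      c(x = 0, m = g, y = b2 * g)
    for (trait in c("x", "m", "y")) {
      se <- approx_se(ns[[trait]], eaf)
      cols[[trait]]$se[jj] <- se
      cols[[trait]]$beta[jj] <- stats::rnorm(1L, eff[[trait]], se)
      cols[[trait]]$swap[jj] <- stats::runif(1L) < config$swap_fraction &&
        trait != "x"
    }
  }
  mk <- function(trait, label, n) {
    cc <- cols[[trait]]
    summary_dataset(data.frame(
      snp_id = snp_id, chrom = as.character(1L + (seq_len(total) - 1L) %% 22L),
      pos = 1e6 * seq_len(total),
      effect_allele = ifelse(cc$swap, oa, ea),
      other_allele = ifelse(cc$swap, ea, oa),
      eaf = ifelse(cc$swap, 1 - eafs, eafs),
      beta = ifelse(cc$swap, -cc$beta, cc$beta), se = cc$se,
      pval = wald_p(cc$beta, cc$se), n = n, stringsAsFactors = FALSE),
      label, default_n = n)
  }
  structure(list(
    exposure = mk("x", "sim_exposure", config$n_exposure),
    mediator = mk("m", "sim_mediator", n_mediator),
    outcome = mk("y", "sim_outcome", config$n_outcome),
    truth = list(b1 = b1, b2 = b2, c_direct = c_direct, beta0 = beta0,
                 mediated_effect = b1 * b2,
                 proportion = if (beta0 == 0) NA_real_ else b1 * b2 / beta0,
                 proportion_defined = beta0 != 0,
                 exposure_snp_ids = snp_id[is_x_set],
                 mediator_snp_ids = snp_id[!is_x_set]),
    config = config),
    class = "simulated_mediation_study")
}

#' Write a simulated study plus its truth sidecar to disk
#'
#' Emits the exposure and outcome tables in the canonical format (readable by
#' [read_summary_stats]) and a tab-delimited truth table, so the pipeline can
#' be run end-to-end on generated files.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_summary_stats(study$exposure, paths[["exposure"]])
  write_summary_stats(study$outcome, paths[["outcome"]])
  tr <- study$truth
  truth_tab <- data.frame(snp_id = study$exposure$data$snp_id,
                          gamma = tr$gamma, alpha = tr$alpha,
                          big_gamma = tr$big_gamma,
                          outlier = study$exposure$data$snp_id %in% tr$outlier_ids,
                          theta = tr$theta, stringsAsFactors = FALSE)
  data.table::fwrite(truth_tab, paths[["truth"]], sep = "\t", quote = FALSE)
  invisible(paths)
}
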