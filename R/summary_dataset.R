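#' @title GWAS summary-statistic dataset
#'
#' @description A `summary_dataset` holds one trait's per-SNP association
#' records: identifier, chromosome label, 1-based position, effect and other
#' allele, effect-allele frequency (EAF), additive effect `beta` (log odds
#' ratio for binary traits), its standard error, p-value, and sample size.
#' Record order is preserved by every operation in the package so that seeded
#' stochastic procedures are reproducible.
#'
#' Chromosome labels are opaque strings compared by equality (`"1" != "chr1"`;
#' no normalization). Positions are 1-based base pairs. Missing `eaf` is
#' permitted at construction; operations that need it (variance explained,
#' palindrome resolution) fail loudly rather than impute.
#'
#' @param data data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`
#'   (`eaf` and `n` may be `NA`).
#' @param trait_label character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"` (binary effects are treated
#'   as log odds ratios throughout; no OR conversion is ever applied).
#' @param default_n optional positive integer used when record-level `n` is
#'   missing.
#' @param check validate records on construction (default `TRUE`).
#' @return An object of class `summary_dataset`.
#' @export
summary_dataset <- function(data, trait_label,
                            trait_type = c("continuous", "binary"),
                            default_n = NULL, check = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_label), length(trait_label) == 1L)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  needed <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
              "eaf", "beta", "se", "pval", "n")
  for (col in setdiff(c("eaf", "n"), names(data))) data[[col]] <- NA_real_
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("summary_dataset: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[needed]
  data$snp_id <- as.character(data$snp_id)
  data$chrom <- as.character(data$chrom)
  data$pos <- as.integer(data$pos)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) data[[col]] <- as.numeric(data[[col]])
  data$n <- as.numeric(data$n)
  if (!is.null(default_n)) {
    stopifnot(length(default_n) == 1L, is.finite(default_n), default_n > 0)
    default_n <- as.numeric(default_n)
  }
  rownames(data) <- NULL
  out <- structure(
    list(trait_label = trait_label, trait_type = trait_type,
         default_n = default_n, data = data),
    class = "summary_dataset")
  if (check) {
    report <- validate_dataset(out)
    if (nrow(report)) {
      stop("summary_dataset '", trait_label, "': ", nrow(report),
           " record violation(s); first: ", report$message[1L],
           " (run validate_dataset() on check = FALSE input for the full report)",
           call. = FALSE)
    }
  }
  out
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s), %d SNPs%s\n",
              x$trait_label, x$trait_type, nrow(x$data),
              if (is.null(x$default_n)) "" else sprintf(", default n = %g", x$default_n)))
  if (nrow(x$data)) print(utils::head(x$data, 6L))
  if (nrow(x$data) > 6L) cat("...", nrow(x$data) - 6L, "more rows\n")
  invisible(x)
}

#' @export
as.data.frame.summary_dataset <- function(x, ...) x$data

#' Number of SNP records in a dataset
#' @param x a `summary_dataset`.
#' @return integer record count.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "summary_dataset"))
  nrow(x$data)
}

#' Effective per-record sample sizes
#'
#' Record-level `n` where present, otherwise the dataset-level `default_n`.
#' Errors if neither is available for some record.
#' @param x a `summary_dataset`.
#' @return numeric vector of sample sizes, one per record.
#' @export
effective_n <- function(x) {
  stopifnot(inherits(x, "summary_dataset"))
  n <- x$data$n
  if (anyNA(n)) {
    if (is.null(x$default_n)) {
      stop("dataset '", x$trait_label,
           "' has records with missing n and no default_n", call. = FALSE)
    }
    n[is.na(n)] <- x$default_n
  }
  n
}

# subset records by logical/integer index, preserving order
subset_dataset <- function(x, idx) {
  y <- x
  y$data <- x$data[idx, , drop = FALSE]
  rownames(y$data) <- NULL
  y
}

#' Validate a summary dataset
#'
#' Pure reporting operation: lists per-record violations (duplicate ids,
#' non-positive standard errors, frequencies outside \[0, 1\], identical or
#' non-ACGT alleles, positions below 1, p-values outside (0, 1\]). An empty
#' report (zero rows) means the dataset is valid. Repeated calls on the same
#' input yield identical reports.
#'
#' @param dataset a `summary_dataset` (possibly built with `check = FALSE`).
#' @return data.frame with columns `row`, `snp_id`, `field`, `message`;
#'   zero rows when valid.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "summary_dataset"))
  d <- dataset$data
  rep0 <- data.frame(row = integer(), snp_id = character(),
                     field = character(), message = character(),
                     stringsAsFactors = FALSE)
  add <- function(rep, rows, field, msg) {
    if (!length(rows)) return(rep)
    rbind(rep, data.frame(row = rows, snp_id = d$snp_id[rows], field = field,
                          message = sprintf(msg, d$snp_id[rows]),
                          stringsAsFactors = FALSE))
  }
  rep <- rep0
  dup <- which(duplicated(d$snp_id) | duplicated(d$snp_id, fromLast = TRUE))
  rep <- add(rep, dup, "snp_id", "duplicated snp_id '%s'")
  rep <- add(rep, which(is.na(d$snp_id) | d$snp_id == ""), "snp_id",
             "missing snp_id ('%s')")
  ok_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  rep <- add(rep, which(!ok_allele(d$effect_allele)), "effect_allele",
             "'%s': effect allele not a single A/C/G/T base")
  rep <- add(rep, which(!ok_allele(d$other_allele)), "other_allele",
             "'%s': other allele not a single A/C/G/T base")
  rep <- add(rep, which(ok_allele(d$effect_allele) & ok_allele(d$other_allele) &
                          d$effect_allele == d$other_allele), "alleles",
             "'%s': effect and other allele identical")
  rep <- add(rep, which(is.na(d$pos) | d$pos < 1L), "pos",
             "'%s': position missing or < 1")
  rep <- add(rep, which(is.na(d$beta) | !is.finite(d$beta)), "beta",
             "'%s': beta missing or non-finite")
  rep <- add(rep, which(is.na(d$se) | !(d$se > 0)), "se",
             "'%s': se missing or not > 0")
  rep <- add(rep, which(!is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1)), "eaf",
             "'%s': eaf outside [0, 1]")
  rep <- add(rep, which(is.na(d$pval) | d$pval <= 0 | d$pval > 1), "pval",
             "'%s': p-value outside (0, 1]")
  rep <- add(rep, which(!is.na(d$n) & d$n <= 0), "n",
             "'%s': non-positive sample size")
  rep <- rep[order(rep$row), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Causal-effect estimate container
#'
#' One causal estimate with its method label, standard error, 95% confidence
#' interval, p-value and instrument count, as produced by every estimator in
#' the package.
#'
#' @param method one of `wald_ratio`, `ivw_fe`, `ivw_mre`, `egger`,
#'   `simple_median`, `weighted_median`, `simple_mode`, `weighted_mode`,
#'   `presso_raw`, `presso_outlier_corrected`, `mvmr_ivw`.
#' @param beta,se point estimate and standard error (`se > 0`).
#' @param ci_low,ci_high 95% interval bounds.
#' @param pval two-sided p-value in (0, 1].
#' @param n_snps number of instruments used.
#' @return object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, ci_low, ci_high, pval, n_snps) {
  methods <- c("wald_ratio", "ivw_fe", "ivw_mre", "egger", "simple_median",
               "weighted_median", "simple_mode", "weighted_mode",
               "presso_raw", "presso_outlier_corrected", "mvmr_ivw")
  method <- match.arg(method, methods)
  stopifnot(is.finite(beta), is.finite(se), se > 0,
            ci_low <= beta, beta <= ci_high,
            pval > 0, pval <= 1, n_snps >= 1)
  structure(list(method = method, beta = beta, se = se, ci_low = ci_low,
                 ci_high = ci_high, pval = pval, n_snps = as.integer(n_snps)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, nsnp = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             stringsAsFactors = FALSE)
}

# normal-based estimate wrapper; p floored at machine minimum to stay in (0,1]
normal_estimate <- function(method, beta, se, n_snps) {
  z <- beta / se
  p <- max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  mr_estimate(method, beta, se, beta - 1.96 * se, beta + 1.96 * se, p, n_snps)
}
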