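#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a comma-, tab- or whitespace-delimited table (delimiter
#' auto-detected by [data.table::fread]) and maps arbitrary header names onto
#' the canonical fields via `column_map`. Allele strings are upper-cased.
#' Rows violating record invariants (identical alleles, non-positive se,
#' frequency outside \[0, 1\], ...) are rejected with row-indexed diagnostics
#' attached to the result as attribute `"rejected"` (and a warning); rows with
#' non-numeric `beta`/`se` are a hard error listing the offending rows.
#'
#' @param path file path to the delimited table.
#' @param column_map named character vector mapping canonical field names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `pval`, and optionally `eaf`, `n`) to the file's column names.
#' @param default_n optional dataset-level sample size used where record-level
#'   `n` is missing.
#' @param trait_label trait name for the resulting dataset.
#' @param trait_type `"continuous"` (default) or `"binary"`.
#' @param sep optional delimiter override passed to `fread`.
#' @return a [summary_dataset]; attribute `"rejected"` holds a data.frame of
#'   dropped rows (`row`, `snp_id`, `field`, `message`), empty when all rows
#'   were valid.
#' @export
read_summary_stats <- function(path, column_map, default_n = NULL,
                               trait_label = basename(path),
                               trait_type = c("continuous", "binary"),
                               sep = "auto") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pval")
  if (is.null(names(column_map)) || !all(required %in% names(column_map))) {
    stop("column_map must name at least: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  tab <- data.table::fread(path, sep = sep, header = TRUE,
                           colClasses = "character", data.table = FALSE,
                           showProgress = FALSE)
  missing_cols <- setdiff(unname(column_map), names(tab))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("no data rows in ", path, call. = FALSE)
  d <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                  lapply(column_map, function(col) tab[[col]]))
  names(d) <- names(column_map)
  bad_num <- which(is.na(suppressWarnings(as.numeric(d$beta))) |
                     is.na(suppressWarnings(as.numeric(d$se))))
  if (length(bad_num)) {
    stop("non-numeric beta/se in ", path, " at data row(s): ",
         paste(utils::head(bad_num, 20L), collapse = ", "), call. = FALSE)
  }
  raw <- summary_dataset(d, trait_label = trait_label,
                         trait_type = trait_type, default_n = default_n,
                         check = FALSE)
  report <- validate_dataset(raw)
  if (nrow(report)) {
    keep <- setdiff(seq_len(nrow(raw$data)), unique(report$row))
    warning(sprintf("%s: rejected %d of %d rows failing record invariants",
                    path, nrow(raw$data) - length(keep), nrow(raw$data)),
            call. = FALSE)
    raw <- subset_dataset(raw, keep)
  }
  if (nrow(raw$data) == 0L) {
    stop("no valid summary-statistic rows in ", path, call. = FALSE)
  }
  attr(raw, "rejected") <- report
  raw
}

#' Write a summary dataset to the canonical tab-delimited format
#'
#' Writes a tab-delimited file with the fixed header `snp_id chrom pos
#' effect_allele other_allele eaf beta se pval n`; numeric fields are rendered
#' with 15 significant digits so that a write/read round trip is the identity
#' on field values.
#'
#' @param dataset a valid [summary_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(dataset, path) {
  stopifnot(inherits(dataset, "summary_dataset"))
  d <- dataset$data
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.15g", x))
  out <- data.frame(snp_id = d$snp_id, chrom = d$chrom, pos = d$pos,
                    effect_allele = d$effect_allele,
                    other_allele = d$other_allele,
                    eaf = fmt(d$eaf), beta = fmt(d$beta), se = fmt(d$se),
                    pval = fmt(d$pval), n = fmt(d$n),
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

# canonical column map for files produced by write_summary_stats
canonical_column_map <- function(with_eaf = TRUE, with_n = TRUE) {
  cm <- c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
          effect_allele = "effect_allele", other_allele = "other_allele",
          beta = "beta", se = "se", pval = "pval")
  if (with_eaf) cm <- c(cm, eaf = "eaf")
  if (with_n) cm <- c(cm, n = "n")
  cm
}

#' The packaged overweight instrument table
#'
#' Loads the 14-SNP overweight instrument fixture shipped with the package:
#' the genome-wide significant SNPs from the GIANT overweight case/control
#' GWAS (93,105 cases + 65,840 controls, total n = 158,945) with effect
#' allele, other allele, EAF, beta, SE and p-value. Base-pair positions are
#' supplemental approximate GRCh37 coordinates of the named loci (the source
#' table reports only chromosome numbers); they are used solely by the
#' distance-pruning rule, under which all 14 loci are mutually independent.
#'
#' @return a [summary_dataset] of 14 records with `default_n = 158945`.
#' @export
overweight_instruments <- function() {
  path <- system.file("extdata", "overweight_giant_snps.tsv",
                      package = "mrsummary", mustWork = TRUE)
  read_summary_stats(path, canonical_column_map(with_n = FALSE),
                     default_n = 158945, trait_label = "overweight",
                     trait_type = "binary")
}
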