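COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic_pair <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome associations to a common effect allele
#'
#' Matches records by `snp_id` and places both traits' effects on the
#' exposure's effect-allele convention. For each exposure SNP found in the
#' outcome:
#'
#' * identical alleles: effects copied unchanged;
#' * effect/other alleles swapped: outcome beta negated and its frequency
#'   complemented (`flipped = TRUE`);
#' * strand complement (A<->T, C<->G) of either case: complement applied
#'   first, then the same rules;
#' * palindromic SNP (A/T or C/G pair): the strand cannot be resolved from
#'   alleles, so both frequencies must be present and at least
#'   `palindrome_window` away from 0.5; the orientation is then chosen so the
#'   two frequencies agree on the minor allele, otherwise the record is
#'   dropped as `ambiguous_palindrome`;
#' * no consistent allele correspondence: dropped as `allele_mismatch`;
#' * exposure SNP absent from the outcome: dropped as `missing_in_outcome`;
#' * palindromic SNP with a missing frequency: dropped as `invalid_record`
#'   (the ambiguity cannot even be assessed; never silently imputed).
#'
#' Harmonization never changes any |beta| or any standard error — only signs
#' and frequency complements.
#'
#' @param exposure,outcome valid [summary_dataset]s.
#' @param palindrome_window minimum |eaf − 0.5| required to resolve a
#'   palindromic SNP (default 0.08, i.e. drop palindromes with either eaf in
#'   (0.42, 0.58)); conservative common MR practice.
#' @param strict_palindrome drop all palindromic SNPs regardless of frequency
#'   (default `FALSE`).
#' @return object of class `harmonized_set`: list with `exposure_label`,
#'   `outcome_label`, `records` (data.frame `snp_id`, `gamma`, `se_gamma`,
#'   `big_gamma`, `se_big_gamma`, `eaf_exposure`, `eaf_outcome`, `flipped`,
#'   `palindromic`) and `dropped` (data.frame `snp_id`, `reason`).
#' @export
align_alleles <- function(exposure, outcome, palindrome_window = 0.08,
                          strict_palindrome = FALSE) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"),
            palindrome_window >= 0, palindrome_window <= 0.5)
  ex <- exposure$data
  out <- outcome$data
  idx <- match(ex$snp_id, out$snp_id)
  rec <- vector("list", nrow(ex))
  dropped <- vector("list", nrow(ex))
  for (i in seq_len(nrow(ex))) {
    id <- ex$snp_id[i]
    j <- idx[i]
    if (is.na(j)) { dropped[[i]] <- c(id, "missing_in_outcome"); next }
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- out$effect_allele[j]; oa_y <- out$other_allele[j]
    pal <- unname(is_palindromic_pair(ea_x, oa_x))
    big_gamma <- out$beta[j]; eaf_y <- out$eaf[j]
    if (pal) {
      if (strict_palindrome) { dropped[[i]] <- c(id, "ambiguous_palindrome"); next }
      if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
        dropped[[i]] <- c(id, "allele_mismatch"); next
      }
      eaf_x <- ex$eaf[i]
      if (is.na(eaf_x) || is.na(eaf_y)) {
        dropped[[i]] <- c(id, "invalid_record"); next
      }
      # nominal orientation from labels, then frequency agreement check
      flipped <- ea_y != ea_x
      eaf_al <- if (flipped) 1 - eaf_y else eaf_y
      if (abs(eaf_x - 0.5) < palindrome_window ||
          abs(eaf_al - 0.5) < palindrome_window) {
        dropped[[i]] <- c(id, "ambiguous_palindrome"); next
      }
      if ((eaf_x < 0.5) != (eaf_al < 0.5)) {
        # frequencies disagree: the outcome is on the other strand, which for
        # a palindrome exchanges the alleles -> flip the nominal orientation
        flipped <- !flipped
        eaf_al <- 1 - eaf_al
      }
      if (flipped) big_gamma <- -big_gamma
      eaf_y <- eaf_al
    } else {
      direct <- identical(c(ea_y, oa_y), c(ea_x, oa_x))
      swapped <- identical(c(oa_y, ea_y), c(ea_x, oa_x))
      comp_ea <- unname(COMPLEMENT[ea_y]); comp_oa <- unname(COMPLEMENT[oa_y])
      comp_direct <- identical(c(comp_ea, comp_oa), c(ea_x, oa_x))
      comp_swapped <- identical(c(comp_oa, comp_ea), c(ea_x, oa_x))
      if (direct || comp_direct) {
        flipped <- FALSE
      } else if (swapped || comp_swapped) {
        flipped <- TRUE
        big_gamma <- -big_gamma
        if (!is.na(eaf_y)) eaf_y <- 1 - eaf_y
      } else {
        dropped[[i]] <- c(id, "allele_mismatch"); next
      }
    }
    rec[[i]] <- data.frame(
      snp_id = id, gamma = ex$beta[i], se_gamma = ex$se[i],
      big_gamma = big_gamma, se_big_gamma = out$se[j],
      eaf_exposure = ex$eaf[i], eaf_outcome = eaf_y,
      flipped = flipped, palindromic = pal, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec[!vapply(rec, is.null, logical(1L))])
  if (is.null(records)) {
    records <- data.frame(snp_id = character(), gamma = numeric(),
                          se_gamma = numeric(), big_gamma = numeric(),
                          se_big_gamma = numeric(), eaf_exposure = numeric(),
                          eaf_outcome = numeric(), flipped = logical(),
                          palindromic = logical(), stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  drops <- dropped[!vapply(dropped, is.null, logical(1L))]
  dropped_df <- if (length(drops)) {
    data.frame(snp_id = vapply(drops, `[`, "", 1L),
               reason = vapply(drops, `[`, "", 2L), stringsAsFactors = FALSE)
  } else {
    data.frame(snp_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(exposure_label = exposure$trait_label,
                 outcome_label = outcome$trait_label,
                 records = records, dropped = dropped_df),
            class = "harmonized_set")
}

#' Construct a harmonized set directly from aligned effect pairs
#'
#' Convenience constructor for already-aligned exposure/outcome effects
#' (e.g. simulation truth or unit-test toys), bypassing allele logic.
#'
#' @param gamma,se_gamma exposure effects and SEs.
#' @param big_gamma,se_big_gamma outcome effects and SEs.
#' @param snp_id optional identifiers (default `snp1..snpJ`).
#' @param exposure_label,outcome_label trait names.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(gamma, se_gamma, big_gamma, se_big_gamma,
                           snp_id = NULL, exposure_label = "exposure",
                           outcome_label = "outcome") {
  j <- length(gamma)
  stopifnot(length(se_gamma) == j, length(big_gamma) == j,
            length(se_big_gamma) == j, all(se_gamma > 0),
            all(se_big_gamma > 0))
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(j))
  records <- data.frame(snp_id = as.character(snp_id), gamma = gamma,
                        se_gamma = se_gamma, big_gamma = big_gamma,
                        se_big_gamma = se_big_gamma,
                        eaf_exposure = NA_real_, eaf_outcome = NA_real_,
                        flipped = FALSE, palindromic = FALSE,
                        stringsAsFactors = FALSE)
  structure(list(exposure_label = exposure_label,
                 outcome_label = outcome_label, records = records,
                 dropped = data.frame(snp_id = character(),
                                      reason = character(),
                                      stringsAsFactors = FALSE)),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d aligned SNPs, %d dropped\n",
              x$exposure_label, x$outcome_label, nrow(x$records),
              nrow(x$dropped)))
  if (nrow(x$dropped)) print(table(x$dropped$reason))
  invisible(x)
}

#' @export
as.data.frame.harmonized_set <- function(x, ...) x$records

check_harmonized <- function(h, min_snps = 1L, what = "estimation") {
  stopifnot(inherits(h, "harmonized_set"))
  if (nrow(h$records) < min_snps) {
    stop(sprintf("%s needs at least %d harmonized instruments (have %d)",
                 what, min_snps, nrow(h$records)), call. = FALSE)
  }
  invisible(h)
}
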