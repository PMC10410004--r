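#' Genome-wide significance filter
#'
#' Retains exactly the records with `pval < p_threshold` (strict), preserving
#' input order. The conventional instrument-selection cutoff is 5e-8.
#'
#' @param dataset a [summary_dataset].
#' @param p_threshold significance cutoff in (0, 1); default `5e-8`.
#' @return a [summary_dataset] (possibly empty).
#' @export
select_genome_wide <- function(dataset, p_threshold = 5e-8) {
  stopifnot(inherits(dataset, "summary_dataset"),
            p_threshold > 0, p_threshold < 1)
  subset_dataset(dataset, dataset$data$pval < p_threshold)
}

#' Pruning configuration
#'
#' Settings for LD/distance pruning of candidate instruments: significance
#' cutoff, maximum pairwise LD r-squared, distance window in base pairs, and
#' an optional pairwise LD matrix. Without an LD matrix only the distance
#' rule applies (what summary data alone permit).
#'
#' @param p_threshold significance cutoff (default 5e-8).
#' @param r2_max LD r-squared above which the weaker record is removed
#'   (default 0.001, i.e. remove when pairwise r² > 0.001).
#' @param window_bp distance window in base pairs (default 1e6, i.e. 1 Mb).
#' @param ld_matrix optional symmetric numeric matrix of pairwise r² with
#'   snp_id dimnames, or `NULL`.
#' @return object of class `prune_config`.
#' @export
prune_config <- function(p_threshold = 5e-8, r2_max = 0.001,
                         window_bp = 1e6, ld_matrix = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_max >= 0, r2_max < 1, window_bp >= 0)
  if (!is.null(ld_matrix)) {
    stopifnot(is.matrix(ld_matrix), !is.null(rownames(ld_matrix)),
              identical(rownames(ld_matrix), colnames(ld_matrix)))
  }
  structure(list(p_threshold = p_threshold, r2_max = r2_max,
                 window_bp = window_bp, ld_matrix = ld_matrix),
            class = "prune_config")
}

#' Read a pairwise LD table into a symmetric r-squared matrix
#'
#' Accepts a 3-column delimited table (`id_a`, `id_b`, `r2`) and returns the
#' symmetrized matrix (diagonal 1, unlisted pairs 0).
#'
#' @param path delimited file with columns id_a, id_b, r2 (header required).
#' @return symmetric numeric matrix with snp_id dimnames.
#' @export
read_ld_matrix <- function(path) {
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  if (ncol(tab) < 3L) stop("LD table needs 3 columns (id_a, id_b, r2)",
                           call. = FALSE)
  ids <- sort(unique(c(as.character(tab[[1L]]), as.character(tab[[2L]]))))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  for (i in seq_len(nrow(tab))) {
    a <- as.character(tab[i, 1L]); b <- as.character(tab[i, 2L])
    r2 <- as.numeric(tab[i, 3L])
    m[a, b] <- r2; m[b, a] <- r2
  }
  m
}

#' Prune candidate instruments for LD and distance
#'
#' Greedy clumping: repeatedly keep the remaining record with the smallest
#' p-value (ties broken by smaller SE, then lexicographic snp_id — making the
#' result independent of input order), then remove every other record on the
#' same chromosome within `window_bp` base pairs (inclusive) and, when an LD
#' matrix is supplied, every record with pairwise r² exceeding `r2_max`
#' against the kept one. Cross-chromosome pairs are never distance-pruned.
#'
#' @param dataset a [summary_dataset].
#' @param config a [prune_config].
#' @return list with `retained` (a [summary_dataset], original record order)
#'   and `removals` (data.frame `removed_id`, `kept_id`, `reason` in
#'   `{distance, ld}`).
#' @export
prune_instruments <- function(dataset, config = prune_config()) {
  stopifnot(inherits(dataset, "summary_dataset"),
            inherits(config, "prune_config"))
  d <- dataset$data
  if (!is.null(config$ld_matrix)) {
    missing_ids <- setdiff(d$snp_id, rownames(config$ld_matrix))
    if (length(missing_ids)) {
      stop("ld_matrix lacks snp_id(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
  }
  remaining <- seq_len(nrow(d))
  kept <- integer()
  removals <- list()
  ord_key <- order(d$pval, d$se, d$snp_id)
  rank <- integer(nrow(d)); rank[ord_key] <- seq_along(ord_key)
  while (length(remaining)) {
    keep <- remaining[which.min(rank[remaining])]
    kept <- c(kept, keep)
    others <- setdiff(remaining, keep)
    hit_dist <- others[d$chrom[others] == d$chrom[keep] &
                         abs(d$pos[others] - d$pos[keep]) <= config$window_bp]
    hit_ld <- integer()
    if (!is.null(config$ld_matrix)) {
      r2 <- config$ld_matrix[d$snp_id[others], d$snp_id[keep]]
      hit_ld <- setdiff(others[r2 > config$r2_max], hit_dist)
    }
    if (length(hit_dist) || length(hit_ld)) {
      removals[[length(removals) + 1L]] <- data.frame(
        removed_id = d$snp_id[c(hit_dist, hit_ld)],
        kept_id = d$snp_id[keep],
        reason = c(rep("distance", length(hit_dist)), rep("ld", length(hit_ld))),
        stringsAsFactors = FALSE)
    }
    remaining <- setdiff(others, c(hit_dist, hit_ld))
  }
  removals <- if (length(removals)) do.call(rbind, removals) else
    data.frame(removed_id = character(), kept_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(retained = subset_dataset(dataset, sort(kept)), removals = removals)
}

#' Variance in the exposure explained by a SNP
#'
#' `R² = 2 β² EAF (1 − EAF)`, the proportion of exposure variance explained
#' by a single variant under Hardy–Weinberg equilibrium and a standardized
#' trait. Returned unrounded; round to 4 decimals with [display_r2] for
#' comparison with published tables.
#'
#' @param beta per-allele effect size (vectorized).
#' @param eaf effect-allele frequency in \[0, 1\] (vectorized); missing values
#'   are an error — no imputation.
#' @return numeric vector of R² values.
#' @export
compute_r2 <- function(beta, eaf) {
  if (anyNA(eaf)) stop("compute_r2: eaf missing (no imputation)", call. = FALSE)
  stopifnot(all(eaf >= 0 & eaf <= 1))
  2 * beta^2 * eaf * (1 - eaf)
}

#' @rdname compute_r2
#' @param r2 unrounded R² values.
#' @export
display_r2 <- function(r2) round(r2, 4L)

#' Instrument-strength F-statistic
#'
#' `F = R²/(1 − R²) × (N − k − 1)/k`, where `N` is the exposure GWAS sample
#' size and `k` the number of candidate instruments at the moment F is
#' evaluated. Per-SNP F uses each SNP's own R². Values below 10 conventionally
#' flag weak instruments.
#'
#' @param r2 variance explained, in \[0, 1) (vectorized).
#' @param n sample size; must exceed `k + 1`.
#' @param k number of candidate instruments (>= 1).
#' @return numeric vector of F statistics.
#' @export
compute_f <- function(r2, n, k) {
  stopifnot(all(r2 >= 0), all(r2 < 1), k >= 1)
  if (any(n <= k + 1)) stop("compute_f: need n > k + 1", call. = FALSE)
  r2 / (1 - r2) * (n - k - 1) / k
}

#' Exclude weak instruments by F-statistic
#'
#' Grades every record with its own R² and F (using the supplied `n` and
#' `k` = the candidate-set size before exclusion, unless overridden) and
#' splits the dataset into retained (`F >= f_min`) and excluded (`F < f_min`,
#' strict) parts.
#'
#' @param dataset a [summary_dataset]; every record needs `eaf`.
#' @param n exposure GWAS sample size; defaults to the dataset's per-record /
#'   default sample sizes (which must then agree or be per-record).
#' @param f_min weak-instrument cutoff (default 10).
#' @param k instrument count plugged into F; default `n_records(dataset)`.
#' @return list with `retained`, `excluded` (both [summary_dataset]s) and
#'   `diagnostics` (data.frame `snp_id`, `r2`, `f_stat`, `weak`; attributes
#'   `n_used`, `k_used`).
#' @export
filter_weak <- function(dataset, n = NULL, f_min = 10, k = NULL) {
  stopifnot(inherits(dataset, "summary_dataset"))
  d <- dataset$data
  if (nrow(d) == 0L) {
    diag0 <- data.frame(snp_id = character(), r2 = numeric(),
                        f_stat = numeric(), weak = logical(),
                        stringsAsFactors = FALSE)
    return(list(retained = dataset, excluded = dataset, diagnostics = diag0))
  }
  if (anyNA(d$eaf)) {
    stop("filter_weak: missing eaf for ",
         paste(d$snp_id[is.na(d$eaf)], collapse = ", "), call. = FALSE)
  }
  n <- if (is.null(n)) effective_n(dataset) else rep_len(as.numeric(n), nrow(d))
  if (is.null(k)) k <- nrow(d)
  r2 <- compute_r2(d$beta, d$eaf)
  f <- compute_f(r2, n, k)
  weak <- f < f_min
  diagnostics <- data.frame(snp_id = d$snp_id, r2 = r2, f_stat = f,
                            weak = weak, stringsAsFactors = FALSE)
  attr(diagnostics, "n_used") <- n
  attr(diagnostics, "k_used") <- k
  list(retained = subset_dataset(dataset, !weak),
       excluded = subset_dataset(dataset, weak),
       diagnostics = diagnostics)
}

#' Full instrument-selection chain
#'
#' significance filter -> LD/distance pruning -> weak-instrument exclusion,
#' with a stage-by-stage audit (counts in/out and excluded ids per stage).
#'
#' @param dataset exposure [summary_dataset].
#' @param config a [prune_config].
#' @param n sample size for the F-statistic (default: dataset sample sizes).
#' @param f_min weak-instrument cutoff (default 10).
#' @return list with `instruments` (retained [summary_dataset]),
#'   `diagnostics` (from [filter_weak]), `audit` (data.frame of per-stage
#'   counts) and `excluded` (data.frame `snp_id`, `stage`).
#' @export
select_instruments <- function(dataset, config = prune_config(), n = NULL,
                               f_min = 10) {
  sig <- select_genome_wide(dataset, config$p_threshold)
  pruned <- prune_instruments(sig, config)
  weak <- filter_weak(pruned$retained, n = n, f_min = f_min)
  audit <- data.frame(
    stage = c("input", "significance", "prune", "weak_filter"),
    n_in = c(n_records(dataset), n_records(dataset), n_records(sig),
             n_records(pruned$retained)),
    n_out = c(n_records(dataset), n_records(sig), n_records(pruned$retained),
              n_records(weak$retained)),
    stringsAsFactors = FALSE)
  mk_excl <- function(ids, stage) {
    data.frame(snp_id = ids, stage = rep_len(stage, length(ids)),
               stringsAsFactors = FALSE)
  }
  excluded <- rbind(
    mk_excl(setdiff(dataset$data$snp_id, sig$data$snp_id), "significance"),
    mk_excl(pruned$removals$removed_id, "prune"),
    mk_excl(weak$excluded$data$snp_id, "weak_filter"))
  list(instruments = weak$retained, diagnostics = weak$diagnostics,
       audit = audit, excluded = excluded, removals = pruned$removals)
}
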