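# Independent oracle implementations and fixture builders. These deliberately
# use different code paths from the package internals they check.

# weighted median by explicit cumulative-weight walk with interpolation
oracle_weighted_median <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]
  p <- w[ord] / sum(w)
  s <- numeric(length(p))
  run <- 0
  for (i in seq_along(p)) {
    s[i] <- run + p[i] / 2
    run <- run + p[i]
  }
  below <- which(s < 0.5)
  if (!length(below)) return(th[1L])
  i <- max(below)
  if (i == length(th)) return(th[length(th)])
  th[i] + (th[i + 1L] - th[i]) * (0.5 - s[i]) / (s[i + 1L] - s[i])
}

# weighted least squares via explicit normal equations
oracle_wls <- function(X, y, w) {
  X <- as.matrix(X)
  W <- diag(w, nrow = length(w))
  drop(solve(t(X) %*% W %*% X, t(X) %*% W %*% y))
}

# dense-grid argmax of the weighted kernel density
oracle_mode <- function(theta, w, bw, n_grid = 8192L) {
  grid <- seq(min(theta), max(theta), length.out = n_grid)
  dens <- sapply(grid, function(x) sum(w * dnorm(x, theta, bw)))
  grid[which.max(dens)]
}

# random valid summary dataset
random_dataset <- function(n, seed, label = "random_trait") {
  set.seed(seed)
  pairs <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
  al <- t(sapply(seq_len(n), function(i) pairs[[sample.int(4L, 1L)]]))
  summary_dataset(data.frame(
    snp_id = sprintf("rs%06d", sample.int(1e6, n)),
    chrom = as.character(sample.int(22L, n, replace = TRUE)),
    pos = sample.int(1e8, n),
    effect_allele = al[, 1L], other_allele = al[, 2L],
    eaf = runif(n, 0.05, 0.95),
    beta = rnorm(n, 0, 0.1), se = runif(n, 0.005, 0.05),
    pval = runif(n, .Machine$double.xmin, 1),
    n = sample.int(5e5, n), stringsAsFactors = FALSE), label)
}

# synthetic outcome generated from an exposure dataset under a linear causal
# model with effect theta (same alleles/frequencies; outcome-scale SEs)
make_outcome_from <- function(exposure, theta, n_outcome = 472174, seed = 1) {
  set.seed(seed)
  d <- exposure$data
  se_y <- 1 / sqrt(2 * n_outcome * d$eaf * (1 - d$eaf))
  by <- rnorm(nrow(d), theta * d$beta, se_y)
  summary_dataset(data.frame(
    snp_id = d$snp_id, chrom = d$chrom, pos = d$pos,
    effect_allele = d$effect_allele, other_allele = d$other_allele,
    eaf = d$eaf, beta = by, se = se_y,
    pval = pmax(2 * pnorm(-abs(by / se_y)), .Machine$double.xmin),
    n = n_outcome, stringsAsFactors = FALSE),
    paste0("synthetic_outcome_theta", theta), default_n = n_outcome)
}

# quick harmonized toy from ratio estimates: gamma = 1 so theta_j = big_gamma
toy_from_ratios <- function(theta, sigma) {
  harmonized_set(gamma = rep(1, length(theta)),
                 se_gamma = rep(1e-6, length(theta)),
                 big_gamma = theta, se_big_gamma = sigma)
}
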