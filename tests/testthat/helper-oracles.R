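# Independent oracles used across the suite. Each is a direct transcription
# of the defining formula, kept deliberately naive and separate from the
# package's implementation path.

# BH step-up by definition: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1,
# computed with an explicit per-element minimum over the upper tail.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))),
               numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}

# Hypergeometric upper tail by combinatorial enumeration over all draws
# with overlap >= k.
hyper_oracle <- function(N, K, n, k) {
  hi <- min(n, K)
  if (k > hi) stop("impossible k")
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# Welch's t-test p-value from the textbook formulas.
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Pearson correlation from the covariance / sd definition.
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# FPKM by spreadsheet-style evaluation of the definition, cell by cell.
fpkm_oracle <- function(counts, lengths) {
  out <- counts * NA_real_
  lib <- colSums(counts)
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts)))
      out[i, j] <- counts[i, j] * 1e9 / (lengths[i] * lib[j])
  out
}

# small planted fixture shared by DE-level tests
small_sim <- function(seed = 42, ...) {
  gen_count_matrix(de_truth(n_genes = 200, lib_sizes = rep(5e5, 6),
                            seed = seed, ...))
}
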