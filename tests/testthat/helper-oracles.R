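# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use naive loops / pairwise sums so
# they share no code path with the functions under test.

# Shannon entropy by direct summation.
bf_entropy <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log(v)
  s
}

# BALD = H(mean) - mean per-row H, from the sample matrix.
bf_bald <- function(samples) {
  mean_p <- colMeans(samples)
  row_h <- numeric(nrow(samples))
  for (t in seq_len(nrow(samples))) row_h[t] <- bf_entropy(samples[t, ])
  bf_entropy(mean_p) - mean(row_h)
}

# Percentile by sorted-list linear interpolation between closest ranks
# (inclusive endpoints).
bf_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# ROC AUC as the Mann-Whitney pair statistic (ties count 1/2).
bf_auc_pairs <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(pos) * length(neg))
}

# Random row-stochastic matrix.
random_posterior <- function(T, M) {
  x <- matrix(rexp(T * M), T, M)
  x / rowSums(x)
}
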