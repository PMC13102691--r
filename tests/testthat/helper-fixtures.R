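# Small shared fixtures; everything generated in code.

fixture_cortex <- function(n = 120, seed = 1)
  make_toy_cortex(n, n_networks = 5, n_parcels = 15,
                  medial_fraction = 0.05, seed = seed)

fixture_truth <- function(cortex = fixture_cortex()) planted_truth(cortex)

abs_cos <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# independent brute-force oracles ---------------------------------------

oracle_pearson <- function(ts) {
  n <- ncol(ts)
  out <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- ts[, i]; y <- ts[, j]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    out[i, j] <- out[j, i] <- r
  }
  out
}

oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  thresh <- q * seq_len(m) / m
  passed <- which(p[ord] <= thresh)
  reject <- rep(FALSE, m)
  if (length(passed)) reject[ord[seq_len(max(passed))]] <- TRUE
  reject
}

oracle_percentile <- function(x, p) {
  # linear interpolation between order statistics (type-7 definition)
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

zscore_for_test <- function(x) (x - mean(x)) / sd(x)
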