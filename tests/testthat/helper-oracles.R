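# Independent oracles, deliberately written on different code paths than
# the package (brute force on raw values, no ranks, no vectorised identities).

# exhaustive two-sided Mann-Whitney: enumerate every assignment of the
# pooled values to group A, count (a > b) pairs plus half ties by double
# loop, and take the permutation tail probability of |U - n_a n_b / 2|
oracle_u_stat <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) {
    if (x > y) u <- u + 1 else if (x == y) u <- u + 0.5
  }
  u
}

oracle_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  mu <- n_a * length(b) / 2
  u_obs <- oracle_u_stat(a, b)
  splits <- utils::combn(length(pooled), n_a)
  us <- apply(splits, 2, function(idx) {
    oracle_u_stat(pooled[idx], pooled[-idx])
  })
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# textbook Benjamini-Hochberg step-up, written directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    adj_sorted[i] <- min(adj_sorted[i], adj_sorted[i + 1])
  }
  adj <- numeric(m)
  adj[ord] <- pmin(adj_sorted, 1)
  adj
}

# quantile at position (n-1)p by explicit sort-and-interpolate, plus
# box-and-whisker outer limits, independent of stats::quantile
oracle_quartile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}

oracle_limits <- function(x, method) {
  q1 <- oracle_quartile(x, 0.25)
  q3 <- oracle_quartile(x, 0.75)
  iqr <- q3 - q1
  lo_f <- q1 - 1.5 * iqr
  hi_f <- q3 + 1.5 * iqr
  if (method == "fence") c(lo_f, hi_f)
  else {
    inside <- x[x >= lo_f & x <= hi_f]
    c(min(inside), max(inside))
  }
}
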