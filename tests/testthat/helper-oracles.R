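# Independent oracles, kept deliberately separate from the package's
# computational paths.

# Welch statistic/df/p recomputed directly from the textbook formulas.
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  s1 <- sum((x - sum(x) / n1)^2) / (n1 - 1)
  s2 <- sum((y - sum(y) / n2)^2) / (n2 - 1)
  a <- s1 / n1; b <- s2 / n2
  stat <- (sum(x) / n1 - sum(y) / n2) / sqrt(a + b)
  df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  list(statistic = stat, df = df, p = 2 * pt(-abs(stat), df))
}

# Exact WMW two-sided p by brute-force enumeration, computing U for every
# assignment from pairwise comparisons (not ranks).
oracle_wmw_enum <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(N, n1), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Bisection on the lognormal skewness equation, independent of uniroot.
oracle_lognormal_sigma <- function(skew, iters = 200) {
  lo <- 1 + 1e-14; hi <- 1e6
  g <- function(w) (w + 2) * sqrt(w - 1) - skew
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  sqrt(log((lo + hi) / 2))
}

sample_skewness <- function(v) {
  m <- mean(v)
  mean((v - m)^3) / mean((v - m)^2)^1.5
}

# Estimate a statistic and its Monte-Carlo SE from disjoint batches.
batch_estimate <- function(v, nbatch, stat) {
  b <- matrix(v, ncol = nbatch)
  ests <- apply(b, 2, stat)
  list(est = mean(ests), se = sd(ests) / sqrt(nbatch))
}

# Half-width of the central normal band for a proportion estimated from R
# replications (z = 2.576 for 99%, 3.29 for 99.9%).
prop_band <- function(p, R, z) z * sqrt(p * (1 - p) / R)

# 3 x combined Monte-Carlo SE tolerance for comparing an estimated
# percentage with a printed percentage, both at their replication counts.
combined_tol_pct <- function(printed_pct, R_est, R_printed = 10000) {
  p1 <- printed_pct / 100
  3 * 100 * sqrt(p1 * (1 - p1) / R_printed + p1 * (1 - p1) / R_est)
}
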