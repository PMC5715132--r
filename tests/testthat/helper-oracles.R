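# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths.

# Pearson chi-square statistic on a groups x 2 count matrix, from the
# definition.
pearson_chisq_direct <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Benjamini-Hochberg step-up, from the definition (no p.adjust).
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# 2x2 chi-square p-value for a responded/tested pair of groups.
chisq_p_2x2 <- function(x1, n1, x2, n2) {
  m <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  suppressWarnings(stats::chisq.test(m, correct = FALSE))$p.value
}

# Exact Clopper-Pearson coverage at a given p and n, by enumeration of
# the full binomial support (no simulation error).
cp_coverage_exact <- function(p, n, conf = 0.95) {
  cover <- vapply(0:n, function(x) {
    ci <- perkin::proportion_ci(x, n, conf)
    as.numeric(p >= ci[["lower"]] && p <= ci[["upper"]])
  }, numeric(1))
  sum(stats::dbinom(0:n, n, p) * cover)
}

# One-way ANOVA F statistics for many simulated datasets at once.
# groups: k, per-group n, means: length-k vector, unit variance.
simulate_anova_F <- function(n_sims, k, n_per, means) {
  N <- k * n_per
  g <- rep(seq_len(k), each = n_per)
  X <- matrix(stats::rnorm(N * n_sims, mean = rep(means[g], n_sims)),
              nrow = N)
  gm <- rowsum(X, g) / n_per                  # k x n_sims group means
  tot <- colMeans(X)
  ssb <- n_per * colSums((gm - matrix(tot, k, n_sims, byrow = TRUE))^2)
  ssw <- colSums((X - gm[g, ])^2)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# A rectangular test pulse as a distance trace.
pulse_trace <- function(n = 400, from = 101, to = 160, height = 10,
                        fr = 200) {
  d <- numeric(n)
  d[from:to] <- height
  perkin::distance_trace(d, fr)
}
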