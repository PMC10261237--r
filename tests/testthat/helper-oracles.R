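# Independent oracles and fixture builders used across the suite.
# Each oracle deliberately avoids the code path it checks.

# Mann-Whitney AUC by exhaustive pair enumeration, ties counting one half.
oracle_auc <- function(pos_scores, neg_scores) {
  cmp <- outer(pos_scores, neg_scores, function(x, y) {
    (x > y) + 0.5 * (x == y)
  })
  mean(cmp)
}

# DeLong placement variance by explicit comparison loops (no ranks).
oracle_delong_se <- function(pos_scores, neg_scores) {
  m <- length(pos_scores); n <- length(neg_scores)
  v10 <- vapply(pos_scores, function(x) {
    (sum(neg_scores < x) + 0.5 * sum(neg_scores == x)) / n
  }, numeric(1))
  v01 <- vapply(neg_scores, function(y) {
    (sum(pos_scores > y) + 0.5 * sum(pos_scores == y)) / m
  }, numeric(1))
  s10 <- if (m > 1) stats::var(v10) else 0  # singleton class: no variance info
  s01 <- if (n > 1) stats::var(v01) else 0
  sqrt(s10 / m + s01 / n)
}

# Least squares through the normal equations, independent of stats::lm.
oracle_lsq <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# Paired cohort with lognormal scores by index class; AUC has the closed
# form pnorm(delta / sqrt(2)) for unit-variance log-scores.
make_lognormal_pairs <- function(n_pos, n_neg, delta) {
  ref <- c(exp(rnorm(n_pos, mean = delta)), exp(rnorm(n_neg, mean = 0)))
  paired_samples(ref, rep(c(1L, 0L), c(n_pos, n_neg)))
}

random_pairs <- function(n, tie_grid = NULL) {
  ref <- runif(n, 0, 10)
  if (!is.null(tie_grid) && !is.na(tie_grid)) {
    ref <- round(ref, tie_grid)  # induce score ties
  }
  paired_samples(ref, rbinom(n, 1, 0.5))
}
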