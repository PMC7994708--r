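## Independent brute-force oracles and small fixture builders used across the
## suite. These deliberately avoid the package's own code paths.

## Average ranks computed by counting, not via rank()
rank_by_hand <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, 0)
}

## Spearman correlation as product-moment correlation of hand-computed ranks
spearman_oracle <- function(x, y) {
  rx <- rank_by_hand(x)
  ry <- rank_by_hand(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## Pearson correlation by the textbook formula
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

## Partial correlations via nodewise regression on a population correlation
## matrix: w_ij = sign(beta_ij) * sqrt(beta_ij * beta_ji)
pcor_nodewise_oracle <- function(C) {
  p <- ncol(C)
  Beta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    Beta[j, -j] <- solve(C[-j, -j], C[-j, j])
  }
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      W[i, j] <- W[j, i] <- sign(Beta[i, j]) * sqrt(Beta[i, j] * Beta[j, i])
    }
  }
  dimnames(W) <- dimnames(C)
  W
}

## OLS R^2 of each node on all others, from the correlation matrix
r2_ols_oracle <- function(C) {
  p <- ncol(C)
  vapply(seq_len(p), function(j) {
    r <- C[-j, j]
    as.numeric(crossprod(r, solve(C[-j, -j], r)))
  }, 0)
}

## Random positive-definite correlation matrix (Wishart-style)
rand_pd_cor <- function(p, n = 5 * p) {
  X <- matrix(stats::rnorm(n * p), n, p)
  stats::cov2cor(crossprod(X) / n)
}

## Draw n rows from N(0, Sigma) via Cholesky
rmvn <- function(n, Sigma) {
  p <- ncol(Sigma)
  matrix(stats::rnorm(n * p), n, p) %*% chol(Sigma)
}

## Small complete ordinal panel with deterministic scores
toy_panel <- function(n = 6, waves = 3, p = 3, seed = 42) {
  set.seed(seed)
  sc <- array(sample(0:4, n * waves * p, replace = TRUE),
              dim = c(n, waves, p))
  symptom_panel(sc, subject_ids = sprintf("s%02d", seq_len(n)))
}

## Sparse 11-node partial-correlation matrix used in several simulations
chain_pcor <- function(p = 11, w = 0.12) {
  P <- matrix(0, p, p)
  for (i in seq_len(p - 1)) P[i, i + 1] <- P[i + 1, i] <- w
  P[1, p] <- P[p, 1] <- w
  P
}
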