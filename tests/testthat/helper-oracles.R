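# Independent oracles and small fixture builders used across the suite.

# ridge solution via the augmented least-squares system [W; sqrt(nu) I] x = [Y; 0]
ridge_oracle <- function(W, Y, nu) {
  k <- ncol(W)
  A <- rbind(W, sqrt(nu) * diag(k))
  B <- rbind(Y, matrix(0, k, ncol(Y)))
  qr.solve(A, B)
}

# largest principal angle (radians, small-angle regime) between the column
# spaces of A and B, via the orthogonal-projection residual: sin(theta) =
# ||(I - Qa Qa') Qb||_2, which resolves angles near machine precision where
# the arccos of a near-1 cosine cannot
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  resid <- qb - qa %*% crossprod(qa, qb)
  asin(min(1, svd(resid)$d[1]))
}

# brute-force Pearson correlation from first principles
pearson_oracle <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) /
    sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
}

# named random samples-by-genes matrix
rand_expr <- function(m, n, sd = 1) {
  matrix(rnorm(m * n, sd = sd), m, n,
         dimnames = list(paste0("s", seq_len(m)), paste0("g", seq_len(n))))
}

# correlation_set from an explicit symmetric matrix with unit diagonal
corr_set <- function(vals, ids = NULL, m = 10) {
  n <- nrow(vals)
  if (is.null(ids)) ids <- paste0("g", seq_len(n))
  dimnames(vals) <- list(ids, ids)
  correlation_set(vals, m_samples = m)
}

# symmetric matrix from the upper-triangle values (column-major pair order)
sym_from_upper <- function(n, upper) {
  M <- diag(n)
  M[upper.tri(M)] <- upper
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

# small default-structure simulation for fast end-to-end tests
small_sim <- function(seed = 1, ...) {
  simulate_coexpression(simulation_design(
    m = 60, n = 120, n_signal = 60, n_blocks = 6, seed = seed, ...))
}

# disease-module scenario for prioritization checks: a small co-regulated
# module inside a mostly-uncorrelated transcriptome (keeps the random-gene
# null honest), with tight co-regulation and robust expression
disease_module_design <- function(seed, ...) {
  simulation_design(m = 180, n = 500, n_signal = 50, n_blocks = 2,
                    within_block_corr = 0.6, loading_range = c(0.6, 1.0),
                    seed = seed, ...)
}
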