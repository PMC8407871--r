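# Internal numerical helpers.

# Row-wise log-sum-exp of a matrix; returns a vector of length nrow(m).
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Pack/unpack an unconstrained parameterization of a d x d covariance
# matrix via its lower Cholesky factor: log-diagonals, free off-diagonals
# (column-major order of the lower triangle).
chol_npar <- function(d) d * (d + 1L) / 2L

theta_to_chol <- function(theta, d) {
  L <- matrix(0, d, d)
  k <- 1L
  for (j in seq_len(d)) {
    for (i in j:d) {
      L[i, j] <- if (i == j) exp(theta[k]) else theta[k]
      k <- k + 1L
    }
  }
  L
}

chol_to_theta <- function(L) {
  d <- nrow(L)
  out <- numeric(chol_npar(d))
  k <- 1L
  for (j in seq_len(d)) {
    for (i in j:d) {
      out[k] <- if (i == j) log(max(L[i, j], 1e-10)) else L[i, j]
      k <- k + 1L
    }
  }
  out
}

# Lower Cholesky of a covariance given componentwise entries (vectorized
# over subjects): s11, s21, s22 are N-vectors.
chol2_vec <- function(s11, s21, s22) {
  c11 <- sqrt(s11)
  c21 <- s21 / c11
  c22 <- sqrt(pmax(s22 - c21^2, 1e-300))
  list(c11 = c11, c21 = c21, c22 = c22)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
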