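# Independent oracle for the constrained inverse problem: an accelerated
# projected-gradient (FISTA) minimizer of sum_t ||n(t+1) - M n(t)||^2 over
# the same feasible set (entries >= 0, per-column survival sums <= 1),
# coded without reference to the package's QP route.

# Euclidean projection of v onto the probability simplex {x >= 0, sum x = s}
proj_simplex <- function(v, s = 1) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u) - s
  rho <- max(which(u - css / seq_along(u) > 0))
  tau <- css[rho] / rho
  pmax(v - tau, 0)
}

# projection onto {x >= 0, sum x <= s}
proj_capped_nonneg <- function(v, s = 1) {
  x <- pmax(v, 0)
  if (sum(x) <= s) x else proj_simplex(v, s)
}

# project a parameter vector (in structure-arc order) onto the feasible set
project_feasible <- function(theta, structure) {
  a <- structure$arcs
  out <- pmax(theta, 0)
  for (j in seq_len(structure$n_classes)) {
    idx <- which(a$source == j & a$role %in% c("stasis", "growth", "shrinkage"))
    if (length(idx) > 0) out[idx] <- proj_capped_nonneg(theta[idx], 1)
  }
  out
}

# FISTA on f(theta) = ||A theta - y||^2; returns theta and objective
pg_oracle <- function(series, structure, iters = 20000) {
  a <- structure$arcs
  k <- structure$n_classes
  p <- nrow(a)
  nt <- ncol(series) - 1L
  A <- matrix(0, k * nt, p)
  y <- numeric(k * nt)
  for (t in seq_len(nt)) {
    for (i in seq_len(k)) {
      row <- (t - 1L) * k + i
      y[row] <- series[i, t + 1L]
      for (g in seq_len(p)) {
        if (a$target[g] == i) A[row, g] <- series[a$source[g], t]
      }
    }
  }
  AtA <- crossprod(A)
  Aty <- crossprod(A, y)
  L <- 2 * max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) L <- 1
  theta <- z <- numeric(p)
  tk <- 1
  for (it in seq_len(iters)) {
    grad <- 2 * (AtA %*% z - Aty)
    theta_new <- project_feasible(as.numeric(z - grad / L), structure)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- theta_new + (tk - 1) / tk_new * (theta_new - theta)
    theta <- theta_new
    tk <- tk_new
  }
  obj <- sum((A %*% theta - y)^2)
  list(theta = theta, objective = obj)
}

# brute-force one projection step: plain per-entry dot product
slow_matvec <- function(M, n) {
  k <- nrow(M)
  out <- numeric(k)
  for (i in seq_len(k)) {
    acc <- 0
    for (j in seq_len(k)) acc <- acc + M[i, j] * n[j]
    out[i] <- acc
  }
  out
}
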