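# Independent oracles used across the suite.

# Cyclic coordinate-descent solver for the orthant-constrained QP
#   min_x (b - x)' W (b - x)  s.t.  sign * x >= 0.
# Independent of the package's face-enumeration solver.
cd_orthant <- function(b, W, sign = 1, max_iter = 20000,
                       tol = 1e-14) {
  x <- sign * pmax(sign * b, 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in 1:4) {
      xj <- b[j] - sum(W[j, -j] * (x[-j] - b[-j])) / W[j, j]
      xj <- if (sign > 0) max(xj, 0) else min(xj, 0)
      delta <- max(delta, abs(xj - x[j]))
      x[j] <- xj
    }
    if (delta < tol) break
  }
  list(x = x, qdist = drop(t(b - x) %*% W %*% (b - x)))
}

cd_cone <- function(b, W) {
  nn <- cd_orthant(b, W, 1)
  np <- cd_orthant(b, W, -1)
  if (nn$qdist <= np$qdist) nn else np
}

# Generic delete-1 pseudo-value jackknife for an arbitrary statistic of
# row indices; recomputes from scratch for every leave-one-out set.
jackknife_oracle <- function(n, stat_fn) {
  full <- stat_fn(seq_len(n))
  ps <- t(vapply(seq_len(n), function(i)
    n * full - (n - 1) * stat_fn(setdiff(seq_len(n), i)),
    numeric(length(full))))
  center <- colMeans(ps)
  dev <- sweep(ps, 2L, center)
  crossprod(dev) / (n * (n - 1))
}

# random symmetric positive-definite 4x4
random_pd4 <- function() {
  A <- matrix(rnorm(16), 4L)
  crossprod(A) + diag(0.05, 4L)
}

# random all-positive 3x3 count table
random_table3 <- function(n = 900) {
  p <- matrix(rexp(9) + 0.2, 3L)
  p <- p / sum(p)
  tab <- matrix(as.numeric(rmultinom(1, n, as.vector(p))), 3L)
  tab + (tab == 0) * 0.5
}

# subset a posterior_matrix by row indices
post_subset <- function(post, idx) {
  posterior_matrix(post$pG[idx, , drop = FALSE],
                   post$pH[idx, , drop = FALSE])
}
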