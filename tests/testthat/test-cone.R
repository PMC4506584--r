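test_that("cone projection handles interior points and ties", {
  pr <- project_to_cone(c(1, 1, 1, 1), diag(4))
  expect_equal(unname(pr$beta_star), c(1, 1, 1, 1))
  expect_equal(pr$qdist, 0)
  expect_equal(pr$active_dim, 4L)

  # equidistant from both orthants: tie breaks to the nonnegative one
  pr <- project_to_cone(c(1, -1, 0, 0), diag(4))
  expect_equal(unname(pr$beta_star), c(1, 0, 0, 0))
  expect_equal(pr$qdist, 1)
  expect_equal(pr$active_dim, 1L)

  pr <- project_to_cone(c(-2, -1, -3, -0.5), random_pd4())
  expect_equal(unname(pr$beta_star), c(-2, -1, -3, -0.5))
  expect_equal(pr$qdist, 0)
})

test_that("face enumeration agrees with an iterative QP solver", {
  set.seed(17)
  for (k in 1:300) {
    b <- rnorm(4, sd = 2)
    V <- random_pd4()
    W <- solve(V)
    pr <- project_to_cone(b, V)
    oracle <- cd_cone(b, W)
    expect_equal(pr$qdist, oracle$qdist, tolerance = 1e-8)
    expect_equal(unname(pr$beta_star), oracle$x, tolerance = 1e-6)
  }
})

test_that("single-orthant weights at V = identity are binomial(4, 1/2)", {
  w <- chibar_weights(diag(4), mc_draws = 100000, seed = 4,
                      cone = "nonnegative")
  expected <- choose(4, 0:4) / 16
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_true(all(abs(w$w - expected) <= 3 * se))
  expect_equal(sum(w$w), 1)
})

test_that("weights are scale invariant and deterministic given a seed", {
  V <- random_pd4()
  w1 <- chibar_weights(V, 5000, seed = 8)
  w2 <- chibar_weights(5 * V, 5000, seed = 8)
  w3 <- chibar_weights(V, 5000, seed = 8)
  expect_identical(w1$w, w2$w)
  expect_identical(w1$w, w3$w)
  expect_equal(sum(w1$w), 1)
  expect_error(chibar_weights(V, 500), "at least 1000")
})

test_that("chi-bar mixture is exact on a single orthant cone", {
  # classical chi-bar-square theorem: for a convex cone the squared
  # projection norm is exactly the weight mixture
  set.seed(33)
  V <- random_pd4()
  W <- solve(V)
  w <- chibar_weights(V, mc_draws = 50000, seed = 12,
                      cone = "nonnegative")
  ndraw <- 20000
  L <- t(chol(V))
  stats <- numeric(ndraw)
  for (i in seq_len(ndraw)) {
    z <- drop(L %*% rnorm(4))
    full <- drop(t(z) %*% W %*% z)
    stats[i] <- full - project_to_cone(z, V,
                                       cone = "nonnegative")$qdist
  }
  for (t0 in c(1, 2.7, 5, 9)) {
    emp <- mean(stats >= t0)
    mix <- sum(w$w[2:5] * pchisq(t0, 1:4, lower.tail = FALSE))
    se <- sqrt(emp * (1 - emp) / ndraw) + 0.002
    expect_lt(abs(emp - mix), 3 * se)
  }
})

test_that("union-cone tail approximation is a tightening upper bound", {
  # the constrained statistic on the union of orthants is the larger of
  # the two orthant projections; the doubled union-weight mixture used
  # for p-values equals the Bonferroni sum of the two orthant chi-bar
  # tails, hence bounds the true tail from above by exactly the
  # (vanishing) overlap probability P(both orthant stats >= t)
  set.seed(34)
  V <- random_pd4()
  W <- solve(V)
  w_u <- chibar_weights(V, 50000, seed = 13)
  w_nn <- chibar_weights(V, 50000, seed = 14, cone = "nonnegative")
  w_np <- chibar_weights(V, 50000, seed = 15, cone = "nonpositive")
  # union weights are the average of the two orthant laws
  expect_equal(w_u$w, (w_nn$w + w_np$w) / 2, tolerance = 0.01)
  mixtail <- function(w, t0)
    sum(w$w[2:5] * pchisq(t0, 1:4, lower.tail = FALSE))
  ndraw <- 20000
  L <- t(chol(V))
  stats <- numeric(ndraw)
  for (i in seq_len(ndraw)) {
    z <- drop(L %*% rnorm(4))
    stats[i] <- drop(t(z) %*% W %*% z) - project_to_cone(z, V)$qdist
  }
  excess <- numeric(0)
  for (t0 in c(1, 2.7, 5, 9)) {
    emp <- mean(stats >= t0)
    se <- sqrt(max(emp * (1 - emp), 1e-4) / ndraw) + 0.002
    ptail <- min(1, 2 * mixtail(w_u, t0))
    # conservative: approximation never understates the tail ...
    expect_gte(ptail + 3 * se, emp)
    # ... and overshoots by at most the smaller orthant tail
    expect_lte(ptail - emp,
               min(mixtail(w_nn, t0), mixtail(w_np, t0)) + 3 * se)
    excess <- c(excess, ptail - emp)
  }
  expect_lt(excess[4], 0.01)  # tight where testing happens
})
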