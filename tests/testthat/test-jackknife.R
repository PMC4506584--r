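# emulated posteriors shared by several blocks
jk_post <- local({
  set.seed(101)
  dist <- case_joint_distribution(penetrance_model("multiplicative"),
                                  0.3, 0.3)
  gh <- sample_cases(dist, 300)
  emulate_imputation(gh$G, gh$H,
                     imputation_config(0.3, r = 0.9),
                     imputation_config(0.3, r = 0.8))
})

test_that("grouped and ungrouped jackknife agree", {
  Vg <- jackknife_variance(jk_post, grouping = TRUE)
  Vu <- jackknife_variance(jk_post, grouping = FALSE)
  expect_equal(unname(Vg), unname(Vu), tolerance = 1e-12)
})

test_that("jackknife matches a from-scratch recomputation oracle", {
  set.seed(55)
  gh <- sample_cases(matrix(1/9, 3, 3), 40)
  post <- emulate_imputation(gh$G, gh$H,
                             imputation_config(0.4, r = 0.7),
                             imputation_config(0.4, r = 0.7))
  V <- jackknife_variance(post, grouping = FALSE)
  Vo <- jackknife_oracle(post$n, function(idx)
    as.numeric(estimate_beta(build_expected_table(
      post_subset(post, idx)))))
  expect_equal(unname(V), unname(Vo), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pseudo-value jackknife of a mean is the sample covariance / n", {
  set.seed(77)
  X <- matrix(rnorm(120), 30, 4)
  V <- jackknife_oracle(30, function(idx) colMeans(X[idx, ]))
  expect_equal(V, cov(X) / 30, tolerance = 1e-12)
})

test_that("jackknife is consistent for the analytic variance on hard calls", {
  set.seed(88)
  gh <- sample_cases(matrix(1/9, 3, 3), 5000)
  post <- as_posterior(gh$G, gh$H)
  Vj <- jackknife_variance(post)
  Va <- analytic_variance(build_count_table(gh$G, gh$H))
  expect_true(all(abs(diag(Vj) / diag(Va) - 1) < 0.10))
  # PSD by construction
  expect_gte(min(eigen((Vj + t(Vj)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
})

test_that("jackknife is invariant to shuffling individuals", {
  set.seed(99)
  idx <- sample(jk_post$n)
  Vp <- jackknife_variance(post_subset(jk_post, idx))
  V <- jackknife_variance(jk_post)
  expect_equal(unname(V), unname(Vp), tolerance = 1e-12)
})

test_that("jackknife guards its preconditions", {
  gh <- list(G = rep(0:2, 2), H = rep(0:2, 2))
  expect_error(jackknife_variance(as_posterior(gh$G, gh$H)),
               "at least 9")
  # one observation per cell: every leave-one-out table has a zero
  g <- rep(0:2, each = 3); h <- rep(0:2, 3)
  post <- as_posterior(g, h)
  expect_error(jackknife_variance(post), "leave-one-out")
  expect_silent(jackknife_variance(post, zero_policy = "haldane"))
})

test_that("row grouping identifies categorical posteriors", {
  gr <- unique_row_groups(jk_post, tol = 0)
  expect_lte(length(gr$group_sizes), 9L)
  expect_equal(sum(gr$group_sizes), jk_post$n)
  expect_identical(gr$group_ids,
                   unique_row_groups(jk_post, tol = 1e-12)$group_ids)

  set.seed(6)
  pg <- matrix(rexp(60), 20, 3); pg <- pg / rowSums(pg)
  ph <- matrix(rexp(60), 20, 3); ph <- ph / rowSums(ph)
  gr2 <- unique_row_groups(posterior_matrix(pg, ph), tol = 0)
  expect_equal(length(gr2$group_sizes), 20L)
})
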