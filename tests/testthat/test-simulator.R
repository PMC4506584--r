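test_that("penetrance tables follow the union/intersection set logic", {
  f <- 0.02; g <- 0.01
  tab <- penetrance_table(penetrance_model("DnD", f = f, g = g))
  expect_true(all(tab[2:3, 2:3] == f))
  expect_true(all(tab[1, ] == g) && all(tab[, 1] == g))

  tab <- penetrance_table(penetrance_model("RnR", f = f, g = g))
  expect_equal(sum(tab == f), 1)
  expect_equal(tab[3, 3], f)

  tab <- penetrance_table(penetrance_model("DuD", f = f, g = g))
  expect_equal(sum(tab == g), 1)
  expect_equal(tab[1, 1], g)

  tab <- penetrance_table(penetrance_model("RuR", f = f, g = g))
  expect_true(all(tab[3, ] == f) && all(tab[, 3] == f))
  expect_true(all(tab[1:2, 1:2] == g))

  tab <- penetrance_table(penetrance_model("DuR", f = f, g = g))
  expect_true(all(tab[2:3, ] == f) && all(tab[1, 3] == f))
  expect_true(all(tab[1, 1:2] == g))

  tab <- penetrance_table(penetrance_model("RnD", f = f, g = g))
  expect_true(all(tab[3, 2:3] == f))
  expect_equal(sum(tab == f), 2)

  tab <- penetrance_table(penetrance_model("multiplicative",
                                           mu = 0.02))
  expect_true(all(tab == 0.02))

  expect_error(penetrance_model("DnD", f = 0.01, g = 0.02),
               "smaller than f")
})

test_that("multiplicative penetrances give an exactly rank-1 case law", {
  for (mafs in list(c(0.1, 0.4), c(0.3, 0.3), c(0.5, 0.2))) {
    m <- penetrance_model("multiplicative", mu = 0.005,
                          alpha = c(1, 1.4, 1.9), gamma = c(1, 0.8, 0.7))
    dist <- case_joint_distribution(m, mafs[1], mafs[2])
    expect_equal(unname(estimate_beta(dist)), rep(0, 4),
                 tolerance = 1e-12)
  }
})

test_that("RnR perturbs exactly one local log odds ratio by log(f/g)", {
  dist <- case_joint_distribution(
    penetrance_model("RnR", f = 0.02, g = 0.01), 0.3, 0.3)
  b <- estimate_beta(dist)
  expect_equal(unname(b), c(0, 0, 0, log(2)), tolerance = 1e-12)
})

test_that("all epistasis kinds give one-signed interaction vectors", {
  kinds <- c("DuD", "RuR", "DuR", "RnD", "RnR", "DnD")
  for (kind in kinds)
    for (fg in list(c(0.02, 0.01), c(0.3, 0.05), c(0.011, 0.01)))
      for (mafs in list(c(0.1, 0.3), c(0.5, 0.25))) {
        dist <- case_joint_distribution(
          penetrance_model(kind, f = fg[1], g = fg[2]),
          mafs[1], mafs[2])
        b <- estimate_beta(dist)
        expect_true(all(b >= -1e-12) || all(b <= 1e-12),
                    label = paste(kind, fg[1], fg[2]))
      }
})

test_that("case sampling is seeded and hits multinomial frequencies", {
  u <- matrix(1/9, 3, 3)
  s1 <- sample_cases(u, 100, seed = 5)
  s2 <- sample_cases(u, 100, seed = 5)
  expect_identical(s1, s2)

  s <- sample_cases(u, 1e6, seed = 6)
  freq <- build_count_table(s$G, s$H) / 1e6
  expect_true(all(abs(freq - 1/9) < 0.002))

  s1 <- sample_cases(u, 1, seed = 7)
  expect_true(s1$G %in% 0:2 && s1$H %in% 0:2)
})

test_that("a perfect tag yields degenerate posteriors at the truth", {
  set.seed(31)
  gh <- sample_cases(matrix(1/9, 3, 3), 200)
  cfg <- imputation_config(0.3, r = 1)
  post <- emulate_imputation(gh$G, gh$H, cfg, cfg)
  expect_equal(post$pG[cbind(1:200, gh$G + 1L)], rep(1, 200))
  expect_equal(imputation_info(post, gh$G, "G"), 1)
})

test_that("an uninformative tag returns the panel's HWE prior", {
  set.seed(32)
  gh <- sample_cases(matrix(1/9, 3, 3), 300)
  cfg <- imputation_config(0.3, r = 0, reference_haplotypes = 500000)
  post <- emulate_imputation(gh$G, gh$H, cfg, cfg)
  phat <- attr(post, "etahat_G")[["h10"]] + attr(post, "etahat_G")[["h11"]]
  prior <- c((1 - phat)^2, 2 * phat * (1 - phat), phat^2)
  expect_true(all(abs(sweep(post$pG, 2L, prior)) < 0.01))
  expect_lt(imputation_info(post, gh$G, "G"), 0.01)
})

test_that("information increases with tag correlation", {
  infos <- vapply(c(0.3, 0.6, 0.9), function(r) {
    set.seed(40)
    gh <- sample_cases(matrix(1/9, 3, 3), 4000)
    post <- emulate_imputation(gh$G, gh$H,
                               imputation_config(0.3, r = r),
                               imputation_config(0.3, r = r),
                               seed = 41)
    imputation_info(post, gh$G, "G")
  }, numeric(1))
  expect_true(all(diff(infos) > 0))
})

test_that("posterior marginals cohere with the panel-implied HWE law", {
  set.seed(50)
  gh <- sample_cases(case_joint_distribution(
    penetrance_model("multiplicative"), 0.3, 0.3), 20000)
  cfg <- imputation_config(0.3, r = 0.8, reference_haplotypes = 200000)
  post <- emulate_imputation(gh$G, gh$H, cfg, cfg)
  phat <- attr(post, "etahat_G")[["h10"]] + attr(post, "etahat_G")[["h11"]]
  hwe <- c((1 - phat)^2, 2 * phat * (1 - phat), phat^2)
  expect_true(all(abs(colMeans(post$pG) - hwe) < 0.02))
})

test_that("infeasible LD configurations are rejected", {
  expect_error(imputation_config(0.05, 0.5, r = 0.9), "infeasible")
  expect_error(imputation_config(0.7, r = 0.5), "\\(0, 0.5\\]")
  expect_error(case_joint_distribution(
    penetrance_model("multiplicative"), 0, 0.3), "0.5")
})
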