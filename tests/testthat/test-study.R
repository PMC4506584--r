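small_null_cfg <- function(replicates = 30, seed = 123, ...) {
  study_config(penetrance_model("multiplicative"), 0.3, 0.3,
               imputation_G = imputation_config(0.3, r = 0.9),
               imputation_H = imputation_config(0.3, r = 0.8),
               n_cases = 1000L, replicates = replicates,
               mc_draws = 1000L, seed = seed, ...)
}

test_that("studies are bit-reproducible from the master seed", {
  r1 <- run_study(small_null_cfg())
  r2 <- run_study(small_null_cfg())
  expect_identical(r1$pvalues, r2$pvalues)
  expect_identical(r1$rejection, r2$rejection)
  r3 <- run_study(small_null_cfg(seed = 124))
  expect_false(identical(r1$pvalues, r3$pvalues))
})

test_that("study results carry rates, MC errors and realized info", {
  res <- run_study(small_null_cfg(replicates = 20))
  expect_true(all(res$rejection >= 0 & res$rejection <= 1))
  expect_equal(unname(res$mc_se),
               unname(sqrt(res$rejection * (1 - res$rejection) / 20)))
  expect_true(all(is.finite(res$info)))
  expect_equal(res$alpha, 0.01)  # null model: size level
  # power-model config uses the power level
  cfgp <- study_config(penetrance_model("RnR", f = 0.05, g = 0.01),
                       0.3, 0.3, methods = c("truth_WTT"),
                       n_cases = 500L, replicates = 10L, seed = 3)
  expect_equal(run_study(cfgp)$alpha, 0.05)
})

test_that("excess zero-cell exclusions abort loudly", {
  cfg <- study_config(penetrance_model("multiplicative"), 0.05, 0.05,
                      methods = c("truth_WTT"), n_cases = 50L,
                      replicates = 20L, seed = 9)
  expect_error(run_study(cfg), "excluded")
})

test_that("KS uniformity statistic matches hand-computed cases", {
  ks <- ks_uniformity((1:1000) / 1000)
  expect_lte(ks$D, 0.001 + 1e-12)
  ks <- ks_uniformity(rep(0.5, 100))
  expect_equal(ks$D, 0.5)
  expect_error(ks_uniformity(runif(5)), "at least 10")
})

test_that("variance calibration is clean for degenerate posteriors", {
  cfg <- study_config(penetrance_model("multiplicative"), 0.3, 0.3,
                      imputation_G = imputation_config(0.3, r = 1),
                      imputation_H = imputation_config(0.3, r = 1),
                      n_cases = 2000L, seed = 21)
  cal <- variance_calibration(cfg, K = 150)
  # perfect tags: no imputation uncertainty, both estimators track the
  # empirical variance (MC slack at K = 150)
  expect_true(all(abs(cal$mean_naive / cal$empirical_var - 1) < 0.45))
  expect_true(all(abs(cal$mean_jackknife / cal$empirical_var - 1) < 0.45))
})

test_that("study serialization writes one row per method", {
  res <- run_study(small_null_cfg(replicates = 10))
  tsv <- tempfile(fileext = ".tsv")
  write_study_tsv(res, tsv)
  df <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(df), length(res$rejection))
  expect_true(all(c("method", "rejection_rate", "mc_se", "excluded")
                  %in% names(df)))
})
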