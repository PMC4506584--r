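#' Configuration of a size/power simulation study
#'
#' Bundles the data-generating model, the imputation emulator settings
#' and the evaluation parameters for [run_study()].  The defaults mirror
#' a standard case-only design: 5000 cases, 3000 replicates for size
#' under the multiplicative null (evaluated at level 0.01) and 100
#' replicates for power under an epistasis model (evaluated at 0.05).
#'
#' @param model a [penetrance_model()].
#' @param maf_G,maf_H risk allele frequencies.
#' @param imputation_G,imputation_H [imputation_config()] per marker;
#'   required when any imputed-arm method is requested.
#' @param n_cases number of cases per replicate (default 5000).
#' @param replicates number of simulated studies; default 3000 for the
#'   multiplicative (null) model, 100 otherwise.
#' @param alpha_size,alpha_power significance levels used for size
#'   (null model) and power (epistasis models).
#' @param methods subset of `"truth_WTT"`, `"truth_WTTc"` (tests on
#'   the true genotypes, analytic variance), `"WTT"`, `"WTT_c"`
#'   (imputed posteriors, jackknife variance), `"naive_dosage_WTT"`,
#'   `"naive_dosage_WTTc"` (imputed posteriors, plug-in variance).
#' @param seed master seed; all per-replicate seeds derive from it.
#' @param mc_draws Monte Carlo draws for chi-bar weights per replicate.
#' @param zero_policy passed to the estimators.
#' @param shared_weights reuse the chi-bar weights of the first
#'   replicate for all replicates (fast mode; default `FALSE`, weights
#'   are recomputed from each replicate's own covariance estimate).
#' @return Object of class `"study_config"`.
#' @export
study_config <- function(model, maf_G, maf_H,
                         imputation_G = NULL, imputation_H = NULL,
                         n_cases = 5000L, replicates = NULL,
                         alpha_size = 0.01, alpha_power = 0.05,
                         methods = c("truth_WTT", "truth_WTTc", "WTT",
                                     "WTT_c", "naive_dosage_WTT",
                                     "naive_dosage_WTTc"),
                         seed = 1L, mc_draws = 20000L,
                         zero_policy = c("error", "haldane"),
                         shared_weights = FALSE) {
  if (!inherits(model, "penetrance_model"))
    stop("model must be a penetrance_model", call. = FALSE)
  all_methods <- c("truth_WTT", "truth_WTTc", "WTT", "WTT_c",
                   "naive_dosage_WTT", "naive_dosage_WTTc")
  bad <- setdiff(methods, all_methods)
  if (length(bad))
    stop("unknown methods: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(replicates))
    replicates <- if (model$kind == "multiplicative") 3000L else 100L
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  for (a in c(alpha_size, alpha_power))
    if (a <= 0 || a >= 1) stop("alphas must lie in (0, 1)",
                               call. = FALSE)
  need_imp <- any(methods %in% all_methods[3:6])
  if (need_imp && (is.null(imputation_G) || is.null(imputation_H)))
    stop("imputed-arm methods need imputation_G and imputation_H",
         call. = FALSE)
  structure(list(model = model, maf_G = maf_G, maf_H = maf_H,
                 imputation_G = imputation_G,
                 imputation_H = imputation_H,
                 n_cases = as.integer(n_cases),
                 replicates = as.integer(replicates),
                 alpha_size = alpha_size, alpha_power = alpha_power,
                 methods = methods, seed = as.integer(seed),
                 mc_draws = as.integer(mc_draws),
                 zero_policy = match.arg(zero_policy),
                 shared_weights = isTRUE(shared_weights)),
            class = "study_config")
}

#' Run a size/power simulation study
#'
#' Per replicate: sample case genotype pairs from the model's case
#' joint distribution; for the truth arm, test the true genotypes with
#' the analytic variance; for the imputed arms, emulate marginal
#' imputation and test the expected-count estimate with either the
#' grouped jackknife variance (`WTT`, `WTT_c`) or the naive plug-in
#' variance (`naive_dosage_*`).  Constrained tests recompute the
#' chi-bar weights from the replicate's own covariance estimate (unless
#' `shared_weights`).  Rejection is evaluated at `alpha_size` for the
#' multiplicative model and `alpha_power` otherwise.  The run is fully
#' reproducible from the master seed; methods are paired within
#' replicate (all see the same data).  Replicates failing the zero-cell
#' policy are excluded and counted; more than 1% exclusions aborts the
#' run, since silent exclusion biases size estimates.
#'
#' @param cfg a [study_config()].
#' @return Object of class `"study_result"`: list with `rejection`
#'   (named rates), `mc_se`, `alpha`, `pvalues` (replicates x methods),
#'   `info` (realized imputation information per replicate and marker),
#'   `excluded`, `config`.
#' @export
run_study <- function(cfg) {
  if (!inherits(cfg, "study_config"))
    stop("cfg must be a study_config", call. = FALSE)
  methods <- cfg$methods
  dist <- case_joint_distribution(cfg$model, cfg$maf_G, cfg$maf_H)
  is_null <- cfg$model$kind == "multiplicative"
  alpha <- if (is_null) cfg$alpha_size else cfg$alpha_power
  need_truth <- any(methods %in% c("truth_WTT", "truth_WTTc"))
  need_jack <- any(methods %in% c("WTT", "WTT_c"))
  need_naive <- any(methods %in% c("naive_dosage_WTT",
                                   "naive_dosage_WTTc"))
  need_imp <- need_jack || need_naive

  set.seed(cfg$seed)
  rep_seeds <- sample.int(2147483646L, cfg$replicates)

  pmat <- matrix(NA_real_, cfg$replicates, length(methods),
                 dimnames = list(NULL, methods))
  info <- matrix(NA_real_, cfg$replicates, 2L,
                 dimnames = list(NULL, c("G", "H")))
  excluded <- 0L
  shared_w <- new.env(parent = emptyenv())

  weights_for <- function(tag, V) {
    if (!cfg$shared_weights)
      return(chibar_weights(V, mc_draws = cfg$mc_draws))
    if (is.null(shared_w[[tag]]))
      shared_w[[tag]] <- chibar_weights(V, mc_draws = cfg$mc_draws)
    shared_w[[tag]]
  }

  for (k in seq_len(cfg$replicates)) {
    set.seed(rep_seeds[k])
    out <- tryCatch({
      gh <- sample_cases(dist, cfg$n_cases)
      p <- numeric(0)
      if (need_truth) {
        tab <- build_count_table(gh$G, gh$H)
        beta <- estimate_beta(tab, cfg$zero_policy)
        V <- analytic_variance(tab)
        attr(V, "provenance") <- "analytic"
        if ("truth_WTT" %in% methods)
          p["truth_WTT"] <- wtt(beta, V)$p.value
        if ("truth_WTTc" %in% methods)
          p["truth_WTTc"] <- wtt_c(beta, V,
                                   weights_for("truth", V))$p.value
      }
      inf_k <- c(NA_real_, NA_real_)
      if (need_imp) {
        post <- emulate_imputation(gh$G, gh$H, cfg$imputation_G,
                                   cfg$imputation_H)
        inf_k <- c(imputation_info(post, gh$G, "G"),
                   imputation_info(post, gh$H, "H"))
        tabE <- build_expected_table(post)
        betau <- estimate_beta(tabE, cfg$zero_policy)
        if (need_jack) {
          Vj <- jackknife_variance(post, grouping = TRUE,
                                   zero_policy = cfg$zero_policy)
          if ("WTT" %in% methods)
            p["WTT"] <- wtt(betau, Vj)$p.value
          if ("WTT_c" %in% methods)
            p["WTT_c"] <- wtt_c(betau, Vj,
                                weights_for("jack", Vj))$p.value
        }
        if (need_naive) {
          Vn <- analytic_variance(tabE)
          attr(Vn, "provenance") <- "naive_dosage"
          if ("naive_dosage_WTT" %in% methods)
            p["naive_dosage_WTT"] <- wtt(betau, Vn)$p.value
          if ("naive_dosage_WTTc" %in% methods)
            p["naive_dosage_WTTc"] <-
              wtt_c(betau, Vn, weights_for("naive", Vn))$p.value
        }
      }
      list(p = p, info = inf_k)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      excluded <- excluded + 1L
    } else {
      pmat[k, names(out$p)] <- out$p
      info[k, ] <- out$info
    }
  }

  if (excluded > 0.01 * cfg$replicates)
    stop("more than 1% of replicates (", excluded, "/",
         cfg$replicates, ") were excluded by the zero-cell policy; ",
         "results would be biased", call. = FALSE)

  kept <- cfg$replicates - excluded
  rej <- colMeans(pmat <= alpha, na.rm = TRUE)
  se <- sqrt(rej * (1 - rej) / kept)
  structure(list(rejection = rej, mc_se = se, alpha = alpha,
                 pvalues = pmat, info = info, excluded = excluded,
                 replicates_kept = kept, config = cfg),
            class = "study_result")
}

#' @export
print.study_result <- function(x, digits = 4, ...) {
  cat("Simulation study:", x$config$model$kind, "model, n =",
      x$config$n_cases, ", replicates =", x$config$replicates,
      if (x$excluded) paste0("(", x$excluded, " excluded)"), "\n")
  if (!all(is.na(x$info)))
    cat("  realized imputation info (mean): G =",
        round(mean(x$info[, "G"], na.rm = TRUE), 3), ", H =",
        round(mean(x$info[, "H"], na.rm = TRUE), 3), "\n")
  cat("  rejection rates at alpha =", x$alpha, "\n")
  tab <- cbind(rate = round(x$rejection, digits),
               mc_se = round(x$mc_se, digits))
  print(tab)
  invisible(x)
}

#' Kolmogorov-Smirnov uniformity check for null p-values
#'
#' One-sample KS test of a p-value vector against Uniform(0,1): a
#' stronger requirement than holding size at one nominal level.  A
#' well-calibrated test's null p-values should fail to reject.
#'
#' @param pvalues numeric vector in \[0, 1\], length >= 10.
#' @return List with the KS statistic `D` and asymptotic p-value `p`.
#' @export
ks_uniformity <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < 10L)
    stop("need at least 10 p-values", call. = FALSE)
  if (any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  kt <- suppressWarnings(ks.test(pvalues, "punif"))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Variance calibration under the null
#'
#' Across `K` null replicates, compares the mean of each variance
#' estimator's diagonal with the empirical variance of the interaction
#' estimate itself.  The naive plug-in (expected counts treated as
#' observed) systematically exceeds the empirical variance when
#' posteriors are nondegenerate - imputation makes dosages less
#' variable than real genotypes - while the jackknife tracks it.
#'
#' @param cfg a [study_config()] with a multiplicative model and both
#'   imputation configs.
#' @param K number of replicates (>= 100).
#' @return List with 4-vectors `mean_jackknife`, `mean_naive`,
#'   `empirical_var` (per local log odds ratio coordinate) and the
#'   logical 4-vector `naive_overestimates`.
#' @export
variance_calibration <- function(cfg, K = 500L) {
  if (!inherits(cfg, "study_config"))
    stop("cfg must be a study_config", call. = FALSE)
  if (cfg$model$kind != "multiplicative")
    stop("variance calibration is defined under the null ",
         "(multiplicative model)", call. = FALSE)
  if (is.null(cfg$imputation_G) || is.null(cfg$imputation_H))
    stop("variance calibration needs both imputation configs",
         call. = FALSE)
  K <- as.integer(K)
  if (K < 100L) stop("K must be at least 100", call. = FALSE)
  dist <- case_joint_distribution(cfg$model, cfg$maf_G, cfg$maf_H)
  set.seed(cfg$seed)
  rep_seeds <- sample.int(2147483646L, K)
  betas <- matrix(NA_real_, K, 4L)
  dj <- matrix(NA_real_, K, 4L)
  dn <- matrix(NA_real_, K, 4L)
  for (k in seq_len(K)) {
    set.seed(rep_seeds[k])
    gh <- sample_cases(dist, cfg$n_cases)
    post <- emulate_imputation(gh$G, gh$H, cfg$imputation_G,
                               cfg$imputation_H)
    tabE <- build_expected_table(post)
    betas[k, ] <- estimate_beta(tabE, cfg$zero_policy)
    dj[k, ] <- diag(jackknife_variance(post, grouping = TRUE,
                                       zero_policy = cfg$zero_policy))
    dn[k, ] <- diag(analytic_variance(tabE))
  }
  emp <- apply(betas, 2L, var)
  mj <- colMeans(dj)
  mn <- colMeans(dn)
  names(emp) <- names(mj) <- names(mn) <- .beta_names
  list(mean_jackknife = mj, mean_naive = mn, empirical_var = emp,
       naive_overestimates = mn > emp, K = K)
}
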