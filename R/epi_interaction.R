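#' Fit the case-only interaction model for one SNP pair
#'
#' The main user-facing entry point.  Estimates the four local log odds
#' ratios of the joint genotype table among cases, chooses (or is told)
#' a covariance estimator appropriate to the input, and carries out
#' both the unconstrained Wald-type test (chi-square, 4 df) and the
#' sign-constrained test (chi-bar-square mixture).
#'
#' Input is either hard genotype calls (both markers typed) or a
#' [posterior_matrix()] of marginally imputed genotype posteriors (one
#' or both markers untyped).  With calls, the analytic multinomial
#' covariance applies.  With posteriors, the default is the delete-1
#' jackknife on posterior rows, which propagates imputation
#' uncertainty; `variance = "naive"` instead plugs the expected table
#' into the analytic formula (the conservative "dosage as observed"
#' baseline, kept for comparison).
#'
#' @param posteriors a [posterior_matrix()], e.g. from
#'   [read_gen_pair()] or [emulate_imputation()].
#' @param calls alternatively, a list with genotype vectors `G` and
#'   `H` (e.g. from [read_calls_tsv()]).
#' @param variance `"auto"` (analytic for calls, jackknife for
#'   posteriors), `"analytic"`, `"jackknife"` or `"naive"`.
#' @param zero_policy passed to [estimate_beta()].
#' @param mc_draws Monte Carlo draws for the chi-bar weights.
#' @param seed optional seed for the weight estimation.
#' @return An object of class `"epi_interaction"` with components
#'   `beta`, `vcov`, `n`, `table`, `tests` (list of
#'   `"epi_test_result"` for `WTT` and `WTT_c`), `weights`,
#'   `provenance`.  Methods: `print`, `summary`, `coef`, `vcov`,
#'   `confint`, `plot`.
#' @examples
#' dist <- case_joint_distribution(penetrance_model("RnR", f = 0.04,
#'                                                  g = 0.01), 0.3, 0.3)
#' gh <- sample_cases(dist, 2000, seed = 1)
#' fit <- epi_interaction(calls = gh, seed = 1)
#' summary(fit)
#' @export
epi_interaction <- function(posteriors = NULL, calls = NULL,
                            variance = c("auto", "analytic",
                                         "jackknife", "naive"),
                            zero_policy = c("error", "haldane"),
                            mc_draws = 20000L, seed = NULL) {
  variance <- match.arg(variance)
  zero_policy <- match.arg(zero_policy)
  if (is.null(posteriors) == is.null(calls))
    stop("supply exactly one of posteriors or calls", call. = FALSE)
  if (!is.null(calls)) {
    post <- as_posterior(calls$G, calls$H)
    tab <- build_count_table(calls$G, calls$H)
    if (variance == "auto") variance <- "analytic"
  } else {
    if (!inherits(posteriors, "posterior_matrix"))
      stop("posteriors must be a posterior_matrix", call. = FALSE)
    post <- posteriors
    tab <- build_expected_table(post)
    if (variance == "auto") variance <- "jackknife"
  }
  beta <- estimate_beta(tab, zero_policy)
  V <- switch(variance,
    analytic = analytic_variance(tab),
    naive = {
      v <- analytic_variance(tab)
      attr(v, "provenance") <- "naive_dosage"
      v
    },
    jackknife = jackknife_variance(post, grouping = TRUE,
                                   zero_policy = zero_policy))
  if (!is.null(seed)) set.seed(seed)
  w <- chibar_weights(V, mc_draws = mc_draws)
  tests <- list(WTT = wtt(beta, V),
                WTT_c = wtt_c(beta, V, weights = w))
  structure(list(beta = beta, vcov = V, n = post$n, table = tab,
                 tests = tests, weights = w,
                 provenance = attr(V, "provenance"),
                 zero_policy = zero_policy),
            class = "epi_interaction")
}

#' @export
print.epi_interaction <- function(x, digits = 4, ...) {
  cat("Case-only SNP-SNP interaction test (n =", x$n,
      "cases, variance:", x$provenance, ")\n")
  cat("Local log odds ratios:\n")
  print(round(x$beta, digits))
  for (t in x$tests)
    cat("  ", t$method, ": statistic = ",
        format(t$statistic, digits = digits), ", p = ",
        format.pval(t$p.value, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
coef.epi_interaction <- function(object, ...) object$beta

#' @export
vcov.epi_interaction <- function(object, ...) object$vcov

#' @export
confint.epi_interaction <- function(object, parm = 1:4,
                                    level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$beta - z * se, object$beta + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2,
                                       1 - (1 - level) / 2),
                               trim = TRUE), "%")
  ci[parm, , drop = FALSE]
}

#' @export
summary.epi_interaction <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- as.numeric(object$beta) / se
  coefs <- cbind(Estimate = as.numeric(object$beta),
                 `Std. Error` = se, `z value` = z,
                 `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  rownames(coefs) <- .beta_names
  out <- list(coefficients = coefs, tests = object$tests,
              n = object$n, provenance = object$provenance,
              weights = object$weights)
  class(out) <- "summary.epi_interaction"
  out
}

#' @export
print.summary.epi_interaction <- function(x, digits = 4, ...) {
  cat("Local log odds ratio estimates (n =", x$n,
      "cases; variance:", x$provenance, ")\n")
  stats::printCoefmat(x$coefficients, digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat("\nOverall interaction tests:\n")
  for (t in x$tests)
    cat("  ", t$method, ": statistic = ",
        format(t$statistic, digits = digits), " (", t$reference,
        "), p = ", format.pval(t$p.value, digits = digits), "\n",
        sep = "")
  cat("Chi-bar weights (w0..w4):",
      paste(round(x$weights$w, 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.epi_interaction <- function(x, level = 0.95, ...) {
  ci <- confint(x, level = level)
  est <- as.numeric(x$beta)
  ylim <- range(0, ci)
  plot(1:4, est, xaxt = "n", xlab = "local odds ratio",
       ylab = "log OR", ylim = ylim, pch = 19,
       main = "Interaction estimates", ...)
  graphics::axis(1, at = 1:4, labels = .beta_names)
  graphics::arrows(1:4, ci[, 1], 1:4, ci[, 2], angle = 90, code = 3,
                   length = 0.05)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
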