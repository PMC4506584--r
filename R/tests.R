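# The Wald-type tests themselves.  Both consume an interaction estimate
# and a covariance; how the covariance was obtained (analytic,
# jackknife, naive plug-in on expected counts) is carried along as
# provenance so results are self-describing.

.test_result <- function(statistic, p.value, method, reference,
                         provenance, weights = NULL) {
  structure(list(statistic = statistic, p.value = p.value,
                 method = method, reference = reference,
                 provenance = provenance, weights = weights),
            class = "epi_test_result")
}

#' @export
print.epi_test_result <- function(x, digits = 4, ...) {
  cat(x$method, " (variance: ", x$provenance, ")\n", sep = "")
  cat("  statistic = ", format(x$statistic, digits = digits),
      ",  reference: ", x$reference,
      ",  p-value = ", format.pval(x$p.value, digits = digits),
      "\n", sep = "")
  invisible(x)
}

#' Unconstrained Wald-type interaction test (WTT)
#'
#' Computes the quadratic form \eqn{\hat\beta^T V^{-1} \hat\beta} and
#' refers it to a chi-square distribution with 4 degrees of freedom.
#' Valid whenever `V` consistently estimates the covariance of
#' `beta` - the analytic multinomial covariance for fully typed
#' markers, or the jackknife covariance for marginally imputed ones.
#'
#' @param beta numeric 4-vector of local log odds ratios.
#' @param V 4x4 symmetric positive-definite covariance, e.g. from
#'   [analytic_variance()] or [jackknife_variance()].
#' @return An object of class `"epi_test_result"`: list with
#'   `statistic`, `p.value`, `method`, `reference`, `provenance`.
#' @export
wtt <- function(beta, V) {
  beta <- as.numeric(beta)
  if (length(beta) != 4L || any(!is.finite(beta)))
    stop("beta must be a finite 4-vector", call. = FALSE)
  W <- .pd_inverse(V)
  stat <- drop(crossprod(beta, W %*% beta))
  .test_result(statistic = stat,
               p.value = pchisq(stat, df = 4, lower.tail = FALSE),
               method = "WTT", reference = "chi-square(4)",
               provenance = attr(V, "provenance") %||% "user")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sign-constrained Wald-type interaction test (WTT_c)
#'
#' The constrained statistic is the unconstrained quadratic form minus
#' the squared `V^{-1}`-distance from `beta` to the one-signed cone
#' \eqn{\Theta_1} (see [project_to_cone()]); equivalently the squared
#' norm of the cone projection.  It satisfies
#' `0 <= WTT_c <= WTT`, with equality to WTT exactly when `beta` lies
#' in the cone.  Its null tail is approximated by the chi-bar-square
#' mixture \eqn{P(WTT_c \ge t) \approx \sum_{l=1}^{4} w_l
#' P(\chi^2_l \ge t)} with weights from [chibar_weights()]; since the
#' one-signed space is the union of two orthants, the union weights
#' average the two orthants' laws and the mixture tail is doubled and
#' capped at one (see [chibar_weights()]), which is slightly
#' conservative.  The point mass `w0` at zero is excluded from the
#' tail sum; at `statistic = 0` the p-value is 1.
#'
#' @inheritParams wtt
#' @param weights a [chibar_weights()] object; if `NULL`, weights are
#'   estimated from `V` with `mc_draws` draws.
#' @param mc_draws,seed passed to [chibar_weights()] when `weights` is
#'   `NULL`.
#' @return An `"epi_test_result"` with the mixture weights attached.
#' @export
wtt_c <- function(beta, V, weights = NULL, mc_draws = 20000L,
                  seed = NULL) {
  beta <- as.numeric(beta)
  if (length(beta) != 4L || any(!is.finite(beta)))
    stop("beta must be a finite 4-vector", call. = FALSE)
  W <- .pd_inverse(V)
  full <- drop(crossprod(beta, W %*% beta))
  pr <- cone_project_cpp(beta, W, 0L)
  stat <- max(full - pr$qdist, 0)
  if (is.null(weights))
    weights <- chibar_weights(V, mc_draws = mc_draws, seed = seed)
  if (!inherits(weights, "chibar_weights"))
    stop("weights must come from chibar_weights()", call. = FALSE)
  mult <- if (identical(weights$cone, "union")) 2 else 1
  p <- if (stat <= 0) 1 else
    mult * sum(weights$w[2:5] * pchisq(stat, df = 1:4,
                                       lower.tail = FALSE))
  .test_result(statistic = stat, p.value = min(p, 1),
               method = "WTT_c",
               reference = "chi-bar-square(1-4)",
               provenance = attr(V, "provenance") %||% "user",
               weights = weights)
}

#' Naive dosage baseline tests
#'
#' The "treat dosage as observed" baseline: build the expected joint
#' genotype table from the marginal posteriors, estimate the local log
#' odds ratios from it, and plug the expected table straight into the
#' analytic multinomial covariance as if the expected counts were
#' observed counts.  Because imputation shrinks dosages toward their
#' prior mean, the expected table is less variable than real genotypes
#' and this plug-in overstates the variance, making the tests
#' conservative and less powerful than the jackknife-based ones.  It is
#' provided as the comparison arm, not for inference.
#'
#' @param post a [posterior_matrix()].
#' @param constrained if `TRUE` run the sign-constrained test, else the
#'   unconstrained one.
#' @param zero_policy passed to [estimate_beta()].
#' @param mc_draws,seed passed to [chibar_weights()] when
#'   `constrained = TRUE`.
#' @return An `"epi_test_result"` with method tag
#'   `naive_dosage_WTT` or `naive_dosage_WTTc`.
#' @export
naive_dosage_test <- function(post, constrained = FALSE,
                              zero_policy = c("error", "haldane"),
                              mc_draws = 20000L, seed = NULL) {
  tab <- build_expected_table(post)
  beta <- estimate_beta(tab, zero_policy)
  V <- analytic_variance(tab)
  attr(V, "provenance") <- "naive_dosage"
  res <- if (constrained)
    wtt_c(beta, V, mc_draws = mc_draws, seed = seed)
  else wtt(beta, V)
  res$method <- if (constrained) "naive_dosage_WTTc" else
    "naive_dosage_WTT"
  res$provenance <- "naive_dosage"
  res
}
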