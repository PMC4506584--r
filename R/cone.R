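#' Project the interaction estimate onto the one-signed cone
#'
#' The constrained alternative space for the interaction vector is
#' \eqn{\Theta_1}: all four local log odds ratios non-negative, or all
#' non-positive (a union of two orthants; the classical two-locus
#' epistasis penetrance models all satisfy it).  This computes
#' \deqn{\min_{\beta^* \in \Theta_1}
#'   (\hat\beta - \beta^*)^T V^{-1} (\hat\beta - \beta^*)}
#' exactly, by solving each orthant's sign-constrained quadratic program
#' through enumeration of all 16 faces (fix a subset of coordinates to
#' zero, solve the unconstrained problem on the face, keep sign-feasible
#' candidates, take the minimum) and then taking the smaller orthant
#' value.  Ties between the orthants break to the non-negative one.
#'
#' @param beta numeric 4-vector of local log odds ratios.
#' @param V 4x4 symmetric positive-definite covariance of `beta`.
#' @param cone which cone to project onto: the default `"union"` is
#'   \eqn{\Theta_1}; a single orthant can be selected (used for weight
#'   diagnostics).
#' @return A list: `beta_star` (the projection), `qdist` (the attained
#'   minimum), `active_dim` (number of nonzero coordinates of
#'   `beta_star`, 0..4).
#' @examples
#' project_to_cone(c(1, -1, 0, 0), diag(4))  # qdist 1
#' @export
project_to_cone <- function(beta, V, cone = c("union", "nonnegative",
                                              "nonpositive")) {
  beta <- as.numeric(beta)
  if (length(beta) != 4L || any(!is.finite(beta)))
    stop("beta must be a finite 4-vector", call. = FALSE)
  W <- .pd_inverse(V)
  res <- cone_project_cpp(beta, W, .cone_code(cone))
  res$beta_star <- as.numeric(res$beta_star)
  names(res$beta_star) <- .beta_names
  res
}

#' Monte Carlo chi-bar-square mixture weights
#'
#' Under the null the constrained Wald-type statistic follows a
#' chi-bar-square law: a mixture of chi-square distributions with 0-4
#' degrees of freedom whose weights depend on the covariance of the
#' interaction estimate and on the cone.  The weights are estimated by
#' simulation: draw `Z ~ N(0, V)`, project onto the cone in the
#' `V^{-1}` metric, and record the number of active (nonzero)
#' coordinates of the projection; `w[l]` is the proportion of
#' projections with `l` active coordinates.  `w[0]` is the point mass
#' at 0 and is excluded from the tail sum used for p-values.
#'
#' For a single orthant the squared projection norm is exactly the
#' `w`-mixture of chi-squares (the classical chi-bar-square theorem for
#' convex cones).  The one-signed space is the *union* of the
#' non-negative and non-positive orthants, and its constrained
#' statistic is the larger of the two orthant projections; its tail is
#' the sum of the two orthant tails minus their (far-tail negligible)
#' overlap.  For `cone = "union"` the recorded weights are therefore
#' the average of the two orthants' active-dimension laws, and the
#' p-value machinery ([wtt_c()]) doubles the tail mixture and caps it
#' at one - a slightly conservative approximation that is tight at
#' conventional significance levels.
#'
#' The weights are invariant to rescaling `V` by a positive constant
#' and, for `V = identity` on a single orthant, equal the binomial
#' `(1, 4, 6, 4, 1) / 16`.
#'
#' @inheritParams project_to_cone
#' @param mc_draws number of Monte Carlo draws (>= 1000; default
#'   20000).
#' @param seed optional integer; if supplied, `set.seed(seed)` is
#'   called first, otherwise the current RNG stream is used.
#' @return Object of class `"chibar_weights"`: list with `w`
#'   (named 5-vector `w0..w4` summing to 1), `cone`, `mc_draws`,
#'   `seed`.
#' @export
chibar_weights <- function(V, mc_draws = 20000L, seed = NULL,
                           cone = c("union", "nonnegative",
                                    "nonpositive")) {
  cone <- match.arg(cone)
  mc_draws <- as.integer(mc_draws)
  if (mc_draws < 1000L)
    stop("mc_draws must be at least 1000", call. = FALSE)
  W <- .pd_inverse(V)
  if (!is.null(seed)) set.seed(seed)
  L <- t(chol((V + t(V)) / 2))
  counts <- chibar_counts_cpp(L, W, mc_draws, .cone_code(cone))
  w <- counts / sum(counts)
  names(w) <- paste0("w", 0:4)
  structure(list(w = w, cone = cone, mc_draws = mc_draws,
                 seed = seed),
            class = "chibar_weights")
}

#' @export
print.chibar_weights <- function(x, digits = 4, ...) {
  cat("Chi-bar-square mixture weights (", x$mc_draws, " MC draws)\n",
      sep = "")
  print(round(x$w, digits))
  invisible(x)
}
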