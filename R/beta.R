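#' Local log odds ratios of a 3x3 joint genotype table
#'
#' The interaction parameter is the 4-vector of local log odds ratios
#' of the joint genotype distribution among cases,
#' \deqn{\beta_{lm} = \log\frac{p_{l,m}\,p_{l+1,m+1}}
#'   {p_{l,m+1}\,p_{l+1,m}}, \qquad l, m = 0, 1,}
#' estimated by plugging in the observed (or expected) cell counts.
#' Under multiplicative penetrances at two unlinked loci the case joint
#' distribution is rank-1 and all four local log odds ratios vanish.
#'
#' @param tab 3x3 table of counts or expected counts, as returned by
#'   [build_count_table()] or [build_expected_table()].
#' @param zero_policy what to do about non-positive cells, which make
#'   the estimator undefined: `"error"` (default) aborts naming the
#'   offending cell; `"haldane"` adds the Haldane-Anscombe 0.5 to every
#'   cell first and flags the result with `attr(, "haldane")`.
#' @return Named numeric 4-vector `(b00, b01, b10, b11)` of local log
#'   odds ratios.
#' @examples
#' tab <- matrix(100, 3, 3); tab[2, 2] <- 200
#' estimate_beta(tab)   # (log 2, -log 2, -log 2, log 2)
#' @export
estimate_beta <- function(tab, zero_policy = c("error", "haldane")) {
  zero_policy <- match.arg(zero_policy)
  tab <- .check_table3(tab)
  haldane <- FALSE
  if (zero_policy == "haldane") {
    tab <- tab + 0.5
    haldane <- TRUE
  } else if (any(tab <= 0)) {
    bad <- which(tab <= 0, arr.ind = TRUE)[1L, ]
    stop("cell ", .cell_name(bad[1L] - 1L, bad[2L] - 1L),
         " of the joint genotype table is not positive; the local odds ",
         "ratio estimator is undefined (zero_policy = \"haldane\" adds ",
         "0.5 to every cell)", call. = FALSE)
  }
  beta <- numeric(4L)
  k <- 1L
  for (l in 1:2) for (m in 1:2) {
    beta[k] <- log(tab[l, m] * tab[l + 1L, m + 1L] /
                     (tab[l, m + 1L] * tab[l + 1L, m]))
    k <- k + 1L
  }
  names(beta) <- .beta_names
  if (haldane) attr(beta, "haldane") <- TRUE
  beta
}

.check_table3 <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 3L || ncol(tab) != 3L)
    stop("expected a 3x3 joint genotype table", call. = FALSE)
  if (any(!is.finite(tab)) || any(tab < 0))
    stop("table cells must be finite and non-negative", call. = FALSE)
  tab
}

#' Multinomial (delta-method) covariance of the local log odds ratios
#'
#' The large-sample covariance of the four local log odds ratio
#' estimates from a multinomial 3x3 table, evaluated at the observed
#' cell proportions \eqn{\hat p_{lm}}:
#' diagonal entries are sums of reciprocal proportions over the four
#' cells entering each local odds ratio, and off-diagonal entries
#' collect the (signed) reciprocals of shared cells, all divided by the
#' total count.  Valid for fully observed genotypes; with imputed
#' posteriors plugged in as expected counts it overstates the true
#' sampling variance (use [jackknife_variance()] there).
#'
#' @param tab 3x3 table with all cells strictly positive.
#' @return A symmetric positive-definite 4x4 matrix with
#'   `attr(, "provenance") = "analytic"`, rows/columns ordered
#'   `(b00, b01, b10, b11)`.
#' @export
analytic_variance <- function(tab) {
  tab <- .check_table3(tab)
  if (any(tab <= 0)) {
    bad <- which(tab <= 0, arr.ind = TRUE)[1L, ]
    stop("cell ", .cell_name(bad[1L] - 1L, bad[2L] - 1L),
         " is not positive; the analytic variance is undefined",
         call. = FALSE)
  }
  n <- sum(tab)
  r <- n / tab                       # 1 / p_lm, indexed [l+1, m+1]
  V <- matrix(0, 4L, 4L, dimnames = list(.beta_names, .beta_names))
  V[1, 1] <- r[1, 1] + r[1, 2] + r[2, 1] + r[2, 2]
  V[1, 2] <- -r[1, 2] - r[2, 2]
  V[1, 3] <- -r[2, 1] - r[2, 2]
  V[1, 4] <- r[2, 2]
  V[2, 2] <- r[1, 2] + r[1, 3] + r[2, 2] + r[2, 3]
  V[2, 3] <- r[2, 2]
  V[2, 4] <- -r[2, 2] - r[2, 3]
  V[3, 3] <- r[2, 1] + r[2, 2] + r[3, 1] + r[3, 2]
  V[3, 4] <- -r[2, 2] - r[3, 2]
  V[4, 4] <- r[2, 2] + r[2, 3] + r[3, 2] + r[3, 3]
  V <- (V + t(V)) - diag(diag(V))
  V <- V / n
  attr(V, "provenance") <- "analytic"
  V
}
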