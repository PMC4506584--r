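#' Delete-1 jackknife covariance of the imputed interaction estimate
#'
#' Leave-one-out resampling on the per-individual posterior rows.  With
#' \eqn{\hat\beta_n} the estimate on all n individuals and
#' \eqn{\hat\beta^i_{n-1}} the estimate with individual i removed, the
#' pseudo-values are
#' \eqn{\hat\beta^i_{ps} = n\hat\beta_n - (n-1)\hat\beta^i_{n-1}}
#' and the jackknife covariance is
#' \deqn{\hat V = \frac{1}{n(n-1)} \sum_i
#'   (\hat\beta^i_{ps} - \tilde\beta)(\hat\beta^i_{ps} - \tilde\beta)^T,}
#' centred at the pseudo-value mean \eqn{\tilde\beta}.  Resampling the
#' imputed rows directly (without re-imputation) is exactly valid when
#' imputation of one individual does not depend on the other study
#' individuals - i.e. when the imputation model parameters come from an
#' external reference panel only, as the emulator in this package and
#' reference-panel-only imputation tools guarantee.
#'
#' Each leave-one-out table is obtained by subtracting the individual's
#' outer-product contribution from the full expected table (O(1) per
#' individual).  With `grouping = TRUE`, individuals with identical
#' posterior row pairs share a single leave-one-out computation,
#' weighted by group size - a large saving when posteriors are
#' categorical (e.g. they depend only on a tag genotype, giving at most
#' 9 distinct pairs); the result agrees with the ungrouped sum up to
#' floating-point summation order.
#'
#' @param post a [posterior_matrix()]; at least 9 individuals.
#' @param grouping share leave-one-out computations across identical
#'   posterior rows (default `TRUE`).
#' @param zero_policy passed to [estimate_beta()] for the full and
#'   every leave-one-out table.
#' @return A symmetric positive-semidefinite 4x4 matrix with
#'   `attr(, "provenance") = "jackknife"`.
#' @export
jackknife_variance <- function(post, grouping = TRUE,
                               zero_policy = c("error", "haldane")) {
  zero_policy <- match.arg(zero_policy)
  if (!inherits(post, "posterior_matrix"))
    stop("post must be a posterior_matrix", call. = FALSE)
  n <- post$n
  if (n < 9L)
    stop("jackknife needs at least 9 individuals, got ", n,
         call. = FALSE)
  tab <- build_expected_table(post)
  beta_n <- as.numeric(estimate_beta(tab, zero_policy))

  if (grouping) {
    gr <- unique_row_groups(post, tol = 0)
    reps <- match(seq_along(gr$group_sizes), gr$group_ids)
    wts <- gr$group_sizes
  } else {
    reps <- seq_len(n)
    wts <- rep(1, n)
  }

  ps <- matrix(0, length(reps), 4L)
  for (k in seq_along(reps)) {
    i <- reps[k]
    tab_i <- tab - tcrossprod(post$pG[i, ], post$pH[i, ])
    beta_i <- tryCatch(
      as.numeric(estimate_beta(tab_i, zero_policy)),
      error = function(e)
        stop("leave-one-out table for sample ", i, ": ",
             conditionMessage(e), call. = FALSE))
    ps[k, ] <- n * beta_n - (n - 1) * beta_i
  }
  center <- colSums(ps * wts) / n
  dev <- sweep(ps, 2L, center)
  V <- crossprod(dev * wts, dev) / (n * (n - 1))
  V <- (V + t(V)) / 2
  dimnames(V) <- list(.beta_names, .beta_names)
  attr(V, "provenance") <- "jackknife"
  V
}

#' Group individuals with identical posterior rows
#'
#' Individuals whose `(pG, pH)` row pairs agree within `tol` share a
#' group; leave-one-out statistics are identical within a group, which
#' is what makes the grouped jackknife cheap for categorical posteriors
#' (at most 9 groups when posteriors depend only on a tag genotype
#' pair).
#'
#' @param post a [posterior_matrix()].
#' @param tol non-negative grouping tolerance; `0` requires exact
#'   equality, a positive value snaps entries to a grid of spacing
#'   `tol` before comparison.
#' @return List with `group_ids` (n-vector of 1-based ids) and
#'   `group_sizes` (sizes summing to n).
#' @export
unique_row_groups <- function(post, tol = 0) {
  if (!inherits(post, "posterior_matrix"))
    stop("post must be a posterior_matrix", call. = FALSE)
  M <- cbind(post$pG, post$pH)
  if (tol > 0) M <- round(M / tol)
  key <- do.call(paste, c(asplit(M, 2L), sep = "\r"))
  ids <- match(key, unique(key))
  list(group_ids = ids, group_sizes = tabulate(ids))
}
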