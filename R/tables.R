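#' Tally the 3x3 joint genotype table from hard calls
#'
#' Counts, over case individuals, the joint genotypes at two markers G
#' and H.  Genotypes are coded 0/1/2 = copies of the coded allele.
#' The 3x3 table of counts is the sufficient statistic for the local
#' log odds ratio estimator and every test in the package.
#'
#' @param genotypes_G,genotypes_H integer vectors of equal length with
#'   values in `{0, 1, 2}`.
#' @return A 3x3 numeric matrix with `dimnames` `list(G = 0:2, H = 0:2)`;
#'   rows index the genotype at G, columns at H.  `sum(counts)` equals
#'   the number of individuals.
#' @seealso [build_expected_table()] for the imputed analogue.
#' @examples
#' build_count_table(c(0, 0, 1), c(0, 1, 1))
#' @export
build_count_table <- function(genotypes_G, genotypes_H) {
  if (length(genotypes_G) != length(genotypes_H))
    stop("genotype vectors differ in length: ", length(genotypes_G),
         " vs ", length(genotypes_H), call. = FALSE)
  if (length(genotypes_G) == 0L)
    stop("no samples", call. = FALSE)
  for (v in list(G = genotypes_G, H = genotypes_H)) {
    bad <- which(!(v %in% 0:2))
    if (length(bad))
      stop("genotype out of {0,1,2} at index ", bad[1L], call. = FALSE)
  }
  tab <- matrix(0, 3L, 3L, dimnames = list(G = 0:2, H = 0:2))
  t0 <- table(factor(genotypes_G, levels = 0:2),
              factor(genotypes_H, levels = 0:2))
  tab[] <- as.numeric(t0)
  tab
}

#' Per-individual marginal genotype posteriors for a marker pair
#'
#' Bundles the n x 3 matrices of marginal genotype posterior
#' probabilities for markers G and H, the output of (emulated) marginal
#' imputation and the resampling unit of the jackknife.  Each row is a
#' probability vector over genotypes 0/1/2.  The joint posterior for an
#' individual under the no-interaction null is the outer product of the
#' two marginal rows.  Hard calls are the degenerate special case with a
#' single unit entry per row.
#'
#' @param pG,pH numeric n x 3 matrices; row i is
#'   `P(genotype = 0,1,2)` for individual i at the marker.
#' @param renormalize divide each row by its sum after validation, so
#'   rows sum to 1 exactly.
#' @param tol maximum tolerated deviation of a row sum from 1 before
#'   renormalization (default `1e-8`; file readers relax this).
#' @return An object of class `"posterior_matrix"`: a list with
#'   elements `pG`, `pH`, `n`.
#' @export
posterior_matrix <- function(pG, pH, renormalize = TRUE, tol = 1e-8) {
  pG <- as.matrix(pG); pH <- as.matrix(pH)
  if (ncol(pG) != 3L || ncol(pH) != 3L)
    stop("posterior matrices must have 3 columns", call. = FALSE)
  if (nrow(pG) != nrow(pH))
    stop("posterior matrices differ in rows: ", nrow(pG), " vs ",
         nrow(pH), call. = FALSE)
  if (nrow(pG) == 0L)
    stop("no samples", call. = FALSE)
  for (nm in c("pG", "pH")) {
    m <- if (nm == "pG") pG else pH
    if (any(!is.finite(m)) || any(m < 0) || any(m > 1 + tol))
      stop(nm, " entries must be probabilities in [0,1]", call. = FALSE)
    dev <- abs(rowSums(m) - 1)
    if (any(dev > tol))
      stop(nm, " row ", which.max(dev), " sums to ",
           format(rowSums(m)[which.max(dev)]), ", not 1", call. = FALSE)
  }
  if (renormalize) {
    pG <- pG / rowSums(pG)
    pH <- pH / rowSums(pH)
  }
  dimnames(pG) <- dimnames(pH) <- NULL
  structure(list(pG = pG, pH = pH, n = nrow(pG)),
            class = "posterior_matrix")
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat("Marginal genotype posteriors for", x$n, "case individuals\n")
  ug <- nrow(unique(round(x$pG, 12)))
  uh <- nrow(unique(round(x$pH, 12)))
  cat("  distinct rows: G =", ug, ", H =", uh, "\n")
  invisible(x)
}

#' Encode hard genotype calls as degenerate posteriors
#'
#' @param genotypes_G,genotypes_H integer vectors in `{0,1,2}`.
#' @return A [posterior_matrix()] with one unit entry per row.
#' @export
as_posterior <- function(genotypes_G, genotypes_H) {
  enc <- function(g) {
    bad <- which(!(g %in% 0:2))
    if (length(bad))
      stop("genotype out of {0,1,2} at index ", bad[1L], call. = FALSE)
    m <- matrix(0, length(g), 3L)
    m[cbind(seq_along(g), g + 1L)] <- 1
    m
  }
  if (length(genotypes_G) != length(genotypes_H))
    stop("genotype vectors differ in length", call. = FALSE)
  if (length(genotypes_G) == 0L) stop("no samples", call. = FALSE)
  posterior_matrix(enc(genotypes_G), enc(genotypes_H))
}

#' Expected joint genotype table from marginal posteriors
#'
#' Sums, over individuals, the outer product of the marginal posterior
#' rows at the two markers: `counts[l, m] = sum_i pG[i, l] * pH[i, m]`.
#' This is the expected count of each joint genotype given the observed
#' data and the (null-evaluated) imputation model - the dosage analogue
#' of the hard-call table.  With degenerate posteriors it reduces
#' exactly to [build_count_table()].
#'
#' @param post a [posterior_matrix()].
#' @return A 3x3 numeric matrix of expected counts summing to `post$n`.
#' @export
build_expected_table <- function(post) {
  if (!inherits(post, "posterior_matrix"))
    stop("post must be a posterior_matrix", call. = FALSE)
  tab <- crossprod(post$pG, post$pH)   # t(pG) %*% pH, 3x3
  dimnames(tab) <- list(G = 0:2, H = 0:2)
  tab
}
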