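#' Two-locus penetrance models
#'
#' Classical two-locus epistasis penetrance models built from
#' dominant/recessive conditions at each locus, plus the multiplicative
#' (no-interaction) model.  A locus condition is *dominant* when the
#' genotype carries at least one risk allele and *recessive* when it
#' carries two.  Union kinds assign penetrance `f` where either locus
#' condition holds and `g` elsewhere; intersection kinds assign `f`
#' where both hold.  The multiplicative model has penetrance
#' `mu * alpha[l+1] * gamma[m+1]`, whose case joint genotype
#' distribution is exactly rank-1: all four local log odds ratios are
#' zero, the null of no interaction.  All six epistasis kinds with
#' `f > g` give one-signed interaction vectors, i.e. lie in the
#' constrained space of [wtt_c()].
#'
#' @param kind one of `"DuD"`, `"RuR"`, `"DuR"`, `"RnD"`, `"RnR"`,
#'   `"DnD"` (u = union, n = intersection; first letter is the mode at
#'   marker G, second at marker H) or `"multiplicative"`.
#' @param f,g penetrances in (0, 1] with `g < f`, for the six epistasis
#'   kinds.
#' @param mu,alpha,gamma baseline and per-genotype marginal multipliers
#'   for the multiplicative model (`alpha`, `gamma` length-3, indexed
#'   by genotype 0/1/2).
#' @return An object of class `"penetrance_model"`.
#' @export
penetrance_model <- function(kind = c("DuD", "RuR", "DuR", "RnD",
                                      "RnR", "DnD", "multiplicative"),
                             f = NULL, g = NULL, mu = NULL,
                             alpha = c(1, 1, 1), gamma = c(1, 1, 1)) {
  kind <- match.arg(kind)
  if (kind == "multiplicative") {
    if (is.null(mu)) mu <- 0.01
    if (length(alpha) != 3L || length(gamma) != 3L)
      stop("alpha and gamma must have length 3", call. = FALSE)
    tab <- mu * tcrossprod(alpha, gamma)
    if (any(tab <= 0) || any(tab > 1))
      stop("multiplicative penetrances must lie in (0, 1]",
           call. = FALSE)
    m <- list(kind = kind, mu = mu, alpha = alpha, gamma = gamma)
  } else {
    if (is.null(f) || is.null(g))
      stop("epistasis kinds need penetrances f and g", call. = FALSE)
    if (g >= f) stop("g must be smaller than f", call. = FALSE)
    if (f <= 0 || f > 1 || g <= 0 || g > 1)
      stop("penetrances must lie in (0, 1]", call. = FALSE)
    m <- list(kind = kind, f = f, g = g)
  }
  structure(m, class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("Two-locus penetrance model:", x$kind, "\n")
  print(penetrance_table(x))
  invisible(x)
}

#' Penetrance table of a two-locus model
#'
#' @param model a [penetrance_model()].
#' @return 3x3 matrix of penetrances, rows indexing the genotype at G,
#'   columns at H (0/1/2 copies of the risk allele).
#' @export
penetrance_table <- function(model) {
  if (!inherits(model, "penetrance_model"))
    stop("model must be a penetrance_model", call. = FALSE)
  if (model$kind == "multiplicative") {
    tab <- model$mu * tcrossprod(model$alpha, model$gamma)
  } else {
    cond <- function(mode, geno)
      if (mode == "D") geno >= 1L else geno == 2L
    modeG <- substr(model$kind, 1L, 1L)
    op <- substr(model$kind, 2L, 2L)
    modeH <- substr(model$kind, 3L, 3L)
    cg <- cond(modeG, 0:2)
    ch <- cond(modeH, 0:2)
    hit <- if (op == "u") outer(cg, ch, `|`) else outer(cg, ch, `&`)
    tab <- ifelse(hit, model$f, model$g)
  }
  dimnames(tab) <- list(G = 0:2, H = 0:2)
  tab
}

#' Joint genotype distribution among cases
#'
#' By Bayes' rule, the case joint genotype distribution is proportional
#' to penetrance times the population joint genotype frequency.  The
#' two loci are assumed unlinked and in linkage equilibrium, with
#' Hardy-Weinberg marginal genotype frequencies at each, so the
#' population joint frequency is the product of the HWE marginals.
#'
#' @param model a [penetrance_model()].
#' @param maf_G,maf_H risk (coded) allele frequencies in (0, 0.5].
#' @return 3x3 probability table summing to 1.
#' @export
case_joint_distribution <- function(model, maf_G, maf_H) {
  for (p in c(maf_G, maf_H))
    if (!is.finite(p) || p <= 0 || p > 0.5)
      stop("allele frequencies must lie in (0, 0.5]", call. = FALSE)
  hw <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)
  num <- penetrance_table(model) * tcrossprod(hw(maf_G), hw(maf_H))
  tab <- num / sum(num)
  dimnames(tab) <- list(G = 0:2, H = 0:2)
  tab
}

#' Sample case genotype pairs
#'
#' i.i.d. multinomial draws of joint genotypes from a 3x3 case
#' distribution.
#'
#' @param dist 3x3 probability table (rows = genotype at G).
#' @param n number of cases.
#' @param seed optional integer seed; `NULL` uses the current RNG
#'   stream.
#' @return List with integer vectors `G` and `H` of length `n`.
#' @export
sample_cases <- function(dist, n, seed = NULL) {
  dist <- .check_table3(dist)
  if (abs(sum(dist) - 1) > 1e-8)
    stop("dist must sum to 1", call. = FALSE)
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(9L, n, replace = TRUE, prob = as.vector(dist))
  list(G = (idx - 1L) %% 3L, H = (idx - 1L) %/% 3L)
}

#' Configuration of the single-tag imputation emulator
#'
#' The emulator replaces a full imputation pipeline with its
#' statistical essence: for each untyped target marker there is one
#' typed tag SNP, and target/tag alleles on a haplotype follow a 2x2
#' haplotype frequency model parameterised by the target risk-allele
#' frequency `p = maf`, the tag allele frequency `q = tag_maf`, and the
#' haplotype (allelic) correlation `r`.  The imputation model
#' parameters are *estimated* from a finite simulated reference panel
#' of `reference_haplotypes` haplotypes, so posteriors carry realistic
#' reference-panel noise.  `|r|` controls how informative the tag is
#' (`r = +-1` with `p = q` gives a perfect tag, `r = 0` an
#' uninformative one); see [imputation_info()].
#'
#' @param maf target risk-allele frequency in (0, 0.5].
#' @param tag_maf tag allele frequency (default `maf`).
#' @param r haplotype correlation between target and tag alleles in
#'   \[-1, 1\]; must be feasible for the given frequencies (all four
#'   implied haplotype frequencies non-negative).
#' @param reference_haplotypes size of the simulated reference panel
#'   (default 120 haplotypes, a HapMap-sized panel).
#' @return Object of class `"imputation_config"` carrying the implied
#'   haplotype frequencies `h` (order: 00, 01, 10, 11 for
#'   target/tag allele pairs).
#' @export
imputation_config <- function(maf, tag_maf = maf, r,
                              reference_haplotypes = 120L) {
  p <- maf; q <- tag_maf
  if (!is.finite(p) || p <= 0 || p > 0.5)
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  if (!is.finite(q) || q <= 0 || q >= 1)
    stop("tag_maf must lie in (0, 1)", call. = FALSE)
  if (!is.finite(r) || abs(r) > 1)
    stop("r must lie in [-1, 1]", call. = FALSE)
  h11 <- p * q + r * sqrt(p * (1 - p) * q * (1 - q))
  h <- c(h00 = 1 - p - q + h11, h01 = q - h11, h10 = p - h11,
         h11 = h11)
  h[abs(h) < 1e-12] <- 0
  if (any(h < 0))
    stop("infeasible (maf, tag_maf, r): implied haplotype frequency ",
         names(h)[which(h < 0)[1L]], " = ",
         format(h[which(h < 0)[1L]]), " is negative", call. = FALSE)
  R <- as.integer(reference_haplotypes)
  if (R < 4L) stop("reference_haplotypes must be at least 4",
                   call. = FALSE)
  structure(list(maf = p, tag_maf = q, r = r,
                 reference_haplotypes = R, h = h),
            class = "imputation_config")
}

# Emulate one marker: draw a reference panel (eta-hat), draw observed
# tag genotypes given the truth, return the posterior rows implied by
# eta-hat under HWE (random union of haplotypes).  Returns list(post,
# tag, etahat, retries).
.emulate_marker <- function(truth, cfg, max_retries = 10L) {
  n <- length(truth)
  h <- cfg$h
  p <- cfg$maf
  # observed tag genotype | true target genotype, via the true model:
  # each of the individual's haplotypes carries the tag risk allele
  # with probability P(S=1 | T=t)
  pS1_T1 <- if (p > 0) h[["h11"]] / p else 0
  pS1_T0 <- h[["h01"]] / (1 - p)
  tag <- rbinom(n, truth, pS1_T1) + rbinom(n, 2L - truth, pS1_T0)

  obs_tags <- sort(unique(tag))
  retries <- 0L
  repeat {
    panel <- drop(rmultinom(1L, cfg$reference_haplotypes, prob = h))
    hhat <- panel / cfg$reference_haplotypes
    # genotype-pair distribution under eta-hat, HWE: convolve two
    # independent haplotypes
    J <- matrix(hhat, 2L, 2L, byrow = TRUE)  # J[t+1, s+1]
    acc <- matrix(0, 3L, 3L)                 # acc[g+1, s+1]
    for (t1 in 0:1) for (s1 in 0:1) for (t2 in 0:1) for (s2 in 0:1)
      acc[t1 + t2 + 1L, s1 + s2 + 1L] <-
        acc[t1 + t2 + 1L, s1 + s2 + 1L] +
        J[t1 + 1L, s1 + 1L] * J[t2 + 1L, s2 + 1L]
    marg <- colSums(acc)                     # P(tag genotype)
    if (all(marg[obs_tags + 1L] > 0)) break
    retries <- retries + 1L
    if (retries > max_retries)
      stop("reference panel repeatedly left an observed tag genotype ",
           "class empty (", max_retries, " retries); increase the ",
           "panel or the tag allele frequency", call. = FALSE)
  }
  postmap <- sweep(acc, 2L, pmax(marg, .Machine$double.xmin), "/")
  post <- t(postmap[, tag + 1L, drop = FALSE])
  list(post = post, tag = tag, etahat = hhat, retries = retries)
}

#' Emulate marginal imputation of two untyped markers
#'
#' For each marker independently: (1) estimate the two-SNP haplotype
#' frequencies from a simulated reference panel drawn from the true
#' `(maf, tag_maf, r)` model - the emulated imputation-model fit; (2)
#' draw each case's observed tag genotype conditional on its true
#' target genotype under the true haplotype model; (3) hide the target
#' and emit the posterior `P(target genotype | tag genotype)` computed
#' from the panel estimate under Hardy-Weinberg.  Posterior rows depend
#' only on the tag genotype (at most 3 distinct rows per marker), and
#' imputation of one individual never depends on another - the
#' assumption under which the jackknife may resample imputed rows
#' directly.  A panel draw that leaves an observed tag genotype class
#' with zero probability is redrawn (bounded retries, counted in the
#' output attributes).
#'
#' @param G,H true genotype vectors (from [sample_cases()]).
#' @param cfg_G,cfg_H [imputation_config()] for each marker.
#' @param seed optional integer seed; `NULL` uses the current stream.
#' @param max_retries panel redraws allowed per marker (default 10).
#' @return A [posterior_matrix()] with attributes `tag_G`, `tag_H`
#'   (observed tag genotypes), `etahat_G`, `etahat_H` (panel haplotype
#'   frequency estimates) and `retries`.
#' @export
emulate_imputation <- function(G, H, cfg_G, cfg_H, seed = NULL,
                               max_retries = 10L) {
  if (!inherits(cfg_G, "imputation_config") ||
      !inherits(cfg_H, "imputation_config"))
    stop("cfg_G and cfg_H must be imputation_config objects",
         call. = FALSE)
  if (length(G) != length(H))
    stop("genotype vectors differ in length", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mg <- .emulate_marker(as.integer(G), cfg_G, max_retries)
  mh <- .emulate_marker(as.integer(H), cfg_H, max_retries)
  post <- posterior_matrix(mg$post, mh$post)
  attr(post, "tag_G") <- mg$tag
  attr(post, "tag_H") <- mh$tag
  attr(post, "etahat_G") <- mg$etahat
  attr(post, "etahat_H") <- mh$etahat
  attr(post, "retries") <- c(G = mg$retries, H = mh$retries)
  post
}

#' Imputation information content
#'
#' Squared Pearson correlation between the posterior-mean dosage and
#' the true genotype across individuals - a proxy for multi-locus LD
#' information measures: 1 for degenerate correct posteriors, 0 for
#' uninformative (constant-dosage) posteriors.
#'
#' @param post either an n x 3 matrix of posterior rows for one marker
#'   or a [posterior_matrix()] (then `marker` selects G or H).
#' @param truth true genotype vector.
#' @param marker which marker of a `posterior_matrix` to score.
#' @return A number in \[0, 1\].
#' @export
imputation_info <- function(post, truth, marker = c("G", "H")) {
  if (inherits(post, "posterior_matrix")) {
    marker <- match.arg(marker)
    post <- if (marker == "G") post$pG else post$pH
  }
  post <- as.matrix(post)
  if (nrow(post) != length(truth))
    stop("post and truth differ in length", call. = FALSE)
  if (var(truth) == 0)
    stop("true genotypes have zero variance", call. = FALSE)
  dosage <- drop(post %*% (0:2))
  if (var(dosage) == 0) return(0)
  cor(dosage, truth)^2
}
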