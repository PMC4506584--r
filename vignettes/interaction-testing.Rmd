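---
title: "Case-only interaction tests on imputed SNPs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-only interaction tests on imputed SNPs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epijack)
```

## The model

Consider two biallelic markers $G$ and $H$ on different chromosomes,
assumed in linkage equilibrium in the general population, and a sample
of $n$ cases.  Genotypes are coded $0,1,2$ = copies of the coded
(risk) allele.  The interaction parameter is the vector of local log
odds ratios of the $3\times 3$ joint genotype distribution
$p_{lm} = P(y_G = l, y_H = m \mid \text{case})$:

$$\beta_{lm} = \log\frac{p_{l,m}\,p_{l+1,m+1}}{p_{l,m+1}\,p_{l+1,m}},
\qquad l, m \in \{0, 1\}.$$

If penetrance is multiplicative, $f(l,m) = \mu\,\alpha_l\,\gamma_m$,
Bayes' rule makes the case distribution proportional to
$\alpha_l \gamma_m P(G=l)P(H=m)$ — a rank-1 table — so
$\boldsymbol\beta = 0$ regardless of the marginal effects.  This is
the case-only null of "no interaction"; it requires population-level
independence of the two loci (unlinked markers, LE), which is also
what licenses working with cases alone.

With both markers typed, $\hat\beta_{lm}$ plugs the observed cell
counts $n_{lm}$ into the formula.  With untyped markers only marginal
posterior genotype probabilities per individual are available
(the standard output of imputation tools).  Under the null the joint
posterior factorizes, so the expected joint counts are

$$E[N_{lm}] = \sum_{i=1}^n p^{(G)}_{i,l}\,p^{(H)}_{i,m},$$

the sum of outer products of the two marginal posterior rows — a
dosage generalised to joint genotypes — and $\hat\beta^{0u}$ plugs
these in instead (`build_expected_table()`, `estimate_beta()`).  With
degenerate posteriors the two constructions coincide exactly, a
reduction the test suite asserts.

## The tests

**WTT.**  $\hat\beta^\top \hat V^{-1} \hat\beta \sim \chi^2_4$ under
the null, valid for any consistent $\hat V$.  For typed markers
`analytic_variance()` supplies the multinomial delta-method covariance
evaluated at the observed proportions.

**WTT~c~.**  All six classical two-locus epistasis penetrance models
(unions/intersections of dominant and recessive conditions with
$f > g$) give interaction vectors whose four coordinates share one
sign.  Restricting the alternative to
$\Theta_1 = \{\beta \ge 0\} \cup \{\beta \le 0\}$ yields

$$\mathrm{WTT}_c = \hat\beta^\top \hat V^{-1}\hat\beta -
\min_{\beta^* \in \Theta_1}
(\hat\beta - \beta^*)^\top \hat V^{-1} (\hat\beta - \beta^*),$$

i.e. the squared $\hat V^{-1}$-norm of the cone projection.  Each
orthant's sign-constrained quadratic program is solved *exactly* by
enumerating all 16 faces (fix a coordinate subset to zero, solve the
unconstrained problem on the face, keep sign-feasible candidates, take
the minimum); the cone minimum is the smaller orthant value, with ties
broken to the non-negative orthant for determinism.  The face
enumeration is compiled (RcppArmadillo) and is cross-checked in the
tests against an independent cyclic coordinate-descent QP solver on
1000 random instances.

**The chi-bar-square reference.**  For a *convex* cone the squared
projection norm follows, exactly, a mixture
$\sum_l w_l \chi^2_l$ whose weights are the probabilities of the
projection having $l$ active coordinates — the classical
chi-bar-square theorem, which the tests verify against the closed-form
binomial weights $(1,4,6,4,1)/16$ at $V = I$.  No closed form is
implemented for general $V$; weights are estimated by seeded Monte
Carlo (default 20&nbsp;000 draws of $Z \sim N(0, V)$ through the same
projection code).

$\Theta_1$, however, is a *union* of two orthants, and the constrained
statistic is the larger of the two orthant projections.  A plain
mixture over the law of the winning projection's active dimension
understates the null tail (the max is stochastically larger than
either term), which in early experiments made WTT~c~ visibly
anti-conservative.  The package therefore uses the two-orthant
(Bonferroni) approximation: `chibar_weights(cone = "union")` records
the *average* of the two orthants' active-dimension laws, and the
p-value doubles the mixture tail and caps it at one,

$$P(\mathrm{WTT}_c \ge t) \approx \min\Big(1,\;
\sum_{l=1}^4 (w^+_l + w^-_l)\, P(\chi^2_l \ge t)\Big).$$

This overstates the true tail by exactly the overlap probability that
*both* orthant statistics exceed $t$, which vanishes in the far tail:
the test is slightly conservative in the bulk of the distribution
(its null p-values are stochastically above uniform, so a KS test
against uniformity rejects in the conservative direction) and
accurately calibrated at conventional significance levels, which is
what the acceptance suite measures.  The point mass $w_0$ at zero is
excluded from the tail sum; a zero statistic reports $p = 1$.

## Jackknife variance for imputed markers

Treating expected counts as observed counts in the analytic covariance
is wrong in this design: imputation shrinks each individual's
contribution toward its prior mean, making dosages *less* variable
than genotypes, so the plug-in *over*states the variance and the
resulting test (`naive_dosage_*`) is conservative and loses power.
The acceptance suite computes this calibration directly: across null
replicates the mean naive diagonal exceeds the empirical variance of
$\hat\beta^{0u}$ in every coordinate, while the jackknife mean tracks
it within 15%.

The proper covariance is the delete-1 jackknife on posterior rows
(`jackknife_variance()`), with pseudo-values
$\hat\beta^i_{ps} = n\hat\beta_n - (n-1)\hat\beta^i_{n-1}$ and

$$\hat V = \frac{1}{n(n-1)} \sum_i
(\hat\beta^i_{ps} - \tilde\beta)(\hat\beta^i_{ps} - \tilde\beta)^\top,$$

centred at the pseudo-value mean $\tilde\beta$ (not at
$\hat\beta_n$).  Resampling imputed rows without re-imputation is
exactly valid when the imputation model is fitted on an external
reference panel only, so that one individual's posterior does not
depend on the other study individuals; the emulator below honours
this by construction, and reference-panel-only tools satisfy it in
practice.  Each leave-one-out estimate subtracts one outer product
from the full expected table ($O(1)$ per individual), and individuals
with identical posterior row pairs share a single leave-one-out
computation weighted by group size — at most $3\times 3 = 9$ groups
when posteriors depend only on a tag genotype pair, which reduces the
whole estimator to a handful of $3\times 3$ operations regardless of
$n$.  Grouped and ungrouped paths agree to summation-order rounding
(asserted at $10^{-12}$).

## The imputation emulator

The simulator reproduces the *statistical structure* of marginal
imputation without external software or reference data:

1. each untyped target marker has one typed tag SNP; target/tag
   alleles on a haplotype follow a $2\times2$ frequency model
   parameterised by target MAF $p$, tag MAF $q$ and haplotype
   correlation $r$;
2. the imputation model parameters $\hat\eta_0$ are *estimated* from a
   simulated reference panel of $R$ haplotypes (default 120, a
   HapMap-sized panel), so posteriors carry realistic panel noise;
3. each case's tag genotype is drawn conditional on its true target
   genotype under the *true* haplotype law, the target is hidden, and
   the posterior $P(\text{target} \mid \text{tag})$ is computed from
   $\hat\eta_0$ under Hardy–Weinberg.

Posterior rows depend only on the tag genotype (at most 3 distinct
rows per marker).  A panel draw that assigns zero probability to an
*observed* tag genotype class cannot produce a posterior and is
redrawn (bounded retries, counted).  Redrawing is deliberately *not*
triggered by merely empty haplotype classes: at strong LD the rare
recombinant class is frequently absent from a 120-haplotype panel,
and that misestimation is precisely the $\hat\eta_0$ noise the
jackknife is supposed to absorb; censoring such panels would bias the
emulated uncertainty downward.

Information content is summarised by `imputation_info()`, the squared
correlation between posterior-mean dosage and truth (1 = perfect,
0 = uninformative), a proxy for multi-locus LD information measures.
For a single tag this is approximately $r^2$, so emulator settings
target an information level by $r = \sqrt{\text{target}}$; the study
harness records the realized value per replicate.

What the emulator does *not* reproduce: multi-marker haplotype models,
phasing uncertainty structure across many tags, study-data-dependent
imputation (IMPUTE2-style), linked markers, or genotyping error.
Passing tests therefore certify the estimators' behaviour under
reference-panel-only marginal imputation with tag-controlled
information — not the end-to-end behaviour of any specific imputation
software on real LD structure.

## Study conditions and defaults

The study harness (`run_study()`) mirrors a standard evaluation
design: **5000 cases per replicate; 3000 replicates for size at level
0.01 under the multiplicative null; 100 replicates for power at level
0.05** (the acceptance suite raises power runs to 1000 replicates for
tighter Monte Carlo error).  Three arms are paired within replicate:
truth (tests on the sampled genotypes, analytic variance), jackknife
(emulated imputation, jackknife variance) and naive dosage (same
posteriors, plug-in variance).  Chi-bar weights are recomputed from
each replicate's own covariance estimate by default, since the
mixture is tied to the variance estimator; a shared-weights fast mode
exists but is off by default.  Replicates rejected by the zero-cell
policy are excluded and counted, and more than 1% exclusions aborts
the run — silent exclusion would bias size estimates.

Defaults fixed at design time:

* **MAF 0.3 at both markers** — a common-variant setting in which all
  nine cells have comfortably positive expected counts at
  $n = 5000$ (smallest $\approx 40$).
* **Epistasis penetrances $f = 0.0125$, $g = 0.01$** for power runs: a
  noncentrality calculation for the dominant-union model at these
  frequencies gives truth-arm power around 0.8 at level 0.05, so the
  arm and constraint orderings are informative rather than saturated.
* **Emulator $r = \sqrt{0.9003}$ and $\sqrt{0.7615}$** for the
  high-information pair of markers, $r = \sqrt{0.0235}$ for the
  low-information regime, reproducing realized information levels of
  about 0.90/0.76 and 0.02; panel size 120 haplotypes.
* Baseline penetrance $\mu = 0.01$ for the multiplicative null.

## Numerical choices

* Covariances are inverted through a Cholesky factorisation after a
  symmetry check ($10^{-8}$) and a positive-definiteness check with
  tolerance $10^{-10}$ on the smallest eigenvalue (relative to the
  largest); failures produce a diagnostic pointing at zero cells and
  the grouping/Haldane remedies.
* Zero cells make the log odds ratio estimator undefined.  The default
  policy is a hard error naming the cell; `zero_policy = "haldane"`
  adds the Haldane–Anscombe 0.5 to *all nine* cells and flags the
  estimate.  The leave-one-out tables of the jackknife inherit the
  caller's policy.
* Face-enumeration candidates are accepted as sign-feasible within
  $10^{-9}$ and active coordinates counted above $10^{-10}$; orthant
  ties break to the non-negative orthant.
* GEN probability triples are renormalized on load (files are rounded
  to a few decimals); sums outside $[0.95, 1.05]$ are rejected.
* Per-replicate seeds in studies derive deterministically from the
  master seed, so identical configurations give bit-identical results
  and methods are compared on the same data.

## Limitations

* Low allele frequencies break the asymptotics (and the jackknife)
  through near-empty cells; the Haldane option is a palliative, not a
  fix.  Collapsing genotype configurations for rare variants is out of
  scope.
* The truth-arm WTT inherits the finite-sample skew of log odds
  ratios: with the smallest expected cell around 40, its size at
  level 0.01 runs marginally above nominal (within the Monte Carlo
  bands asserted in the acceptance suite) and tightens as counts
  grow.
* The union-cone chi-bar tail is a bounded approximation (see above):
  slightly conservative overall, tight at small levels.
* Markers must be unlinked and in LE; the linked-SNP extension with
  controls is not implemented.  Case-control logistic interaction
  tests, full-likelihood joint imputation-and-testing, BGEN/VCF dosage
  parsing and batch pair scanning are out of scope.
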