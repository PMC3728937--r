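---
title: "Genomic cline analysis with gencline: models, outlier detection, and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic cline analysis with gencline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gencline)
```

## The problem

In a hybrid zone or admixed population between parental populations P1 and
P2, each individual (or pooled locality) carries a genome-wide ancestry
$S$ — the proportion of its genome inherited from P1.  If every locus
introgressed identically, the locus-specific ancestry probability $p_i$
would equal $S$ everywhere.  Genomic cline analysis asks how each locus
*deviates* from that expectation: loci tied to hybrid dysfunction, hybrid
vigor, or local adaptation trace distinctive curves of $p_i$ against $S$.
The statistical difficulty is that genetic drift alone also moves loci
away from $p_i = S$, so rejecting that naive null hypothesis is *not*
evidence of selection.  `gencline` implements (i) a family of cline
models fitted by maximum likelihood, (ii) multivariate outlier detection
that is robust to drift, and (iii) an individual-based simulator of
secondary contact used to evaluate both.

## The cline models

All models map $S \in [0,1]$ to $p \in [0,1]$ with two free parameters.

* **Logit-logistic** (`logit_logistic_cline`):
  $\mathrm{logit}(p) = u + v\,\mathrm{logit}(S)$, $v > 0$.  This is the
  form implied by logistic geographic clines for both the focal locus and
  the genome average: $u$ is the relative cline position and $v$ the
  relative slope, with $(u,v) = (0,1)$ the concordant cline $p = S$.  It
  is monotone, respects both endpoint constraints ($p = 0$ at $S = 0$,
  $p = 1$ at $S = 1$), and is the only model here with a
  population-genetic derivation.
* **Beta** (`beta_cline`): $p = I_S(\mu\nu, (1-\mu)\nu)$, the regularized
  incomplete beta function, i.e. the CDF of a Beta distribution in a
  location ($\mu$) / precision ($\nu$) parameterization.  Strictly
  monotone, endpoint-respecting, very flexible; $(\mu,\nu) = (0.5, 2)$
  is the identity.
* **Spliced Barton** (`barton_cline`): the quadratic-deviation polynomial
  $p = S + 2S(1-S)\bigl(a + b(2S-1)\bigr)$, hard-clipped to $[0,1]$.  The
  raw polynomial can leave $[0,1]$ and can be non-monotone; we splice
  horizontal lines at 0 and 1 but deliberately *retain* interior
  non-monotonicity, which is a genuinely distinctive shape this model
  alone can express.  No re-normalization is applied after clipping — the
  spliced curve is exactly the clipped polynomial.
* **Binomial regression** (`fit_binomial_regression`):
  $\mathrm{logit}(p) = \alpha + \beta S$, the standard GLM.  It shares
  the likelihood with the cline models but does not force $p$ to 0/1 at
  the ends of the ancestry range — a violation of the definition of $S$,
  or useful flexibility, depending on one's assumptions.
* **Multinomial regression** (`fit_multinomial_regression`): a
  baseline-category logit for the three diploid genotype classes with
  linear predictors in $S$ (4 parameters).  It is the only model that
  sees heterozygosity, so it can expose genotype-scoring artifacts
  ("ringer" loci with no heterozygotes) invisible to allele counts.
  Note its linear-in-$S$ predictors cannot represent Hardy–Weinberg
  proportions $2S(1-S)$ exactly; the fitted curves are approximations.

## Likelihood and fitting

Diagnostic biallelic markers are scored as counts: unit $k$ contributes
$x_k$ P1 alleles out of $2n_k$ sampled, with ancestry $S_k$.  The
likelihood is the product of binomials
$\prod_k \binom{2n_k}{x_k} p_k^{x_k} (1-p_k)^{2n_k - x_k}$ with $p_k$
given by the cline model at $S_k$.  Binomial coefficients are included so
log-likelihoods are comparable across models.  Units may be individuals
($2n = 2$) or pooled localities; pooling counts and ancestry per locality
(`pool_counts(..., level = "locality")`) accounts for non-independence of
individuals sampled at the same site.

Numerical choices:

* Optimization is unconstrained via smooth reparameterization:
  $(u, \log v)$, $(\mathrm{logit}\,\mu, \log\nu)$, $(a, b)$.
* `fit_cline_ml` runs Nelder–Mead from the null (identity) parameters
  plus up to 8 *fixed* dispersed offsets (default 5 starts in total) and
  keeps the best exact log-likelihood.  Deterministic offsets were chosen
  over random jitter so fitting consumes no RNG; the null point is always
  a candidate, which guarantees the nesting property
  $\ell(\hat\theta) \ge \ell_0$ for the cline models.  Multi-start
  matters mainly for the Barton model, whose clipped surface can be
  multimodal.
* Inside the optimizer, probabilities at interior $S$ are clipped to
  $[10^{-12}, 1-10^{-12}]$ so the spliced Barton model has a finite
  surface; the reported log-likelihood is exact (un-clipped).  Units at
  $S = 0$ or $1$ are used as-is: the cline models pin $p$ there, so
  consistent counts contribute zero log-likelihood and contradictory
  counts make the model infinitely bad (reported, not dropped).
* Internally the likelihood is collapsed over unique $S$ values (an exact
  sufficient reduction) so per-individual datasets with ~1000 individuals
  fit quickly.
* The multinomial log-likelihood is concave, so a single BFGS run with
  the analytic gradient suffices; with fewer than two distinct $S$
  values an intercept-only model is fitted (its MLE reproduces the
  observed genotype proportions).

`lrt_vs_null` tests the naive null $p = S$ with
$2(\ell(\hat\theta) - \ell_0) \sim \chi^2_d$, $d$ = number of fitted
parameters.  For binomial regression the same reference point is used,
though $p = S$ is not exactly representable within that family; no LRT is
defined for the multinomial (there is no genotype-level naive null).
`aicc` compares models per locus with the small-sample AIC, using the
number of sampling units $K$ as the sample size (units are the
independent observations in the likelihood); ties are broken by a fixed,
documented model order.

## Outlier detection

Drift spreads the *true* per-locus cline parameters over time, so the
null-hypothesis tests above reject more and more neutral loci as a hybrid
zone ages.  `detect_outliers` instead compares each locus to the
*empirical* among-locus distribution of fitted parameters: with
$\hat\theta_i$ approximately multivariate normal across loci, the squared
Mahalanobis distance $D^2_i$ from the among-locus mean (standardized by
the among-locus covariance) is approximately $\chi^2_d$.  A locus is
flagged when its upper-tail probability falls below the
Bonferroni-adjusted threshold $\alpha/L$.  Because the reference
distribution is re-estimated from the data at hand, it widens along with
drift, keeping the false-positive rate low at any age of the zone — the
property the simulation study verifies.

Choices: the classical mean/covariance estimator is the default (a
leave-one-out variant is available via `leave_one_out = TRUE`, off by
default); Q–Q coordinates use plotting positions $(i - 0.5)/L$.  The
scale on which $D^2$ is computed matters and both are exposed
(`fit_snapshot` returns `npar` and `tpar`): the log/logit optimization
scale looks closer to multivariate normality for interior estimates, but
loci whose MLE sits on a boundary — a flat locus drives the slope
towards $v = 0$, and the likelihood is essentially flat below some small
$v$ — end up with $\log \hat v$ equal to wherever the optimizer stopped
(−10, −16, ...), an arbitrary coordinate many SDs from the bulk that the
covariance screen then flags.  In simulation these log-scale artifacts
dominated the false positives of the allele-count models.  On the
natural scale the same loci sit harmlessly near $v = 0$, and the
per-model false-positive pattern (Barton lowest, beta above the
logit-logistic, multinomial far highest) matches the known behavior of
these methods, so the **natural scale is the default** for
`run_study`/`detect_outliers` workflows, with `outlier_scale = "optim"`
available.
`mahalanobis_d2` requires more loci than parameters plus one and reports
singular covariances with guidance rather than proceeding.

## The simulator

`run_simulation` implements stochastic, individual-based secondary
contact on the continuous square $[-3,3]^2$ with non-overlapping
generations.  Defaults state the standard scenario:

| parameter | default | meaning |
|---|---|---|
| founders | 500/side | pure P1 (left half) and P2 (right half) at contact |
| loci | 100 | unlinked, diagnostic; up to 4 under selection |
| dispersal, mating SD | 0.3 | 5% of the space |
| density-kernel SD | 0.2 | neighborhood defining local density |
| R | 2 | uncrowded growth rate |
| K | 14 | local density at which fecundity = 1 |

Each individual mothers a Poisson number of offspring with mean
$f(D)\,w$, where $f(D) = R / (1 + (R-1) D / K)$ is a Beverton–Holt
function of local density $D$ and $w$ is her relative fitness (selection
acts on female fecundity only).  $D$ is the sum over all individuals
(self included) of the univariate normal density of their distance
(SD 0.2).  This reading of "a normal density of distance" is what
calibrates the model: in the mean field it gives a steady state of
$36 \cdot 14/(0.2\sqrt{2\pi}) \approx 1000$ individuals, matching the
stated demography, whereas a bivariate-kernel reading would equilibrate
near 500.  Fathers are drawn per offspring with weight proportional to a
normal density of distance (SD 0.3, self excluded) in the hybrid-zone
model, or uniformly in the admixture model; inheritance is Mendelian
with free recombination; offspring disperse from the mother (bivariate
normal, SD 0.3) or uniformly (admixture).

Boundaries: closed populations clamp out-of-space draws to the nearest
edge.  Open populations replace offspring that *draw* an x-position
within the 5% strip adjoining either x-boundary with a pure parental
genotype (P1 on the founders' P1 side), keeping the position; draws
beyond the boundary get the generic nearest-edge reassignment with
genotype kept.  Extending replacement to clamped overshoots would pile
immigrants into an atom at the edge and push the per-side replacement
rate to ~7.5% per generation, contradicting the ~5% the strip geometry
implies; the implemented rule yields 4–5% per side.

Selection components multiply (independent effects): a logistic
environmental gradient $g(x)$ with Gaussian stabilizing selection
$e^{-s_E (z - g)^2}$ on the E-locus phenotype $z \in \{0, 0.5, 1\}$;
heterozygote disadvantage ($w_{het} = 1 - h$) or advantage
($w_{hom} = 1 - s_H$) at the H locus; and a partially recessive
Dobzhansky–Muller incompatibility between loci A and B ($1 - d$ for the
doubly homozygous incompatible combination, $1 - d/2$ for its singly
heterozygous neighbors).  The exact functional forms of the fitness
components and the two interior DMI cells are implementation decisions
consistent with the stated "partial recessive" structure; numeric
examples derived under them are decisions of this package, not external
ground truth.  A direct genotype-fitness mode
(`selection_config(direct = c(0.2, 0.6, 1))`) expresses a plain P1
advantage without the gradient machinery.

### What the generator emulates — and what it does not

The simulator produces diploid, unlinked, diagnostic markers under
drift, migration and the four selection modes, with realistic spatial
structure.  It does **not** model linkage, genotyping error, male-side
selection, overlapping generations, non-diagnostic markers, or coupling
among many selected loci (at most 4 of 100 loci are selected — "low
coupling" by design, so stepped multilocus clines do not arise).  A green
test therefore establishes correct behavior *within* this stated world;
it says nothing about, e.g., linked selection or stepped clines.

## The study harness

`run_study` reproduces the evaluation protocol: simulate each cell of
the 18-row selection grid (`table2_grid()`) under closed/open and
hybrid-zone/admixture conditions, fit all five models to every locus at
each census (10, 25, 50, 100 generations), and tabulate (i) Bonferroni
LRT rejections of $p = S$ among neutral loci in no-selection runs, (ii)
AICc best-fit percentages, and (iii) outlier precision and sensitivity
pooled over runs.  Fitting treats individuals as units with
per-individual $S$ computed from their own 100 loci (simulations have no
localities).  The full factorial is 72 runs; the desk-scale rerun used in
the acceptance tests takes `study_cells(conditions = "round_robin")` —
each selection row once, the four conditions assigned in rotation — with
250 founders per side and censuses 25 and 50, which preserves the
qualitative method ordering (logit-logistic dominating Barton on
precision and sensitivity, multinomial paying with false positives) at a
fraction of the cost.  Published single-run tallies are matched in trend
only; every cell of a study is reproducible bit-for-bit from its seed.

## Known limitations

* Ancestry $S$ is estimated from the same markers being fit (as in
  empirical practice); a leave-one-locus-out option is not provided.
* Non-diagnostic or multiallelic markers are out of scope; genotypes must
  be 0/1/2 counts of the declared P1 allele.
* The hierarchical Bayesian treatment of genotyping error and parental
  allele-frequency uncertainty is out of scope; the likelihood machinery
  here is the groundwork such an extension would reuse.
* Stepped/asymmetric geographic cline forms arising from multilocus
  coupling are not modeled.
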