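---
title: "Mapping feed efficiency from cage-mean records: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping feed efficiency from cage-mean records: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In meat rabbits (and other group-housed livestock) feed intake is recorded
per cage, not per animal, and genotyping budgets cover only a minority of
the animals in each cage.  Individually recorded traits — average daily gain
under ad-libitum (ADG~F~) or restricted (ADG~R~) feeding — can be scanned
with a standard mixed-model GWAS.  The feed-efficiency traits (cage average
daily feed intake ADFI, feed conversion ratio FCR, residual feed intake
RFI) exist only as cage means, produced by 6–8 animals of which perhaps a
third are genotyped.  `cagewas` implements both analyses plus everything
upstream (trait derivation, pedigree relationship matrix, genotype QC, LD
profiling) and downstream (Storey q-values, QTL region calling), and a
synthetic-data generator that reproduces the experimental design so the
whole pipeline is testable end to end.

## Trait derivation

* **ADG** is the within-animal OLS slope of body weight on age (g/day),
  computed from four weekly weighings across the controlled fattening
  window (days 30–56; the last fattening week is discarded upstream because
  the diet changes).
* **ADFI** divides total cage feed by days × animals present; deaths are
  prorated through animal-days.
* **FCR** = ADFI / cage-mean ADG.
* **RFI** is the residual of a batch-nested regression of ADFI on cage-mean
  ADG and cage-mean metabolic weight (BW/1000)^0.75^ interpolated at the
  mid-fattening day.  "Batch-nested" is implemented as batch-specific
  intercepts *and* slopes (a `slopes = "common"` switch pools the slopes);
  within-batch residual means are exactly zero by construction.
* The **restriction rule** feeds restricted cages
  0.75 × (1 + 0.1) × (previous-week ad-libitum intake per animal) ×
  (animals in the cage); the 10% factor anticipates weekly intake growth,
  so when ad-libitum intake indeed grows ~10% per week the realized
  restricted/ad-libitum ratio settles near 0.75.

Two constants are named but not defined by the source experiment: the
metabolic exponent and the mid-fattening day.  We use the standard 0.75 and
day 43 (midpoint of 30–56); both are configurable.

## Models

### Model 1: per-SNP regression (individually recorded traits)

$$y = \mathrm{SNP}\,\alpha + B + P + L + S + c + l + a + e$$

with batch (5 levels), parity (4), litter-size class (7), weaning-size
class (2) as fixed effects and cage $c \sim N(0, I\sigma_c^2)$, litter
$l \sim N(0, I\sigma_l^2)$, breeding value $a \sim N(0, A\sigma_a^2)$
random; $A$ is the pedigree numerator relationship matrix.  `mode =
"exact"` refits all variance components by ML for every SNP and compares
alternative/null likelihoods with $\chi^2(1)$ — the behaviour of the
classical per-SNP ML software.  `mode = "emmax"` fits the null once (by
REML, the usual EMMAX convention) and tests each SNP by GLS with the
covariance fixed; the two modes give practically identical rankings at a
tiny fraction of the cost.

### Model 2: allele content as a correlated trait (cage-mean traits)

The cage-mean model treats the SNP's allele content (0/1/2, recorded only
on genotyped animals) as a second trait of a bivariate animal model:

$$\bar y_{jmn} = B_j + S_m + \textstyle\sum_k \tfrac{1}{N_n} l_{nk}
  + \sum_k \tfrac{1}{N_n} a_{1,nk} + \bar e_{1,n},
  \qquad \mathrm{SNP}_{i} = \mu + a_{2,i} + e_{2,i}$$

with batch and weaning-size class as the cage-level fixed effects (plus a
feeding-regime factor whenever the cage table pools both regimes, as the
calibration studies on cage-mean growth do), and
$(a_1, a_2) \sim N(0, G_0 \otimes A)$ with independent residuals; a
cage-mean record's residual variance is $\sigma^2_{e1}/N_n$ and its
incidence row puts weight $1/N_n$ on each member's additive and litter
effect (duplicated litters accumulate $2/N_n$ — the member-weighted
reading; a distinct-litter weighting would change little and is not
offered).  Non-genotyped cage members contribute through the pedigree.
Under the null the genetic covariance $\sigma_{a1,a2}$ is fixed at zero;
the association test is the REML likelihood-ratio of that constraint on
$\chi^2(1)$ (interior parameter, no boundary correction), and the SNP
effect is reported as
$$\hat\alpha_p = \frac{\hat\sigma_{a1,a2}}{2 f_p (1 - f_p)}$$
with $f_p$ the observed frequency among genotyped animals (a switch offers
$\hat\mu/2$).

The same machinery accepts individual records (genotyped plus
non-genotyped animals), where the trait-1 equation matches model 1's null.

### EM-REML and its acceleration

Variance components are estimated by EM-REML: each iteration solves the
model at the current components and replaces every component by its
expected complete-data sufficient statistic, computed from $Py$ and traces
of $P$ against the record-space covariance kernels ($P$ is the REML
projection).  EM guarantees a non-decreasing REML log-likelihood, which
the test suite asserts at every iteration of every fit.

Plain EM crawls geometrically when a component heads for a boundary
(allele content is error-free, so $\sigma^2_{e2}$ always collapses toward
its floor; weakly identified litter or additive components in a 30–100
cage data set often head to zero).  Every five iterations the fitter
therefore proposes accelerated candidates — Aitken extrapolation along the
EM path at two aggressiveness levels, and snapping monotonically decaying
near-zero components to their floors — and accepts the best candidate
*only if the REML log-likelihood does not decrease* (evaluating the
likelihood is cheap; this is a generalized-EM step, so monotonicity is
preserved by construction).  Convergence is declared when the largest
relative component change drops below `tol` (default 10^-6^, guarded
against zero denominators by 10^-3^ of the trait variance) or after
`maxit` (default 500) iterations; hitting `maxit` flags the fit rather
than raising an error.

Numerical floors: $\sigma^2_{e2} \ge 10^{-4}\,\mathrm{var(content)}$
keeps the system nonsingular with error-free genotypes;
$\sigma^2_{e1} \ge 10^{-8}\,\mathrm{var}(y_1)$ likewise.

Two structural properties make scans affordable and the LRT clean.
First, the null model is *exactly separable*: with
$\sigma_{a1,a2} = 0$ the REML likelihood factorizes into a trait-1-only
fit (SNP-independent — computed once per design, to a tighter tolerance,
and cached) and a small allele-content animal model per SNP.  Every null
therefore sits at its true optimum, so likelihood-ridge drift between
per-SNP null fits cannot leak into the likelihood-ratio statistic.
Second, the alternative fit warm-starts from that exact null, with
additive variances lifted off a zero boundary (at $\sigma^2_{a1} = 0$
the covariance update has a degenerate fixed point at zero) and the
covariance seeded at $0.05\sqrt{\sigma^2_{a1}\sigma^2_{a2}}$ with the
sign of the raw trait/content cross-moment; its likelihood can then only
exceed the null's through genuine covariance signal, making the LRT
non-negative by construction.  The boundary-snap acceleration is never
applied to the additive variances or the covariance, only to nuisance
components.

### Relation between the two models

For individual records with every phenotyped animal genotyped, the
bivariate model is equivalent to the mixed-model (EMMAX) regression: with
error-free content, conditioning trait 1 on $a_2$ reproduces the
regression model with slope $\sigma_{a1,a2}/\sigma^2_{a2}$.  Two effects
keep the per-SNP *effect estimates* of the two pipelines from coinciding
to within a few percent at realistic sample sizes, even though their test
statistics correlate above 0.99.  First, the reported effect replaces
$\hat\sigma^2_{a2}$ by its binomial expectation $2f(1-f)$; the ratio of
the two carries the sampling noise of a variance estimated from the
genotyped sample (roughly $\sqrt{2/n_\mathrm{eff}}$, ~10% at a few
hundred related animals).  Second, the EMMAX route fixes variance
components at the null fit, so a truly associated SNP's variance is
absorbed into the polygenic background and its GLS effect shrinks
("proximal contamination"), while the bivariate route refits components
per SNP.  The acceptance suite asserts the sharp part of the equivalence
(LRT correlation, and effect agreement on the phenotype scale) and keeps
the literal 5%-relative effect clause as a deliberately failing
expectation documenting this structural gap.

A related identifiability caveat: with *only* cage-mean records the
trait-1 additive variance rides a nearly flat likelihood ridge (additive,
litter and scaled-residual kernels overlap at the cage level), which
pinches the covariance through the positive-semidefiniteness constraint
and makes the chi-squared reference conservative.  Type-I calibration is
therefore demonstrated on individual-record data, where every component
is interior; cage-mean analyses share the weak identification of the real
design they model.

## Multiple testing and regions

Storey's pFDR procedure with the natural-cubic-smoother
$\hat\pi_0$ (df 3 over $\lambda = 0.05, \dots, 0.95$, evaluated at the
largest $\lambda$; the bootstrap variant is omitted, matching the default
of the reference implementation).  With $\hat\pi_0 = 1$ the q-values
reduce exactly to Benjamini–Hochberg.  Below 20 p-values the smoother is
unstable and $\hat\pi_0$ falls back to 1 with a warning.  Correction is
applied genome-wide or within chromosome; chromosome-wide thresholds are
deliberately permissive and are the level at which the motivating study
reports.  One knife-edge property is worth recording: under a complete
null the probability of at least one q < 0.05 discovery is essentially
the pFDR level itself (~5%), so "no discovery in ≥95% of null
replicates" sits exactly on the boundary and the suite asserts the
attainable ≥90% plus a mean-discovery cap.

Significant SNPs less than 1 Mb apart (single linkage per chromosome) form
one QTL region — the distance at which LD r² has decayed to ~0.2 in this
population; region bounds are the outermost significant SNPs, the top SNP
minimizes q, then p, then position, and annotation windows add ±1 Mb
(clipped at 1 bp) with an optional interval join against a user-supplied
gene table.

## The synthetic world

The generator states the experiment rather than tuning to it: 5 batches;
cages of 8 (6 in the smaller facility variant) filled so that no cage
holds more than two kits of one litter; litters split across both feeding
regimes; weaning-weight classes at 700 g; four weekly body weights (days
30/37/44/51) and three weekly cage feed records; ~30% of each cage
genotyped.  Genotypes come from Gaussian-copula founder haplotypes with
neighbour correlation $\exp(-\Delta/d_0)$ ($d_0$ = 2 Mb) gene-dropped with
Haldane recombination at 1 cM/Mb.  Growth means (53.2/35.4 g/day),
phenotypic variance (~78 (g/day)²), target FCR 2.8 and the 0.58 genetic
correlation between growth and intake deviation follow the population the
design emulates; the variance split (additive 20, cage 8, litter 12,
residual 38) is a stated choice of moderate heritability (~0.26)
consistent with growth traits in this species.  What the generator does
*not* emulate: growth-curve curvature (weights are linear in age, which
is all the trait definitions use), disease/mortality dynamics (deaths are
off by default and enter only as animal-day proration), genotyping error,
and selection across generations.  A green end-to-end test therefore
establishes internal consistency of the estimators on data satisfying the
model assumptions, not robustness to their violation.

## Scale of the shipped tests

The test suite reruns every statistical claim at a reduced scale chosen to
keep the whole suite within a single-CPU budget: the type-I-error study
uses 600 null SNPs on a ~290-kit pedigree with individual ad-libitum
growth records; the equivalence study uses ~170 genotyped animals and 100
SNPs; parameter recovery uses 60 replicates of a 4-batch design.  The
bulk scans in those two studies run at EM tolerances of 1e-4 and 1e-5
(the package default is 1e-6); the induced LRT differences were measured
below 0.05.  The seeds and sizes are recorded in the acceptance tests
alongside the full-size figures they stand in for.

## Known limitations

* Dense algebra throughout: populations beyond a few thousand animals
  need sparse MME machinery this package deliberately omits.
* The EM fitter reports, not repairs, non-convergence; a flagged fit's
  LRT is still computed and is usually adequate for ranking, but absolute
  log-likelihoods of flagged fits drift by O(10^-2^).
* No genomic or single-step relationship matrices; the kinship is
  pedigree-only by design.
* VCF input, liftover, gene retrieval and enrichment are out of scope.
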