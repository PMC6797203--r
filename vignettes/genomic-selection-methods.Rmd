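---
title: "Genomic selection with fixed large-effect SNPs and G-by-E: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection with fixed large-effect SNPs and G-by-E: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GSfix)
```

GSfix implements an end-to-end genomic-selection workflow for a maize
biparental BC1F3:4 population: a breeding-scheme simulator, the
multi-environment phenotype mixed model, mixed-model GWAS with a VanRaden
relationship matrix, a sequential-regression decomposition of phenotypic
variance over top-ranked SNPs, and GBLUP/Bayesian multi-kernel genomic
prediction with optional large-effect SNPs fitted as fixed effects, under
repeated five-fold, CV1 and CV2 cross-validation. This vignette explains
the models, the default parameters, and the design choices that were
genuinely open.

## The population and its simulator

The population emulated is derived from two elite inbreds: a donor
(Zheng58) crossed to a recurrent parent (PH4CV), the F1 backcrossed to
PH4CV to give BC1F1, each BC1F1 mother pollinated with bulked pollen from
at least ten other BC1F1 plants (giving "bulk-BC1F2" families), and plants
selfed once so that BC1F3 individuals are genotyped while their selfed
BC1F3:4 families are phenotyped.

Genotypes are coded −1/0/+1 for Zheng58 homozygote, heterozygote and PH4CV
homozygote. Under this scheme the donor-allele frequency in BC1F1 gametes
is 1/4, random union at the intermating step gives genotype classes
(9, 6, 1)/16, and one selfing halves heterozygosity, so the expected
genome composition of a BC1F3 plant is

* PH4CV homozygous: 10.5/16 = 65.625%
* heterozygous: 3/16 = 18.75%
* Zheng58 homozygous: 2.5/16 = 15.625%

— within sampling error of what the field population showed. The
simulator (`simulateCross()`) implements this pedigree gamete by gamete
with a Haldane meiosis model: crossover counts are Poisson in the
chromosome's genetic length, breakpoints uniform, no interference. The
default map is 10 chromosomes of 1.8 Morgans each (a typical maize
chromosome length; the study provides no genetic map), with marker
positions interpolated linearly between bp and cM. Defaults for the scheme
are the study's sizes: 43 bulk-BC1F2 families, 3 selfed plants per family,
481 BC1F3 plants allocated round-robin over the 129 ears. The description
of "481 BC1F3 plants from three BC1F2 ears" is ambiguous between three
ears in total and three per family; we read it as three selfed plants per
family (configurable via `CrossingScheme()`), since three ears in total
could not produce 481 segregating lines with the observed diversity.

`simulateTrait()` generates
$y_{ijm} = \mu_j + \sum_q a_q g_{iq} + \sum_q d_{qj} g_{iq} + \delta_{(j)m} + \varepsilon_{ijm}$
from the BC1F3 parent genotypes: additive QTL effects $a_q$,
per-(QTL, environment) deviations $d_{qj} \sim N(0, \sigma_{d,q}^2)$ held
fixed across replicates (a variance-component reading of G×E),
replicate-within-environment effects and i.i.d. residuals. Phenotyping the
BC1F3:4 family is approximated by the BC1F3 parent's genotype
(family-mean approximation); within-family segregation variance is folded
into the residual. When `targetH2` is set, the residual standard deviation
is solved from the entry-mean heritability formula given the *realized*
genetic and interaction variances of the simulated population, so the
heritability calibration is exact in expectation rather than nominal.

What the simulator does **not** emulate: dominance and epistasis,
selection during pedigree propagation, genotyping error, sequence-level
variation, and field spatial structure. Tests passing on these data
demonstrate correctness of the estimators under the stated model, not
robustness to those real-data features.

## Phenotype mixed model

BLUEs and variance components come from
$y_{ijm} = \mu + g_i + e_j + ge_{ij} + \delta_{(j)m} + \varepsilon_{ijm}$
with replicate nested in environment, fitted by REML through lme4 (the
standard tool for exactly this model). For BLUEs the genotype is fixed and
reported as $\hat\mu + \hat g_i$, which is invariant to the contrast
parameterization; the replicate term is kept in both the BLUE fit and the
variance-component fit (the model statement includes it; dropping it only
for BLUEs would change nothing in balanced data and is harder to defend in
unbalanced data). Entry-mean heritability is
$H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_{ge}^2/N_e + \sigma_\varepsilon^2/(rN_e))$.
On balanced data the REML estimates coincide with the ANOVA
expected-mean-squares method of moments; the test suite checks that
equality to 1e−6, which required tightening lme4's optimizer (bobyqa with
`rhoend = 1e-13`). Families absent from an environment are handled by REML
itself; no phenotype imputation is done.

## Kinship, GWAS, PVE

Marker QC removes markers missing in either parent, non-polymorphic
between parents, or with population missing rate strictly above 0.05
(exactly 0.05 is kept). Missing calls are imputed with the marker's
expected code under observed genotype frequencies — the observed column
mean, possibly fractional. The VanRaden relationship matrix is
$K = WW' / (2\sum_j p_j q_j)$ with $W = M - P$ and $P_{\cdot j} = 2(p_j - 0.5)$,
allele frequencies taken from the imputed sample rather than the pedigree
expectation (the matrix then reflects the realized population).

The GWAS model is $y^* = X\beta + Zg + W\tau + \varepsilon$ with
$g \sim N(0, K\sigma_u^2)$, fitted on BLUEs. The null-model variance
components are estimated once by spectral REML on the eigendecomposition
of $K$ and reused for every marker (P3D); each marker is then tested by
generalized least squares in the rotated space with a Wald t-test on
$n - 2$ degrees of freedom. Exact per-marker REML is available via
`perMarkerReml = TRUE`; at this scale the difference is negligible and
P3D is two orders of magnitude faster. The tested marker stays in $K$
during its own test, matching common single-locus mixed-model tools. No
multiple-testing correction is applied — the scan ranks markers, it does
not declare significance.

The top-50 SNPs (descending $-\log_{10} p$, ties broken by chromosome and
position) are fitted jointly in one multiple regression on the BLUEs and
each SNP's sequential (Type-I) sum of squares, in rank order, is divided
by a denominator to give its PVE. The denominator is ambiguous in the
field's usage ("sum of squares of the linear model" vs total); we default
to the **total corrected SS** of the response, because only then is the
ratio a fraction of phenotypic variance, and expose the model-SS reading
via `denominator = "model"`. Under the total-SS convention the SNP PVEs
plus the residual fraction sum to one. Collinear SNPs are dropped with a
warning.

## Prediction engines

Two solvers fit $y = X_f\beta + \sum_k Z_k u_k + \varepsilon$ with
$u_k \sim N(0, K_k\sigma_k^2)$:

* **Spectral REML** (`solveGblupReml()`): single-kernel, deterministic
  one-dimensional optimization of the restricted likelihood in
  $\delta = \sigma_\varepsilon^2/\sigma_u^2$ on the eigendecomposition of
  $K$, GLS fixed effects, BLUP genetic values. Used by default for
  single-response cross-validation, where speed and determinism matter.
* **Gibbs sampler** (`solveBayesGibbs()`): any number of kernels,
  scaled-inverse-χ² priors on all variances (df 5, prior modes splitting
  half the response variance over the kernels and half to the residual —
  a common default in Bayesian genomic-selection software, configurable
  via `ChainConfig()`), flat prior on β. Each kernel is eigendecomposed
  once and its genetic values are sampled jointly in the eigencoefficient
  space, which reduces to independent scalar updates whenever the
  incidence cross-product is diagonal (all unmasked designs) and to one
  Cholesky per iteration otherwise. Defaults are 20,000 iterations with
  5,000 burn-in and thinning 5; the cross-validation helpers default to
  shorter chains, which is a documented trade of Monte-Carlo error for
  runtime at desk scale.

For linear kernels the marker-effect (ridge) and kernel (GBLUP/RKHS)
formulations are the same Gaussian model; the suite verifies the identity
$\hat u = W(W'W + \lambda I)^{-1}W'(y - X\hat\beta)$ with
$\lambda = \sigma_\varepsilon^2 c/\sigma_u^2$ to 1e−8, and checks the
Gibbs posterior means against REML BLUPs within Monte-Carlo error. The
latter comparison is only meaningful when $K$ has real structure: with
near-identity kinship the likelihood identifies only
$\sigma_u^2 + \sigma_\varepsilon^2$, and REML and a posterior mean split
the ridge differently.

The three environment models (`fitEnvironmentModel()`) are: **SE**, one
environment at a time; **AE**, environments stacked with per-environment
intercepts and one shared genetic kernel; **GXE**, the AE design plus one
block kernel per environment, so the marker effect decomposes into a
constant part and environment-specific deviations with variances
$\sigma_{u0}^2, \sigma_{u1}^2, \sigma_{u2}^2, \ldots$. This kernel
formulation is algebraically identical to the stacked marker-effect
formulation and avoids sampling in marker dimension. For full-data
variance decomposition the responses are standardized to mean 0, sd 1 per
environment (the per-environment reading of "scaled to standard normal",
consistent with per-environment intercepts); cross-validation predicts on
the original scale — Pearson correlation is scale-invariant, so the two
conventions do not interact.

A caution from the synthetic experiments: the three-way
$\sigma_{u0}^2/\sigma_{u1}^2/\sigma_{u2}^2$ split is identified only
through the cross-environment covariance, and at a few hundred lines a
single realization carries 15–20% sampling error in that split (an
independent dense REML optimizer shows the same deviations as the
sampler). Recovery claims in the tests therefore average over replicate
trait draws.

## Cross-validation

`runCvSingle()` runs repeated k-fold CV (default 100 × 5-fold) on BLUEs.
The relationship matrix is built once from **all** lines — genotypes are
known for everyone; only phenotypes are masked — and per repeat the pooled
out-of-fold predictions are correlated with the observed values once
(pooling stabilizes $r$ relative to per-fold correlation; a per-fold
aggregation would be a straightforward variant). One master seed derives
per-repeat (and per-draw) seeds through a fixed counter scheme
(`deriveSeed()`), so results are bit-reproducible and any single repeat
can be re-run in isolation.

`chooseNFixedSnps()` walks down the GWAS ranking, comparing the PA vector
with the top-n SNPs fixed against top-(n−1) by a two-tailed Welch t-test
at α = 0.05 over repeats that share fold partitions (pairing; the
equal-variance form is a free choice since variance equality is untestable
here, and Welch is the safer default). n* is the largest n with every step
up to n significant. Two structural caveats, both verified empirically:
because the candidate SNPs are ranked on the full data, the procedure has
selection leakage — on a pure-noise trait, GWAS-ranked SNPs fitted as
fixed effects can *genuinely* raise cross-validated PA — and because all
repeats share one dataset, the t-test's repeats are not independent
replicates of anything beyond the fold partition. The tests therefore
check the null behaviour with an a-priori candidate list and as a
selection *rate* across independent null datasets.

`runCvMulti()` implements CV1 (fold lines masked in every environment —
"untested lines") and CV2 (line-by-environment cells masked, every masked
line keeping its record in the other environment — "sparse testing").
CV2's masked environment alternates deterministically within each fold
and the starting environment rotates across folds, so masked-cell counts
are balanced. Families are restricted to those phenotyped in all selected
environments. PA is computed per validation environment over that
environment's masked cells, pooled within a repeat. `masPredictCv()` is
the marker-assisted-selection baseline: plain OLS on the selected SNPs in
the training folds.

## Numerical choices and degenerate inputs

* REML profile optimization is on $\log\delta \in [-12, 12]$ with
  `optimize()` at tolerance 1e−9; an exact fit (zero residual) is guarded
  by flooring the profiled RSS.
* Kernel eigenvalues below 1e−8 of the maximum are truncated; kernels
  must be PSD to that tolerance or are rejected.
* Variance components are kept nonnegative by construction (REML ratio
  parameterization; inverse-χ² draws); lme4 handles its own boundaries.
* A constant response yields zero variance components and an explicit
  error from the heritability formula (0/0).
* Monomorphic markers contribute nothing to $K$; an all-monomorphic set
  is rejected with an explicit message (zero denominator).
* Ties in the GWAS ranking break deterministically by (chromosome,
  position); divergent Gibbs chains (non-finite or exploding variances)
  abort with the iteration number.

## Problem sizes used in the tests

The packaged checks run at desk scale, chosen once as the smallest sizes
at which each property is statistically clean: pedigree checks at the
study's 481 plants (and 10,000 plants for the goodness-of-fit property);
oracle equivalences at 50–150 lines; architecture recovery at 200–300
lines with 400–1,000 markers; ordering patterns (fixed-QTL benefit over
100 trait replicates, GXE vs AE, CV2 vs CV1) at 120–150 lines with
reduced chain lengths. Full-fidelity settings (20,000/5,000 chains,
100 repeats) remain the package defaults.

## Known limitations

Single trait; pairs (or more) of environments but no factor-analytic
structure across many environments; no dominance/epistasis; no spatial
modelling; the Gibbs sampler's priors are weakly informative rather than
flat, so very small datasets show visible shrinkage; and the paper-data
reproduction path requires the user to supply the study's supplementary
files, which are not redistributed with the package.
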