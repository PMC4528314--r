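---
title: "Genomic prediction across purebred and crossbred pig populations: models and design"
author: "crossblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction across purebred and crossbred pig populations: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossblup)
```

## The problem

Pig breeding selects purebred (PB) nucleus animals, but the commercial
product is a crossbred (CB): typically an F1 sow from two maternal lines.
Whether genomic selection on purebred data improves crossbred performance
depends on two things this package quantifies: the accuracy of genomic
breeding values across training/validation designs (within one line,
pooling lines, across lines, and purebreds predicting crossbreds), and the
genetic correlation `r_g` between the purebred and crossbred expression of
the trait. When `r_g` is well below 1 (in sow reproduction traits it can
be anywhere from ~0.3 to ~0.9), purebred data carry limited information
about crossbred merit, and purebred-to-crossbred prediction accuracy
collapses toward zero as `r_g` does.

`crossblup` implements the full analysis pipeline as reusable components:

* **Deregression** of estimated breeding values (EBVs) into pseudo-records
  (DEBVs) with heterogeneous residual weights.
* **Relationship matrices**: the pedigree numerator matrix **A** (tabular
  method, compiled kernel) and genomic matrices **G**, including an
  across-population construction centered with line-specific allele
  frequencies.
* **Mixed-model machinery**: Henderson's equations for GBLUP/PED-BLUP with
  weighted residuals, univariate REML for variance components, and
  bivariate REML for the PB/CB genetic correlation.
* **A scenario engine** running replicated training/validation designs and
  reporting accuracy and dispersion bias.
* **A synthetic-population generator** producing two drifted purebred
  lines plus an F1 cross with a recent pedigree, so the entire pipeline is
  testable without proprietary data.

## Models

### GBLUP / PED-BLUP

The prediction model is the animal model

y = X b + Z g + e,   g ~ N(0, K σ²ₐ),   e ~ N(0, D σ²ₑ),

where `y` holds the DEBVs of the training animals, `b` is an intercept
plus a fixed line effect whenever training spans more than one line,
`K` is **G** (GBLUP) or **A** (PED-BLUP) over training *and* validation
animals, and `D = diag(1/w_i)` carries the deregression weights.
Validation animals simply carry no record; their genomic estimated
breeding values (GEBVs) flow through the relationships. `solveBlup()`
solves the mixed-model equations by dense factorization — problem sizes in
this setting (hundreds to a few thousand animals) never justify sparse
machinery — and returns prediction-error variances from the inverse
coefficient matrix. Before inversion, `K` receives an eigenvalue floor
(`eps = 1e-6 * mean(diag)`, applied only when the smallest eigenvalue is
below `1e-8`, and recorded in the fit): genomic matrices from finite SNP
panels are routinely singular.

### Relationship matrices

`buildG()` is the centered cross-product `G = ZZ' / (2 Σ p q)` with
`Z = M − 2p`. With observed allele frequencies each column of `Z` sums to
zero, so `G` has zero row sums and is invariant to flipping any SNP's
allele coding — both are tested identities. `buildGAcross()` centers each
animal's row with its **own line's** frequencies; the default
`blockwise` scaling divides the (line j, line k) block by
`sqrt(d_j d_k)` with `d_l = 2 Σ p_l q_l`, which preserves each line's own
VanRaden block exactly — the property that makes within- and
across-population runs comparable. A pooled single denominator is
available for sensitivity analysis; the choice is recorded in the object.
For small F1 groups (< 30 animals) the F1 centering frequencies fall back
to the mean of the parental lines.

### Deregression

EBVs are shrunken and contain the parent average (PA), so validating
predictions against EBVs would reward the wrong things. `deregress()`
implements the two-effect decomposition: for each animal, with
`λ = (1 − h²)/h²`, the information contents of PA and of the animal's own
contribution are solved from the pair (EBV, reliability) so that pushing
the solved pseudo-record back through the two-effect mixed-model equations
reproduces both exactly — `deregressRoundTrip()` performs that inversion
and the test suite holds it to 1e-8 over a thousand random records. The
DEBV is the own-information pseudo-record; its reliability becomes
`zzI/(zzI + λ)`, and the residual weight is

w = (1 − h²) / ((c + (1 − r²)/r²) h²),

with `c` the fraction of genetic variance not captured by markers
(default 0; weights are capped at the value implied by r² = 0.99).
Animals lacking recorded parents fall back to the simple `EBV/r²` form,
and the count is reported. In multi-population runs the fixed line effect
removed by the evaluation is added back onto the DEBVs
(`addBackLineEffect()`), and the prediction model then re-fits a line
effect — this keeps between-line means in the data so that SNPs with
diverged frequencies can explain them.

### REML

`remlUnivariate()` estimates `(σ²ₐ, σ²ₑ)` after rotating the
weight-standardized system into the eigenbasis of `K`, which makes every
iteration O(n). Two modes: pure EM (each step provably does not decrease
the restricted likelihood — a tested invariant) and the default EM warm-up
followed by average-information (AI) updates with step-halving back to EM.
Convergence is declared at a relative parameter change below `1e-8` or a
log-likelihood change below `1e-10`; non-convergence within `maxIter`
(default 500) returns the last iterate flagged.

`remlBivariate()` treats PB and CB performance as two traits with genetic
covariance `G0 ⊗ A`. Because no animal expresses both traits, the residual
covariance is structurally inestimable and fixed at zero. The maximizer is
AI-REML on the variance representation (one Cholesky + inverse of the
n×n phenotypic covariance per iteration) with an EM fallback for the
variance parameters; if an update pushes `|g12|` past
`0.999·sqrt(g11·g22)` the covariance is bent back to that bound and the
fit is flagged. The analytic score was cross-checked against a numeric
gradient of an independently coded restricted likelihood. `r_g` and its
delta-method standard error come from the AI matrix at the optimum.

### Accuracy and bias

Accuracy is the Pearson correlation between predictions and validation
DEBVs; replicates with zero-variance predictions are reported as
*undefined* (distinct from zero) and excluded, with a count. Dispersion
bias is an OLS slope; because the field uses both regression directions,
`biasSlope()` computes the regression of DEBV on GEBV by default
(`slope`) and the reverse (`slopeRev`), and scenario outputs carry both —
the package never silently picks one.

## The scenario suite

`scenarioSuiteSpecs()` materializes 17 designs in four groups for a
two-line + F1 data set: within-population (3), multi-population (4),
across-population (4), and purebred-to-crossbred (6). Replicated designs
(20 replicates by default) hold out a random validation set (default 50
animals) per replicate; single-replicate designs train on everything and
validate on the entire other population. Equalized designs draw the same
number of animals per training line; that number defaults to one third of
the smaller purebred line, and "reduced" single-line designs use twice
it, so a two-line equalized training and a reduced single-line training
have equal total size. Variance components are re-estimated by REML on
each training set by default (`varComponents = "fixed"` reproduces the
estimate-once shortcut). PED-BLUP is skipped, with the reason recorded,
whenever a training line is unrelated to the validation line in the
pedigree — the pedigree then contains no channel for information to flow,
and the corresponding mixed model is degenerate.

Replicate seeds are derived deterministically from the scenario seed, so
two models evaluated on the same scenario see identical training and
validation draws (paired comparisons), and the whole pipeline is
byte-reproducible from a single master seed.

## The synthetic population

`simulatePopulation()` generates, in order:

1. **Founder panel**: SNP minor-allele frequencies uniform on
   `founderMafRange` (default 0.05–0.5), genotypes in Hardy–Weinberg
   proportions.
2. **Line divergence**: each line's frequencies drift through
   `driftGenerations` rounds of binomial resampling of `2·Ne` gametes
   (defaults 30 and 100, giving realized Fst ≈ 0.14; 21 generations give
   Fst ≈ 0.1). Realized Fst is reported against the Wright expectation
   `1 − (1 − 1/(2Ne))^t`.
3. **Recent pedigree**: `pedGenerations` generations per line with about
   one sire per eight matings (half-sib families, as in a nucleus herd);
   the last generation is genotyped. The F1's purebred parents sit
   `gapGenerations` behind the genotyped generation, reflecting that
   genotyped crossbreds are generally not offspring of the genotyped
   nucleus animals.
4. **Trait architecture**: `nQtl` of the SNPs are causal; each carries a
   pair of effects (purebred-, crossbred-expressed) from a bivariate
   normal with correlation `rhoPbCb`. TBVs are rescaled so the mean
   within-line additive variance equals `h²` on a unit phenotypic
   variance; line means are added as configured. Purebred animals express
   the PB trait, F1 animals the CB trait.
5. **Records and pseudo-EBVs**: every non-founder gets 2–6 own (parity)
   records (`parityRange`), entering a pedigree-BLUP evaluation as
   weighted record means with a fixed line effect. EBVs are the resulting
   BLUPs; per-animal reliability is `1 − PEV/(σ²ₐ A_ii)`. Multi-parity
   records matter: they make each EBV own-information dominated, which is
   what the deregression theory assumes and what commercial sow data look
   like (mean reliabilities around 0.4–0.8). With single records,
   evaluation errors are so strongly pedigree-correlated that
   pedigree-based prediction appears to beat marker-based prediction on
   deregressed responses — an artifact of the pseudo-data, not a property
   of the estimators.
6. **Missingness**: genotype calls are masked at `missingRate` (default
   1%) to exercise QC and imputation.

Identical spec + seed gives bit-identical output; the generator's RNG is
isolated from the caller's.

### What the generator does *not* emulate

SNPs assort independently: there is no linkage map, so no LD between
markers and QTL beyond the markers *being* the QTL, and no LD-phase
differences between populations. This is deliberate — the estimators under
test never use map positions — but it means across-population prediction
degrades here only through allele-frequency divergence and drift of QTL
variance, not through the LD-phase breakdown that dominates in real data.
Simulated across-population accuracies are therefore *much higher* than
real ones; only orderings (within > across, and purebred-to-crossbred
accuracy tracking `r_g`) are meaningful, and only those are asserted.
Selection during drift, genotyping error, dominance, and multi-trait
evaluations are likewise out of scope; the additive two-context model is
exactly the model the estimators assume.

## Quality control

`snpFilters()` applies, on the input statistics (hence idempotently):
call rate < 0.95, minor-allele frequency < 0.01, Hardy–Weinberg
goodness-of-fit χ² > 600 (1-df statistic over the three genotype classes,
pooled across lines — the extreme threshold makes Wahlund inflation from
pooling immaterial), and a chromosome exclusion list (X, Y, unmapped).
`individualFilter()` then removes animals with a missing fraction
strictly above 0.05. Remaining gaps are imputed single-site: mean mode
fills `2p` (real-valued), draw mode samples from Hardy–Weinberg at `p`,
with `p` estimated within line by default. Haplotype-based imputation is
intentionally not reimplemented: at ~1% missingness downstream G
construction only needs approximately unbiased dosages.

## Numerical choices

* Mixed-model equations and REML use dense LAPACK factorizations;
  the largest matrices (≈ 5,000²) fit comfortably in memory.
* The eigenvalue floor on `K` is applied once per solve and recorded.
* Reference-level coding for line effects (first line absorbed into the
  intercept); accuracies and slopes are invariant to that choice.
* Ties in `meanRelatednessSplit()` break by the supplied id order, making
  the most/least-related split deterministic.
* All derived seeds are kept below 2³¹.

## Problem sizes used in the shipped checks

The package validates itself at desk scale, chosen so the whole suite runs
in minutes while keeping every estimator in its asymptotic comfort zone:
heritability recovery at n = 500 with 2,000 SNPs; genetic-correlation
recovery on populations of 1,000 per line plus 1,000 F1 (every F1 with
both parents phenotyped, h² = 0.5 — the high-information reproduction
trait, where `r_g` ≈ 0.9 and genomic h² estimates reach ~0.6, is the
natural template for a correlation-recovery check); ordering checks on
two lines of 700 at Fst ≈ 0.1; and an end-to-end suite run on 300 per
line + 150 F1. The default `populationSpec()` mirrors the motivating
data more closely (two lines of 1,200 sows, 290 F1, 5,000 SNPs, 500 QTL)
and is used by the acceptance script's pipeline run in reduced form.

## Known limitations

* `r_g` estimates from a single simulated population carry a standard
  error of ~0.1 even under the favorable design above; single-seed values
  near the parameter-space boundary (|r_g| → 1) are bent and flagged.
* The pseudo-EBV evaluation treats PB and CB phenotypes as one trait
  (as the motivating evaluations do); when `rhoPbCb` is far below 1 this
  slightly misstates F1 reliabilities.
* Across-population magnitudes are optimistic (see above); the package
  makes no claim to reproduce real-data accuracy levels, only the
  estimators and their orderings.
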