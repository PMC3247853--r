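---
title: "Decomposing antibody-array variance in a longitudinal twin design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing antibody-array variance in a longitudinal twin design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinvar)
```

## The question and the design

Antibody suspension bead arrays measure dozens of serum proteins at once,
but a measured fluorescence intensity mixes biology with technical noise.
Before such profiles can be candidate biomarkers one needs to know *how
much* of their variation is stable biology. A twin design with repeated
visits and duplicate aliquots identifies exactly that split: monozygotic
(MZ) co-twins share all familial variance, dizygotic (DZ) co-twins share
part of it, two visits separate stable from short-term biology, and two
aliquots of the same serum sample differ only by experimental error.

`twinvar` implements the full analysis chain for such a study: a synthetic
cohort generator mirroring the sampling design, probabilistic quotient
normalization (PQN), replicate-concordance QC, multivariate outlier
screening, per-antibody Box-Cox transformation, and constrained maximum
likelihood for the twin mixed-effects model, with AIC choosing between two
fixed-effect forms.

The default cohort is the design the methods were built around: 56 MZ and
21 DZ pairs (154 women), all sampled at visit 1; 34 MZ pairs re-attending
(222 samples); the visit-1 samples of 24 MZ pairs split into duplicate
aliquots (270 aliquots); everything randomised onto three 96-well plates
carrying 6 reference wells each (288 occupied wells).

## The model

For one antibody, the transformed intensity of aliquot $l$ of twin $j$ in
pair $i$ at visit $k$ is modelled as

$$Y_{ijkl} = \mu_{p(i,j,k,l)} + H_{i} + M_{ij}^{*} + E_{ij} + W_{ik} +
V_{ijk} + \varepsilon_{ijkl},$$

with independent Gaussian random effects and a fixed mean per plate $p$.
The classical decomposition into additive genetic (A), dominance (D) and
common-environment (C) variance is not identifiable from MZ/DZ covariances
alone, so the familial part is re-parameterised into two identifiable
effects: $H$ grouped by pair, and $M^{*}$ grouped by pair for MZ twins but
by individual for DZ twins, with
$\mathrm{Var}(H) = \tfrac12 \mathrm{Var}(A) + \tfrac14 \mathrm{Var}(D) +
\mathrm{Var}(C)$ and
$\mathrm{Var}(M) = \tfrac12 \mathrm{Var}(A) + \tfrac34 \mathrm{Var}(D)$.
This is the unique additive grouping that reproduces both co-twin
covariances: $\mathrm{Var}(H)+\mathrm{Var}(M)+\mathrm{Var}(W)$ within MZ
pairs and $\mathrm{Var}(H)+\mathrm{Var}(W)$ within DZ pairs
(`marginal_covariance()` writes these blocks down; the simulator and the
test suite verify them by Monte Carlo). The remaining effects are E
(individual environment, stable), W (common visit: co-twins are sampled the
same day), V (individual visit, short-term biology) and $\varepsilon$
(experimental error, identified by the duplicate aliquots).

Reported quantities are percentages of total variance:
familiality $= 100\,(\mathrm{Var}(H)+\mathrm{Var}(M))/\mathrm{Var}(Y)$,
and likewise env, cv, iv, exp; a second breakdown divides by the
non-experimental variance only. A, C and D are never estimated separately.

Model form 1 fits one mean per plate. Form 2 adds a plate-specific linear
term in the well index (1–96, centered within plate) to absorb instrument
drift across a plate; the centering only re-parameterises the plate mean.
`select_model()` fits both and keeps the form with the smaller
$\mathrm{AIC} = 2k - 2\ln L$, where $k$ counts all fixed effects plus the
six variance parameters (plates + 6, or 2·plates + 6); ties go to form 1.

## Estimation choices

The likelihood is the full ML criterion, not REML, maximised over the six
variance components with the fixed effects profiled out by generalized
least squares at every iterate. Because no random effect spans twin pairs
the covariance is block-diagonal; blocks with the same sharing pattern are
factorised once per evaluation, which makes cohorts of thousands of pairs
cheap. Numerical details:

* parameterisation on the standard-deviation scale with lower bound 0, so
  boundary estimates (exactly zero variances, common in practice) are
  reachable;
* `L-BFGS-B`, convergence tolerance `factr = 1e3`, numerical gradients;
* five deterministic multistarts from dispersed splits (equal shares,
  residual-dominant, familial-dominant, environment-dominant, mixed) of
  the OLS residual variance, keeping the best converged solution;
* the response is centered and scaled internally and estimates mapped
  back, making the fit exactly equivariant under $y \mapsto a y + b$;
* unbalanced data (a missing visit, dropped outliers) enter through the
  observed-likelihood blocks only — no imputation;
* `var_eps` estimated at zero while duplicates exist is reported via a
  `boundary_eps` flag rather than an error.

The blockwise log-likelihood is tested against an independently coded
dense multivariate-Gaussian likelihood (tolerance 1e-8) and the whole
fitter against `lme4::lmer(..., REML = FALSE)` on a simulated cohort.
With MZ pairs only the likelihood is exactly flat along
$\mathrm{Var}(H)+\mathrm{Var}(M) = \text{const}$ — the package therefore
refuses single-zygosity designs rather than returning an arbitrary split.

## Pre-processing

**PQN** (`pqn_normalize()`): the reference spectrum is the antibody-wise
median over study aliquots (reference wells excluded); each aliquot is
divided by the median of its per-antibody quotients. Normalization is
applied to the whole matrix at once, not per plate — additive plate
effects belong to the model's plate means. PQN removes a *common*
multiplicative factor per aliquot; its quotient-median is only as stable
as the panel is wide. On narrow panels (a handful of antibodies) the
estimated factor is noisy enough to *hurt* replicate concordance; at the
study's 69-antibody width it reliably helps, which is what the acceptance
checks measure.

**Replicate concordance** (`replicate_concordance()`): per antibody, the
Spearman correlation (average ranks on ties) between first and second
aliquots across duplicated samples; constant vectors give `NA` and are
excluded from the cohort median. At least 3 complete pairs are required.

**Outliers** (`detect_outliers()`): columns standardized to mean 0, SD 1;
SVD; squared Mahalanobis distance of each aliquot's first two
principal-component scores from the origin, using the empirical diagonal
covariance of the scores (distinct singular directions are exactly
orthogonal). The squared distance is referred to $\chi^2_2$; the default
tail $\alpha = 10^{-4}$ gives the threshold 18.42. Removal is single-pass
— the screen is not iterated.

**Box-Cox** (`boxcox_fit_transform()`): $t(y;\lambda) = (y^\lambda -
1)/\lambda$, $\ln y$ at $\lambda = 0$; $\lambda$ maximises the profile
log-likelihood over $[-2, 2]$ by golden-section search (tolerance 1e-6).
The fixed pipeline order is normalize → drop reference wells and outliers
→ transform.

IQRs everywhere use linear interpolation between order statistics (R's
default quantile type); comparisons against published integer medians use
round-half-away-from-zero.

## What the generator emulates — and what it does not

`simulate_intensities()` draws the latent values exactly from the model
above, then distorts them onto a raw scale: inverse Box-Cox at a chosen
$\lambda$ (default 0, i.e. log-normal raw intensities, typical of
fluorescence readouts around plate means of ~7 on the log scale), a
per-aliquot log-normal dilution factor (SD 0.15 by default — one
standard-normal draw per aliquot scaled by each antibody's `dilution_sd`,
so equal SDs give the aliquot-wide factor PQN assumes), optional
plate-specific linear well drift, and fixed noise-free reference-well
profiles. `default_antibody_specs()` draws each antibody's variance shares
from the bundled 66-row published reference decomposition, so simulated
cohorts reproduce the observed spread of familial and experimental
variance.

The generator deliberately omits bead-count noise and median-fluorescence
aggregation (simulation starts at per-aliquot intensity), assortative
mating, gene–environment interaction, age and batch covariates beyond
plate, and non-monotone raw-scale distortions. Passing tests on simulated
data therefore certify the *estimator* under the model's assumptions, not
the assay itself: real data can violate additivity, Gaussianity after
Box-Cox, or the shared-dilution structure in ways the generator cannot
produce.

Duplicate aliquots are generated from the visit-1 samples of the
designated MZ pairs (the published design's "48 samples from 24 MZ pairs";
the visit is our choice since visit 1 always exists), and visit-2
attendance is pair-complete, as twins attend in pairs. Reference wells
occupy the last six well positions of each plate; study aliquots fill the
rest under a single seeded permutation.

## Problem sizes used in the checks

The test suite and the acceptance script choose sizes that keep every
Monte Carlo answer statistically meaningful: co-twin covariance identities
at 4000–5000 pairs (errors bounded by 3 Monte Carlo standard errors);
parameter recovery at 500 MZ + 500 DZ pairs with revisits and duplicates,
10 replicates, comparing the mean estimated proportions to the truth
within ±3 points (single-replicate proportions scatter with SE ≈ 3 at
this size — the replicates are what turn the check into a bias test); AIC
operating characteristics at the study's own 270-aliquot design, 100
replicates per arm, with "strong drift" defined as slope × well range ≈ 2
total SD; PQN concordance on a 69-antibody panel, 20 replicates. The
acceptance script re-runs the whole pipeline at the study scale — 270
aliquots × 69 antibodies, AIC selection per antibody — and summarises the
resulting breakdowns.

## Known limitations

* No standard errors or confidence intervals for variance components are
  produced.
* A, C and D are reported only through their identifiable combination
  (familiality); narrow-sense heritability is out of reach by design.
* AIC with boundary variance estimates uses the nominal parameter count;
  no boundary correction is applied.
* Published per-antibody fits used a general mixed-model tool whose
  default criterion differs from plain ML; small AIC discrepancies against
  published tables can trace to that difference.
* The pipeline treats the outlier screen as one pass; iterating it would
  change thresholds and is intentionally not done.
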