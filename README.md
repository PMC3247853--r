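# twinvar

Variance decomposition of antibody-array protein profiles in a
longitudinal twin design.

Serum protein profiles measured by antibody suspension bead arrays vary
between people, within a person over time, and between repeated
measurements of the same sample. `twinvar` is for biostatisticians and
proteomics groups who need to know how much of each source is present
before trusting a profile as a biomarker. It partitions the phenotypic
variance of every antibody into five components:

| component | symbol | shared by | meaning |
|---|---|---|---|
| familiality | H + M | co-twins (fully MZ, partly DZ) | genetics + common environment |
| individual environment | E | repeat visits of one person | stable, person-specific |
| common visit | W | co-twins at one visit | same-day shared variation |
| individual visit | V | aliquots of one sample | short-term biology |
| experimental | ε | nothing | duplicate-aliquot disagreement |

The model for a transformed intensity is the linear mixed-effects model

    Y_ijkl = mu_p(i,j,k,l) + H_i + M*_ij + E_ij + W_ik + V_ijk + eps_ijkl

with a fixed mean per assay plate `p` and independent Gaussian random
effects. Additive-genetic, dominance and common-environment variances are
not separately identifiable from MZ/DZ covariances, so the familial part
uses the identifiable re-parameterisation Var(H) = ½Var(A) + ¼Var(D) +
Var(C), Var(M) = ½Var(A) + ¾Var(D); reported familiality is
Var(H) + Var(M). Estimation is constrained maximum likelihood with the
plate effects profiled out by GLS, evaluated blockwise per twin pair; a
second model form adds a plate-specific linear well-position drift term,
and `AIC = 2k − 2 ln L` selects between the forms.

Around the model sits the pre-processing used for such arrays:
probabilistic quotient normalization, Spearman replicate concordance,
outlier screening by the squared Mahalanobis distance of the first two
principal-component scores against a χ²(2) cutoff (18.42 at α = 10⁻⁴),
and per-antibody Box-Cox transformation chosen by profile likelihood. A
synthetic cohort generator reproduces the study design the methods come
from — 56 MZ + 21 DZ pairs, 34 MZ pairs revisiting, duplicate aliquots
from 24 MZ pairs, three 96-well plates with 6 reference wells each — so
every stage is testable without external data.

## Worked example

```r
library(twinvar)
design <- generate_design(seed = 1)          # the default study design
design
#> Twin cohort design: 56 MZ + 21 DZ pairs; 154 individuals; 222 samples;
#>   270 aliquots on 3 plate(s) ( 18 reference wells)

specs <- default_antibody_specs(6, design$n_plates, seed = 2)
raw   <- simulate_intensities(design, specs, seed = 3)
prep  <- preprocess_pipeline(raw, design)
prep$outliers
#> Outlier screen: 4 of 270 aliquots above squared-distance threshold 18.42
prep$concordance_after
#> Replicate concordance over 48 duplicate pairs: median Spearman r = 0.312 (IQR 0.268-0.453)

y   <- setNames(prep$transformed$values[, "AB001"],
                rownames(prep$transformed$values))
fit <- select_model(y, design)               # AIC picks the model form
fit
#> Twin variance-component fit (model 1 ): n = 266 , lnL = -332.56 , AIC = 683.11
#>   var_H   var_M   var_E   var_W   var_V var_eps
#> 0.00000 0.22613 0.06109 0.09470 0.17025 0.30509
variance_proportions(fit)
#> fam 26.4 | env 7.1 | cv 11.0 | iv 19.9 | exp 35.6 (% of total)
#> fam 41.0 | env 11.1 | cv 17.2 | iv 30.8 (% of non-experimental)
```

Reading the output: 266 of the 270 aliquots survive the outlier screen;
for antibody AB001 about 26% of the variance is familial, 36% is pure
experimental noise (the share that distinguishes duplicate aliquots), and
the drift-free model form 1 fits best. `fit_all_antibodies()` applies this
to every antibody and `cohort_summary()` reports medians and IQRs across
the panel:

```r
res <- fit_all_antibodies(prep$transformed, design)
cohort_summary(res)[1:6, ]
#>  component median    q1    q3 n
#>        fam 16.204 10.15 23.88 6
#>        env  3.563  0.00  8.16 6
#>         cv  0.252  0.00  8.41 6
#>         iv 15.141  5.45 19.83 6
#>        exp 69.634 47.20 70.95 6
#>     stable 22.835 12.27 31.40 6
```

`run_all()` (or the thin CLI wrapper `inst/cli/twinvar.R` with subcommands
`simulate | preprocess | fit | summarize | run-all`) chains the stages and
writes every intermediate CSV plus a run log. `reference_variance_table()`
returns the published 66-antibody decomposition bundled with the package
(medians: familial 12%, experimental 63%).

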