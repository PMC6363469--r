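# limbrsa

Representational similarity analysis (RSA) of sensorimotor digit maps, with a
synthetic-data generator that plants a known representational geometry so the
whole pipeline is testable end to end.

## The problem

Does the cortical hand representation persist after hand loss? The analysis
this package implements addresses that question by comparing the fine-grained
*representational structure* of digit-movement activity patterns in the
primary somatosensory (SI) and motor (M1) hand areas across three groups:
acquired amputees moving their phantom digits, congenital one-handers
attempting movements of a hand they never had, and two-handed controls. It is
written for researchers who want a tested, reusable implementation of this
analysis chain — either on simulated cohorts with known ground truth, or on
their own exported pattern matrices (delimited text plus a JSON sidecar).

## The statistic at the core

Dissimilarity between digit pairs is the cross-validated squared Mahalanobis
("crossnobis") distance. With run-wise pattern differences
δ<sub>r</sub> = b<sub>r</sub>(a) − b<sub>r</sub>(b), noise covariance Σ
estimated from GLM residuals (shrinkage toward the diagonal), and V voxels:

d(a,b) = mean over run pairs m&lt;n of δ<sub>m</sub>ᵀ Σ⁻¹ δ<sub>n</sub> / V

Cross-validation across independent runs makes the estimator unbiased: its
expected value is zero when two patterns do not truly differ (entries may be
negative). From the resulting 5×5 RDM the pipeline computes **mean
dissimilarity** (strength of digit individuation), **typicality** (Spearman
correlation with a canonical hand RDM — how normally organised the
representation is), and **split-half consistency** (odd-run vs even-run RDM
correlation — within-participant reliability). The inferential layer adds
Bonferroni-adjusted group contrasts, a mixed group×region ANOVA, forward
stepwise regression of typicality on phantom-sensation covariates with
bootstrap replicability (inclusion proportion over 1000 resamples), and a
Bayes factor whose one-tailed t prior is calibrated by the
congenital-versus-control difference (BF &lt; 1/3 read as evidence that
amputees' representation is preserved).

See `vignettes/digit-rsa-methods.Rmd` for the full model description.

## Worked example

```r
library(limbrsa)
res <- run_study(study_config(rng_seed = 1), B = 1000)
print(res)
```

```
Simulated study results (seed 1 , config 76b7b2de )

Group means, contralateral SI:
      group mean_dissimilarity typicality splithalf_rho
    amputee               7.41      0.773         0.353
 congenital               1.24      0.352         0.220
    control               8.34      0.780         0.513

Stepwise regression of amputee SI typicality:
Forward stepwise model (n = 18 )
  included: kinaesthesia -> vividness_acute 
  R2 = 0.623, adjusted R2 = 0.573, F = 12.397, p = 0.000664
  kinaesthesia bootstrap inclusion: 74.3% (B = 1000)

BF (amputee vs control typicality): 0.158  [supports the null]
```

Reading the output: amputees' simulated missing-hand representation is about
as typically organised as controls' (0.77 vs 0.78, dissimilarity in arbitrary
units), while the congenital group shows weak, unreliable structure (0.35,
split-half 0.22). The stepwise regression recovers phantom kinaesthesia as
the dominant predictor of typicality, and the calibrated Bayes factor (0.158
< 1/3) supports the null hypothesis of no amputee-control difference, i.e. a
preserved representation. `report(res, "out/")` writes the tidy tables, the
aligned MDS coordinates and a run manifest.

A command-line front end is installed at `inst/exec/limbrsa`
(`simulate` / `analyze` / `report`) for driving the same pipeline from a
shell, including analysis of user-supplied pattern directories.

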