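---
title: "Representational similarity analysis of digit maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representational similarity analysis of digit maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbrsa)
```

# The scientific question and the estimator

Individual finger movements evoke overlapping but distinct activity patterns
in the primary somatosensory (SI) and motor (M1) hand areas. Representational
similarity analysis summarizes this fine-grained organisation by the
*representational dissimilarity matrix* (RDM): for the five digits D1-D5,
the $5 \times 5$ matrix of pairwise dissimilarities between condition-evoked
voxel patterns (ten unique pairs). This package implements that analysis for
groups of acquired amputees, congenital one-handers and two-handed controls,
together with a synthetic-data generator that plants a known representational
geometry so every stage can be validated without access to human data.

## The crossnobis distance

Dissimilarity is the cross-validated squared Mahalanobis ("crossnobis")
distance. Let $b_r(a)$ be the condition-$a$ pattern estimated from run $r$,
$\delta_r = b_r(a) - b_r(b)$, $\Sigma$ the voxel noise covariance and $V$ the
voxel count. For every unordered pair of runs $m \neq n$,

$$ d(a,b) \;=\; \frac{1}{\binom{R}{2}} \sum_{m<n}
   \frac{\delta_m^\top \Sigma^{-1} \delta_n}{V}. $$

Because the two factors come from independent runs, noise terms multiply with
zero expectation: the estimator is *unbiased*, with expected value zero when
two conditions do not truly differ, and individual entries may legitimately
be negative. Division by $V$ makes values comparable across region sizes.
All unordered run pairs are used (not leave-one-run-out folds).

## Multivariate noise normalization

$\Sigma$ is estimated from GLM residuals pooled across runs, as a shrinkage
blend of the sample covariance (normalized by its degrees of freedom) toward
its diagonal, with a Ledoit-Wolf/Schafer-Strimmer intensity estimated
analytically from the residuals. Shrinkage guarantees invertibility even with
more voxels than timepoints; intensity 1 reduces to univariate (per-voxel)
normalization. Zero-variance voxels are floored with a warning. For
noiseless data the appropriate whitening is the identity
(`noise_identity()`), since there is no noise structure to normalize.

## Summary measures

* **Mean dissimilarity** — the arithmetic mean of the ten unique pairs:
  overall strength of digit individuation.
* **Typicality** — Spearman's rho (midranks) between the measured pair
  vector and a canonical reference RDM: how *normally organised* the
  representation is, independent of overall scale. It is invariant under any
  strictly increasing transform of either RDM. Values equal to 10
  significant digits are treated as tied, because rank statistics are
  unstable to floating-point jitter when the reference contains exactly tied
  dissimilarities.
* **Split-half consistency** — crossnobis RDMs computed within odd runs
  (1, 3, ...) and within even runs (2, 4, ...), Spearman-correlated:
  within-participant reliability even when the structure is atypical.

The canonical reference shipped here is parametric
(`canonical_rdm(a, b, c_thumb)`): baseline distance `a`, neighbourhood
gradient `b` per digit separation, thumb-distinctiveness boost `c_thumb`.
The defaults (1, 0.5, 0.5) produce a matrix that is Euclidean-embeddable
under the squared-distance reading (required by the generator, below) and
whose two-dimensional projection orders the digits D1-D5 along the first
dimension. Users analysing real exported data should supply the group-mean
RDM of an independent two-handed cohort instead; the parametric fixture
stands in for such a reference and is synthetic.

## Visualization

Classical MDS (`stats::cmdscale` on the RDM entries, the field's convention
for crossnobis RDMs) projects each participant's RDM to two dimensions;
negative-eigenvalue dimensions are dropped and an all-zero RDM maps to the
origin. Configurations are aligned by orthogonal Procrustes — rotation and
reflection, no scaling, so within-participant distances are untouched —
to the first participant and then refined once against the running mean
(order-stable and cheap). Per-digit between-subject standard errors of the
aligned coordinates give the dispersion ellipses. Projections are for
visualization only; no statistics are computed from them.

# The synthetic-data generator

`simulate_participant()` emulates a block-design digit-mapping session:
4 runs, 10 digit conditions (both hands) plus rest, 12 s blocks, 3 repeats
per condition per run, TR 1.5 s, i.e. 264 volumes per run. Four abstract
regions are simulated: contralateral SI and M1 (missing-hand digits),
ipsilateral SI (intact-hand digits), and a V5-like visual control region
that never carries digit signal for any group.

**Geometry injection.** Condition-mean patterns are built by
Cholesky/eigen-embedding the double-centred target second-moment matrix so
that the *realized* pairwise squared pattern distances (per voxel) equal
`signal_scale` times the canonical RDM exactly — the ground truth carries no
sampling variability. A per-participant log-normal multiplier
(`subject_sigma`, default 0.55) creates between-subject spread in effective
signal, the source of the typicality distribution across amputees.

**Noise.** Run-wise patterns add Gaussian noise with an exponential-decay
spatial correlation over a 1-D voxel index (length `noise_spatial_corr`,
default 5 voxels) and per-voxel variances drawn in [0.8, 1.2] — the simplest
structure that makes pre-whitening non-trivial. The emitted residual matrix
pools `n_runs` runs of direct draws from the same covariance, with
`dof = rows - 1` (they are draws, not design-projected residuals). With
`noise_sd = 0` the betas equal the true means exactly and unit-variance
white residuals are emitted, so the estimated whitening is approximately the
identity.

**Default signal scales are calibration constants, not validation.** The
per-group, per-region `signal_scale` defaults were tuned once, by Monte
Carlo at the default noise level, so that the default pipeline lands near
the group statistics the generator is meant to emulate: amputee SI
typicality ~0.75 and split-half rho ~0.41, control split-half ~0.52,
congenital typicality ~0.3, amputee M1 typicality ~0.44. Matching these
numbers shows only that the calibration worked, not that the pipeline would
reproduce them from real scans.

**Covariates.** `simulate_covariates()` generates the amputee table:
kinaesthesia (0-5, the number of phantom digits with volitional movement
sensation), chronic/acute nonpainful vividness (0-100), chronic/acute pain
(0-100), years since and age at amputation, intact-hand typicality.
Kinaesthesia is coupled to *realized* typicality through a Gaussian copula.
Two deliberate choices: (i) the latent correlation is inflated by the
6-level binning attenuation factor 0.978 (measured by simulation) so the
rank correlation after integer binning equals the requested coupling; and
(ii) the latent noise is orthogonalized within the sample, pinning the
realized latent correlation to its target (the `MASS::mvrnorm(empirical =
TRUE)` idiom). The coupling is thus a *condition* of the simulated study
rather than a random draw — without this, the sample Spearman at n = 18 has
a standard deviation of ~0.14 and "the cohort's coupling" would mostly be a
draw from a wide distribution.

**What the generator does not emulate:** hemodynamic nonlinearity, motion
and physiological artefacts, temporal autocorrelation of noise, cortical
surface geometry, or realistic covariate joint distributions (covariates
other than kinaesthesia are independent of typicality by construction).
Passing tests therefore validate the estimators and inference machinery
under a known, well-behaved generative model — not robustness to real fMRI
artefacts.

**Timeseries mode.** `simulate_timeseries()` emits
`design x betas + drift + noise` so the GLM module can be tested end to end;
beta mode (direct pattern emission) is the default for speed.

# The GLM module

Design matrices convolve condition boxcars with a double-gamma HRF
(response peak 6 s, undershoot 16 s, ratio 6 — the community-standard
parameterization; the convolution uses a 0.1 s internal grid). High-pass
filtering projects out a discrete-cosine basis with a 100 s cutoff plus an
explicit linear-trend column, so constant and linear drift are removed
exactly; the filter is linear, hence filtering data and design is equivalent
to adding the basis as confounds. Estimation is ordinary least squares per
run (matching the run-wise cross-validation downstream); an optional
per-timepoint weight vector is applied as diagonal weighting to down-weight
noisy volumes — full volume-wise variance estimation is out of scope.
A sustained 12 s block peaks roughly 12 s after block onset (just after the
block ends), unlike a brief event which peaks at 5-6 s.

# The inferential layer

* **Group contrasts** — classical pooled-variance two-tailed t tests
  (paired or independent), with the Bonferroni-adjusted alpha (0.05/3 for
  the three inter-group comparisons) recorded in every result; one-sample t
  tests compare group means to zero (meaningful because crossnobis is
  unbiased around zero under the null).
* **Correlations** — Spearman's rho with the t-approximation p value on
  n - 2 degrees of freedom; partial correlation by multiple regression
  (`y ~ x + covariate`, coefficient t test).
* **Mixed ANOVA** — `aov(value ~ group * area + Error(subject))` for the
  group-by-region interaction in the ipsilateral/V5 control analysis.
* **Mann-Whitney U** — exact p when the combined n is at most 20 and there
  are no ties, normal approximation with continuity correction otherwise.
* **ICC** — two-way mixed, consistency, single-measure ICC(3,1) from the
  ANOVA mean squares with an F-based confidence interval.
* **Trial classification** — each force-task trial is assigned to the digit
  whose force channel correlates most strongly with the instructed time
  course; ties break to the lowest digit with a warning.

## Forward stepwise regression with bootstrap replicability

Greedy forward selection adds, at each step, the predictor with the largest
raw-R² gain if the gain exceeds 0.1 (raw R² for the criterion, adjusted R²
reported for the final model — the conventional pairing); ties break by
column order; selection stops with a warning when another step would leave
fewer than one residual degree of freedom. Predictors enter in raw units so
coefficients stay interpretable (standardization available by flag).
Because stepwise selection is exploratory, `bootstrap_stepwise()` resamples
rows with replacement (response jointly with its predictor row), reruns the
selection B = 1000 times, and reports per-predictor inclusion proportions —
above 0.75 is read as internal replicability — plus a percentile interval
on the final adjusted R². Resampled predictors with zero variance are
skipped for that iteration.

## The calibrated Bayes factor

To ask whether amputees' representation is *preserved* (support for a null
difference versus controls), the alternative hypothesis is calibrated by an
independent group difference: the prior on the effect is a t distribution
centred at zero, truncated to one tail (the side of the
congenital-versus-control difference), with scale equal to that difference;
the likelihood of the observed amputee-versus-control difference is a
shifted, scaled t with the observed comparison's degrees of freedom (not a
normal):

$$ \mathrm{BF} = \frac{\int L(\hat d \mid \delta)\,\pi(\delta)\,d\delta}
                      {L(\hat d \mid 0)}. $$

BF < 1/3 is flagged as positive evidence for the null (preserved
representation). Integration is adaptive quadrature over twelve prior widths
with absolute tolerance 1e-8; t tails make the truncation error negligible
at realistic effect sizes, and the reported `integration_error` bounds the
quadrature error. The prior's degrees of freedom default to the calibrating
comparison's dof and are configurable, since the exact prior-dof convention
of calculator-style implementations is not standardized. Contracts: BF tends
to 1 as the prior width shrinks to zero (the alternative collapses onto the
null), and BF is monotone in the observed effect along the prior's tail.

# Numerical and design choices, collected

* Shrinkage target: diagonal of the sample covariance; intensity clipped to
  [0, 1]; zero-variance voxels floored at 1e-6 of the largest variance.
* Noise covariance pooled across runs (a per-run `shrinkage` argument and
  run-wise estimation remain available by calling `estimate_noise()` on
  per-run residual blocks).
* Odd/even split keyed to 1-based run indices (runs 1,3 vs 2,4).
* Spearman ties: midranks; typicality ties detected at 10 significant
  digits.
* Procrustes: reflections permitted (the sign of MDS eigenvectors is
  arbitrary); scaling off by default with a switch; translation on.
* Stepwise R² ties: first column wins, deterministically.
* Quadrature: `stats::integrate`, absolute and relative tolerance 1e-8,
  range 12 prior widths.
* Degenerate inputs: all-zero RDMs project to the origin (not an error);
  constant RDMs give NaN typicality with a warning; fewer than 2 runs (or 2
  per split half) is an error; rank-deficient designs error naming the
  collinear columns.
* Determinism: every stochastic function takes an explicit seed;
  `simulate_cohort()` derives participant seeds by multiplicative spreading
  (x 48271 modulo 2^31 - 1) so nearby master seeds give disjoint cohorts.

# Problem sizes used by the test suite

The packaged tests validate the estimators at sizes chosen to make
Monte-Carlo error small relative to the tolerances while keeping the default
suite quick: null-bias and split-half null checks use 1000 simulated
participants (4 runs, 100 voxels); oracle-equivalence checks use 50 random
instances at 30 voxels; the bootstrap-replicability check uses 20 simulated
studies of 18 amputees with B = 1000 resamples; the family-wise-error check
uses 1000 simulated three-comparison families.

# Known limitations

* The parametric canonical RDM is a synthetic stand-in; typicality values
  against it are only meaningful relative to the same reference.
* Beta-mode residuals are draws from the noise covariance, not actual GLM
  residuals; their dof bookkeeping reflects that.
* The mixed ANOVA uses the classical aov decomposition (Type I in the
  within stratum); with the balanced within-subject factor used here that
  matches the definitional sums of squares.
* Robust volume-weighted GLM estimation is reduced to user-supplied
  diagonal weights.
* No searchlight mapping, pattern-component modelling, encoding models, or
  non-metric MDS.
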