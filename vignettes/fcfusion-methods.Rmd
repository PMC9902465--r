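---
title: "Methods: multi-measure resting-state FC classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-measure resting-state FC classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fcfusion)
```

This vignette documents the models behind every stage of the package, the
parameters that matter, the numerical choices, and what the synthetic
cohorts do and do not establish about real data.

## The study design

The pipeline follows the multi-measure case–control design now common in
resting-state fMRI classification work: extract several complementary
summaries of each subject's signal (voxel-wise activity measures and six
ROI-wise connectivity estimators), evaluate each summary's discriminative
power under a nested cross-validation with within-fold feature selection,
fuse modalities, and report the features that drive the separation. Each
stage is an exported function; `run_pipeline()` orchestrates them from a
configuration list.

## Voxel-wise measures

**Spectrum estimator.** ALFF and fALFF are computed from a single-taper
periodogram of the demeaned series: per frequency bin, amplitude is the
square root of periodogram power, scaled so a unit-amplitude sinusoid on
an exact bin has amplitude 1. We deliberately use no Welch averaging: the
classical definitions are stated in terms of the raw spectrum and the
single-taper form is exactly testable on sinusoids (a pure in-band tone
must give fALFF = 1 to machine precision, and doubling a signal must
exactly double ALFF). ALFF averages in-band amplitude; fALFF divides the
in-band amplitude sum by the amplitude summed over all positive
frequencies up to Nyquist, excluding DC — the natural reading of "total
power in the detectable range", kept configurable. fALFF is computed on
unfiltered data (filtering first would make the ratio trivially 1); ALFF
maps are not z-standardized — nuisance structure is removed once, at the
feature stage, by covariate residualization.

**Band-pass.** The reference filter is an ideal frequency-domain mask:
Fourier bins outside [low, high] are zeroed and the mean is always
removed. An ideal filter has ringing in the time domain, but it is exact
on band-limited signals, which is what makes the analytic tests (and the
fALFF identity above) sharp. The admissible band is validated against the
Nyquist frequency `1/(2 TR)`.

**ReHo.** Kendall's coefficient of concordance of the ranked time series
over a voxel's 27-, 19-, or 7-voxel neighbourhood, computed on
band-passed but *unsmoothed* data (smoothing would manufacture local
concordance). Ranks use midranks for ties and the classical formula
without the tie-correction term; with continuous data ties are
measure-zero, but exactly periodic signals sampled commensurately do tie,
which caps W just below 1 — the test suite works with tie-free signals
where exactness is asserted. Boundary voxels use whatever in-mask
neighbours exist rather than returning NaN; voxels with fewer than two
in-mask series get 0 and a flag. The processing order around the measures
is enforced by `voxel_measures()`: nuisance regression → smoothing
(except ReHo) → band-pass (except fALFF) → measure.

**Smoothing.** Separable Gaussian convolution with
`sigma = FWHM / (2 sqrt(2 ln 2))` per axis in voxel units, renormalized
against the smoothed mask so constants are preserved at mask edges.

## Connectivity estimators

**Pairwise and high-order correlation.** `pearson_fc()` is the plain
correlation matrix. `thofc()` correlates two ROIs' connectivity profiles
over the remaining ROIs, excluding both ROIs' own entries (the `k ≠ i, j`
constraint); its diagonal is set to 1 by convention, and profile pairs
with zero variance after the exclusions yield 0 with a flag rather than
NaN. `sliding_window_fc()` uses rectangular, contiguous windows — the
windowed-correlation definition implies plain Pearson per window, and
tapering would be an unstated extension — with the window count
`Θ = ⌊(T−L)/s⌋ + 1`. Pairs are ordered row-major over the upper triangle
(i < j), a convention fixed once and carried through feature names.

**Dynamic high-order network.** Pair series are grouped by Ward's
minimum-variance linkage (`hclust` method `ward.D2`, squared Euclidean
geometry) and each cluster's member series are averaged without weights;
the K × K network is the correlation matrix of the cluster means. Ward
linkage on a fixed distance matrix is deterministic here; distances
between distinct pair series are continuous-valued, so exact ties do not
arise in practice and `hclust`'s ordering resolves any that did. For
cohort feature extraction the clustering is fitted once on the pooled
window series of all subjects, so cluster identities align across
subjects; each subject's network is then built from its own windows under
that shared assignment.

**Sparse-representation family.** All four estimators standardize
columns to zero mean and unit ℓ2 norm first, which puts the regularization
weights on a comparable scale across instances, and constrain
`diag(W) = 0` — without that constraint the per-subject objectives admit
the trivial minimizer W = I, and the group formulation already excludes
the target ROI from its own design. Solvers:

- SR and GSR: per-column (per-ROI) proximal gradient with FISTA
  acceleration and a monotone safeguard (the accelerated point is
  rejected in favour of a plain proximal step whenever it would increase
  the objective, so objective traces are non-increasing); prox operators
  are the soft threshold and the row-wise group soft threshold. Stopping
  at relative objective change below `tol` (default 1e-6), cap 5000
  iterations. Initialization at zero makes the analytic null thresholds
  exact: `max_j ‖X_{-j}ᵀ x_j‖_∞` (single subject) and the row-wise ℓ2
  norm of stacked gradients (group) produce exactly zero solutions.
- SLR: consensus ADMM with two auxiliary copies of W — one carrying the
  ℓ1 prox together with the diagonal projection (both elementwise, so
  they commute), one carrying the singular-value soft threshold — and an
  exact smooth-block solve through a cached eigendecomposition of the
  Gram matrix. The sparse copy is reported; λ2 = 0 reproduces SR.
- SSGSR: the weighted ℓ2,1 term is handled by the exact change of
  variables `v = b ⊙ w` (valid because `b = exp(−w0²) > 0` always),
  which rescales design columns by 1/b and reduces the penalty to the
  standard row-group prox; the similarity quadratic
  `λ₂ Σ_{pq} l^{pq} ‖w^p − w^q‖²` stays in the smooth part as a graph
  Laplacian, and the step size comes from a power-iteration bound on the
  composite Hessian. Note the finite-λ₂ optimum retains inter-subject
  differences of order 1/λ₂; the consensus limit is only reached
  asymptotically.

Correctness of all four is certified in the test suite against a generic
convex-programming oracle: L-BFGS-B on an ε-smoothed objective
(`|x| → sqrt(x² + ε)`, `‖W‖₊ → Σ sqrt(σ² + ε)`, ε = 1e-9), with
objective values compared on the original nonsmooth objective at 1e-4
relative tolerance, plus an independent glmnet cross-check for the lasso
column problems. Degenerate correlations anywhere in the package are set
to 0 with a recorded flag, never silent NaN, so downstream feature
matrices stay finite.

Because the directed coefficient matrices are reported as undirected
connections, features are read from the symmetrized matrix
`(W + Wᵀ)/2`, upper triangle only.

## Classification protocol

Features are assembled per modality (FC upper triangle, K × K network
upper triangle, or masked voxel values), then residualized on the
nuisance covariates (sex, scanner manufacturer, site, head motion;
categorical covariates one-hot encoded, residuals exactly orthogonal to
the design). Residualization uses covariates only — never labels — so it
is done once, before cross-validation.

`nested_cv()` runs stratified outer folds (default 10): shadow-feature
selection on the outer-training set only, an inner stratified grid search
(default 5 folds) maximizing AUC, a refit on the full outer-training set,
and a single evaluation on the untouched outer-test fold. Stratification
is the defensible default for a roughly balanced cohort evaluated by AUC.
A leakage audit is built in: `audit_poison = TRUE` overwrites outer-test
feature rows with noise immediately after each split, and the test suite
asserts that no selection or tuning decision changes for any of the nine
classifier families.

The selector follows the Boruta scheme: per round, every candidate
feature gets a column-shuffled shadow copy, a random forest scores
importances, and a feature is credited a hit when it beats the best
shadow; two-sided binomial tests on hit counts (chance rate 1/2,
Bonferroni-corrected over the undecided set, first decision after 5
rounds) accept or reject, and whatever is undecided at the round cap is
rejected. Defaults — 300 trees, α = 0.05, cap 100 rounds — follow common
practice; inside the demonstration pipeline we use 150 trees and a cap of
25 rounds, which the power simulations show lose nothing at the demo
effect size while keeping the full nested protocol fast. If a fold
accepts nothing, the fold falls back to all features with a flag — a
selector that returns the empty set would otherwise make the fold
undefined.

Nine classifier families sit behind one fit/score interface: logistic
regression (`glm`), k-nearest neighbours (`class::knn`), a ridge-penalized
linear classifier (`glmnet`, α = 0), Gaussian naive Bayes (`e1071`),
linear- and RBF-kernel SVMs (`e1071`), random forest (`ranger`),
gradient-boosted trees (`xgboost`), and an in-package discrete AdaBoost
over depth-1 `rpart` stumps (no boosted-stump package is pre-installed,
and the algorithm is 30 lines). SVM decision values are sign-oriented on
the training data, since their raw sign depends on an arbitrary class
order. Hyperparameter grids are deliberately small, documented defaults
(`default_grid()`); the study design statement says grids were searched
but not what they were.

Metrics use the standard confusion-count identities with the case group
positive; zero-denominator ratios report 0 with a flag. AUC is the
rank-based Mann–Whitney statistic with midrank ties, identical to the
trapezoidal ROC area; all-tied scores give exactly 0.5.

**Parameter sensitivity** is a separate, deliberately simpler protocol
mirroring the two-stage design: for each grid point the measure is
recomputed and a plain (non-nested) stratified 10-fold CV with an RBF
SVM at fixed C = 1 records mean AUC; the argmax is reported with ties
resolved toward the smallest parameter values (the grid is evaluated in
ascending lexicographic order).

## Fusion

Early fusion concatenates the per-modality selected features. Model-based
fusion is multiple kernel learning: per modality an RBF Gram matrix with
the median-pairwise-distance bandwidth (a linear kernel is available),
centered in feature space and trace-normalized to the number of subjects;
weights are the positive part of each kernel's centered alignment with
the label kernel, normalized onto the simplex — a convex, deterministic,
testable weighting — and the final predictor is a least-squares kernel
machine (kernel ridge on ±1 labels) on the convex combination. The
weighting is a swappable strategy behind `mkl_fit()`. Fusion is evaluated
under exactly the nested protocol of the unimodal runs (`fusion_cv()`):
selection, kernel parameters, and weights are all fitted inside
outer-training folds. Kernels are built on the per-modality selected
features of the fold, matching the design's statement that fusion
combines the discriminative features of each modality.

## Biomarker identification

ROI-wise: candidates are the features selected in *every* outer fold
(stable candidates); each candidate gets a two-sided two-sample t-test —
pooled variance by default, since no unequal-variance qualification is
stated, with Welch behind a flag — and Benjamini–Hochberg FDR across the
candidate set. Reporting conventions per modality: SLR keeps the top 20
connections by p; SSGSR keeps all significant connections; the dynamic
high-order measure counts each cluster's appearances among significant
cluster-pairs and keeps the 10 highest-count clusters (ties toward the
lower cluster id).

Voxel-wise: a two-sample t-map thresholded at the two-tailed p < 0.001
quantile, suprathreshold voxels grouped into 26-connected clusters
(matching the 27-voxel neighbourhood convention), and cluster-extent
correction by a label-permutation null of maximum cluster sizes at
cluster-level p < 0.05. The permutation analogue replaces parametric
Gaussian-random-field correction deliberately: random-field smoothness
estimation drags in a large dependency with many unstated settings,
while the permutation null gives exact-by-construction familywise control
at the same thresholds; the substitution is recorded in the output
metadata.

## The synthetic cohort generator

The generator defines the conditions under which the pipeline is tested.
Each subject's ROI series is Gaussian AR(1) noise (unit marginal
variance) pushed through the Cholesky factor of a group correlation
matrix — the simplest stationary process with controllable cross- and
auto-correlation. Baselines come from a 3-factor latent structure
(`base_strength = 0.3`, giving off-diagonal correlations mostly within
±0.4, typical of parcel-level resting-state data); group differences are
planted as correlation shifts on a known edge set, clipped to ±0.95 and
repaired to the nearest unit-diagonal SPD matrix by eigenvalue clipping
at 1e-6 only when needed. Dynamic scenarios switch among state
covariances along a cycle with geometric dwell times (mean 40 timepoints
— memoryless, one parameter); the control model's states are identical,
so only the case group is genuinely non-stationary. Head motion is a
log-normal scalar per subject, optionally group-correlated, matching how
a scalar motion summary enters the covariate regression. Voxel scenarios
plant either band-limited oscillatory power (amplitude effects) or a
shared latent signal across a neighbourhood (homogeneity effects; shared
fraction 1 forces concordance 1 exactly).

The demonstration cohort — 20 ROIs, 60 + 60 subjects, 8 planted edges at
correlation shift 0.4, T = 370 timepoints at TR = 0.8 s — matches the
acquisition length and sampling of the motivating study design while
keeping desk-scale runtimes; 20 ROIs rather than a full atlas keeps the
nested protocol (10 × 5 folds with per-fold selection) in seconds per
run, and the effect size is chosen so recovery is expected, making
end-to-end failures attributable to code rather than statistics.

What passing these tests shows: the estimators compute their definitions
exactly, the protocol is leakage-free, error rates are controlled under
the null, and planted effects of plausible size are recovered. What it
does not show: performance on real data, where signals are
non-Gaussian, autocorrelation is spatially heterogeneous, motion is
structured rather than log-normal scalar, and effects are weaker and
distributed — the saturated AUC of the demo cohort carries no claim about
real-world accuracy.

## Problem sizes and runtimes

The test suite and the acceptance script run on one CPU in a few minutes:
solver-oracle certification uses instances with N ≤ 6 ROIs, T ≤ 40
timepoints, S ≤ 4 subjects (20+ instances); Monte-Carlo error-control
checks use 200 null cohorts for FDR and 30–50 null map sets (8³ voxels,
10 + 10 subjects, 100–200 permutations) for cluster-level control; the
demonstration cohort is as above, with 20 label-permutation runs for the
null of the nested protocol. These sizes are the package's chosen
verification conditions and are stated here so they can be scaled up
deliberately rather than discovered in the code.

## Known limitations

- The ideal band-pass assumes regularly sampled, gap-free series.
- The uncorrected KCC ties behaviour (above) is visible only on
  artificially periodic signals.
- `solve_slr()` reports the sparse ADMM copy; at loose tolerances the
  two auxiliary copies can differ at the tolerance scale.
- The MKL weighting is alignment-based, not jointly optimized with the
  classifier; it is deterministic and convex by design, and swappable.
- The pipeline's caching keys on the configuration hash; editing code
  between runs without clearing the cache directory reuses stale stages.
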