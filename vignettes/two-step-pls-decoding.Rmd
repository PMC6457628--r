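---
title: "Two-step PLS decoding of fMRI brain states: models, simulation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step PLS decoding of fMRI brain states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multi-voxel pattern analysis (MVPA) decodes which cognitive task a subject is
performing from the distributed pattern of BOLD activity in an fMRI volume.
The data are extreme in shape: a single run yields on the order of
`n = 100` usable volumes against `p = 10^4`–`10^5` voxels. Partial least
squares regression (PLSR) is well matched to this regime because its latent
components are built from covariance with the class labels rather than from a
`p x p` inverse. `plsdecode` implements a two-step framework in which PLSR
appears twice: once as a *feature selector* (directly, or in a sparse
variant) and once as the *classifier* itself.

## The PLS regression model

Let $X_{n \times p}$ hold the (column-centred) volumes-by-voxels data and
$Y_{n \times q}$ the dummy-coded task labels ($Y_{ij} = 1$ iff volume $i$
belongs to task $j$, columns centred). PLS posits the latent decomposition

$$X = T Q_X^\top + E_X, \qquad Y = T Q_Y^\top + E_Y, \qquad T = X W,$$

with $K$ latent score vectors in $T_{n \times K}$. Predictions use
$\hat{Y} = X \beta$ with $\beta = W Q_Y^\top$.

The components are extracted sequentially. Writing $P_T = T T^{+}$ for the
projection onto the span of the accumulated scores (Moore–Penrose inverse,
singular values below $10^{-12}$ of the largest truncated), stage $k$ works
on the deflated residuals $X_{(k)} = (I - P_{T(k-1)})X$ and
$Y_{(k)} = (I - P_{T(k-1)})Y$ and solves

$$r_{(k)} = \arg\max_r \; r^\top Z_{(k)}^\top Z_{(k)} r
  \quad \text{s.t. } r^\top r = 1, \qquad Z_{(k)} = Y_{(k)}^\top X_{(k)}.$$

We compute $r_{(k)}$ as the dominant right singular vector of $Z_{(k)}$
through the eigendecomposition of the small $q \times q$ matrix
$Z Z^\top$ — the same fixed point the classical NIPALS power iteration
converges to, but deterministic and without a convergence tolerance. The sign
is fixed so the largest-magnitude coordinate is positive. After $K$ stages
the direction matrix is assembled as

$$W = R_{(K)} \left( G_{(K)}^\top R_{(K)} \right)^{-1}, \qquad
  G_{(K)} = X^\top T (T^\top T)^{-1},$$

which guarantees $T = XW$ on the training data. Both $X$ and $Y$ are
deflated; deflating $Y$ is algebraically redundant for $Z_{(k)}$ (the
projection is idempotent) but is kept for fidelity to the printed scheme.
When the residual cross-covariance becomes numerically zero before $K$
components are extracted, the model is returned shorter with a warning, so
heavily penalised sparse fits degrade gracefully rather than failing.

Two useful limits anchor the implementation and are enforced in the test
suite: with $K = \operatorname{rank}(X)$ and $n > p$ the coefficients equal
the ordinary least squares solution, and the score vectors are always
mutually orthogonal with unit-norm raw directions.

## Sparse directions

At any stage, the unpenalised direction solves the multivariate regression
$Z = C r^\top + e$ with covariate $C = Y^\top t$. The sparse variant
penalises each coordinate:

$$Q_\lambda(r) = \sum_{j=1}^{p} \left\{ \tfrac12 \| Z_j - C r_j \|^2
  + \lambda |r_j| \right\},$$

which separates over $j$ and has the closed-form soft-threshold minimiser
$r_j = \operatorname{soft}(C^\top Z_j, \lambda) / C^\top C$ with
$\operatorname{soft}(a, \lambda) = \operatorname{sign}(a)\max(|a| - \lambda, 0)$.
We evaluate $C$ at the unpenalised dominant-singular-vector direction and
apply the closed form once per stage; an optional fixed-point refinement
(re-evaluating $C$ at the sparse direction) is available internally but
changes little in practice. At $\lambda = 0$ the estimator is exactly the
unpenalised direction, so the sparse fit reduces to plain PLSR — an identity
the tests check to $10^{-8}$. The thresholded direction is rescaled to unit
norm, for consistency with the constraint on the dense directions (the
literature is silent on this; it only changes the scale bookkeeping in $W$).

The penalty is shared across components and tuned by stratified
cross-validated mean squared error of the predicted indicator matrix, on a
grid of 0 plus 20 geometric points up to $\max_j |C^\top Z_j|$ of the first
stage. Ties are resolved toward the larger penalty (the sparser model); grid
points whose first direction is entirely thresholded away are dropped, and
only if every point dies is tuning an error.

## Feature selection and the argmax classifier

Selection works on the coefficient matrix $B_{p \times q}$ of a fit to the
task-labelled training volumes. Each column is converted to z scores
(sample standard deviation, $n-1$ denominator), and voxels with $z > 3.5$
(strict) are marked relevant to that task; the final mask is the union
across tasks with per-task provenance retained. The comparator selector fits
a voxel-wise GLM of the full training run on the HRF-convolved task
regressors plus intercept and keeps voxels with one-sided $p < 0.001$
(uncorrected, positive activation), again unioned over tasks. The one-sided
choice follows the positive-activation reading of the thresholding rule; the
sidedness and the sample-sd convention are configurable.

The classifier is PLSR itself: refit on the masked training columns, a test
volume $D_{1 \times k}$ receives the weight vector
$y_{1 \times q} = D B_{k \times q}$ (after centring with the training
offsets) and is assigned to the task with the largest weight. Ties go to the
smallest task index and are counted. Accuracy is $R = M/N$. The comparator
classifier is a linear SVM (delegated to `e1071::svm`): one binary machine
per task pair, its cost chosen by the same stratified CV, combined by
one-vs-one majority vote with the same tie rule.

Both runs are first normalised in two passes, voxel time courses to zero
mean and unit variance, then each volume across voxels, in that order.
Zero-variance voxels are identified *on the training run only* and the same
kept set is applied to the test run, so masks stay aligned without ever
reading test values; the test run enters the pipeline exclusively at
prediction time. This no-leakage contract is tested by poisoning the test
run with sentinel noise and checking the serialised classifier is
byte-identical.

## The simulator

The synthetic study emulates a four-task block design: per run, sixteen 12-s
task blocks (four per task, order randomised independently per run)
alternate with seventeen 6-s rest blocks; TR 2 s; 147 volumes per run;
270 x 270 images with baseline intensity 800. Four disjoint square task ROIs
(side one-ninth of the grid, 900 pixels at full size) sit at the quadrant
centres and one equal-sized shared ROI at the image centre; the shared ROI
receives the sum of all four task signals. The exact ROI geometry of the
original layout is not recoverable from a printed description, so the layout
is parametric with stored ground truth, and all recovery statistics are
computed against that stored truth.

Task signals are boxcars convolved with the canonical double-gamma HRF
(response delay 6 s, undershoot delay 16 s, unit dispersions, 6:1 ratio,
32 s support, sampled at the TR, unit peak). Noise is Rician:
$v \mapsto \sqrt{(v + n_1)^2 + n_2^2}$ with $n_1, n_2 \sim N(0, \sigma^2)$,
the correct model for MRI magnitude images; the sample mean of a corrupted
constant region is tested against the analytic Rician first moment. The
contrast-to-noise ratio is realised as amplitude $= \mathrm{CNR}\cdot\sigma$
with $\sigma = 30$ image units by default; because the convolved regressors
have temporal standard deviation very close to 1, this coincides (to within
a few percent) with defining CNR as signal-sd over noise-sd. Only the ratio
matters after the two-pass normalisation. Optional rigid motion is a
per-volume random-walk 2D translation with bilinear resampling; it is off by
default so unit tests stay deterministic.

### Labels and the haemodynamic lag

Each volume is labelled by the block covering its acquisition time shifted
back by a haemodynamic lag (`label_lag`, default 4 s = two volumes at
TR 2 s); rest volumes are excluded from the classification samples (the
design decodes among the $q$ tasks, with no rest class), leaving 96 task
volumes per run, 24 per task — counts the lag preserves exactly. The lag
default is a deliberate design choice: the BOLD response peaks roughly 5–6 s
after stimulus onset, so without the shift the first volumes of every block
carry the *previous* condition's response and even noise-free data cannot be
decoded perfectly (we measure a ceiling of about 0.89 at very high CNR with
no lag, versus 1.0 with the 4-s lag). The lag remains configurable,
including 0 for strict stimulus-time labelling.

What the simulator does *not* emulate: 3D geometry and rotational motion,
physiological (cardiac/respiratory) noise, spatial autocorrelation of the
noise, scanner drift, and between-subject anatomical variability. Passing
tests on this generator therefore demonstrate the estimators' statistical
behaviour under controlled signal and Rician noise, not performance on real
preprocessed fMRI, where drift removal and realignment residuals matter.

## Group maps and method comparison

Per-task group pattern maps apply a voxel-wise one-sample t test (one-sided,
positive weights) across subjects' coefficient maps, threshold at voxel
$p < 0.001$, and keep 8-neighbour connected components *strictly larger*
than 25 voxels (a 25-voxel component is removed, a 26-voxel one kept);
4-neighbour connectivity is available. Method accuracies are compared with
two-sided Wilcoxon signed-rank tests on the 15 paired per-subject
accuracies, zero differences dropped (the classic convention), significance
at $p < 0.05$, for every pair of methods sharing a selector or a classifier.

## Problem sizes and numerical choices

The package-default experiment sizes follow the full study design (15
subjects per CNR level at CNR 0.05, 0.1, 0.2, 0.4, two runs each). For the
routine regeneration of the simulated experiment — the test suite and
`scripts/acceptance.R` — we run the same design on a 96 x 96 grid, which
preserves the ROI proportions (task ROIs 11 x 11 = 121 pixels, about 1.3% of
the image, as at full size) while keeping a full four-level, six-method
factorial to a few minutes of compute; the full 270 x 270 grid is a single
argument away (`grid = 270`) and needs about 10 GB to hold a whole study in
memory, which is why the experiment driver generates subjects one at a time
from derived seeds instead of materialising the study.

Other numerical defaults: component counts are chosen by 5-fold stratified
CV over `1:min(10, n-1, p)` with ties to the smaller count; the cluster
labelling and argmax are deterministic with documented tie rules; every
random step (block orders, noise, fold assignment) derives from one master
seed through an explicit integer-hash chain, so a repeated run is
bit-identical; all randomness is drawn inside `withr::with_seed` and never
disturbs the caller's RNG state.

## Known limitations

* The selection z-threshold of 3.5 is calibrated for large `p`; with fewer
  than a few thousand voxels the attainable z is bounded by the signal
  fraction and the rule can select nothing (the failure is reported per
  cell, with an optional top-m fallback that is off by default).
* The GLM selector uses plain OLS with no autocorrelation correction —
  adequate for the simulator's white Rician noise, optimistic for real data.
* Sparse group-level maps are not aggregated across subjects by t tests:
  sparse supports vary across subjects, so per-subject patterns are the
  supported output, mirroring how the method is meant to be used.
* The one-vs-one SVM comparator depends on `e1071`'s QP solver; its exact
  support vectors are not bit-reproducible across BLAS builds, though the
  voting predictions are stable in practice.
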