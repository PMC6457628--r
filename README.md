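# plsdecode

Two-step partial least squares (PLS) decoding of brain states from fMRI.

## What problem this solves

Task-fMRI decoding asks which of `q` cognitive tasks a subject was performing
during each acquired volume. The data are wide and short: `n ≈ 10²` usable
volumes against `p ≈ 10⁴–10⁵` voxels, so classical multivariate models are
ill-posed. Partial least squares regression (PLSR) handles `p ≫ n` by
extracting latent components that maximise covariance with the class labels.
`plsdecode` implements a **two-step** framework for researchers doing
multi-voxel pattern analysis (MVPA):

1. **Feature selection.** Fit PLSR — or its sparse variant SPLSR, which
   soft-thresholds the direction vectors so most voxel weights are exactly
   zero — to the training run, convert each task's column of the coefficient
   matrix `B` to z scores, and keep voxels with `z > 3.5`; the union over
   tasks is the feature mask. A voxel-wise GLM t-map selector (one-sided
   `p < 0.001`, uncorrected) is included as the standard baseline.
2. **Classification.** Refit PLSR on the masked features; a test volume
   `D` gets weights `y = D·B` and is assigned to the task with the largest
   weight (`R = M/N` accuracy). A linear SVM with one-vs-one voting is the
   comparator classifier.

Crossing the three selectors with the two classifiers gives the six methods
`SP_PLSR, P_PLSR, G_PLSR, SP_SVM, P_SVM, G_SVM`.

## The model in brief

With column-centred `X (n×p)` and dummy-coded labels `Y (n×q)`:

    X = T Qx' + Ex,   Y = T Qy' + Ey,   T = X W,   Ŷ = X W Qy'

Components come from projection-deflation NIPALS: at stage `k`,
`r_k = argmax r' Z_k' Z_k r` with `‖r‖ = 1` and `Z_k = Y_k' X_k` the deflated
cross-covariance (we take the dominant right singular vector — the NIPALS
fixed point), and `W = R (G'R)⁻¹` with `G = X'T(T'T)⁻¹`. The sparse stage
direction minimises `½‖Z_j − C r_j‖² + λ|r_j|` per coordinate
(`C = Y't`), i.e. `r_j = soft(C'Z_j, λ)/C'C`; `λ` is tuned by stratified
cross-validated MSE. Component counts are chosen by stratified CV with ties
to the smaller count.

The package also ships a block-design BOLD simulator used as ground truth:
four task ROIs plus one ROI shared by all tasks on a 270×270 grid (baseline
800), sixteen 12-s task blocks alternating with seventeen 6-s rest blocks at
TR 2 s (147 volumes/run), canonical double-gamma HRF, Rician noise at CNR ∈
{0.05, 0.1, 0.2, 0.4}, 15 subjects × 2 runs per level, optional rigid
motion. See the vignette (`vignettes/two-step-pls-decoding.Rmd`) for every
modelling decision and default.

## Worked example

Simulate one subject at CNR 0.2 on a 96×96 grid (ROI proportions preserved)
and decode the second run with SPLSR selection + PLSR classification:

```r
library(plsdecode)

layout  <- default_roi_layout(grid = 96)
subject <- generate_subject(cnr = 0.2, layout = layout, sigma = 30, seed = 8)
res <- run_subject(subject$runs[[1]], subject$runs[[2]], "SP_PLSR", seed = 1)
print(as.data.frame(res[, c("method", "n_features", "ncomp", "lambda",
                            "n_test", "n_correct", "accuracy")]), digits = 3)
#>    method n_features ncomp lambda n_test n_correct accuracy
#> 1 SP_PLSR        375     3   4114     96        73     0.76
```

Reading: the sparse selector (penalty `λ = 4114`, 3 latent components chosen
by CV) kept 375 of 9216 voxels; the PLSR argmax classifier then labelled 73
of the 96 task volumes of the held-out run correctly (accuracy 0.76 against
a 0.25 chance level). The full factorial — all six methods, 15 subjects, all
four CNR levels — is one call:

```r
experiment <- run_experiment(grid = 96, seed = 1)   # ~10 min on one core
summarize_experiment(experiment)   # mean ± se accuracy per method × CNR
autoplot(experiment)               # accuracy vs CNR, one line per method
compare_methods(experiment)        # paired Wilcoxon signed-rank tests
```

Fitted objects follow broom conventions (`tidy()`, `glance()`), group-level
pattern maps come from `group_pattern_map()` (voxel `p < 0.001`, cluster
size > 25, 8-connectivity), and `inst/cli/plsdecode` exposes
`simulate` / `evaluate` / `compare` / `group-map` subcommands for shell use.

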