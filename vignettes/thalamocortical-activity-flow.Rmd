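---
title: "Methods: task hubs, activity flow, and virtual lesions in a thalamocortical model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task hubs, activity flow, and virtual lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalamoflow)
```

This vignette documents the models and procedures the package implements,
the choices made where the design was genuinely open, and what passing the
synthetic-data tests does and does not establish about real data.

## The scientific question

Multi-task fMRI shows that evoked activity occupies a low-dimensional
space: a handful of spatial components, mixed task by task, explain most
of the variance of a voxel-by-task beta matrix. Regions that carry strong
weight on many of those components — *task hubs* — and regions whose
connectivity spreads across many cortical networks — *network hubs* — are
candidate substrates for multi-domain cognition. The pipeline asks three
linked questions of a source region (the motivating case is the human
thalamus, with ~2445 voxels against 400 cortical ROIs in 7 networks):
whether its evoked activity is low-dimensional; whether its task hubs and
network hubs coincide; and whether its activity, pushed through its
connectivity, predicts cortical task patterns — tested by cross-validated
prediction, null models, noise ceilings, and virtual lesions.

## The task GLM

Evoked amplitudes are estimated per unit (voxel or ROI) by ordinary least
squares on

* one regressor per trial type: a gamma HRF convolved with the stimulus
  boxcar, sampled at the repetition time and convolved within runs so
  responses never bleed across run boundaries;
* run-wise constant and polynomial drift regressors, zero outside their
  run;
* optional nuisance columns (motion parameters, noise components);
* deletion censoring: volumes with framewise displacement above 0.2 mm are
  removed as rows, not modeled as spikes. Residual rows at censored
  volumes are reported as missing, never zero-filled.

**Estimator.** OLS rather than prewhitened generalized least squares: a
GLS requires an autoregressive noise model that would itself be a free
parameter here, OLS betas are unbiased under the same design, and the
synthetic noise is white by construction. A plug-in whitener can be added
ahead of the fit without touching the interface.

**HRF.** A single peak-normalized gamma kernel, shape 8.6, scale 0.547 s
(peak near 4.7 s) — a standard gamma-variate choice; both parameters are
config fields since nothing downstream depends on the exact shape beyond
"peaks a few seconds after onset".

**Drift order.** Quadratic per run by default (`poly_order = 2`). With the
synthetic run length of 200 volumes this leaves drift and task regressors
far from collinear; the fit errors out loudly, naming the collinear
columns, if a configuration makes the design rank deficient.

**Exclusion rule.** A unit set is flagged for exclusion when any task has
more than 40% of its stimulus-on volumes censored; the inequality is
strict, and the per-task fractions are computed on the boxcar (stimulus
on/off), not the convolved regressor.

**Sub-conditions** are distinct trial types at fit time; their betas are
averaged arithmetically into one estimate per task afterwards. Averaging
betas (not design columns) keeps the per-condition fits untouched.
Instruction periods get their own regressor and are dropped from all beta
tables.

## Decomposition and CompW

The voxel-by-task matrix is standardized *globally*: subtract the grand
mean over all elements, divide by the grand SD. No per-voxel scaling is
applied at this stage; the PCA then treats tasks as observations and
voxels as features, which implies per-voxel mean removal internally. At
full rank `weights %*% loadings` reconstructs that centered matrix to
relative error below 1e-8, and the variance-explained vector equals the
normalized squared singular values — both are enforced by tests against
an independent SVD oracle.

PCA signs are arbitrary, so each component is flipped to make its
largest-magnitude voxel weight positive. CompW is sign-invariant; the
convention only makes loading plots deterministic. Ties in variance
explained keep the original component order.

`CompW(v) = Σ_i |W_vi|` is computed over the top 10 components by default
(or all available when the task count supports fewer); computing the same
sum over components 11–20 is the control path — on planted data its
voxel ranking decorrelates from the top-range ranking, confirming the hub
pattern is carried by the dominant components.

The group path averages beta matrices across subjects (here: across
split halves) *before* standardization and decomposition; per-subject
curves are produced by mapping the same path over subjects and reported
with mean ± SEM.

## Connectivity and the participation coefficient

Voxel-to-ROI connectivity is estimated by principal-component regression:
each ROI's residual series is regressed on the leading components of the
source-voxel series, and component coefficients are back-projected to
voxel weights. Retention is the smallest component count reaching 95% of
source variance (config field); at 100% retention on full-rank data the
weights equal the OLS solution exactly, which the tests assert. PCR,
like partial correlation, accounts for shared variance among voxels but
remains defined when voxels are nearly collinear.

The participation coefficient needs nonnegative strengths, so negative
weights are zeroed before thresholding by default (an absolute-value mode
exists). Density thresholding is matrix-wide: the strongest
`round(d · voxels · ROIs)` entries are kept, ties broken by stable entry
order, for `d` from 0.01 to 0.15 in steps of 0.01 (the grid step is a
choice; only the range is canonical). Per-voxel PC values are averaged
over densities, ignoring densities where the voxel has no retained weight;
a voxel with no retained weight at any density is reported missing. For
hub-recovery scoring such voxels are treated as PC = 0 — no
suprathreshold connectivity is the opposite of distributed connectivity.

Weighted (not binarized) strengths enter the `K` sums, since the defining
formula is written in terms of weight sums; a binarized variant would be a
one-line change behind the same interface.

## Activity flow, nulls, and the noise ceiling

Prediction is the linear map `A_ctx = B_t · FC`. Evaluation is split-half:
fold A predicts from half 1's betas and connectivity and is scored against
half 2's *observed* cortical betas (Pearson r across ROIs, per task), fold
B mirrors, and accuracies average over tasks then folds. The default split
interleaves runs (odd/even); the rule is a logged config field, and a
contiguous split is available.

Three null models run through the identical evaluation: shuffled voxel
order (fresh permutation per fold, seed logged; the identity permutation
reproduces the main model exactly, which is tested), all-ones betas
(predictions collapse to connectivity column sums, identical for every
task), and per-voxel task-average betas. Null accuracies are normalized by
the *main* model's noise ceiling, so normalization cannot flatter a null.

The noise ceiling is the product of the split-half reliability of the
modeled patterns and of the observed patterns, per task. A product of two
small reliabilities is numerically unstable and can flip sign, so tasks
with ceiling at or below 0.05 are excluded from the normalized mean and
logged; excluding them never changes any included task's value. The
product form (rather than the square root of the product) is the printed
convention followed here; the alternative is a config flag away.

## Virtual lesions and patient profiles

Voxels are ranked descending by CompW into percentiles — start 0 holds
the strongest hubs, so the window at start 0 lesions the top 20%. Each
window zeroes the betas of voxels ranked in `[s, s + 20)` percent (for
`s = 0 … 80`, step 1) in both halves, leaves connectivity untouched, and
re-runs the full split-half evaluation. Reduction is
`100 · (acc₀ − acc) / acc₀`; each voxel's map value is the mean reduction
over the windows that lesioned it (the aggregation over overlapping
windows is a choice; windows covering interior percentiles number exactly
window/step = 20). The unlesioned sweep reproduces the baseline evaluation
bit-identically.

Reduction is regressed on window start by OLS (stacking subject × window
observations when several sweeps are supplied). Per-voxel reductions under
hub-overlapping vs non-hub-overlapping lesion masks are compared with a
two-sample Kolmogorov–Smirnov test, exact p when both samples have fewer
than 25 voxels.

Patients are classified from a long table of age-adjusted test z-scores
mapped to functional domains: a domain is impaired when *any* of its
tests falls strictly below −1.645 (the 95th percentile of the normative
distribution), and a patient is MM when strictly more than 2 domains are
impaired. Both inequalities are strict; boundary cases (z exactly at the
threshold, exactly two impaired domains) classify as SM, and tests pin
this down. The any-test-within-domain aggregation is a choice the source
convention leaves open.

## The synthetic generator

The generator plants, jointly: `k = 3` orthonormal spatial component maps
over 100 voxels; a `k × 10` loading matrix with distinct decreasing
singular values (so the decomposition is unique up to sign); a
nonnegative voxel-to-ROI connectivity matrix over 40 ROIs in 7 networks;
and a 20% hub class. Hub voxels load on every component and connect to
every network; non-hub voxels load on exactly one component (with a
signed weight — evoked responses deviate in either direction, keeping the
planted maps near zero spatial mean) and connect to exactly one network.

Orthonormality is achieved *by construction* — an orthonormal hub block
(QR of a Gaussian matrix, row-norm balanced by Givens rotations) plus
disjoint-support non-hub blocks — because a post-hoc Gram–Schmidt pass
would smear weight onto non-hub voxels and destroy the
single-component property. The hub block is scaled so every hub row's L2
norm strictly exceeds `sqrt(k)` times the largest non-hub weight; since
the PCA weight matrix of the noiseless beta matrix is an orthogonal
rotation of the planted maps, this guarantees CompW separates the classes
perfectly at zero noise (an enforced, bounded redraw makes the guarantee
deterministic given the seed).

Betas are signal plus iid Gaussian noise, two halves from independent
draws — exactly the structure split-half reliability assumes. Time series
are a latent low-dimensional series mapped through the component maps,
plus HRF-convolved task-locked responses scaled by the planted betas
(at amplitude 1 the GLM recovers the planted matrix), with ROI series the
connectivity-weighted voxel signal; framewise displacement plants a
configurable fraction of suprathreshold volumes. Noise is iid Gaussian
throughout; no effect-size anchors exist for the motivating datasets, so
the default amplitudes are free parameters chosen once for a clearly
detectable but noisy regime (per-element beta SNR near 1), not calibrated
to any empirical dataset.

**What the synthetic conditions do not emulate:** hemodynamic
nonlinearity, physiological (1/f, respiratory, cardiac) noise spectra,
spatial autocorrelation of BOLD, inter-subject variability in hub
placement, and real lesion geometry. Passing the recovery tests
establishes that the estimators are correct and the pipeline is coherent
under its own assumptions; it does not establish effect sizes, noise
ceilings, or hub locations in real data.

## Numerical conventions and problem sizes

Tolerances: orthonormality and variance-oracle agreement at 1e-10;
reconstruction and OLS equivalences at 1e-8; analytic participation
coefficients at 1e-12. Degenerate inputs error loudly rather than
propagate: constant matrices cannot be standardized or ranked,
zero-variance ROI series name the offending ROI, unlabeled ROIs and
unmapped conditions are errors, and zero-variance observed patterns drop
their task with a warning.

The default run — 100 voxels, 40 ROIs, 7 networks, 10 tasks, 4 runs of
200 volumes, an 81-window lesion sweep — completes in a few seconds on
one CPU; the test suite's heaviest piece, a 100-replicate null-model
ordering experiment at 25 tasks, runs in well under a minute. These sizes
were chosen so each stage has nontrivial work while a full run stays
interactive; every stage scales linearly in voxels × tasks except PCR
(cubic-ish in min(time, voxels)) and the sweep (linear in windows).

## Known limitations

* OLS in place of prewhitened GLS understates autocorrelated noise in
  real BOLD; betas stay unbiased but their standard errors (not used
  downstream) would not be trusted.
* The participation coefficient depends on the negative-weight policy and
  the density grid; both are config fields, and the zero-negative default
  discards genuine anticorrelation structure.
* The noise-ceiling product can exceed raw accuracy's scale at high
  reliability and become unstable near zero; the 0.05 floor is a
  pragmatic, logged cutoff, not a principled estimator.
* Per-voxel reduction maps average overlapping windows; attribution of a
  window-level effect to single voxels is inherently smoothed at the
  window scale.
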