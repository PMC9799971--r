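# thalamoflow

How is task-evoked fMRI activity in the thalamus organized, and can it
predict cortical task activity? `thalamoflow` implements a complete,
tested analysis pipeline for this question, exercised end-to-end on
synthetic data with planted ground truth so that every claim the analysis
makes — low-dimensional structure, hub metrics, activity-flow prediction,
lesion effects — is a testable recovery target rather than an untestable
description.

It is written for cognitive-neuroscience researchers who work with
multi-task fMRI: people who estimate evoked responses with a GLM, care
about head-motion censoring and split-half reliability, and want the hub
and prediction metrics of network neuroscience with their assumptions
spelled out and checkable.

## The analysis in brief

1. **Task GLM.** Evoked amplitudes (betas) per voxel and task are
   estimated by OLS from time series, with task regressors built by
   convolving a gamma HRF with the stimulus boxcar, run-wise constant and
   polynomial drift, motion nuisance columns, and deletion censoring of
   volumes with framewise displacement > 0.2 mm. A task with more than
   40% of its volumes censored flags the fit for exclusion. Residuals are
   kept for connectivity estimation so evoked co-activation cannot
   masquerade as connectivity.
2. **Low-dimensional decomposition and task hubs.** The voxel-by-task
   matrix is grand z-scored and decomposed by PCA into a voxel-by-component
   weight matrix `W` and a component-by-task loading matrix. The task-hub
   metric is

   `CompW(v) = Σ_i |W_vi|` over the top components.

3. **Connectivity and network hubs.** Voxel-to-ROI functional
   connectivity is estimated by principal-component regression (PCR) on
   residual series. After density thresholding, the participation
   coefficient

   `PC(v) = 1 − Σ_s (K_vs / K_v)²`

   (with `K_vs` the voxel's weight into network `s`) is averaged over
   densities 0.01–0.15.
4. **Activity-flow mapping.** Cortical task patterns are predicted as
   `A_ctx = B_t · FC`, evaluated by split-half cross-validation (Pearson
   r across ROIs per task), compared against shuffled-voxel, uniform, and
   task-average null models, and normalized by the noise ceiling
   `Reliability(modeled) × Reliability(observed)` from split-half
   reliabilities.
5. **Virtual lesions.** Voxels ranked by CompW are zeroed in sliding
   windows of 20% (starts 0–80%, step 1%); the percentage reduction in
   prediction accuracy is regressed on window rank, mapped back to
   voxels, and compared between lesion masks that overlap hub vs non-hub
   territory (two-sample KS test). A patient z-score table is classified
   into multi-domain (MM, > 2 impaired domains at z < −1.645) vs
   single/no-domain (SM) impairment profiles.

The synthetic generator plants all of this structure jointly: hub voxels
load on every latent component *and* connect to every network, so task-hub
and network-hub metrics must agree on the planted classes, and lesioning
top-ranked windows must hurt prediction most.

## Worked example

```r
library(thalamoflow)
res <- run_pipeline(default_run_config(seed = 1), out_dir = "results/pipeline")
```

The run takes a few seconds and prints its tables under
`results/pipeline/`. The numbered drivers in `analysis/` walk the same
run stage by stage; with seed 1 they report:

```
top-3 components explain 99.8% of variance (planted k = 3)
CompW: hub mean 1.020 vs non-hub mean 0.677
main model: accuracy 0.961, noise ceiling mean 0.911, normalized 1.055
null_shuffle: accuracy 0.322 (normalized 0.353)
null_uniform: accuracy 0.074 (normalized 0.084)
null_average: accuracy 0.281 (normalized 0.309)
reduction ~ rank: b = -0.066 (SE 0.005, t = -12.76, p = 7.1e-21)
MM vs SM lesion sites: KS D = 0.80, p = 0.0021
patient classification: 12 MM / 8 SM
```

Reading these: the evoked matrix is rank-3 by construction, so the
variance curve saturates at 3 components; planted hubs carry visibly more
CompW weight; the activity-flow model predicts held-out cortical patterns
far better than any null; lesioning strong hubs reduces prediction
accuracy steeply (negative slope of reduction on rank); and the
impairment-grouping rule reproduces the planted 12/8 split.

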