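# shared in-code fixtures; everything is generated at test time

fixture_gt <- function(seed = 1L, n_tasks = 20L, n_voxels = 100L) {
  generate_ground_truth(n_voxels, 40L, 7L, 3L, n_tasks, 0.2, seed = seed)
}

# split-half flow input built directly from planted betas and fc_true
fixture_flow_halves <- function(gt, noise_sd, seed = gt$seed) {
  b <- generate_betas(gt, noise_sd = noise_sd, seed = seed)
  list(
    half1 = list(betas_source = b$half1$thalamic, fc = gt$fc_true,
                 betas_cortex = b$half1$cortical),
    half2 = list(betas_source = b$half2$thalamic, fc = gt$fc_true,
                 betas_cortex = b$half2$cortical))
}

# one-run event table for design-matrix tests
fixture_events <- function(onsets, durations, types, run = 1L) {
  data.frame(onset = onsets, duration = durations, trial_type = types,
             run = rep(run, length.out = length(onsets)),
             stringsAsFactors = FALSE)
}

as_conn <- function(m) thalamoflow:::as_connectivity(m)

# independent SVD oracle for variance explained: tasks are observations,
# voxels features, per-voxel (column) centering
svd_variance_oracle <- function(values) {
  X <- t(values)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  d <- svd(Xc)$d
  d^2 / sum(d^2)
}
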