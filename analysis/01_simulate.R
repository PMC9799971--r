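#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with planted ground truth.
#
# A planted structure drives everything downstream: 3 orthonormal spatial
# components over 100 thalamic voxels, 20 of which are hubs that load on
# every component and connect to all 7 cortical networks; 80 non-hubs load
# on exactly one component and one network. Four runs of 200 volumes carry
# task-locked evoked responses for 10 tasks plus latent and observation
# noise. All tables are written under results/synthetic/.

suppressPackageStartupMessages(library(thalamoflow))

seed <- 1L
out <- "results/synthetic"

gt <- generate_ground_truth(n_voxels = 100, n_rois = 40, n_networks = 7,
                            k_components = 3, n_tasks = 10,
                            hub_fraction = 0.2, seed = seed, n_runs = 4)
ts <- generate_timeseries(gt, n_volumes_per_run = 200, seed = seed)
lesions <- generate_lesion_fixtures(gt, seed = seed)
write_synthetic_dataset(ts, gt, out, lesions = lesions)

message(sprintf("ground truth: %d hub voxels planted among %d",
                sum(gt$hub_mask), length(gt$hub_mask)))
message(sprintf("time series: %d runs x %d volumes, %d events, %.1f%% volumes censorable",
                gt$n_runs, ts$n_volumes_per_run, nrow(ts$events),
                100 * mean(ts$fd_trace > ts$fd_threshold)))
message(sprintf("tables written to %s", out))
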