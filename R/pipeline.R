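#' Default run configuration
#'
#' All pipeline constants in one declarative list: censoring threshold
#' 0.2 mm, 40% per-task censoring exclusion, top-10 CompW components,
#' density grid 0.01-0.15 in steps of 0.01, 95% PCR variance retention,
#' noise-ceiling floor 0.05, lesion windows of 20% stepping by 1% over
#' starts 0-80, and the three null models. Synthetic-data defaults are
#' sized so a full run is quick on one CPU while every stage still has
#' work to do: 100 voxels, 40 ROIs in 7 networks, 3 latent components, 10
#' tasks, 20% hubs, 4 runs of 200 volumes.
#'
#' @param seed integer seed driving every random draw in the run.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    data_dir = NULL,               # non-NULL: read tables from disk
    split_rule = "odd_even",
    # synthetic ground truth
    n_voxels = 100L, n_rois = 40L, n_networks = 7L, k_components = 3L,
    n_tasks = 10L, hub_fraction = 0.2, n_runs = 4L,
    n_volumes_per_run = 200L, tr_seconds = 1,
    noise_sd_beta = 0.5, noise_sd_ts = 1, evoked_amplitude = 1,
    fd_fraction = 0.05,
    # glm
    hrf_shape = 8.6, hrf_scale = 0.547, poly_order = 2L,
    fd_threshold = 0.2, censor_exclusion = 0.40,
    # decomposition / hubs
    top_k = 10L,
    densities = seq(0.01, 0.15, by = 0.01),
    # connectivity / flow
    variance_kept = 0.95, ceiling_floor = 0.05,
    nulls = c("shuffle", "uniform", "average"),
    # lesion
    lesion_window = 20, lesion_step = 1, lesion_span = c(0, 80)
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Unknown fields are an error (so typos do not silently fall back to
#' defaults); fields not present keep their default values. Overrides are
#' recorded in the run manifest with provenance.
#'
#' @param path YAML file.
#' @param seed seed used for fields the file does not set.
#' @return `run_config` list with an `overrides` attribute.
#' @export
load_run_config <- function(path, seed = 1L) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop_config(unknown[1], "is not a recognized configuration field")
  }
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  attr(cfg, "overrides") <- names(user)
  cfg
}

## split run indices into two halves; default rule interleaves runs
split_runs <- function(n_runs, rule = "odd_even") {
  switch(rule,
    odd_even = list(half1 = seq(1L, n_runs, by = 2L),
                    half2 = seq(2L, n_runs, by = 2L)),
    first_last = list(half1 = seq_len(n_runs %/% 2L),
                      half2 = (n_runs %/% 2L + 1L):n_runs),
    stop_config("split_rule", "must be 'odd_even' or 'first_last'")
  )
}

## concatenate the runs of one half and fit the task GLM for voxel and ROI
## series; returns betas (units x tasks, in canonical task order) and
## residuals
fit_half <- function(ts, runs, cfg) {
  run_lengths <- rep(ts$n_volumes_per_run, length(runs))
  ev <- ts$events[ts$events$run %in% runs, , drop = FALSE]
  ev$run <- match(ev$run, runs)
  vol_idx <- unlist(lapply(runs, function(r) {
    (r - 1L) * ts$n_volumes_per_run + seq_len(ts$n_volumes_per_run)
  }))
  nuis <- do.call(rbind, ts$motion[runs])
  design <- build_design(ev, ts$tr_seconds, run_lengths,
                         hrf_params = list(shape = cfg$hrf_shape,
                                           scale = cfg$hrf_scale),
                         poly_order = cfg$poly_order, nuisance = nuis)
  cens <- censor_mask(ts$fd_trace[vol_idx], cfg$fd_threshold)
  vox <- do.call(rbind, ts$voxel_ts[runs])
  roi <- do.call(rbind, ts$roi_ts[runs])
  fit_v <- fit_glm(vox, design, censor = cens$mask,
                   exclusion_threshold = cfg$censor_exclusion)
  fit_r <- fit_glm(roi, design, censor = cens$mask,
                   exclusion_threshold = cfg$censor_exclusion)
  reorder <- intersect(ts$task_names, fit_v$task_cols)
  list(
    thalamic = task_betas(fit_v)[, reorder, drop = FALSE],
    cortical = task_betas(fit_r)[, reorder, drop = FALSE],
    resid_vox = fit_v$residuals, resid_roi = fit_r$residuals,
    censored_fraction = cens$censored_fraction,
    excluded = fit_v$excluded || fit_r$excluded,
    design = design
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> GLM -> decomposition -> hub metrics ->
#' connectivity -> activity flow (with nulls and noise ceiling) -> virtual
#' lesions -> report, writing every stage's tables plus a JSON manifest
#' into `out_dir`. The whole run is a deterministic function of
#' `config$seed`.
#'
#' @param config a [default_run_config()] (or [load_run_config()]) list.
#' @param out_dir output directory; created if missing.
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("run")) {
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  gt <- run_stage("simulate", generate_ground_truth(
    cfg$n_voxels, cfg$n_rois, cfg$n_networks, cfg$k_components,
    cfg$n_tasks, cfg$hub_fraction, seed = cfg$seed,
    noise_sd_beta = cfg$noise_sd_beta, noise_sd_ts = cfg$noise_sd_ts,
    n_runs = cfg$n_runs, tr_seconds = cfg$tr_seconds))
  ts <- run_stage("simulate", generate_timeseries(
    gt, cfg$n_volumes_per_run, seed = cfg$seed,
    evoked_amplitude = cfg$evoked_amplitude, fd_fraction = cfg$fd_fraction,
    fd_threshold = cfg$fd_threshold))
  if (!is.null(cfg$data_dir)) {
    ## external-table mode: events and nuisance come from disk
    ev_path <- file.path(cfg$data_dir, "events.tsv")
    if (!file.exists(ev_path)) {
      stop(sprintf("stage `simulate` failed: events file not found: %s",
                   ev_path), call. = FALSE)
    }
    ts$events <- read_tsv(ev_path)
  }

  halves_idx <- split_runs(cfg$n_runs, cfg$split_rule)
  glm_halves <- run_stage("glm", lapply(halves_idx, function(runs) {
    fit_half(ts, runs, cfg)
  }))

  decomp <- run_stage("decompose", {
    group_betas <- (glm_halves$half1$thalamic + glm_halves$half2$thalamic) / 2
    pca_activity(standardize(group_betas))
  })
  hub_compw <- run_stage("hubs", compw(
    decomp, seq_len(min(cfg$top_k, decomp$n_components))))

  fc_halves <- run_stage("fc", lapply(glm_halves, function(h) {
    pcr_fc(h$resid_vox, h$resid_roi, variance_kept = cfg$variance_kept)
  }))
  fc_full <- run_stage("fc", pcr_fc(
    rbind(glm_halves$half1$resid_vox, glm_halves$half2$resid_vox),
    rbind(glm_halves$half1$resid_roi, glm_halves$half2$resid_roi),
    variance_kept = cfg$variance_kept))
  hub_pc <- run_stage("hubs", pc_across_densities(
    fc_full, gt$network_labels, densities = cfg$densities))
  projection <- run_stage("hubs", project_to_cortex(hub_compw, fc_full))

  flow_halves <- list(
    half1 = list(betas_source = glm_halves$half1$thalamic,
                 fc = fc_halves$half1,
                 betas_cortex = glm_halves$half1$cortical),
    half2 = list(betas_source = glm_halves$half2$thalamic,
                 fc = fc_halves$half2,
                 betas_cortex = glm_halves$half2$cortical))
  flow_main <- run_stage("flow", split_half_cv(
    flow_halves, ceiling_floor = cfg$ceiling_floor))
  flow_nulls <- run_stage("flow", {
    out <- list()
    if ("shuffle" %in% cfg$nulls) {
      out$null_shuffle <- null_shuffle(flow_halves, seed = cfg$seed,
                                       main = flow_main,
                                       ceiling_floor = cfg$ceiling_floor)
    }
    if ("uniform" %in% cfg$nulls) {
      out$null_uniform <- null_uniform(flow_halves, main = flow_main,
                                       ceiling_floor = cfg$ceiling_floor)
    }
    if ("average" %in% cfg$nulls) {
      out$null_average <- null_average(flow_halves, main = flow_main,
                                       ceiling_floor = cfg$ceiling_floor)
    }
    out
  })

  lesion <- run_stage("lesion", {
    ranks <- rank_voxels(hub_compw)
    sweep <- lesion_sweep(flow_halves, ranks, window = cfg$lesion_window,
                          step = cfg$lesion_step, span = cfg$lesion_span,
                          ceiling_floor = cfg$ceiling_floor)
    reg <- reduction_regression(sweep)
    fix <- generate_lesion_fixtures(gt, seed = cfg$seed)
    groups <- compare_lesion_groups(sweep$voxel_reduction_map,
                                    fix$mm_mask, fix$sm_mask)
    patients <- classify_patients(fix$patient_scores)
    list(ranks = ranks, sweep = sweep, regression = reg,
         fixtures = fix, group_comparison = groups, patients = patients)
  })

  atlas <- run_stage("report", atlas_summary(hub_compw, gt$voxel_nuclei))

  results <- list(config = cfg, ground_truth = gt, timeseries = ts,
                  glm = glm_halves, decomposition = decomp,
                  compw = hub_compw, pc = hub_pc, projection = projection,
                  fc = list(halves = fc_halves, full = fc_full),
                  flow = c(list(main = flow_main), flow_nulls),
                  lesion = lesion, atlas = atlas)
  run_stage("report", write_pipeline_outputs(results, out_dir))
  invisible(results)
}

## serialize stage outputs as TSV/JSON and a short human-readable report
write_pipeline_outputs <- function(res, out_dir) {
  cfg <- res$config
  d <- res$decomposition
  write_tsv(data.frame(k = seq_len(d$n_components),
                       variance_explained = d$variance_explained,
                       cumulative = cumsum(d$variance_explained)),
            file.path(out_dir, "variance_curve.tsv"))
  write_tsv(data.frame(voxel = seq_along(res$compw$values),
                       compw = res$compw$values,
                       pc = res$pc$values,
                       hub = as.integer(res$ground_truth$hub_mask)),
            file.path(out_dir, "hub_maps.tsv"))
  write_tsv(data.frame(roi = seq_along(res$projection),
                       cortical_compw = res$projection,
                       network = res$ground_truth$network_labels),
            file.path(out_dir, "cortical_projection.tsv"))
  acc <- do.call(rbind, lapply(res$flow, function(f) {
    data.frame(model = f$model_tag,
               task = names(f$accuracy_per_task) %||%
                 seq_along(f$accuracy_per_task),
               accuracy = f$accuracy_per_task,
               noise_ceiling = f$normalization_ceiling,
               normalized = f$normalized_per_task)
  }))
  write_tsv(acc, file.path(out_dir, "flow_accuracy.tsv"))
  write_tsv(data.frame(start = res$lesion$sweep$window_starts,
                       accuracy = res$lesion$sweep$accuracy_per_window,
                       reduction = res$lesion$sweep$reduction_per_window),
            file.path(out_dir, "lesion_curve.tsv"))
  write_tsv(data.frame(voxel = seq_along(res$lesion$sweep$voxel_reduction_map),
                       reduction = res$lesion$sweep$voxel_reduction_map),
            file.path(out_dir, "voxel_reduction.tsv"))
  write_tsv(res$atlas, file.path(out_dir, "atlas_summary.tsv"))
  write_tsv(res$lesion$patients, file.path(out_dir, "patient_classification.tsv"))

  summary <- list(
    accuracy = res$flow$main$accuracy,
    normalized_accuracy = res$flow$main$normalized_accuracy,
    null_accuracy = lapply(res$flow[names(res$flow) != "main"],
                           function(f) f$accuracy),
    lesion_regression = res$lesion$regression,
    lesion_group_comparison = res$lesion$group_comparison,
    n_mm_patients = sum(res$lesion$patients$group == "MM"),
    cumvar_top3 = cumulative_variance(d, min(3L, d$n_components))
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("thalamoflow")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    split_rule = cfg$split_rule,
    overrides = attr(cfg, "overrides") %||% character(),
    config = cfg[setdiff(names(cfg), "densities")],
    density_grid = range(cfg$densities)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- c(
    "# Pipeline report",
    "",
    sprintf("Seed %d; %d voxels, %d ROIs, %d tasks, %d runs.",
            cfg$seed, cfg$n_voxels, cfg$n_rois, cfg$n_tasks, cfg$n_runs),
    "",
    sprintf("Top-3 components explain %.1f%% of evoked-activity variance.",
            100 * summary$cumvar_top3),
    sprintf("Activity-flow accuracy %.3f (normalized %.3f).",
            summary$accuracy, summary$normalized_accuracy),
    sprintf("Null accuracies: %s.",
            paste(sprintf("%s %.3f", names(summary$null_accuracy),
                          unlist(summary$null_accuracy)), collapse = ", ")),
    sprintf("Lesion regression slope %.3f (p = %.3g); KS D = %.3f (p = %.3g).",
            summary$lesion_regression$b, summary$lesion_regression$p,
            summary$lesion_group_comparison$D,
            summary$lesion_group_comparison$p))
  writeLines(report, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Per-label summary of a hub map
#'
#' Mean and SEM of the hub metric within each atlas label. With a single
#' map the SEM is across voxels; with a stacked voxels x subjects matrix
#' the label mean is computed per subject and the SEM is across subjects.
#' Labels covering zero voxels are omitted with a warning.
#'
#' @param hub `hub_map`, numeric vector, or voxels x subjects matrix.
#' @param labels label per voxel (vector or factor).
#' @return data frame: `label`, `mean`, `sem`, `n_voxels`.
#' @export
atlas_summary <- function(hub, labels) {
  vals <- if (inherits(hub, "hub_map")) hub$values else hub
  labels <- as.character(labels)
  if (is.matrix(vals)) {
    if (nrow(vals) != length(labels)) {
      stop("label vector must match voxel count", call. = FALSE)
    }
    labs <- unique(labels)
    out <- do.call(rbind, lapply(labs, function(l) {
      m <- colMeans(vals[labels == l, , drop = FALSE], na.rm = TRUE)
      data.frame(label = l, mean = mean(m),
                 sem = sd(m) / sqrt(length(m)), n_voxels = sum(labels == l))
    }))
    return(out)
  }
  if (length(vals) != length(labels)) {
    stop("label vector must match voxel count", call. = FALSE)
  }
  labs <- unique(labels)
  empty <- labs[!labs %in% labels[is.finite(vals)]]
  if (length(empty)) {
    warning(sprintf("labels with no defined voxels omitted: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  out <- do.call(rbind, lapply(setdiff(labs, empty), function(l) {
    v <- vals[labels == l & is.finite(vals)]
    data.frame(label = l, mean = mean(v),
               sem = sd(v) / sqrt(length(v)), n_voxels = length(v))
  }))
  out
}
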