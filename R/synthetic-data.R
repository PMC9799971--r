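#' Generate a planted ground truth for the thalamocortical simulations
#'
#' Constructs the latent structure that all synthetic datasets share: a set of
#' `k_components` mutually orthonormal spatial component maps over voxels, a
#' component-by-task loading matrix, a voxel-to-ROI connectivity matrix
#' `fc_true`, a network assignment for every target ROI, and a planted set of
#' "hub" voxels. Hub voxels load on every spatial component and connect to all
#' cortical networks; non-hub voxels load on exactly one component and connect
#' to exactly one network. Hubs are therefore simultaneously task hubs (high
#' summed absolute component weight, CompW) and network hubs (high
#' participation coefficient), which makes the spatial correspondence between
#' the two metrics a testable recovery target rather than an empirical claim.
#'
#' The component maps are built to be orthonormal *by construction*: an
#' orthonormal hub block (QR of a random Gaussian matrix, row-norm balanced by
#' Givens rotations) is combined with disjoint-support non-hub blocks. A
#' post-hoc Gram-Schmidt pass would smear weight onto non-hub voxels and break
#' the single-component property, so none is applied. The hub block is scaled
#' so that every hub voxel's component-weight row norm strictly dominates
#' `sqrt(k)` times the largest non-hub weight; since the PCA weight matrix of
#' a noiseless beta matrix is an orthogonal rotation of the planted maps, this
#' guarantees that CompW over the top `k` components separates hubs from
#' non-hubs perfectly at zero noise.
#'
#' @param n_voxels number of source voxels (>= 2).
#' @param n_rois number of target ROIs (>= 2, and >= `n_networks`).
#' @param n_networks number of cortical networks the ROIs are assigned to
#'   (>= 2). The canonical analysis uses 7.
#' @param k_components number of latent spatial components (>= 2).
#' @param n_tasks number of tasks (>= 2).
#' @param hub_fraction fraction of voxels planted as hubs, in (0, 0.5).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @param noise_sd_beta default beta-noise SD carried in the object.
#' @param noise_sd_ts default time-series noise SD carried in the object.
#' @param n_runs number of runs the time-series generator will produce.
#' @param tr_seconds repetition time in seconds.
#'
#' @return An object of class `ground_truth`: a list with `component_maps`
#'   (voxels x k, orthonormal columns), `task_loadings` (k x tasks),
#'   `fc_true` (voxels x ROIs, nonnegative), `network_labels` (length
#'   `n_rois`, integers 1..`n_networks`), `hub_mask` (logical per voxel),
#'   `voxel_networks`, `voxel_components`, `voxel_nuclei` (synthetic
#'   "nucleus" labels with hubs concentrated in the first label), the noise
#'   SDs, `n_runs`, `tr_seconds` and `seed`.
#' @export
generate_ground_truth <- function(n_voxels, n_rois, n_networks = 7L,
                                  k_components = 3L, n_tasks = 20L,
                                  hub_fraction = 0.2, seed = 1L,
                                  noise_sd_beta = 0.5, noise_sd_ts = 1,
                                  n_runs = 2L, tr_seconds = 1) {
  for (f in c("n_voxels", "n_rois", "n_networks", "k_components", "n_tasks")) {
    v <- get(f)
    assert_scalar_number(v, f)
    if (v < 2) stop_config(f, "must be >= 2")
  }
  assert_scalar_number(hub_fraction, "hub_fraction")
  if (hub_fraction <= 0 || hub_fraction >= 0.5) {
    stop_config("hub_fraction", "must lie strictly between 0 and 0.5")
  }
  if (n_rois < n_networks) stop_config("n_rois", "must be >= n_networks")
  n_hub <- round(hub_fraction * n_voxels)
  if (n_hub < k_components) {
    stop_config("hub_fraction", "too few hub voxels to span the components")
  }
  if ((n_voxels - n_hub) < k_components) {
    stop_config("k_components", "more components than non-hub voxels")
  }

  with_seed(seed, {
    hub_idx <- sort(sample.int(n_voxels, n_hub))
    hub_mask <- logical(n_voxels)
    hub_mask[hub_idx] <- TRUE
    nonhub_idx <- which(!hub_mask)
    n_non <- length(nonhub_idx)

    comp_assign <- rep_len(seq_len(k_components), n_non)
    net_assign <- rep_len(seq_len(n_networks), n_non)

    ## share of each component's unit energy carried by the hub block; chosen
    ## so hub row norms dominate sqrt(k) * max non-hub weight with margin
    ratio <- 2 * 1.5 * hub_fraction * k_components / (1 - hub_fraction)
    alpha2 <- min(0.95, max(0.5, ratio / (1 + ratio)))

    C <- NULL
    for (attempt in seq_len(100L)) {
      Q <- qr.Q(qr(matrix(rnorm(n_hub * k_components), n_hub, k_components)))
      Q <- balance_row_norms(Q)
      hub_block <- sqrt(alpha2) * Q
      nonhub_vals <- numeric(n_non)
      for (c_id in seq_len(k_components)) {
        rows <- which(comp_assign == c_id)
        ## signed weights: evoked amplitudes are deviations in either
        ## direction, so the planted maps have near-zero spatial mean
        u <- runif(length(rows), 0.8, 1.2) *
          sample(c(-1, 1), length(rows), replace = TRUE)
        nonhub_vals[rows] <- u / sqrt(sum(u^2)) * sqrt(1 - alpha2)
      }
      min_hub <- min(sqrt(rowSums(hub_block^2)))
      if (min_hub > sqrt(k_components) * max(abs(nonhub_vals)) &&
          min(abs(hub_block)) > 1e-4) {
        C <- matrix(0, n_voxels, k_components)
        C[hub_idx, ] <- hub_block
        C[cbind(nonhub_idx, comp_assign)] <- nonhub_vals
        break
      }
    }
    if (is.null(C)) {
      stop("could not construct separable component maps for this geometry",
           call. = FALSE)
    }

    ## distinct decreasing singular values so PCA recovers components uniquely
    s <- seq(2, 1, length.out = k_components) * sqrt(n_voxels)
    V <- qr.Q(qr(matrix(rnorm(n_tasks * k_components), n_tasks, k_components)))
    L <- diag(s, k_components) %*% t(V)
    ## deterministic sign: largest-|weight| entry of each map positive
    for (c_id in seq_len(k_components)) {
      i <- which.max(abs(C[, c_id]))
      if (C[i, c_id] < 0) {
        C[, c_id] <- -C[, c_id]
        L[c_id, ] <- -L[c_id, ]
      }
    }

    network_labels <- rep_len(seq_len(n_networks), n_rois)
    fc <- matrix(0, n_voxels, n_rois)
    fc[hub_idx, ] <- matrix(runif(n_hub * n_rois, 1, 2), n_hub, n_rois)
    for (i in seq_len(n_non)) {
      cols <- which(network_labels == net_assign[i])
      fc[nonhub_idx[i], cols] <- runif(length(cols), 0.5, 1.5)
    }

    voxel_networks <- integer(n_voxels)
    voxel_networks[nonhub_idx] <- net_assign
    voxel_networks[hub_idx] <- 0L # hubs span all networks
    voxel_components <- integer(n_voxels)
    voxel_components[nonhub_idx] <- comp_assign
    voxel_components[hub_idx] <- 0L

    ## synthetic nucleus labels: hubs concentrated in the first "nucleus"
    nuclei <- c("AN", "MD", "VL", "VP", "PuM")
    voxel_nuclei <- character(n_voxels)
    voxel_nuclei[hub_idx] <- nuclei[1L]
    voxel_nuclei[nonhub_idx] <- rep_len(nuclei[-1L], n_non)

    structure(list(
      component_maps = C, task_loadings = L, fc_true = fc,
      network_labels = network_labels, hub_mask = hub_mask,
      voxel_networks = voxel_networks, voxel_components = voxel_components,
      voxel_nuclei = voxel_nuclei,
      noise_sd_beta = noise_sd_beta, noise_sd_ts = noise_sd_ts,
      n_runs = as.integer(n_runs), tr_seconds = tr_seconds,
      seed = as.integer(seed)
    ), class = "ground_truth")
  })
}

## equalize row norms of an orthonormal-column matrix with left Givens
## rotations (preserves column orthonormality)
balance_row_norms <- function(Q, n_sweeps = 6L) {
  n <- nrow(Q)
  for (sweep in seq_len(n_sweeps * n)) {
    rn <- rowSums(Q^2)
    i <- which.max(rn)
    j <- which.min(rn)
    if (rn[i] - rn[j] < 1e-12) break
    target <- (rn[i] + rn[j]) / 2
    u <- Q[i, ]; v <- Q[j, ]
    f <- function(theta) {
      sum((cos(theta) * u + sin(theta) * v)^2) - target
    }
    ## f(0) = rn[i] >= target, f(pi/2) = rn[j] <= target
    theta <- stats::uniroot(f, c(0, pi / 2), tol = 1e-14)$root
    Q[i, ] <- cos(theta) * u + sin(theta) * v
    Q[j, ] <- -sin(theta) * u + cos(theta) * v
  }
  Q
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d voxels (%d hubs), %d ROIs in %d networks, k = %d, %d tasks\n",
    nrow(x$component_maps), sum(x$hub_mask), ncol(x$fc_true),
    max(x$network_labels), ncol(x$component_maps), ncol(x$task_loadings)))
  invisible(x)
}

#' Generate split-half voxel and ROI beta matrices from a ground truth
#'
#' Each half's thalamic beta matrix is `component_maps %*% task_loadings`
#' plus iid Gaussian noise; the cortical beta matrix is
#' `t(fc_true) %*% thalamic_betas` plus iid Gaussian noise. The two halves
#' use independent noise draws of the same ground truth, which is exactly
#' the structure split-half reliability and the noise ceiling assume.
#'
#' @param gt a [generate_ground_truth()] object.
#' @param noise_sd nonnegative noise SD (applied to both levels).
#' @param seed integer seed.
#' @return list with elements `half1` and `half2`, each a list holding
#'   `thalamic` (voxels x tasks) and `cortical` (ROIs x tasks).
#' @export
generate_betas <- function(gt, noise_sd = gt$noise_sd_beta, seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"))
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_config("noise_sd", "must be nonnegative")
  signal <- gt$component_maps %*% gt$task_loadings
  nv <- nrow(signal); nt <- ncol(signal); nr <- ncol(gt$fc_true)
  with_seed(derive_seed(seed, 11L), {
    halves <- lapply(1:2, function(h) {
      thal <- signal + matrix(rnorm(nv * nt, sd = noise_sd), nv, nt)
      ctx <- t(gt$fc_true) %*% thal +
        matrix(rnorm(nr * nt, sd = noise_sd), nr, nt)
      dimnames(thal) <- list(NULL, paste0("task", seq_len(nt)))
      dimnames(ctx) <- list(NULL, paste0("task", seq_len(nt)))
      list(thalamic = thal, cortical = ctx)
    })
    names(halves) <- c("half1", "half2")
    halves
  })
}

#' Generate synthetic time series, events and nuisance traces
#'
#' Produces per-run voxel and ROI time series consistent with the planted
#' connectivity: a low-dimensional latent series is mapped through the
#' component maps to voxels, task-locked evoked responses (the planted beta
#' pattern times an HRF-convolved boxcar) are added, ROI series are the
#' `fc_true`-weighted voxel signal, and iid Gaussian noise is added to both.
#' A framewise-displacement trace with a configurable fraction of
#' suprathreshold volumes and a motion random walk are generated for
#' censoring and nuisance regression.
#'
#' @param gt a [generate_ground_truth()] object with `n_runs >= 2`.
#' @param n_volumes_per_run volumes per run (>= 50 so run-wise drift
#'   polynomials are estimable).
#' @param seed integer seed.
#' @param evoked_amplitude scale of the task-locked response; at 1 the GLM
#'   recovers the planted beta matrix, at 0 the series carry no task signal.
#' @param fd_fraction fraction of volumes planted above `fd_threshold`.
#' @param fd_threshold framewise-displacement censoring threshold in mm.
#' @param noise_sd observation noise SD (default from `gt`).
#' @return list of class `synthetic_timeseries`: `voxel_ts`, `roi_ts` (lists
#'   of time x unit matrices, one per run), `events` (onset, duration,
#'   trial_type, run; onsets in seconds), `fd_trace`, `motion` (per run),
#'   `task_names`, plus the generating parameters.
#' @export
generate_timeseries <- function(gt, n_volumes_per_run = 200L, seed = gt$seed,
                                evoked_amplitude = 1, fd_fraction = 0.05,
                                fd_threshold = 0.2,
                                noise_sd = gt$noise_sd_ts) {
  stopifnot(inherits(gt, "ground_truth"))
  if (gt$n_runs < 2L) stop_config("n_runs", "must be >= 2 for split-half use")
  if (n_volumes_per_run < 50L) {
    stop_config("n_volumes_per_run",
                "must be >= 50 to fit run-wise drift polynomials")
  }
  nv <- nrow(gt$component_maps)
  nroi <- ncol(gt$fc_true)
  k <- ncol(gt$component_maps)
  nt <- ncol(gt$task_loadings)
  tr <- gt$tr_seconds
  T_run <- as.integer(n_volumes_per_run)
  signal_betas <- gt$component_maps %*% gt$task_loadings

  with_seed(derive_seed(seed, 23L), {
    events_list <- list()
    voxel_ts <- roi_ts <- motion <- vector("list", gt$n_runs)
    block_len <- 10 * tr
    gap <- 5 * tr
    task_cursor <- 0L
    for (run in seq_len(gt$n_runs)) {
      ## block design cycling through tasks; the cycle is carried across
      ## runs so long task lists are still covered over the session
      onsets <- seq(10 * tr, (T_run - 15) * tr, by = block_len + gap)
      ids <- ((task_cursor + seq_along(onsets) - 1L) %% nt) + 1L
      task_cursor <- (task_cursor + length(onsets)) %% nt
      tasks <- paste0("task", ids)
      ev <- data.frame(onset = onsets, duration = block_len,
                       trial_type = tasks, run = run,
                       stringsAsFactors = FALSE)
      events_list[[run]] <- ev

      X_task <- task_regressors(ev, tr, T_run)$convolved # T x tasks present
      evoked_vox <- matrix(0, nv, T_run)
      for (j in seq_len(ncol(X_task))) {
        tk <- match(colnames(X_task)[j], paste0("task", seq_len(nt)))
        evoked_vox <- evoked_vox + evoked_amplitude *
          outer(signal_betas[, tk], X_task[, j])
      }
      latent <- matrix(rnorm(k * T_run), k, T_run)
      clean_vox <- gt$component_maps %*% latent + evoked_vox
      voxel_ts[[run]] <- t(clean_vox +
        matrix(rnorm(nv * T_run, sd = noise_sd), nv, T_run))
      roi_clean <- t(gt$fc_true) %*% clean_vox
      roi_ts[[run]] <- t(roi_clean +
        matrix(rnorm(nroi * T_run, sd = noise_sd), nroi, T_run))
      motion[[run]] <- apply(matrix(rnorm(T_run * 6, sd = 0.02), T_run, 6),
                             2, cumsum)
      colnames(motion[[run]]) <- paste0("motion_", 1:6)
    }
    total <- T_run * gt$n_runs
    fd <- runif(total, 0, 0.15)
    n_flag <- round(fd_fraction * total)
    if (n_flag > 0) {
      flag <- sample.int(total, n_flag)
      fd[flag] <- runif(n_flag, fd_threshold + 0.05, 0.5)
    }
    structure(list(
      voxel_ts = voxel_ts, roi_ts = roi_ts,
      events = do.call(rbind, events_list),
      fd_trace = fd, motion = motion,
      task_names = paste0("task", seq_len(nt)),
      n_volumes_per_run = T_run, tr_seconds = tr,
      evoked_amplitude = evoked_amplitude, fd_threshold = fd_threshold,
      seed = as.integer(seed)
    ), class = "synthetic_timeseries")
  })
}

#' Generate lesion masks and a synthetic patient score table
#'
#' Builds a "multi-domain impairment" (MM) lesion mask overlapping planted
#' hub voxels, a "single/no-domain" (SM) mask overlapping planted non-hub
#' voxels, and a synthetic patients-by-tests z-score table in which MM
#' patients have impairment (z below the threshold) in more than two
#' functional domains and SM patients in at most one. Ten standard
#' neuropsychological tests are mapped to seven functional domains
#' (executive, language, learning, memory, visuospatial, psychomotor,
#' construction).
#'
#' @param gt a [generate_ground_truth()] object with at least 10 hub and 10
#'   non-hub voxels.
#' @param seed integer seed.
#' @param n_patients total number of synthetic patients.
#' @param n_mm number of multi-domain-impairment patients among them.
#' @param threshold impairment threshold on the z scale.
#' @return list with `mm_mask`, `sm_mask` (logical per voxel, disjoint) and
#'   `patient_scores` (long table: patient_id, test, domain, z).
#' @export
generate_lesion_fixtures <- function(gt, seed = gt$seed, n_patients = 20L,
                                     n_mm = 12L, threshold = -1.645) {
  stopifnot(inherits(gt, "ground_truth"))
  if (sum(gt$hub_mask) < 10L || sum(!gt$hub_mask) < 10L) {
    stop_config("gt", "needs >= 10 hub and >= 10 non-hub voxels")
  }
  tests <- c(tmt_b = "executive", bnt = "language", cowa = "language",
             ravlt_t1 = "learning", ravlt_total = "learning",
             ravlt_recall = "memory", ravlt_recog = "memory",
             rey_delayed = "visuospatial", tmt_a = "psychomotor",
             rey_copy = "construction")
  domains <- unique(unname(tests))
  with_seed(derive_seed(seed, 37L), {
    hub_idx <- which(gt$hub_mask)
    non_idx <- which(!gt$hub_mask)
    mm_mask <- sm_mask <- logical(length(gt$hub_mask))
    mm_mask[sample(hub_idx, 10L)] <- TRUE
    sm_mask[sample(non_idx, 10L)] <- TRUE

    rows <- list()
    for (p in seq_len(n_patients)) {
      is_mm <- p <= n_mm
      n_imp <- if (is_mm) sample(3:5, 1L) else sample(0:1, 1L)
      impaired <- sample(domains, n_imp)
      z <- ifelse(tests %in% impaired,
                  runif(length(tests), -3.5, threshold - 0.4),
                  runif(length(tests), threshold + 0.4, 0.8))
      rows[[p]] <- data.frame(
        patient_id = sprintf("P%02d", p), test = names(tests),
        domain = unname(tests), z = round(z, 3),
        stringsAsFactors = FALSE)
    }
    list(mm_mask = mm_mask, sm_mask = sm_mask,
         patient_scores = do.call(rbind, rows))
  })
}

#' Write a synthetic dataset to plain-text files
#'
#' Serializes the event, nuisance, parcellation and patient-score tables as
#' tab-separated files in the layout downstream stages read.
#'
#' @param ts a [generate_timeseries()] object.
#' @param gt the matching ground truth.
#' @param dir output directory (created if needed).
#' @param lesions optional [generate_lesion_fixtures()] output.
#' @return invisibly, the directory.
#' @export
write_synthetic_dataset <- function(ts, gt, dir, lesions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(ts$events, file.path(dir, "events.tsv"))
  nuis <- data.frame(framewise_displacement = ts$fd_trace,
                     do.call(rbind, ts$motion))
  write_tsv(nuis, file.path(dir, "nuisance.tsv"))
  write_tsv(data.frame(label = seq_along(gt$network_labels),
                       network = gt$network_labels),
            file.path(dir, "parcellation.tsv"))
  write_tsv(data.frame(voxel = seq_along(gt$hub_mask),
                       nucleus = gt$voxel_nuclei,
                       hub = as.integer(gt$hub_mask)),
            file.path(dir, "voxel_labels.tsv"))
  for (run in seq_along(ts$voxel_ts)) {
    write_tsv(as.data.frame(ts$voxel_ts[[run]]),
              file.path(dir, sprintf("voxel_ts_run%d.tsv", run)))
    write_tsv(as.data.frame(ts$roi_ts[[run]]),
              file.path(dir, sprintf("roi_ts_run%d.tsv", run)))
  }
  if (!is.null(lesions)) {
    write_tsv(lesions$patient_scores, file.path(dir, "patient_scores.tsv"))
    write_tsv(data.frame(voxel = seq_along(lesions$mm_mask),
                         mm = as.integer(lesions$mm_mask),
                         sm = as.integer(lesions$sm_mask)),
              file.path(dir, "lesion_masks.tsv"))
  }
  invisible(dir)
}

#' Embed a flat voxel vector in a 3-D grid and write it as NIfTI
#'
#' The simulation uses a flat voxel index space; for NIfTI round-trips the
#' voxels are embedded row-major into the smallest cubic grid that holds
#' them, with unused cells set to NA-coded zeros and a companion mask.
#'
#' @param values numeric vector, one value per voxel.
#' @param path output `.nii` path (the mask is written alongside with suffix
#'   `_mask.nii`).
#' @return invisibly, the grid dimension used.
#' @export
write_map_nifti <- function(values, path) {
  n <- length(values)
  d <- ceiling(n^(1 / 3))
  arr <- array(0, dim = c(d, d, d))
  arr[seq_len(n)] <- values
  mask <- array(0L, dim = c(d, d, d))
  mask[seq_len(n)] <- 1L
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  RNifti::writeNifti(RNifti::asNifti(mask),
                     sub("\\.nii(\\.gz)?$", "_mask.nii\\1", path))
  invisible(d)
}

#' Read back a flat voxel map written by [write_map_nifti()]
#'
#' @param path `.nii` path.
#' @return numeric vector of the in-mask voxel values.
#' @export
read_map_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  mask <- as.array(RNifti::readNifti(sub("\\.nii(\\.gz)?$", "_mask.nii\\1",
                                         path)))
  as.numeric(arr[mask > 0])
}
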