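#' Gamma hemodynamic response function
#'
#' Peak-normalized gamma-variate kernel used to convolve stimulus boxcars.
#' The default shape/scale pair (8.6, 0.547 s) is a standard gamma-variate
#' choice peaking near 4-5 s.
#'
#' @param t time in seconds (vector).
#' @param shape,scale gamma parameters.
#' @return kernel values, max 1.
#' @export
gamma_hrf <- function(t, shape = 8.6, scale = 0.547) {
  h <- dgamma(t, shape = shape, scale = scale)
  h / max(h)
}

## stimulus boxcars and HRF-convolved regressors for one run's events,
## sampled at the repetition time; boxcars sum where identical-task events
## overlap
task_regressors <- function(events, tr, n_volumes,
                            hrf_params = list(shape = 8.6, scale = 0.547)) {
  tasks <- unique(events$trial_type)
  box <- matrix(0, n_volumes, length(tasks),
                dimnames = list(NULL, tasks))
  times <- (seq_len(n_volumes) - 1) * tr
  for (i in seq_len(nrow(events))) {
    on <- events$onset[i]
    off <- on + events$duration[i]
    if (on < 0 || on > (n_volumes - 1) * tr) {
      stop(sprintf("event %d (onset %.1f s) falls outside the scan", i, on),
           call. = FALSE)
    }
    idx <- which(times >= on & times < off)
    box[idx, events$trial_type[i]] <- box[idx, events$trial_type[i]] + 1
  }
  if (any(box > 1)) {
    warning("overlapping identical-task events within a TR; amplitudes summed",
            call. = FALSE)
  }
  kern <- gamma_hrf(seq(0, 32, by = tr), hrf_params$shape, hrf_params$scale)
  conv <- apply(box, 2, function(b) {
    convolve(b, rev(kern), type = "open")[seq_len(n_volumes)]
  })
  conv <- matrix(conv, n_volumes, length(tasks), dimnames = list(NULL, tasks))
  list(boxcar = box, convolved = conv)
}

#' Build a task GLM design matrix
#'
#' One HRF-convolved regressor per trial type (sub-conditions are distinct
#' trial types and collapsed later with [average_subconditions()]),
#' run-wise constant and polynomial drift columns that are zero outside
#' their run, and optional nuisance columns. Trial types matching
#' `instruction_label` get their own regressors, flagged so they are
#' modeled but excluded from downstream task beta tables. Convolution is
#' performed within runs so evoked responses never bleed across run
#' boundaries.
#'
#' @param events data frame with `onset` (s, relative to run start),
#'   `duration` (s), `trial_type`, `run`.
#' @param tr_seconds repetition time (> 0).
#' @param run_lengths integer vector of volumes per run.
#' @param hrf_params list with `shape` and `scale` for [gamma_hrf()].
#' @param poly_order polynomial drift order per run (0 = constant only).
#' @param nuisance optional numeric matrix (volumes x regressors), e.g.
#'   motion parameters and noise components.
#' @param instruction_label trial types equal to this value are modeled but
#'   flagged as instruction periods.
#' @return object of class `design_matrix`: `X` (volumes x regressors),
#'   `task_cols`, `instruction_cols`, `boxcars` (volumes x trial types),
#'   `run_index`, `tr_seconds`.
#' @export
build_design <- function(events, tr_seconds, run_lengths,
                         hrf_params = list(shape = 8.6, scale = 0.547),
                         poly_order = 2L, nuisance = NULL,
                         instruction_label = "instruction") {
  if (tr_seconds <= 0) stop_config("tr_seconds", "must be > 0")
  run_lengths <- as.integer(run_lengths)
  n_volumes <- sum(run_lengths)
  run_index <- rep(seq_along(run_lengths), run_lengths)
  if (min(run_lengths) <= poly_order + 1L) {
    stop_config("poly_order", "too few volumes per run to fit drift polynomials")
  }

  all_types <- if (nrow(events)) unique(events$trial_type) else character()
  Xtask <- matrix(0, n_volumes, length(all_types),
                  dimnames = list(NULL, all_types))
  boxcars <- Xtask
  for (run in seq_along(run_lengths)) {
    ev_run <- events[events$run == run, , drop = FALSE]
    if (!nrow(ev_run)) next
    offset <- sum(run_lengths[seq_len(run - 1L)])
    reg <- task_regressors(ev_run, tr_seconds, run_lengths[run], hrf_params)
    rows <- offset + seq_len(run_lengths[run])
    Xtask[rows, colnames(reg$convolved)] <- reg$convolved
    boxcars[rows, colnames(reg$boxcar)] <- reg$boxcar
  }

  drift <- matrix(0, n_volumes, (poly_order + 1L) * length(run_lengths))
  dn <- character(ncol(drift))
  col <- 0L
  for (run in seq_along(run_lengths)) {
    rows <- which(run_index == run)
    tt <- seq_along(rows)
    for (p in 0:poly_order) {
      col <- col + 1L
      drift[rows, col] <- if (p == 0) 1 else scale(tt^p, center = TRUE,
                                                   scale = FALSE)
      dn[col] <- sprintf("drift_run%d_p%d", run, p)
    }
  }
  colnames(drift) <- dn

  X <- cbind(Xtask, drift)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_volumes) {
      stop_config("nuisance", "row count must equal total volumes")
    }
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("nuisance_", seq_len(ncol(nuisance)))
    }
    X <- cbind(X, nuisance)
  }
  structure(list(
    X = X,
    task_cols = setdiff(all_types, instruction_label),
    instruction_cols = intersect(all_types, instruction_label),
    boxcars = boxcars, run_index = run_index, tr_seconds = tr_seconds
  ), class = "design_matrix")
}

#' Motion censoring mask from framewise displacement
#'
#' Volumes with framewise displacement above the threshold (default 0.2 mm)
#' are flagged for removal from the regression.
#'
#' @param fd_trace nonnegative FD per volume (mm).
#' @param threshold_mm censoring threshold.
#' @return list with `mask` (TRUE = censored) and `censored_fraction`.
#' @export
censor_mask <- function(fd_trace, threshold_mm = 0.2) {
  if (any(fd_trace < 0)) {
    stop("framewise displacement must be nonnegative", call. = FALSE)
  }
  mask <- fd_trace > threshold_mm
  list(mask = mask, censored_fraction = mean(mask))
}

#' Fit the task GLM by ordinary least squares with deletion censoring
#'
#' Censored volumes are removed from the regression (row deletion, not
#' spike regressors). Residuals at censored volumes are reported as NA,
#' never zero-filled. A unit (voxel/ROI) set is flagged `excluded` when any
#' task has more than `exclusion_threshold` of its active (stimulus-on)
#' volumes censored.
#'
#' @param timeseries volumes x units matrix.
#' @param design a [build_design()] object.
#' @param censor optional logical vector (TRUE = censored), e.g. from
#'   [censor_mask()].
#' @param exclusion_threshold per-task censored-fraction limit (default
#'   0.40).
#' @return object of class `glm_result`: `betas` (units x regressors),
#'   `residuals` (volumes x units, NA at censored rows),
#'   `censored_fraction`, `task_censored_fraction`, `excluded`,
#'   `task_cols`.
#' @export
fit_glm <- function(timeseries, design, censor = NULL,
                    exclusion_threshold = 0.40) {
  stopifnot(inherits(design, "design_matrix"))
  timeseries <- as.matrix(timeseries)
  X <- design$X
  if (nrow(timeseries) != nrow(X)) {
    stop("time series and design have different volume counts", call. = FALSE)
  }
  if (is.null(censor)) censor <- rep(FALSE, nrow(X))
  keep <- !censor
  if (sum(keep) <= ncol(X)) {
    stop("insufficient uncensored volumes to fit the model", call. = FALSE)
  }
  qrX <- qr(X[keep, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  coefs <- qr.coef(qrX, timeseries[keep, , drop = FALSE])
  fitted <- X[keep, , drop = FALSE] %*% coefs
  resid <- matrix(NA_real_, nrow(X), ncol(timeseries))
  resid[keep, ] <- timeseries[keep, , drop = FALSE] - fitted
  colnames(resid) <- colnames(timeseries)

  task_frac <- vapply(design$task_cols, function(tk) {
    active <- design$boxcars[, tk] > 0
    if (!any(active)) return(0)
    mean(censor[active])
  }, numeric(1))
  structure(list(
    betas = t(coefs),
    residuals = resid,
    censored_fraction = mean(censor),
    task_censored_fraction = task_frac,
    excluded = any(task_frac > exclusion_threshold),
    task_cols = design$task_cols
  ), class = "glm_result")
}

#' Extract the voxel-by-task beta matrix from a GLM fit
#'
#' Drops drift, nuisance and instruction-period regressors.
#'
#' @param fit a [fit_glm()] result.
#' @return units x tasks matrix.
#' @export
task_betas <- function(fit) {
  stopifnot(inherits(fit, "glm_result"))
  fit$betas[, fit$task_cols, drop = FALSE]
}

#' Average sub-condition betas into one estimate per task
#'
#' @param betas units x conditions matrix with column names.
#' @param condition_to_task named character vector mapping each condition
#'   (name) to its task (value).
#' @return units x tasks matrix, each task column the arithmetic mean of
#'   its condition columns.
#' @export
average_subconditions <- function(betas, condition_to_task) {
  conds <- colnames(betas)
  unmapped <- setdiff(conds, names(condition_to_task))
  if (length(unmapped)) {
    stop(sprintf("conditions with no task mapping: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  tasks <- unique(unname(condition_to_task[conds]))
  out <- vapply(tasks, function(tk) {
    cols <- conds[condition_to_task[conds] == tk]
    rowMeans(betas[, cols, drop = FALSE])
  }, numeric(nrow(betas)))
  out <- matrix(out, nrow(betas), length(tasks),
                dimnames = list(rownames(betas), tasks))
  out
}

#' Check that residual time series are free of task-locked signal
#'
#' Correlates each unit's residual series with each task regressor
#' (pairwise-complete over uncensored volumes) and summarizes. Residuals of
#' an OLS fit are exactly orthogonal to the design columns, so on the fit's
#' own design the correlations are numerically zero; on independent data
#' this diagnostic verifies the task regression removed evoked variance
#' before FC estimation.
#'
#' @param residuals volumes x units matrix (NA at censored volumes).
#' @param task_regressors volumes x regressors matrix.
#' @return list with `r` (units x regressors), `mean`, `sd` over defined
#'   entries, and `undefined_units` (zero-variance residual series,
#'   excluded from the summary).
#' @export
verify_task_removal <- function(residuals, task_regressors) {
  task_regressors <- as.matrix(task_regressors)
  if (nrow(residuals) != nrow(task_regressors)) {
    stop("residuals and regressors have different volume counts",
         call. = FALSE)
  }
  nunit <- ncol(residuals)
  r <- matrix(NA_real_, nunit, ncol(task_regressors))
  undefined <- logical(nunit)
  for (u in seq_len(nunit)) {
    y <- residuals[, u]
    ok <- is.finite(y)
    if (sd(y[ok]) == 0) {
      undefined[u] <- TRUE
      next
    }
    r[u, ] <- apply(task_regressors, 2, function(x) safe_cor(y, x))
  }
  vals <- r[!undefined, , drop = FALSE]
  list(r = r, mean = mean(vals, na.rm = TRUE), sd = sd(as.vector(vals),
                                                       na.rm = TRUE),
       undefined_units = which(undefined))
}
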