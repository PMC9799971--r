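#' Grand z-score a voxel-by-task beta matrix
#'
#' Standardizes the whole matrix at once: subtract the grand mean over all
#' elements and divide by the standard deviation over all elements. No
#' per-row or per-column scaling is applied at this stage; columns are
#' mean-centered later, inside the PCA.
#'
#' @param betas voxels x tasks numeric matrix (>= 2 voxels, >= 2 tasks).
#' @param task_names optional task names (default taken from columns).
#' @return object of class `activity_matrix` with `values` (standardized
#'   matrix), `task_names`, `n_voxels`.
#' @export
standardize <- function(betas, task_names = colnames(betas)) {
  betas <- as.matrix(betas)
  if (nrow(betas) < 2L || ncol(betas) < 2L) {
    stop("need at least 2 voxels and 2 tasks", call. = FALSE)
  }
  s <- sd(as.vector(betas))
  if (s == 0) stop("constant beta matrix: grand SD is zero", call. = FALSE)
  z <- (betas - mean(betas)) / s
  if (is.null(task_names)) task_names <- paste0("task", seq_len(ncol(z)))
  colnames(z) <- task_names
  structure(list(values = z, task_names = task_names,
                 n_voxels = nrow(z)), class = "activity_matrix")
}

#' Principal component analysis of multi-task evoked activity
#'
#' Decomposes the standardized voxel-by-task matrix into a voxel-by-component
#' weight matrix and a component-by-task loading matrix. Tasks are treated
#' as observations and voxels as features, so the PCA internally removes
#' each voxel's mean across tasks; at full rank `weights %*% loadings`
#' reconstructs that centered matrix exactly. Components are ordered by
#' variance explained (ties broken by original order, the behavior of the
#' underlying SVD) and sign-fixed so each component's largest-magnitude
#' voxel weight is positive: the PCA sign is arbitrary and CompW is
#' sign-invariant, but loading plots need a deterministic orientation.
#'
#' Works equally on a group-averaged matrix or on a single subject's
#' matrix, so per-subject replication curves can be produced by mapping
#' over subjects.
#'
#' @param activity an [standardize()] object (or a bare matrix, which is
#'   used as-is).
#' @param n_components number of components to retain (default: all, i.e.
#'   `min(voxels, tasks - 1)` after centering).
#' @return object of class `activity_decomposition`: `weights` (voxels x
#'   n), `loadings` (n x tasks), `variance_explained`, `center` (per-voxel
#'   means removed), `n_components`.
#' @export
pca_activity <- function(activity, n_components = NULL) {
  values <- if (inherits(activity, "activity_matrix")) activity$values else
    as.matrix(activity)
  X <- t(values) # tasks x voxels: tasks are observations
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  if (is.null(n_components)) n_components <- length(p$sdev)
  if (n_components > length(p$sdev)) {
    stop(sprintf("n_components (%d) exceeds available components (%d)",
                 n_components, length(p$sdev)), call. = FALSE)
  }
  W <- p$rotation # voxels x comps
  Lo <- t(p$x)    # comps x tasks (scores transposed)
  ve <- p$sdev^2 / sum(p$sdev^2)
  for (c_id in seq_len(ncol(W))) {
    i <- which.max(abs(W[, c_id]))
    if (W[i, c_id] < 0) {
      W[, c_id] <- -W[, c_id]
      Lo[c_id, ] <- -Lo[c_id, ]
    }
  }
  keep <- seq_len(n_components)
  structure(list(
    weights = W[, keep, drop = FALSE],
    loadings = Lo[keep, , drop = FALSE],
    variance_explained = ve[keep],
    center = p$center,
    n_components = n_components,
    task_names = colnames(values)
  ), class = "activity_decomposition")
}

#' @export
print.activity_decomposition <- function(x, ...) {
  cat(sprintf("<activity_decomposition> %d voxels, %d components; top-3 var %.1f%%\n",
              nrow(x$weights), x$n_components,
              100 * sum(head(x$variance_explained, 3))))
  invisible(x)
}

#' Cumulative variance explained by the first k components
#'
#' @param decomp an [pca_activity()] object.
#' @param k number of leading components (1 <= k <= n_components).
#' @return fraction of total variance in the first `k` components.
#' @export
cumulative_variance <- function(decomp, k) {
  stopifnot(inherits(decomp, "activity_decomposition"))
  if (k < 1L || k > decomp$n_components) {
    stop(sprintf("k must be in [1, %d]", decomp$n_components), call. = FALSE)
  }
  sum(decomp$variance_explained[seq_len(k)])
}

#' CompW task-hub metric
#'
#' Per-voxel sum of absolute component weights over a component range. The
#' main analysis uses the top 10 components (which carry most of the
#' evoked-activity variance); computing the same sum over components 11-20
#' serves as a control that the hub pattern is driven by the dominant
#' components.
#'
#' @param decomp an [pca_activity()] object.
#' @param component_ids integer vector of component indices.
#' @return object of class `hub_map` with `values` (>= 0, one per voxel),
#'   `metric` = "compw", `component_ids`.
#' @export
compw <- function(decomp, component_ids = seq_len(min(10L, decomp$n_components))) {
  stopifnot(inherits(decomp, "activity_decomposition"))
  if (!length(component_ids)) {
    stop("component_ids must be nonempty", call. = FALSE)
  }
  if (any(component_ids < 1L) || any(component_ids > decomp$n_components)) {
    stop("component_ids outside the decomposition range", call. = FALSE)
  }
  vals <- rowSums(abs(decomp$weights[, component_ids, drop = FALSE]))
  structure(list(values = vals, metric = "compw",
                 component_ids = component_ids), class = "hub_map")
}

#' @export
print.hub_map <- function(x, ...) {
  cat(sprintf("<hub_map> metric %s over %d voxels (%d missing)\n",
              x$metric, length(x$values), sum(!is.finite(x$values))))
  invisible(x)
}

#' Per-subject variance-explained curves
#'
#' Applies the standardization + PCA path to each subject's beta matrix and
#' returns the per-subject cumulative variance curve plus mean and SEM
#' across subjects, the subject-level replication of the group analysis.
#'
#' @param beta_list list of voxels x tasks matrices, one per subject.
#' @param max_k deepest component to report.
#' @return data frame: `k`, per-subject columns, `mean`, `sem`.
#' @export
subject_variance_curves <- function(beta_list, max_k = 10L) {
  curves <- vapply(beta_list, function(b) {
    d <- pca_activity(standardize(b))
    kk <- min(max_k, d$n_components)
    out <- rep(NA_real_, max_k)
    out[seq_len(kk)] <- cumsum(d$variance_explained)[seq_len(kk)]
    out
  }, numeric(max_k))
  curves <- matrix(curves, max_k, length(beta_list))
  colnames(curves) <- names(beta_list) %||%
    paste0("subject", seq_len(ncol(curves)))
  data.frame(k = seq_len(max_k), curves,
             mean = rowMeans(curves, na.rm = TRUE),
             sem = apply(curves, 1, function(v)
               sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))))
}
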