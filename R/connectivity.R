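#' Voxel-to-ROI functional connectivity by principal component regression
#'
#' For each target ROI, regresses its residual time series on the leading
#' principal components of the source voxel time series (the smallest
#' number of components retaining `variance_kept` of the source variance),
#' then back-projects the component coefficients to per-voxel regression
#' weights. Like partial correlation, PCR accounts for shared variance
#' among source voxels; unlike full OLS it remains stable when voxels are
#' nearly collinear. With `variance_kept = 1` on full-rank data the
#' back-projected weights equal the ordinary least-squares solution.
#'
#' Inputs should be task-regressed residuals so evoked co-activation does
#' not inflate connectivity.
#'
#' @param source_ts time x voxels matrix (>= 2 voxels).
#' @param target_ts time x ROIs matrix, same number of rows.
#' @param variance_kept fraction of source variance to retain, in (0, 1].
#' @return object of class `connectivity_matrix`: `weights` (voxels x
#'   ROIs), `n_components`, `variance_kept`, `density` (NA until
#'   thresholded).
#' @export
pcr_fc <- function(source_ts, target_ts, variance_kept = 0.95) {
  source_ts <- as.matrix(source_ts)
  target_ts <- as.matrix(target_ts)
  if (nrow(source_ts) != nrow(target_ts)) {
    stop("source and target series must have equal time length",
         call. = FALSE)
  }
  if (ncol(source_ts) < 2L) stop("need >= 2 source voxels", call. = FALSE)
  if (variance_kept <= 0 || variance_kept > 1) {
    stop_config("variance_kept", "must lie in (0, 1]")
  }
  zerov <- which(apply(target_ts, 2, sd) == 0)
  if (length(zerov)) {
    stop(sprintf("zero-variance target ROI series: %s",
                 paste(zerov, collapse = ", ")), call. = FALSE)
  }
  ## complete rows only (censored volumes enter as NA rows)
  ok <- stats::complete.cases(source_ts) & stats::complete.cases(target_ts)
  source_ts <- source_ts[ok, , drop = FALSE]
  target_ts <- target_ts[ok, , drop = FALSE]

  p <- prcomp(source_ts, center = TRUE, scale. = FALSE)
  pos <- p$sdev > max(p$sdev) * 1e-10
  cum <- cumsum(p$sdev[pos]^2) / sum(p$sdev[pos]^2)
  m <- which(cum >= variance_kept - 1e-12)[1]
  if (is.na(m)) {
    warning("requested variance exceeds available rank; using all components",
            call. = FALSE)
    m <- sum(pos)
  }
  S <- p$x[, seq_len(m), drop = FALSE] # T x m scores (centered)
  tc <- scale(target_ts, center = TRUE, scale = FALSE)
  ## scores have orthogonal columns, so coefficients come from a diagonal solve
  ssq <- colSums(S^2)
  coef <- crossprod(S, tc) / ssq # m x ROIs
  W <- p$rotation[, seq_len(m), drop = FALSE] %*% coef
  dimnames(W) <- list(colnames(source_ts), colnames(target_ts))
  structure(list(weights = W, n_components = m,
                 variance_kept = variance_kept, density = NA_real_),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d voxels x %d ROIs (PCR, %d comps%s)\n",
              nrow(x$weights), ncol(x$weights), x$n_components,
              if (is.finite(x$density)) sprintf(", density %.2f", x$density)
              else ""))
  invisible(x)
}

as_connectivity <- function(weights) {
  structure(list(weights = as.matrix(weights), n_components = NA_integer_,
                 variance_kept = NA_real_, density = NA_real_),
            class = "connectivity_matrix")
}

#' Density-threshold a connectivity matrix
#'
#' Retains the strongest `density` fraction of entries over the whole
#' matrix and zeroes the rest. The participation coefficient is defined
#' for nonnegative strengths, so by default negative weights are zeroed
#' before thresholding; `sign_policy = "absolute"` ranks and keeps
#' magnitudes instead. The retained count is `round(density * voxels *
#' ROIs)`; ties at the cutoff are broken by stable entry order.
#'
#' @param fc a `connectivity_matrix` (or bare matrix).
#' @param density fraction of entries to retain, in (0, 1].
#' @param sign_policy `"zero_negative"` (default) or `"absolute"`.
#' @return thresholded `connectivity_matrix` with `density` recorded.
#' @export
density_threshold <- function(fc, density,
                              sign_policy = c("zero_negative", "absolute")) {
  sign_policy <- match.arg(sign_policy)
  if (!inherits(fc, "connectivity_matrix")) fc <- as_connectivity(fc)
  if (density <= 0 || density > 1) stop_config("density", "must lie in (0, 1]")
  W <- fc$weights
  W <- switch(sign_policy,
              zero_negative = pmax(W, 0),
              absolute = abs(W))
  n_keep <- round(density * length(W))
  if (n_keep < 1L) {
    stop_config("density", "retains fewer than one entry")
  }
  if (n_keep < length(W)) {
    ord <- order(W, decreasing = TRUE) # stable: ties by entry order
    drop_idx <- ord[(n_keep + 1L):length(W)]
    W[drop_idx] <- 0
  }
  out <- fc
  out$weights <- W
  out$density <- density
  out
}

#' Participation coefficient over cortical networks
#'
#' For voxel i with total retained weight `K_i` to all ROIs and `K_is` to
#' ROIs of network s, `PC_i = 1 - sum_s (K_is / K_i)^2`. A voxel whose
#' weight is concentrated in one network scores 0; weight spread evenly
#' over N networks scores `1 - 1/N`. Voxels with no retained weight
#' (`K_i = 0`) are undefined and reported as NA.
#'
#' @param fc a thresholded, nonnegative `connectivity_matrix`.
#' @param network_labels integer/character network id per ROI (no NA).
#' @return `hub_map` with `values` in `[0, 1 - 1/N]` or NA.
#' @export
participation_coefficient <- function(fc, network_labels) {
  if (!inherits(fc, "connectivity_matrix")) fc <- as_connectivity(fc)
  W <- fc$weights
  if (length(network_labels) != ncol(W) || anyNA(network_labels)) {
    stop("every target ROI must carry a network label", call. = FALSE)
  }
  if (any(W < 0)) {
    stop("participation coefficient needs nonnegative weights; threshold first",
         call. = FALSE)
  }
  nets <- unique(network_labels)
  Ki <- rowSums(W)
  Kis <- vapply(nets, function(s) {
    rowSums(W[, network_labels == s, drop = FALSE])
  }, numeric(nrow(W)))
  Kis <- matrix(Kis, nrow(W), length(nets))
  pc <- 1 - rowSums((Kis / Ki)^2)
  pc[Ki == 0] <- NA_real_
  structure(list(values = pc, metric = "participation_coefficient",
                 density = fc$density, n_networks = length(nets)),
            class = "hub_map")
}

#' Participation coefficient averaged across density thresholds
#'
#' Computes the participation coefficient at each density in the grid
#' (default 0.01 to 0.15 in steps of 0.01) and averages per voxel,
#' ignoring densities at which the voxel is undefined. Voxels undefined at
#' every density come back as NA.
#'
#' @param fc an unthresholded `connectivity_matrix`.
#' @param network_labels network id per ROI.
#' @param densities density grid in (0, 1].
#' @param sign_policy passed to [density_threshold()].
#' @return `hub_map` with the density-averaged PC and `density_range`.
#' @export
pc_across_densities <- function(fc, network_labels,
                                densities = seq(0.01, 0.15, by = 0.01),
                                sign_policy = "zero_negative") {
  if (!inherits(fc, "connectivity_matrix")) fc <- as_connectivity(fc)
  if (!length(densities)) stop_config("densities", "must be nonempty")
  per <- vapply(densities, function(d) {
    participation_coefficient(
      density_threshold(fc, d, sign_policy = sign_policy),
      network_labels)$values
  }, numeric(nrow(fc$weights)))
  per <- matrix(per, nrow(fc$weights), length(densities))
  vals <- rowMeans(per, na.rm = TRUE)
  vals[!is.finite(vals)] <- NA_real_
  structure(list(values = vals, metric = "participation_coefficient",
                 density_range = range(densities),
                 n_networks = length(unique(network_labels))),
            class = "hub_map")
}

#' Project a voxel hub map onto cortex through the connectivity matrix
#'
#' ROI value = sum over voxels of `hub(v) * FC(v, roi)` — the dot product
#' between the voxel-wise hub metric and each ROI's connectivity column.
#'
#' @param hub a `hub_map` (or numeric vector per voxel).
#' @param fc a `connectivity_matrix` with matching voxel count.
#' @return named numeric vector over ROIs.
#' @export
project_to_cortex <- function(hub, fc) {
  vals <- if (inherits(hub, "hub_map")) hub$values else as.numeric(hub)
  if (!inherits(fc, "connectivity_matrix")) fc <- as_connectivity(fc)
  if (length(vals) != nrow(fc$weights)) {
    stop("hub map and connectivity matrix have different voxel counts",
         call. = FALSE)
  }
  drop(crossprod(fc$weights, vals))
}

#' Spatial correlation between two voxel maps, with group inference
#'
#' Pearson correlation across voxels (missing voxels pairwise-deleted),
#' computed per subject when lists are supplied. The group p-value is a
#' two-sided one-sample t-test of the Fisher-z transformed correlations
#' against zero.
#'
#' @param map_a,map_b numeric vectors, or lists of vectors (one per
#'   subject).
#' @return list with `r` (per subject), `mean`, `sd`, `p` (NA with a
#'   single subject).
#' @export
spatial_correlation <- function(map_a, map_b) {
  if (!is.list(map_a)) map_a <- list(map_a)
  if (!is.list(map_b)) map_b <- list(map_b)
  stopifnot(length(map_a) == length(map_b))
  r <- mapply(function(a, b) {
    a <- if (inherits(a, "hub_map")) a$values else a
    b <- if (inherits(b, "hub_map")) b$values else b
    if (length(a) < 3L) stop("need >= 3 voxels", call. = FALSE)
    safe_cor(a, b)
  }, map_a, map_b)
  ok <- is.finite(r)
  p <- if (sum(ok) >= 2L && sd(atanh(pmin(pmax(r[ok], -1 + 1e-12),
                                          1 - 1e-12))) > 0) {
    t.test(atanh(pmin(pmax(r[ok], -1 + 1e-12), 1 - 1e-12)))$p.value
  } else NA_real_
  list(r = r, mean = mean(r[ok]), sd = sd(r[ok]), p = p)
}
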