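#' Percentile-rank voxels by a hub metric
#'
#' Ranks voxels descending by the hub metric and returns percentile ranks
#' in `[0, 100)`: the strongest hub gets rank 0, so lesion windows that
#' start at percentile 0 remove the top hubs first. Ties are broken by
#' stable voxel index order.
#'
#' @param hub a `hub_map` or numeric vector with no missing values.
#' @return numeric vector of percentile ranks.
#' @export
rank_voxels <- function(hub) {
  vals <- if (inherits(hub, "hub_map")) hub$values else as.numeric(hub)
  if (anyNA(vals)) stop("hub map contains missing values", call. = FALSE)
  if (length(unique(vals)) == 1L) {
    stop("constant hub map: ranking undefined", call. = FALSE)
  }
  ord <- order(-vals, seq_along(vals)) # descending, ties by index
  ranks <- integer(length(vals))
  ranks[ord] <- seq_along(vals) - 1L
  100 * ranks / length(vals)
}

#' Virtual-lesion sweep over ranked voxel windows
#'
#' For each window start `s` (percentiles `span`, step `step`), sets the
#' source betas of voxels with percentile rank in `[s, s + window)` to
#' zero in both halves — connectivity untouched — and re-runs the full
#' split-half activity-flow evaluation. The reduction per window is
#' `100 * (acc0 - acc_lesioned) / acc0` relative to the unlesioned
#' accuracy `acc0`, and each voxel's reduction-map value is the mean
#' reduction over the windows that lesioned it.
#'
#' @param halves as in [split_half_cv()].
#' @param ranks percentile ranks from [rank_voxels()] (0 = strongest hub).
#' @param window window size in percentiles (default 20).
#' @param step window start step (default 1).
#' @param span window start range (default `c(0, 80)`).
#' @param ceiling_floor as in [split_half_cv()].
#' @return object of class `lesion_sweep`: `window_starts`,
#'   `accuracy_per_window`, `reduction_per_window`, `baseline_accuracy`,
#'   `voxel_reduction_map`, `windows_per_voxel`.
#' @export
lesion_sweep <- function(halves, ranks, window = 20, step = 1,
                         span = c(0, 80), ceiling_floor = 0.05) {
  nv <- nrow(as.matrix(halves$half1$betas_source))
  stopifnot(length(ranks) == nv)
  baseline <- split_half_cv(halves, model_tag = "unlesioned",
                            ceiling_floor = ceiling_floor)
  acc0 <- baseline$accuracy
  if (!is.finite(acc0) || acc0 <= 0) {
    stop("unlesioned accuracy must be positive for reduction percentages",
         call. = FALSE)
  }
  starts <- seq(span[1], span[2], by = step)
  acc <- red <- numeric(length(starts))
  vox_sum <- vox_n <- numeric(nv)
  for (i in seq_along(starts)) {
    s <- starts[i]
    lesioned_vox <- ranks >= s & ranks < s + window
    lesioned <- transform_halves(halves, function(b, h) {
      b <- as.matrix(b)
      b[lesioned_vox, ] <- 0
      b
    })
    res <- split_half_cv(lesioned, model_tag = sprintf("lesion_%g", s),
                         ceiling_floor = ceiling_floor)
    acc[i] <- res$accuracy
    red[i] <- 100 * (acc0 - res$accuracy) / acc0
    vox_sum[lesioned_vox] <- vox_sum[lesioned_vox] + red[i]
    vox_n[lesioned_vox] <- vox_n[lesioned_vox] + 1
  }
  vox_map <- ifelse(vox_n > 0, vox_sum / vox_n, NA_real_)
  structure(list(
    window_starts = starts, window = window, step = step,
    accuracy_per_window = acc, reduction_per_window = red,
    baseline_accuracy = acc0, baseline = baseline,
    voxel_reduction_map = vox_map, windows_per_voxel = vox_n
  ), class = "lesion_sweep")
}

#' @export
print.lesion_sweep <- function(x, ...) {
  cat(sprintf("<lesion_sweep> %d windows of %g%%; baseline accuracy %.3f; reduction %.1f%% (top) to %.1f%% (bottom)\n",
              length(x$window_starts), x$window, x$baseline_accuracy,
              x$reduction_per_window[1],
              x$reduction_per_window[length(x$window_starts)]))
  invisible(x)
}

#' Regression of prediction reduction on lesioned percentile rank
#'
#' Ordinary least-squares fit of reduction (%) on window start percentile.
#' A single sweep gives one observation per window; a list of sweeps (e.g.
#' one per subject) stacks subject x window observations.
#'
#' @param sweep a `lesion_sweep` or list of them.
#' @return list with `b` (slope), `se`, `t`, `p`, `n`.
#' @export
reduction_regression <- function(sweep) {
  if (inherits(sweep, "lesion_sweep")) sweep <- list(sweep)
  df <- do.call(rbind, lapply(sweep, function(s) {
    data.frame(start = s$window_starts, reduction = s$reduction_per_window)
  }))
  if (nrow(df) < 3L) stop("need >= 3 windows", call. = FALSE)
  if (sd(df$start) == 0) stop("degenerate window starts", call. = FALSE)
  fit <- stats::lm(reduction ~ start, data = df)
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 2L || !is.finite(sm["start", 2])) {
    ## constant reductions: slope 0 with undefined inference
    return(list(b = unname(stats::coef(fit)["start"]), se = NA_real_,
                t = NA_real_, p = NA_real_, n = nrow(df)))
  }
  list(b = sm["start", 1], se = sm["start", 2], t = sm["start", 3],
       p = sm["start", 4], n = nrow(df))
}

#' Classify patient impairment profiles from neuropsychological z-scores
#'
#' A functional domain counts as impaired when any of its constituent
#' tests has `z < threshold` (strict). Patients impaired in more than
#' `domain_cutoff` domains are classified MM (multi-domain impairment);
#' the rest SM (single/no-domain). Both inequalities are strict: a z-score
#' exactly at the threshold is not an impairment, and exactly
#' `domain_cutoff` impaired domains is still SM.
#'
#' @param scores long data frame: `patient_id`, `test`, `domain`, `z`.
#' @param threshold impairment threshold (default -1.645, the 95th
#'   percentile of the normative distribution).
#' @param domain_cutoff MM requires strictly more impaired domains than
#'   this (default 2).
#' @return data frame: `patient_id`, `n_impaired_domains`, `group`.
#' @export
classify_patients <- function(scores, threshold = -1.645,
                              domain_cutoff = 2L) {
  need <- c("patient_id", "test", "domain", "z")
  if (!all(need %in% names(scores))) {
    stop("scores must have columns patient_id, test, domain, z",
         call. = FALSE)
  }
  if (anyNA(scores$domain)) {
    stop("every test must be mapped to a functional domain", call. = FALSE)
  }
  ids <- unique(scores$patient_id)
  n_imp <- vapply(ids, function(p) {
    sub <- scores[scores$patient_id == p, ]
    imp_by_domain <- tapply(sub$z < threshold, sub$domain, any)
    sum(imp_by_domain)
  }, integer(1))
  data.frame(patient_id = ids, n_impaired_domains = n_imp,
             group = ifelse(n_imp > domain_cutoff, "MM", "SM"),
             stringsAsFactors = FALSE)
}

#' Compare virtual-lesion reductions under two lesion-site masks
#'
#' Two-sample Kolmogorov-Smirnov test of the per-voxel reduction values
#' under the MM-overlap mask against those under the SM-overlap mask.
#' The exact p-value is used when both samples have fewer than 25 voxels,
#' the asymptotic one otherwise.
#'
#' @param voxel_reduction_map per-voxel reduction values.
#' @param mm_mask,sm_mask disjoint, nonempty logical masks.
#' @return list with `D`, `p`, `n_mm`, `n_sm`.
#' @export
compare_lesion_groups <- function(voxel_reduction_map, mm_mask, sm_mask) {
  if (!any(mm_mask) || !any(sm_mask)) {
    stop("lesion masks must be nonempty", call. = FALSE)
  }
  if (any(mm_mask & sm_mask)) {
    stop("lesion masks must be disjoint", call. = FALSE)
  }
  x <- voxel_reduction_map[mm_mask]
  y <- voxel_reduction_map[sm_mask]
  exact <- length(x) < 25L && length(y) < 25L
  kt <- suppressWarnings(ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_mm = length(x), n_sm = length(y))
}
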