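#' Predict cortical activity patterns from source betas and connectivity
#'
#' Activity-flow prediction: the predicted activity of a target ROI for a
#' task is the connectivity-weighted sum of source voxel activity,
#' `predicted(roi, task) = sum_v betas(v, task) * fc(v, roi)`.
#'
#' @param betas_source voxels x tasks matrix.
#' @param fc `connectivity_matrix` (or voxels x ROIs matrix).
#' @return ROIs x tasks predicted matrix.
#' @export
predict_cortical <- function(betas_source, fc) {
  W <- if (inherits(fc, "connectivity_matrix")) fc$weights else as.matrix(fc)
  betas_source <- as.matrix(betas_source)
  if (nrow(betas_source) != nrow(W)) {
    stop("source betas and connectivity have different voxel counts",
         call. = FALSE)
  }
  crossprod(W, betas_source)
}

## per-task Pearson r across ROIs between predicted and observed patterns;
## zero-variance observed patterns are undefined (NA) with a warning
pattern_accuracy <- function(predicted, observed) {
  stopifnot(all(dim(predicted) == dim(observed)))
  r <- vapply(seq_len(ncol(observed)), function(j) {
    safe_cor(predicted[, j], observed[, j])
  }, numeric(1))
  if (anyNA(r)) {
    warning(sprintf("%d task(s) with undefined pattern correlation excluded",
                    sum(is.na(r))), call. = FALSE)
  }
  names(r) <- colnames(observed)
  r
}

#' Split-half cross-validated activity-flow evaluation
#'
#' Fold A predicts cortical patterns from half 1's source betas and
#' connectivity and evaluates them against half 2's *observed* cortical
#' betas; fold B is the mirror image. Pearson correlation is computed
#' across ROIs separately for each task, averaged across tasks, then
#' averaged across the two folds. Split-half reliabilities of the modeled
#' and observed patterns are computed per task across ROIs, their product
#' is the noise ceiling, and accuracy divided by the ceiling is the
#' normalized accuracy; tasks whose ceiling does not exceed
#' `ceiling_floor` are excluded from the normalized mean (the product of
#' two small reliabilities is numerically unstable and can flip sign).
#'
#' @param halves list with `half1` and `half2`, each holding
#'   `betas_source` (voxels x tasks), `fc` (connectivity), and
#'   `betas_cortex` (ROIs x tasks observed patterns).
#' @param model_tag label stored in the result.
#' @param ceiling_floor minimum usable noise ceiling (default 0.05).
#' @param ceiling override: per-task noise ceiling to normalize by (used
#'   for null models, which are normalized by the main model's ceiling).
#' @return object of class `flow_result`; see Details.
#' @export
split_half_cv <- function(halves, model_tag = "thalamocortical",
                          ceiling_floor = 0.05, ceiling = NULL) {
  h1 <- halves$half1; h2 <- halves$half2
  stopifnot(!is.null(h1), !is.null(h2))
  if (nrow(as.matrix(h1$betas_cortex)) < 3L) {
    stop("need >= 3 target ROIs", call. = FALSE)
  }
  pred1 <- predict_cortical(h1$betas_source, h1$fc)
  pred2 <- predict_cortical(h2$betas_source, h2$fc)
  rA <- pattern_accuracy(pred1, h2$betas_cortex)
  rB <- pattern_accuracy(pred2, h1$betas_cortex)
  acc_task <- colMeans(rbind(rA, rB), na.rm = FALSE)

  rel_mod <- split_half_reliability(pred1, pred2)
  rel_obs <- split_half_reliability(h1$betas_cortex, h2$betas_cortex)
  own_ceiling <- noise_ceiling(rel_mod, rel_obs)
  use_ceiling <- ceiling %||% own_ceiling
  norm <- normalize_accuracy(acc_task, use_ceiling, ceiling_floor)

  structure(list(
    model_tag = model_tag,
    predicted = list(half1 = pred1, half2 = pred2),
    fold_accuracy = rbind(foldA = rA, foldB = rB),
    accuracy_per_task = acc_task,
    accuracy = mean(acc_task, na.rm = TRUE),
    reliability_modeled = rel_mod,
    reliability_observed = rel_obs,
    noise_ceiling = own_ceiling,
    normalization_ceiling = use_ceiling,
    normalized_per_task = norm$per_task,
    normalized_accuracy = norm$mean,
    excluded_tasks = norm$excluded,
    ceiling_floor = ceiling_floor
  ), class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("<flow_result> %s: accuracy %.3f, normalized %.3f (%d tasks, %d excluded)\n",
              x$model_tag, x$accuracy, x$normalized_accuracy,
              length(x$accuracy_per_task), length(x$excluded_tasks)))
  invisible(x)
}

#' Split-half reliability of activity patterns
#'
#' Per task, the Pearson correlation across ROIs between the two halves'
#' patterns (modeled or observed). Zero-variance halves give NA.
#'
#' @param estimates_half1,estimates_half2 ROIs x tasks matrices.
#' @return per-task correlation vector.
#' @export
split_half_reliability <- function(estimates_half1, estimates_half2) {
  estimates_half1 <- as.matrix(estimates_half1)
  estimates_half2 <- as.matrix(estimates_half2)
  stopifnot(all(dim(estimates_half1) == dim(estimates_half2)))
  vapply(seq_len(ncol(estimates_half1)), function(j) {
    safe_cor(estimates_half1[, j], estimates_half2[, j])
  }, numeric(1))
}

#' Noise ceiling from split-half reliabilities
#'
#' The per-task ceiling is the product of the modeled-pattern and
#' observed-pattern split-half reliabilities.
#'
#' @param rel_modeled,rel_observed per-task reliabilities.
#' @return per-task noise ceiling.
#' @export
noise_ceiling <- function(rel_modeled, rel_observed) {
  stopifnot(length(rel_modeled) == length(rel_observed))
  rel_modeled * rel_observed
}

#' Normalize prediction accuracy by the noise ceiling
#'
#' @param accuracy_per_task per-task raw accuracy.
#' @param ceiling per-task noise ceiling.
#' @param floor tasks with ceiling <= floor are excluded from the mean.
#' @return list: `per_task` (NA where excluded), `mean`, `excluded`
#'   (indices).
#' @export
normalize_accuracy <- function(accuracy_per_task, ceiling, floor = 0.05) {
  stopifnot(length(accuracy_per_task) == length(ceiling))
  usable <- is.finite(ceiling) & ceiling > floor & is.finite(accuracy_per_task)
  if (!any(usable)) {
    stop("all tasks fall below the noise-ceiling floor", call. = FALSE)
  }
  per <- ifelse(usable, accuracy_per_task / ceiling, NA_real_)
  list(per_task = per, mean = mean(per[usable]),
       excluded = which(!usable))
}

## apply a transformation to the source betas of both halves
transform_halves <- function(halves, f) {
  for (h in c("half1", "half2")) {
    halves[[h]]$betas_source <- f(halves[[h]]$betas_source, h)
  }
  halves
}

#' Null models for the activity-flow evaluation
#'
#' Three nulls, each run through the identical split-half pipeline and
#' normalized by the *main* model's noise ceiling:
#' * `null_shuffle()` permutes the voxel order of the source betas (one
#'   fresh permutation per fold), destroying the spatial correspondence
#'   between activity and connectivity.
#' * `null_uniform()` sets every source beta to 1, so predictions reduce
#'   to the column sums of the connectivity matrix, identical for every
#'   task.
#' * `null_average()` replaces each voxel's betas by its mean across
#'   tasks, removing between-task differences.
#'
#' @param halves as in [split_half_cv()].
#' @param seed integer seed for the permutations.
#' @param main a `flow_result` from the main model; its ceiling is used for
#'   normalization (if NULL, each null uses its own ceiling).
#' @param ceiling_floor as in [split_half_cv()].
#' @param perm optional list with `half1`/`half2` voxel permutations,
#'   overriding the seed; the identity permutation reproduces the main
#'   model exactly.
#' @return a `flow_result` with the matching `model_tag`.
#' @export
null_shuffle <- function(halves, seed = 1L, main = NULL,
                         ceiling_floor = 0.05, perm = NULL) {
  if (is.null(perm)) {
    perm <- with_seed(derive_seed(seed, 101L), {
      nv <- nrow(as.matrix(halves$half1$betas_source))
      list(half1 = sample.int(nv), half2 = sample.int(nv))
    })
  }
  shuffled <- transform_halves(halves, function(b, h) {
    as.matrix(b)[perm[[h]], , drop = FALSE]
  })
  split_half_cv(shuffled, model_tag = "null_shuffle",
                ceiling_floor = ceiling_floor,
                ceiling = main$noise_ceiling)
}

#' @rdname null_shuffle
#' @export
null_uniform <- function(halves, main = NULL, ceiling_floor = 0.05) {
  unif <- transform_halves(halves, function(b, h) {
    b <- as.matrix(b)
    matrix(1, nrow(b), ncol(b), dimnames = dimnames(b))
  })
  ## uniform betas predict the same pattern for every task: modeled
  ## reliability is defined but the model carries no task information
  split_half_cv(unif, model_tag = "null_uniform",
                ceiling_floor = ceiling_floor,
                ceiling = main$noise_ceiling)
}

#' @rdname null_shuffle
#' @export
null_average <- function(halves, main = NULL, ceiling_floor = 0.05) {
  avg <- transform_halves(halves, function(b, h) {
    b <- as.matrix(b)
    matrix(rowMeans(b), nrow(b), ncol(b), dimnames = dimnames(b))
  })
  split_half_cv(avg, model_tag = "null_average",
                ceiling_floor = ceiling_floor,
                ceiling = main$noise_ceiling)
}

#' Activity-flow comparison models for alternative source regions
#'
#' Applies the identical split-half activity-flow procedure to each
#' candidate source region: per half, the source's connectivity to the
#' cortical targets is recomputed with [pcr_fc()] from residual series,
#' then [split_half_cv()] is run with the source's own noise ceiling.
#'
#' @param sources named list; each element holds `half1` and `half2`, each
#'   with `betas` (voxels x tasks) and `resid_ts` (time x voxels residual
#'   series). A source with fewer than 2 voxels is an error.
#' @param cortex list with `half1`/`half2`, each with `betas` (ROIs x
#'   tasks) and `resid_ts` (time x ROIs).
#' @param variance_kept passed to [pcr_fc()].
#' @param ceiling_floor passed to [split_half_cv()].
#' @return named list of `flow_result`s, tagged `comparison:<name>`.
#' @export
comparison_models <- function(sources, cortex, variance_kept = 0.95,
                              ceiling_floor = 0.05) {
  stopifnot(is.list(sources), length(names(sources)) == length(sources))
  lapply(setNames(names(sources), names(sources)), function(nm) {
    src <- sources[[nm]]
    if (ncol(as.matrix(src$half1$betas)) < 1L ||
        nrow(as.matrix(src$half1$betas)) < 2L) {
      stop(sprintf("source `%s` has fewer than 2 voxels", nm), call. = FALSE)
    }
    halves <- lapply(c("half1", "half2"), function(h) {
      fc <- pcr_fc(src[[h]]$resid_ts, cortex[[h]]$resid_ts,
                   variance_kept = variance_kept)
      list(betas_source = src[[h]]$betas, fc = fc,
           betas_cortex = cortex[[h]]$betas)
    })
    names(halves) <- c("half1", "half2")
    split_half_cv(halves, model_tag = paste0("comparison:", nm),
                  ceiling_floor = ceiling_floor)
  })
}

#' Paired comparison of model accuracies across subjects
#'
#' Two-sided paired t-test across subjects of the main model's normalized
#' accuracy against a comparison (or null) model's.
#'
#' @param main_by_subject,other_by_subject numeric vectors, one value per
#'   subject.
#' @return list with `t`, `df`, `p`, `mean_difference`.
#' @export
paired_model_test <- function(main_by_subject, other_by_subject) {
  stopifnot(length(main_by_subject) == length(other_by_subject))
  d <- main_by_subject - other_by_subject
  if (sd(d) == 0) {
    return(list(t = 0, df = length(d) - 1L, p = 1, mean_difference = mean(d)))
  }
  tt <- t.test(main_by_subject, other_by_subject, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = mean(d))
}
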