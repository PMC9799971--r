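test_that("prediction is the connectivity-weighted sum of source activity", {
  set.seed(1)
  fc <- matrix(rnorm(20 * 5), 20, 5)
  betas <- matrix(rnorm(20 * 3), 20, 3)
  expect_equal(predict_cortical(betas, fc), t(fc) %*% betas)
  expect_equal(predict_cortical(matrix(0, 20, 3), fc), matrix(0, 5, 3))
  expect_error(predict_cortical(matrix(0, 9, 3), fc), "voxel counts")

  # hand-computable 2-voxel example
  fc2 <- rbind(c(1, 0, 1), c(0, 1, 1))
  pred <- predict_cortical(matrix(c(1, 2), 2, 1), fc2)
  expect_equal(as.numeric(pred), c(1, 2, 3))
})

test_that("split-half CV is exact on noiseless data and near zero on noise", {
  gt <- fixture_gt(seed = 2, n_tasks = 10)
  halves0 <- fixture_flow_halves(gt, noise_sd = 0)
  res0 <- split_half_cv(halves0)
  expect_equal(unname(res0$accuracy_per_task), rep(1, 10), tolerance = 1e-10)
  expect_equal(res0$accuracy, 1, tolerance = 1e-10)
  expect_equal(unname(res0$noise_ceiling), rep(1, 10), tolerance = 1e-10)
  expect_equal(res0$normalized_accuracy, 1, tolerance = 1e-10)

  # observed patterns replaced by independent noise: accuracy ~ 0
  set.seed(2)
  gt100 <- generate_ground_truth(100, 40, 7, 3, 100, 0.2, seed = 2)
  hn <- fixture_flow_halves(gt100, noise_sd = 0.5)
  hn$half1$betas_cortex <- matrix(rnorm(40 * 100), 40, 100)
  hn$half2$betas_cortex <- matrix(rnorm(40 * 100), 40, 100)
  resn <- split_half_cv(hn)
  expect_lt(abs(resn$accuracy), 0.05)
})

test_that("zero-variance observed patterns are excluded with a warning", {
  gt <- fixture_gt(seed = 3, n_tasks = 6)
  h <- fixture_flow_halves(gt, noise_sd = 0.3)
  h$half2$betas_cortex[, 2] <- 5 # constant pattern
  expect_warning(res <- split_half_cv(h), "undefined")
  expect_true(is.na(res$accuracy_per_task[2]))
  expect_false(is.na(res$accuracy))
})

test_that("null models follow their defining algebra", {
  gt <- fixture_gt(seed = 4, n_tasks = 8)
  h <- fixture_flow_halves(gt, noise_sd = 0.5)
  main <- split_half_cv(h)

  # uniform null predicts fc column sums, identical for every task
  nu <- null_uniform(h, main = main)
  expect_equal(nu$predicted$half1,
               matrix(colSums(gt$fc_true), 40, 8,
                      dimnames = dimnames(nu$predicted$half1)))
  expect_lt(max(apply(nu$predicted$half1, 1, sd)), 1e-12)
  # nulls are normalized by the main model's ceiling
  expect_equal(nu$normalization_ceiling, main$noise_ceiling)

  # average null with a single task equals the main model
  gt1 <- generate_ground_truth(60, 21, 3, 2, 2, 0.2, seed = 4)
  h1 <- fixture_flow_halves(gt1, noise_sd = 0.3)
  h1$half1$betas_source <- h1$half1$betas_source[, 1, drop = FALSE]
  h1$half2$betas_source <- h1$half2$betas_source[, 1, drop = FALSE]
  h1$half1$betas_cortex <- h1$half1$betas_cortex[, 1, drop = FALSE]
  h1$half2$betas_cortex <- h1$half2$betas_cortex[, 1, drop = FALSE]
  m1 <- split_half_cv(h1)
  a1 <- null_average(h1, main = m1)
  expect_equal(a1$accuracy, m1$accuracy, tolerance = 1e-12)

  # shuffle with identity permutation reproduces the main model exactly
  id <- list(half1 = seq_len(100), half2 = seq_len(100))
  ns_id <- null_shuffle(h, main = main, perm = id)
  expect_equal(ns_id$accuracy, main$accuracy, tolerance = 1e-12)
  # a seeded shuffle is reproducible and degrades accuracy on planted data
  ns <- null_shuffle(h, seed = 4, main = main)
  expect_equal(ns$accuracy, null_shuffle(h, seed = 4, main = main)$accuracy)
  expect_gt(main$accuracy, ns$accuracy)
})

test_that("split-half reliability matches its closed-form attenuation", {
  m <- matrix(rnorm(40 * 5), 40, 5)
  expect_equal(split_half_reliability(m, m), rep(1, 5), tolerance = 1e-12)
  expect_equal(split_half_reliability(m, -m), rep(-1, 5), tolerance = 1e-12)

  # halves = signal + independent noise: E[r] = var_s / (var_s + var_n);
  # Monte-Carlo oracle at matched settings
  set.seed(5)
  var_n <- 2 / 3 # signal variance 1 -> expected r = 0.6
  r_obs <- replicate(300, {
    s <- rnorm(100)
    split_half_reliability(cbind(s + rnorm(100, sd = sqrt(var_n))),
                           cbind(s + rnorm(100, sd = sqrt(var_n))))
  })
  expect_equal(mean(r_obs), 0.6, tolerance = 0.05)
})

test_that("noise ceiling is the reliability product and normalization is guarded", {
  expect_equal(noise_ceiling(1, 1), 1)
  expect_equal(noise_ceiling(0.8, 0.5), 0.4)
  nm <- normalize_accuracy(c(0.3, 0.2), c(1, 1))
  expect_equal(nm$mean, 0.25)
  # low-ceiling tasks are excluded without touching the others
  nm2 <- normalize_accuracy(c(0.3, 0.2), c(1, 0.01))
  expect_equal(nm2$per_task[1], 0.3)
  expect_true(is.na(nm2$per_task[2]))
  expect_identical(nm2$excluded, 2L)
  expect_error(normalize_accuracy(0.5, 0.01), "floor")
  # normalization never flips the sign of accuracy
  nm3 <- normalize_accuracy(c(-0.2, 0.4), c(0.5, 0.8))
  expect_true(all(sign(nm3$per_task) == sign(c(-0.2, 0.4))))
})

test_that("comparison models reproduce the main model for the same source", {
  set.seed(6)
  gt <- generate_ground_truth(40, 21, 3, 2, 6, 0.2, seed = 6)
  Tn <- 300
  mk_half <- function() {
    src_ts <- matrix(rnorm(Tn * 40), Tn, 40)
    roi_ts <- src_ts %*% gt$fc_true + matrix(rnorm(Tn * 21, sd = 0.1), Tn, 21)
    list(src_ts = src_ts, roi_ts = roi_ts)
  }
  b <- generate_betas(gt, noise_sd = 0.3, seed = 6)
  h1 <- mk_half(); h2 <- mk_half()
  cortex <- list(half1 = list(betas = b$half1$cortical, resid_ts = h1$roi_ts),
                 half2 = list(betas = b$half2$cortical, resid_ts = h2$roi_ts))
  src <- list(half1 = list(betas = b$half1$thalamic, resid_ts = h1$src_ts),
              half2 = list(betas = b$half2$thalamic, resid_ts = h2$src_ts))

  res <- comparison_models(list(thalamus = src, thalamus_copy = src), cortex)
  expect_equal(res$thalamus$accuracy, res$thalamus_copy$accuracy)
  expect_match(res$thalamus$model_tag, "comparison:thalamus")

  # a decoy with shuffled connectivity-generating series underperforms
  decoy <- src
  decoy$half1$betas <- src$half1$betas[sample(40), ]
  decoy$half2$betas <- src$half2$betas[sample(40), ]
  res2 <- comparison_models(list(real = src, decoy = decoy), cortex)
  expect_gt(res2$real$accuracy, res2$decoy$accuracy)

  # paired test across subjects: identical models give t = 0
  pt <- paired_model_test(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(pt$t, 0)
  expect_equal(pt$p, 1)
  pt2 <- paired_model_test(c(0.5, 0.6, 0.7), c(0.1, 0.2, 0.15))
  expect_gt(pt2$t, 0)
  expect_lt(pt2$p, 0.05)
})
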