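test_that("voxel ranking is descending with stable ties", {
  set.seed(18)
  r <- rank_voxels(c(3, 1, 2))
  expect_equal(r, c(0, 200 / 3, 100 / 3))
  # 100 distinct values: one voxel per percentile bin
  v <- sample(100)
  expect_setequal(rank_voxels(v), 0:99)
  expect_error(rank_voxels(rep(1, 5)), "constant")
  expect_error(rank_voxels(c(1, NA)), "missing")

  # planted hubs occupy the top hub_fraction percentiles at zero noise
  gt <- fixture_gt(seed = 1)
  b <- generate_betas(gt, noise_sd = 0)
  cw <- compw(pca_activity(standardize(b$half1$thalamic)), 1:3)
  rk <- rank_voxels(cw)
  expect_true(all(rk[gt$hub_mask] < 20))
})

test_that("lesion sweep covers percentiles as specified and conserves the baseline", {
  gt <- fixture_gt(seed = 2, n_tasks = 10)
  h <- fixture_flow_halves(gt, noise_sd = 0.3)
  cw <- compw(pca_activity(standardize(
    (h$half1$betas_source + h$half2$betas_source) / 2)), 1:3)
  rk <- rank_voxels(cw)
  sw <- lesion_sweep(h, rk)

  # every voxel in >= 1 and <= 20 windows; interior percentiles exactly 20
  expect_true(all(sw$windows_per_voxel >= 1 & sw$windows_per_voxel <= 20))
  interior <- rk >= 19 & rk <= 80
  expect_true(all(sw$windows_per_voxel[interior] == 20))
  # each window lesions exactly round(0.2 * n) voxels (distinct ranks)
  expect_true(all(vapply(sw$window_starts, function(s) {
    sum(rk >= s & rk < s + 20)
  }, numeric(1)) == 20))

  # degenerate zero-width window reproduces the baseline bit-identically
  sw0 <- lesion_sweep(h, rk, window = 0, span = c(0, 0))
  expect_identical(sw0$accuracy_per_window, sw$baseline_accuracy)
  expect_identical(sw0$reduction_per_window, 0)

  # planted hubs: lesioning the top window hurts more than the bottom
  expect_gt(sw$reduction_per_window[1],
            sw$reduction_per_window[length(sw$window_starts)])
})

test_that("uniform-contribution construction yields equal reductions", {
  set.seed(19)
  nv <- 100
  fc_row <- runif(21, 0.5, 1.5)
  fc <- matrix(fc_row, nv, 21, byrow = TRUE)
  betas <- matrix(1, nv, 4)
  obs <- t(fc) %*% betas + outer(fc_row, rnorm(4, sd = 0.1))
  h <- list(half1 = list(betas_source = betas, fc = fc, betas_cortex = obs),
            half2 = list(betas_source = betas, fc = fc, betas_cortex = obs))
  sw <- lesion_sweep(h, ranks = seq(0, 99.9, length.out = nv))
  expect_lt(diff(range(sw$reduction_per_window)), 1e-10)
})

test_that("reduction map tracks ground-truth contribution when ranked by it", {
  gt <- fixture_gt(seed = 5, n_tasks = 10)
  h <- fixture_flow_halves(gt, noise_sd = 0.05)
  contrib <- sqrt(rowSums(h$half1$betas_source^2)) *
    sqrt(rowSums(gt$fc_true^2))
  sw <- lesion_sweep(h, rank_voxels(contrib))
  expect_gt(cor(contrib, sw$voxel_reduction_map, method = "spearman"), 0.8)
  # the CompW-ranked path still separates the planted classes
  cw <- compw(pca_activity(standardize(
    (h$half1$betas_source + h$half2$betas_source) / 2)), 1:3)
  sw2 <- lesion_sweep(h, rank_voxels(cw))
  expect_gt(mean(sw2$voxel_reduction_map[gt$hub_mask]),
            mean(sw2$voxel_reduction_map[!gt$hub_mask]))
})

test_that("reduction regression recovers constructed slopes", {
  sw <- structure(list(window_starts = 0:80,
                       reduction_per_window = 40 - 0.43 * (0:80)),
                  class = "lesion_sweep")
  reg <- suppressWarnings(reduction_regression(sw)) # exact fit is intended
  expect_equal(reg$b, -0.43, tolerance = 1e-10)
  expect_lt(reg$p, 0.001)

  flat <- structure(list(window_starts = 0:80,
                         reduction_per_window = rep(5, 81)),
                    class = "lesion_sweep")
  expect_equal(suppressWarnings(reduction_regression(flat))$b, 0,
               tolerance = 1e-10)

  # stacked subject sweeps: planted data give a negative slope
  sweeps <- lapply(1:6, function(s) {
    gt <- fixture_gt(seed = 10 + s, n_tasks = 8)
    h <- fixture_flow_halves(gt, noise_sd = 0.5)
    cw <- compw(pca_activity(standardize(
      (h$half1$betas_source + h$half2$betas_source) / 2)), 1:3)
    lesion_sweep(h, rank_voxels(cw), step = 10)
  })
  reg2 <- reduction_regression(sweeps)
  expect_lt(reg2$b, 0)
  expect_lt(reg2$p, 0.05)
})

test_that("patient classification applies strict boundaries", {
  mk <- function(z_by_domain) {
    data.frame(patient_id = "P1",
               test = paste0("t", seq_along(z_by_domain)),
               domain = paste0("d", seq_along(z_by_domain)),
               z = z_by_domain)
  }
  # three impaired domains -> MM
  expect_equal(classify_patients(mk(c(-2, -1.7, -1.7, 0, 0)))$group, "MM")
  # exactly two impaired domains -> SM ("more than two" is strict)
  expect_equal(classify_patients(mk(c(-2, -2, 0, 0, 0)))$group, "SM")
  # exactly at the threshold is not impairment (strict inequality)
  expect_equal(classify_patients(mk(rep(-1.645, 5)))$group, "SM")
  expect_equal(classify_patients(mk(rep(0, 5)))$group, "SM")
  # any test below threshold impairs its whole domain
  two_tests <- data.frame(patient_id = "P1",
                          test = c("a1", "a2", "b1", "c1"),
                          domain = c("dA", "dA", "dB", "dC"),
                          z = c(-2, 0, -2, -2))
  expect_equal(classify_patients(two_tests)$group, "MM")
  expect_error(classify_patients(data.frame(patient_id = 1, z = 0)),
               "columns")
})

test_that("lesion-group comparison behaves at its analytic extremes", {
  set.seed(20)
  vals <- c(rnorm(50), rnorm(50, 3))
  mm <- c(rep(TRUE, 50), rep(FALSE, 50))
  sm <- !mm
  same <- compare_lesion_groups(c(vals, vals),
                                c(mm, rep(FALSE, 100)),
                                c(rep(FALSE, 100), mm))
  # identical samples: D = 0
  expect_equal(unname(same$D), 0)
  # disjoint point masses: D = 1
  pm <- compare_lesion_groups(c(rep(0, 10), rep(1, 10)),
                              c(rep(TRUE, 10), rep(FALSE, 10)),
                              c(rep(FALSE, 10), rep(TRUE, 10)))
  expect_equal(unname(pm$D), 1)
  expect_error(compare_lesion_groups(vals, mm, mm), "disjoint")
  expect_error(compare_lesion_groups(vals, rep(FALSE, 100), sm), "nonempty")

  # planted fixtures: hub-overlapping lesions show larger reductions
  gt <- fixture_gt(seed = 6, n_tasks = 10)
  h <- fixture_flow_halves(gt, noise_sd = 0.3)
  cw <- compw(pca_activity(standardize(
    (h$half1$betas_source + h$half2$betas_source) / 2)), 1:3)
  sw <- lesion_sweep(h, rank_voxels(cw))
  fix <- generate_lesion_fixtures(gt, seed = 6)
  cmp <- compare_lesion_groups(sw$voxel_reduction_map, fix$mm_mask,
                               fix$sm_mask)
  expect_gt(cmp$D, 0)
  expect_lt(cmp$p, 0.05)
})
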