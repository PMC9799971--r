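test_that("PCR at full retention equals the least-squares oracle", {
  set.seed(1)
  for (rep in 1:10) {
    X <- matrix(rnorm(80 * 10), 80, 10)
    Y <- matrix(rnorm(80 * 4), 80, 4)
    fc <- pcr_fc(X, Y, variance_kept = 1)
    ols <- apply(Y, 2, function(y) lm(y ~ X)$coefficients[-1])
    expect_lt(max(abs(fc$weights - ols)), 1e-8)
  }
})

test_that("PCR identifies an exact-copy target and recovers planted connectivity", {
  set.seed(2)
  X <- matrix(rnorm(300 * 10), 300, 10)
  Y <- cbind(X[, 3], rnorm(300))
  fc <- pcr_fc(X, Y, variance_kept = 1)
  expect_equal(fc$weights[3, 1], 1, tolerance = 1e-6)
  expect_lt(max(abs(fc$weights[-3, 1])), 1e-6)

  gt <- fixture_gt(seed = 3)
  src <- matrix(rnorm(2000 * 100), 2000, 100)
  tgt <- src %*% gt$fc_true
  rec <- pcr_fc(src, tgt, variance_kept = 1)
  cors <- vapply(seq_len(ncol(tgt)), function(r) {
    cor(rec$weights[, r], gt$fc_true[, r])
  }, numeric(1))
  expect_true(all(cors > 0.95))
})

test_that("PCR validates inputs and warns when rank is exhausted", {
  X <- matrix(rnorm(50 * 5), 50, 5)
  expect_error(pcr_fc(X, matrix(0, 50, 2)), "zero-variance")
  expect_error(pcr_fc(X, matrix(rnorm(40), 40, 1)), "equal time length")
  expect_error(pcr_fc(X[, 1, drop = FALSE], matrix(rnorm(50), 50, 1)),
               ">= 2 source voxels")
  # rank-deficient source: components are capped at the positive spectrum
  Xr <- cbind(X[, 1], X[, 1], X[, 2])
  fcr <- pcr_fc(Xr, matrix(rnorm(50), 50, 1), variance_kept = 1)
  expect_lte(fcr$n_components, 2)
  expect_true(all(is.finite(fcr$weights)))
})

test_that("density thresholding retains the exact top fraction", {
  m <- matrix(rnorm(100), 10, 10)
  th <- density_threshold(m, 0.05)
  expect_equal(sum(th$weights != 0), 5)

  m2 <- matrix(1:100, 10, 10)
  th2 <- density_threshold(m2, 0.15)
  expect_setequal(th2$weights[th2$weights != 0], 86:100)

  # density 1 only zeroes negatives under the default sign policy
  m3 <- matrix(c(-1, 2, 3, -4), 2, 2)
  expect_equal(density_threshold(m3, 1)$weights,
               matrix(c(0, 2, 3, 0), 2, 2))
  expect_equal(density_threshold(m3, 1, "absolute")$weights, abs(m3))

  expect_error(density_threshold(m, 0), "density")
  expect_error(density_threshold(matrix(1, 2, 2), 0.01), "fewer than one")

  # retained count strictly increases with density on distinct entries
  counts <- vapply(c(0.05, 0.10, 0.15, 0.30),
                   function(d) sum(density_threshold(m2, d)$weights > 0),
                   numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("participation coefficient matches its closed forms and bounds", {
  labels <- rep(1:7, each = 2)
  one_net <- matrix(0, 3, 14)
  one_net[, labels == 4] <- 1
  pc1 <- participation_coefficient(as_conn(one_net), labels)
  expect_equal(pc1$values, rep(0, 3))

  unif <- matrix(1, 3, 14)
  pc2 <- participation_coefficient(as_conn(unif), labels)
  expect_equal(pc2$values, rep(1 - 1 / 7, 3), tolerance = 1e-12)

  # K_i = 0 voxel is missing, not zero
  mixed <- rbind(unif[1, ], 0)
  pc3 <- participation_coefficient(as_conn(mixed), labels)
  expect_true(is.na(pc3$values[2]))
  expect_error(participation_coefficient(as_conn(unif), labels[-1]),
               "network label")
  expect_error(participation_coefficient(as_conn(-unif), labels),
               "nonnegative")
  # bounds on random nonnegative matrices
  set.seed(4)
  w <- matrix(runif(20 * 14), 20, 14)
  pcv <- participation_coefficient(as_conn(w), labels)$values
  expect_true(all(pcv >= 0 & pcv <= 1 - 1 / 7 + 1e-12))
})

test_that("density-averaged PC reduces to single-density PC and separates hubs", {
  gt <- fixture_gt(seed = 5)
  single <- pc_across_densities(gt$fc_true, gt$network_labels,
                                densities = 0.10)
  direct <- participation_coefficient(
    density_threshold(gt$fc_true, 0.10), gt$network_labels)
  expect_equal(single$values, direct$values)

  lb <- rep(1:7, length.out = 40)
  unif <- matrix(1, 10, 40)
  avg1 <- pc_across_densities(unif, lb, densities = 1.0)
  expect_true(all(abs(avg1$values - (1 - sum((table(lb) / 40)^2))) < 1e-12))

  pc <- pc_across_densities(gt$fc_true, gt$network_labels)
  vals <- pc$values
  vals[is.na(vals)] <- 0 # no suprathreshold connectivity = non-hub
  expect_gt(min(vals[gt$hub_mask]), max(vals[!gt$hub_mask]))
})

test_that("hub projection onto cortex follows the dot-product definition", {
  gt <- fixture_gt(seed = 6, n_voxels = 40)
  expect_equal(project_to_cortex(rep(0, 40), gt$fc_true), rep(0, 40))

  # identity-like pairing (1 voxel <-> 1 ROI): projection permutes the map
  set.seed(6)
  perm <- sample(40)
  eye <- diag(40)[, perm]
  h <- runif(40)
  expect_equal(project_to_cortex(h, eye), as.numeric(t(eye) %*% h))
  expect_equal(sort(project_to_cortex(h, eye)), sort(h))
  # ROIs wired to hubs receive larger projections than non-hub-only ROIs
  b <- generate_betas(gt, noise_sd = 0)
  cw <- compw(pca_activity(standardize(b$half1$thalamic)), 1:3)
  proj <- project_to_cortex(cw, gt$fc_true)
  hub_w <- colSums(gt$fc_true[gt$hub_mask, , drop = FALSE])
  expect_gt(cor(proj, hub_w), 0.5)
  expect_error(project_to_cortex(rep(1, 10), gt$fc_true), "voxel counts")
})

test_that("spatial correlation handles identity, negation and group inference", {
  set.seed(7)
  m <- rnorm(100)
  expect_equal(spatial_correlation(m, m)$r[[1]], 1)
  expect_equal(spatial_correlation(m, -m)$r[[1]], -1)
  expect_error(spatial_correlation(1:2, 2:1), ">= 3 voxels")

  # null calibration: independent maps give |r| < 0.1 typically and the
  # Fisher-z group test rejects at close to its nominal 5% rate
  rejections <- vapply(1:300, function(rep) {
    rs <- spatial_correlation(
      lapply(1:15, function(i) rnorm(150)),
      lapply(1:15, function(i) rnorm(150)))
    rs$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.12)
})
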