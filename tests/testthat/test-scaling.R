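test_that("noiseless saturating data are recovered exactly", {
  A <- c(5, 10, 20, 40)
  truth <- tibble::tibble(n = 1:4, area_cm2 = A, W_mean = 1 * A / (10 + A),
                          W_var = 1e-4, mean_radius_cm = 1 / A,
                          flow_mL_min = 1)
  fit <- fit_saturating(truth, target_area = 120)
  expect_equal(fit$sat_level, 1, tolerance = 1e-6)
  expect_equal(fit$half_area, 10, tolerance = 1e-6)
  expect_equal(extrapolate_w(fit, 1e9), fit$sat_level, tolerance = 1e-6)
  expect_equal(extrapolate_w(fit, fit$half_area), fit$sat_level / 2,
               tolerance = 1e-6)
})

test_that("equal variances make weighted and unweighted fits coincide", {
  A <- c(4, 8, 16, 32, 64)
  set.seed(7)
  W <- 2 * A / (12 + A) * (1 + rnorm(5, sd = 0.03))
  pts_w <- tibble::tibble(area_cm2 = A, W_mean = W, W_var = 0.01)
  pts_u <- tibble::tibble(area_cm2 = A, W_mean = W, W_var = NA_real_)
  f1 <- fit_saturating(pts_w, target_area = 120)
  expect_warning(fit_saturating(pts_u, target_area = 120), "unweighted")
  f2 <- suppressWarnings(fit_saturating(pts_u, target_area = 120))
  expect_equal(f1$sat_level, f2$sat_level, tolerance = 1e-8)
  expect_equal(f1$half_area, f2$half_area, tolerance = 1e-8)
})

test_that("Monte-Carlo parameter recovery under 5% noise is accurate", {
  # areas spanning both sides of the half-saturation point keep both
  # parameters identifiable
  A <- c(2, 4, 8, 16, 32, 64)
  cc <- 0.6; dd <- 4
  set.seed(42)
  errs <- t(replicate(100, {
    W <- cc * A / (dd + A) * (1 + rnorm(length(A), sd = 0.05))
    pts <- tibble::tibble(area_cm2 = A, W_mean = W,
                          W_var = (0.05 * cc * A / (dd + A))^2)
    fit <- fit_saturating(pts, target_area = 120)
    c(abs(fit$sat_level - cc) / cc, abs(fit$half_area - dd) / dd)
  }))
  expect_lt(median(errs[, 1]), 0.10)
  expect_lt(median(errs[, 2]), 0.10)
})

test_that("flow extrapolation is exact on a pure power law", {
  r <- c(20, 40, 80, 160) * 1e-4
  pts <- tibble::tibble(n = 1:4, area_cm2 = 1:4, mean_radius_cm = r,
                        flow_mL_min = 3 * (r / 1e-4)^1.7, W = 1)
  ex <- extrapolate_flow(pts, target_radius_um = 3.9)
  expect_equal(ex$exponent, 1.7, tolerance = 1e-9)
  expect_equal(ex$flow_mL_min, 3 * 3.9^1.7, tolerance = 1e-9)
  expect_error(extrapolate_flow(pts[1:2, ]), "three")
})

test_that("doubling the pressure drop doubles the extrapolated flow", {
  cfg1 <- scaling_config(grid_levels = c(2, 3, 4), replicates = 2,
                         delta_P = 50, seed = 5)
  cfg2 <- scaling_config(grid_levels = c(2, 3, 4), replicates = 2,
                         delta_P = 100, seed = 5)
  p1 <- run_grid_sequence(cfg1)
  p2 <- run_grid_sequence(cfg2)
  e1 <- extrapolate_flow(p1)
  e2 <- extrapolate_flow(p2)
  expect_equal(e2$flow_mL_min / e1$flow_mL_min, 2, tolerance = 1e-9)
})

test_that("grid sequence runs are finite, positive and seed-reproducible", {
  cfg <- scaling_config(grid_levels = 2L, replicates = 3, seed = 9)
  pts <- run_grid_sequence(cfg)
  expect_equal(nrow(pts), 3)
  expect_true(all(is.finite(pts$W) & pts$W > 0))
  expect_true(all(is.finite(pts$flow_mL_min) & pts$flow_mL_min > 0))
  pts2 <- run_grid_sequence(cfg)
  expect_equal(pts, pts2)
})

test_that("partition coefficient reduces to its closed forms", {
  params <- transport_params(v0 = 5)
  # hypothetical uniform tissue concentration equal to the blood level
  expect_equal(partition_coefficient(5, params, tissue_volume = 1), 1)
  # single well-mixed vessel with negligible depletion: w/v0 = k1/(k2 (K+v0))
  w <- params$k1 * params$v0 / (params$k2 * (params$K + params$v0))
  expect_equal(partition_coefficient(w, params, tissue_volume = 1),
               0.0871, tolerance = 1e-3)
})

test_that("fit summaries expose coefficients and the attained fraction", {
  A <- c(5, 10, 20, 40)
  pts <- tibble::tibble(area_cm2 = A, W_mean = 1 * A / (10 + A), W_var = 1e-4)
  fit <- fit_saturating(pts, target_area = 120)
  td <- tidy(fit)
  expect_equal(td$term, c("sat_level", "half_area"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_equal(gl$attained_fraction,
               (40 / (10 + 40)) / (120 / (10 + 120)), tolerance = 1e-6)
  expect_s3_class(autoplot(fit), "ggplot")
})
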