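test_that("strain field is exact for affine deformations", {
  g <- make_marker_dataset(marker_truth(grid_dims = c(8, 8), noise_sd = 0,
                                        applied_strain = 0.10,
                                        lateral_ratio = 0.9))
  r <- local_strain_field(g)
  expect_equal(max(abs(r$quads$strain_y - 0.10)), 0, tolerance = 1e-12)
  expect_equal(max(abs(r$quads$strain_x + 0.09)), 0, tolerance = 1e-12)
  # identity map gives zero strain
  g0 <- make_marker_dataset(marker_truth(grid_dims = c(5, 5), noise_sd = 0,
                                         applied_strain = 0))
  r0 <- local_strain_field(g0)
  expect_lt(max(abs(c(r0$quads$strain_x, r0$quads$strain_y))), 1e-14)
})

test_that("strains are invariant to rigid motion of the deformed grid", {
  g <- make_marker_dataset(marker_truth(grid_dims = c(9, 9), noise_sd = 0.03,
                                        seed = 4))
  r1 <- local_strain_field(g)
  th <- 0.35
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  def <- cbind(g$x_def, g$y_def) %*% t(R)
  g2 <- g
  g2$x_def <- def[, 1] + 5.3
  g2$y_def <- def[, 2] - 2.1
  r2 <- local_strain_field(g2)
  expect_equal(r2$quads$strain_x, r1$quads$strain_x, tolerance = 1e-10)
  expect_equal(r2$quads$strain_y, r1$quads$strain_y, tolerance = 1e-10)
})

test_that("strain estimator is unbiased under zero-mean marker noise", {
  est <- vapply(1:200, function(s) {
    g <- make_marker_dataset(marker_truth(grid_dims = c(11, 11),
                                          noise_sd = 0.02, seed = s))
    local_strain_field(g)$mean_strain_y
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.10), 0.002)  # within 0.2 pp of truth
})

test_that("degenerate quads are skipped with a warning", {
  g <- make_marker_dataset(marker_truth(grid_dims = c(3, 3), noise_sd = 0))
  # collapse one row of reference markers onto a line through the quad
  g$x_ref[c(1, 2)] <- 0; g$y_ref[c(1, 2)] <- 0
  g$x_def[c(1, 2)] <- 0; g$y_def[c(1, 2)] <- 0
  expect_warning(r <- local_strain_field(g), "degenerate")
  expect_gte(r$n_skipped, 1)
})

test_that("ROI polygon restricts the reported means", {
  g <- make_marker_dataset(marker_truth(grid_dims = c(9, 9), noise_sd = 0))
  roi <- cbind(c(-2, 2, 2, -2), c(-2, -2, 2, 2))
  r <- local_strain_field(g, roi = roi)
  expect_lt(r$n_roi, nrow(r$quads))
  expect_equal(r$mean_strain_y, 0.10, tolerance = 1e-12)
})

test_that("sample stress reconciles N and mm^2 into kPa", {
  expect_equal(sample_stress(0.1, 10, 1), 10)
  expect_equal(sample_stress(0, 10, 1), 0)
  expect_error(sample_stress(0.1, -10, 1), "width")
  # paper-scale check: 0.28 N over a 5 x 5 mm cross-section ~ 11.2 kPa
  expect_equal(sample_stress(0.28, 5, 5), 11.2)
})

test_that("composite modulus is the secant stress/strain ratio", {
  expect_equal(composite_modulus(10, 0.10), 100)
  expect_error(composite_modulus(10, 0), "strain")
})

test_that("layered sample reproduces the rule-of-mixtures modulus", {
  # myocardium 50 kPa x 2 mm plus patch 50 MPa x 0.3 mm, width 10 mm,
  # both layers at 10% strain in parallel
  E <- c(50, 50e3); t <- c(2, 0.3); w <- 10; eps <- 0.10
  load_N <- sum(E * eps * t * w) / 1000
  sigma <- sample_stress(load_N, w, sum(t))
  expect_equal(composite_modulus(sigma, eps),
               rule_of_mixtures_modulus(E, t), tolerance = 1e-6)
  # magnitude matches the expected ~6.57 MPa
  expect_equal(rule_of_mixtures_modulus(E, t) / 1000, 6.565, tolerance = 1e-3)
})

test_that("strain heatmap renders to PNG", {
  g <- make_marker_dataset(marker_truth(grid_dims = c(6, 6), seed = 2))
  r <- local_strain_field(g)
  f <- tempfile(fileext = ".png")
  plot(r, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
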