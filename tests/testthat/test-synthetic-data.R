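# generators: marker grids and peak-count tables with known ground truth

test_that("noise-free marker grids are exactly the affine map", {
  g <- make_marker_dataset(marker_truth(noise_sd = 0, applied_strain = 0.10,
                                        lateral_ratio = 1.0))
  expect_equal(g$y_def, 1.10 * g$y_ref)
  expect_equal(g$x_def, 0.90 * g$x_ref)
  r <- local_strain_field(g)
  expect_equal(r$mean_strain_y, 0.10, tolerance = 1e-12)
  expect_equal(r$mean_strain_x, -0.10, tolerance = 1e-12)
})

test_that("marker generator is deterministic under a fixed seed", {
  a <- make_marker_dataset(marker_truth(seed = 42))
  b <- make_marker_dataset(marker_truth(seed = 42))
  expect_identical(a, b)
  c <- make_marker_dataset(marker_truth(seed = 43))
  expect_false(identical(a$x_def, c$x_def))
})

test_that("marker generation does not disturb the caller's RNG stream", {
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(make_marker_dataset(marker_truth(seed = 1)))
  expect_identical(rnorm(1), before)
})

test_that("noisy marker grids recover the applied strain", {
  g <- make_marker_dataset(marker_truth(grid_dims = c(21, 21),
                                        noise_sd = 0.05, seed = 7))
  r <- local_strain_field(g)
  expect_lt(abs(r$mean_strain_y - 0.10), 0.005)   # within 0.5 pp of 10%
})

test_that("marker truth validates its invariants", {
  expect_error(marker_truth(spacing = 0), "spacing")
  expect_error(marker_truth(applied_strain = 1), "applied_strain")
  expect_error(marker_truth(noise_sd = -1), "noise_sd")
  expect_error(marker_truth(grid_dims = c(1, 5)), "grid_dims")
})

test_that("marker CSV round-trips", {
  g <- make_marker_dataset(marker_truth(grid_dims = c(5, 5), seed = 3))
  f <- tempfile(fileext = ".csv")
  write_marker_csv(g, f)
  b <- read_marker_csv(f)
  expect_equal(b$x_def, g$x_def, tolerance = 1e-12)
  r1 <- local_strain_field(g); r2 <- local_strain_field(b)
  expect_equal(r2$mean_strain_y, r1$mean_strain_y, tolerance = 1e-10)
})

test_that("peak tables are deterministic and carry designed effects", {
  d1 <- make_peak_table(screen_truth(n_genes = 800, seed = 5))
  d2 <- make_peak_table(screen_truth(n_genes = 800, seed = 5))
  expect_identical(d1, d2)
  g1 <- d1$labels == "group1"
  ratios <- d1$table$sum_mi[g1] / pmax(d1$table$sum_sham[g1], 1)
  se <- sd(ratios) / sqrt(sum(g1))
  expect_gte(mean(ratios), 1.6 - 3 * se)
})

test_that("null table with near-zero dispersion classifies almost all neither", {
  # deep-count limit: with dispersion -> 0 only Poisson noise remains, and
  # at high baseline abundance the ratios concentrate inside the thresholds
  d <- make_peak_table(screen_truth(n_genes = 1000, frac_group1 = 0,
                                    frac_group2 = 0, dispersion = 0,
                                    base_mean = 5000, base_sdlog = 0.3,
                                    seed = 2))
  lab <- classify_groups(d$table)
  expect_gt(mean(lab$label == "neither"), 0.95)
})

test_that("designed labels are recovered on low-dispersion tables", {
  d <- make_peak_table(screen_truth(n_genes = 2000, effect_up = 1.6,
                                    effect_down = 0.5, dispersion = 0.02,
                                    seed = 11))
  lab <- classify_groups(d$table)
  agree <- mean(as.character(lab$label[d$labels != "neither"]) ==
                  as.character(d$labels[d$labels != "neither"]))
  expect_gte(agree, 0.95)
})

test_that("screen truth validates fractions and effect sizes", {
  expect_error(screen_truth(frac_group1 = 0.6, frac_group2 = 0.6), "<= 1")
  expect_error(screen_truth(effect_up = 1.1), "effect_up")
  expect_error(screen_truth(effect_down = 0.9), "effect_down")
})

test_that("peak-sum TSV round-trips", {
  d <- make_peak_table(screen_truth(n_genes = 50, seed = 1))
  f <- tempfile(fileext = ".tsv")
  write_peak_sums_tsv(d$table, f)
  b <- read_peak_sums_tsv(f)
  expect_equal(b$sum_mi, d$table$sum_mi)
})
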