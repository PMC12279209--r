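test_that("element count equals the resolution product", {
  mesh <- build_idealized_lv(make_lv_presets("healthy"),
                             resolution = c(16, 12, 4))
  expect_identical(nrow(mesh$elems), 16L * 12L * 4L)
  expect_identical(nrow(mesh$endo_faces), 16L * 12L)
  expect_identical(nrow(mesh$epi_faces), 16L * 12L)
})

test_that("meshed cavity volume matches the truncated-ellipsoid closed form", {
  p <- make_lv_presets("healthy")
  mesh <- build_idealized_lv(p, resolution = c(32, 24, 4))
  expect_equal(cavity_volume(mesh), analytic_cavity_volume(p),
               tolerance = 0.02)
})

test_that("invalid presets and resolutions are rejected", {
  expect_error(make_lv_presets("dog"))
  expect_error(lv_preset("x", c(25, 40), wall_thickness_base = 0,
                         infarct_thickness = 0, truncation_height = 0.7),
               "wall_thickness_base")
  expect_error(lv_preset("x", c(25, 40), 10, 12, 0.7), "infarct_thickness")
  expect_error(build_idealized_lv(make_lv_presets("healthy"),
                                  resolution = c(16, 0, 2)), "resolution")
})

test_that("healthy preset has a uniform wall; icm preset is dilated and thinned", {
  h <- make_lv_presets("healthy")
  expect_identical(h$wall_thickness_base, h$infarct_thickness)
  i <- make_lv_presets("icm")
  expect_gt(i$endo_semi_axes[[1]], h$endo_semi_axes[[1]])
  expect_lte(i$infarct_thickness / i$wall_thickness_base, 0.6)
  mesh <- build_idealized_lv(i)
  expect_setequal(unique(mesh$region), c("healthy", "border", "infarct"))
})

test_that("basal nodes lie on z = 0 and all element Jacobians are positive", {
  mesh <- build_idealized_lv(make_lv_presets("icm"), c(20, 12, 2))
  expect_lt(max(abs(mesh$nodes[mesh$base_nodes, 3])), 1e-12)
  expect_gt(min(cardiopatch:::element_volumes(mesh)), 0)
  # endo and epi face sets are disjoint
  expect_length(intersect(as.integer(mesh$endo_faces),
                          as.integer(mesh$epi_faces)), 0)
})

test_that("wall volume converges under mesh refinement", {
  p <- make_lv_presets("icm")
  v1 <- wall_volume(build_idealized_lv(p, c(16, 12, 2)))
  v2 <- wall_volume(build_idealized_lv(p, c(32, 24, 4)))
  v3 <- wall_volume(build_idealized_lv(p, c(64, 48, 8)))
  expect_lt(abs(v3 - v2) / v3, 0.01)
  expect_lt(abs(v3 - v2), abs(v2 - v1))
})

test_that("patch attaches conformingly over the infarct", {
  mesh <- build_idealized_lv(make_lv_presets("icm"), c(24, 16, 2))
  mp <- attach_patch(mesh, patch_spec(20, 0.3))
  expect_true(any(mp$region == "patch"))
  # original labels unchanged
  expect_identical(mp$region[seq_along(mesh$region)], mesh$region)
  # conforming bond: every patch element shares 4 nodes with the epicardium
  epi_nodes <- unique(as.integer(mesh$epi_faces))
  first_layer <- mp$patch$patch_elems[seq_along(mp$patch$footprint_faces)]
  for (e in first_layer)
    expect_identical(sum(mp$elems[e, ] %in% epi_nodes), 4L)
  # footprint sits on the central infarct (partial coverage of the large
  # infarct is the reference configuration)
  inf_faces <- which(mesh$region[mesh$epi_face_elem] == "infarct")
  expect_true(all(mp$patch$footprint_faces %in% inf_faces))
  expect_lt(length(mp$patch$footprint_faces), length(inf_faces))
})

test_that("patch volume matches footprint area times thickness", {
  mesh <- build_idealized_lv(make_lv_presets("icm"), c(24, 16, 2))
  mp <- attach_patch(mesh, patch_spec(20, 0.3))
  expect_equal(patch_volume(mp), mp$patch$footprint_area * 0.3,
               tolerance = 0.05)
})

test_that("patch misuse is rejected", {
  mesh <- build_idealized_lv(make_lv_presets("icm"), c(24, 16, 2))
  expect_error(patch_spec(thickness = 0), "thickness")
  expect_error(patch_spec(diameter = -1), "diameter")
  mp <- attach_patch(mesh, patch_spec(20, 0.3))
  expect_error(attach_patch(mp, patch_spec(20, 0.3)), "already")
  # footprint reaching the base/apex boundary
  expect_error(attach_patch(mesh, patch_spec(diameter = 120, thickness = 0.3)),
               "exceeds")
  # healthy mesh has no infarct to center on
  hm <- build_idealized_lv(make_lv_presets("healthy"), c(16, 12, 2))
  expect_error(attach_patch(hm, patch_spec(20, 0.3)), "center")
})

test_that("preset YAML round-trips", {
  p <- make_lv_presets("icm")
  f <- tempfile(fileext = ".yaml")
  write_preset_yaml(p, f)
  q <- read_preset_yaml(f)
  expect_equal(q$endo_semi_axes, p$endo_semi_axes)
  expect_equal(q$infarct_extent, p$infarct_extent)
  expect_equal(q$resolution, p$resolution)
})

test_that("VTU files round-trip nodes, elements, labels and fields", {
  mesh <- build_idealized_lv(make_lv_presets("icm"), c(12, 8, 1))
  fib <- assign_fiber_field(mesh)
  f <- tempfile(fileext = ".vtu")
  write_vtu(mesh, f, fibers = fib)
  back <- read_vtu(f)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(back$elems, mesh$elems)
  expect_identical(back$region, mesh$region)
  expect_true("f0" %in% names(back$fields))
})

test_that("a solved load path exports as a VTU series with curves", {
  mesh <- build_idealized_lv(make_lv_presets("healthy"), c(10, 6, 1))
  fib <- assign_fiber_field(mesh)
  sim <- solve_inflation(mesh, fib, material_map(), load_protocol(0.2, 2))
  pre <- file.path(tempdir(), "series")
  files <- write_vtu_series(mesh, sim, pre)
  expect_length(files, 3 + 1)   # initial state + 2 increments + curves
  last <- read_vtu(files[3])
  expect_equal(last$fields$displacement, sim$u, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(file.exists(paste0(pre, "_curves.csv")))
})
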