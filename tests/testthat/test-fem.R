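test_that("zero pressure produces zero displacement", {
  mesh <- build_idealized_lv(make_lv_presets("healthy"), c(12, 8, 1))
  fib <- assign_fiber_field(mesh)
  s <- solve_inflation(mesh, fib, material_map(), load_protocol(0, 1))
  expect_identical(max(abs(s$u)), 0)
})

test_that("assembled tangent is consistent with the residual", {
  set.seed(52)
  mesh <- build_idealized_lv(make_lv_presets("healthy"), c(8, 4, 1))
  fib <- assign_fiber_field(mesh)
  prm <- cardiopatch:::material_rows(mesh, material_map())
  n <- nrow(mesh$nodes)
  U <- matrix(rnorm(3 * n, 0, 0.05), n, 3)
  a <- cardiopatch:::cpp_assemble(mesh$nodes, U, mesh$elems, prm,
                                  fib$f0, fib$s0, mesh$endo_faces, 0.4, TRUE)
  K <- Matrix::sparseMatrix(i = a$Ki, j = a$Kj, x = a$Kx,
                            dims = c(3 * n, 3 * n))
  h <- 1e-6
  for (dof in sample(3 * n, 12)) {
    nd <- (dof - 1) %/% 3 + 1; cp <- (dof - 1) %% 3 + 1
    Up <- U; Um <- U
    Up[nd, cp] <- Up[nd, cp] + h; Um[nd, cp] <- Um[nd, cp] - h
    ap <- cardiopatch:::cpp_assemble(mesh$nodes, Up, mesh$elems, prm,
                                     fib$f0, fib$s0, mesh$endo_faces, 0.4, FALSE)
    am <- cardiopatch:::cpp_assemble(mesh$nodes, Um, mesh$elems, prm,
                                     fib$f0, fib$s0, mesh$endo_faces, 0.4, FALSE)
    kfd <- ((ap$fint - ap$fext) - (am$fint - am$fext)) / (2 * h)
    kcol <- as.numeric(K[, dof])
    expect_lt(max(abs(kfd - kcol)) / max(abs(kcol), 1), 1e-5)
  }
})

test_that("constant-strain patch test is exact on a distorted mesh", {
  box <- make_box_mesh()
  fib <- uniform_fibers(box)
  A <- matrix(c(0.02, 0.01, 0, 0.005, -0.015, 0.01, 0, 0.02, 0.01), 3, 3)
  target <- box$nodes %*% t(A)
  dc <- rowSums((box$nodes -
                   matrix(colMeans(box$nodes), nrow(box$nodes), 3,
                          byrow = TRUE))^2)
  interior <- which.min(dc)
  bn <- setdiff(seq_len(nrow(box$nodes)), interior)
  cons <- do.call(rbind, lapply(1:3, function(d)
    data.frame(node = bn, dof = d, value = target[bn, d])))
  mm <- material_map(infarct = iso_params(E = 50, nu = 0.3))
  sim <- solve_inflation(box, fib, mm, load_protocol(0, 1),
                         base_fix = "none", constraints = cons)
  expect_lt(max(abs(sim$u[interior, ] - target[interior, ])), 1e-9)
})

test_that("Newton converges quadratically near the solution", {
  h <- healthy_sim()
  r <- h$sim$log[[length(h$sim$log)]]$residuals
  r <- r[r > 1e-9 * max(r)]            # drop round-off-floored iterates
  expect_gte(length(r), 3)
  orders <- vapply(3:length(r), function(k)
    log(r[k] / r[k - 1]) / log(r[k - 1] / r[k - 2]), numeric(1))
  expect_gte(max(orders), 1.8)
})

test_that("pressurized thick sphere matches the Lame closed form", {
  expect_lt(lame_errors()[3], 0.05)
})

test_that("external pressure work balances stored energy at small load", {
  mesh <- build_idealized_lv(make_lv_presets("healthy"), c(12, 8, 2))
  fib <- assign_fiber_field(mesh)
  s <- solve_inflation(mesh, fib, material_map(), load_protocol(0.05, 10))
  expect_equal(pressure_work(s), strain_energy(s), tolerance = 0.01)
})

test_that("peak displacement converges under mesh refinement", {
  p <- make_lv_presets("healthy")
  pd <- vapply(list(c(8, 6, 2), c(12, 9, 3), c(16, 12, 4)), function(r) {
    m <- build_idealized_lv(p, r)
    s <- solve_inflation(m, assign_fiber_field(m), material_map(),
                         load_protocol(1, 5))
    tail(s$curves$peak_disp_mm, 1)
  }, numeric(1))
  expect_lt(abs(pd[3] - pd[2]) / pd[3], 0.03)
})

test_that("the solver is deterministic", {
  mesh <- build_idealized_lv(make_lv_presets("healthy"), c(10, 6, 1))
  fib <- assign_fiber_field(mesh)
  s1 <- solve_inflation(mesh, fib, material_map(), load_protocol(0.5, 5))
  s2 <- solve_inflation(mesh, fib, material_map(), load_protocol(0.5, 5))
  expect_identical(s1$u, s2$u)
  expect_identical(s1$curves, s2$curves)
})

test_that("non-convergence raises an explicit failure carrying the log", {
  mesh <- build_idealized_lv(make_lv_presets("healthy"), c(8, 4, 1))
  fib <- assign_fiber_field(mesh)
  err <- tryCatch(
    solve_inflation(mesh, fib, material_map(),
                    load_protocol(500, 1, max_newton_iters = 2)),
    error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "failed to converge")
  expect_true(!is.null(err$log))
})

test_that("equibiaxial extension matches the incompressible closed form", {
  z <- equibiaxial_extension_test(hgo_params(), 1)
  expect_identical(c(z$sigma_ff, z$sigma_ss), c(0, 0))
  m <- hgo_params(kappa = 5e4)   # incompressible limit for the oracle
  lam <- 1.1
  r <- equibiaxial_extension_test(m, lam)
  I1 <- 2 * lam^2 + lam^-4; I4 <- lam^2
  p1 <- m$a / 2 * exp(m$b * (I1 - 3))
  p4f <- m$a_f * (I4 - 1) * exp(m$b_f * (I4 - 1)^2)
  p4s <- m$a_s * (I4 - 1) * exp(m$b_s * (I4 - 1)^2)
  s_ff <- 2 * p1 * (lam^2 - lam^-4) + 2 * p4f * lam^2
  s_ss <- 2 * p1 * (lam^2 - lam^-4) + 2 * p4s * lam^2
  expect_equal(r$sigma_ff, s_ff, tolerance = 5e-3)
  expect_equal(r$sigma_ss, s_ss, tolerance = 5e-3)
  expect_gt(r$sigma_ff, r$sigma_ss)  # fiber direction stiffer
  expect_gt(r$sigma_ss, 0)
  # isotropy symmetry
  e <- equibiaxial_extension_test(iso_params(), 1.1)
  expect_equal(e$sigma_ff, e$sigma_ss, tolerance = 1e-12)
})

test_that("uniaxial extension: small-strain slope and fiber anisotropy", {
  expect_identical(uniaxial_test(hgo_params(), 1)$sigma_axial, 0)
  u <- uniaxial_test(iso_params(E = 50, nu = 0.49), 1.001)
  expect_equal(u$sigma_axial / 0.001, 50, tolerance = 0.01)
  on_axis <- uniaxial_test(hgo_params(), 1.1, angle_deg = 0)$sigma_axial
  off_axis <- uniaxial_test(hgo_params(), 1.1, angle_deg = 45)$sigma_axial
  expect_gt(on_axis, off_axis)
  expect_error(uniaxial_test(hgo_params(), -1), "lambda")
})

test_that("dead-load mode is available and close to follower at small load", {
  mesh <- build_idealized_lv(make_lv_presets("healthy"), c(10, 6, 1))
  fib <- assign_fiber_field(mesh)
  sf <- solve_inflation(mesh, fib, material_map(), load_protocol(0.02, 2))
  sd_ <- solve_inflation(mesh, fib, material_map(),
                         load_protocol(0.02, 2, follower = FALSE))
  expect_equal(max(abs(sd_$u - sf$u)), 0, tolerance = 0.02 * max(abs(sf$u)))
})
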