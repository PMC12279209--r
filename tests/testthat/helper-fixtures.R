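# shared fixtures and independent oracles

# cache for expensive meshes/solves shared across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# central finite-difference Cauchy stress from an energy function:
# sigma = (1/J) dPsi/dF F^T
fd_cauchy <- function(psifun, F, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fm <- F
    Fp[i, j] <- Fp[i, j] + h
    Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (psifun(Fp) - psifun(Fm)) / (2 * h)
  }
  P %*% t(F) / det(F)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2+b^2-c^2-d^2, 2*(b*c-a*d),     2*(b*d+a*c),
           2*(b*c+a*d),     a^2-b^2+c^2-d^2, 2*(c*d-a*b),
           2*(b*d-a*c),     2*(c*d+a*b),     a^2-b^2-c^2+d^2),
         3, 3, byrow = TRUE)
}

random_sym3 <- function(scale = 10) {
  A <- matrix(rnorm(9, 0, scale), 3, 3)
  (A + t(A)) / 2
}

random_F <- function(spread = 0.08) {
  repeat {
    F <- diag(3) + matrix(rnorm(9, 0, spread), 3, 3)
    if (det(F) > 0.3) return(F)
  }
}

# closed-form largest eigenvalue of a symmetric 3x3 (trigonometric method);
# independent of eigen()
analytic_max_eig <- function(A) {
  q <- mean(diag(A))
  B <- A - q * diag(3)
  p <- sqrt(sum(B^2) / 6)
  if (p < 1e-300) return(q)
  detB <- det(B / p)
  r <- max(-1, min(1, detB / 2))
  q + 2 * p * cos(acos(r) / 3)
}

# brute-force screen classifier applying the thresholds verbatim
brute_force_classify <- function(s, m, p) {
  n <- length(s)
  out <- character(n)
  for (i in seq_len(n)) {
    if (s[i] == 0 || p[i] == 0) { out[i] <- "excluded"; next }
    up <- (m[i] / s[i] > 1.2) || (m[i] / p[i] > 1.1)
    dn <- (m[i] / s[i] < 0.8) || (m[i] / p[i] < 0.9)
    out[i] <- if (up && dn) "conflict" else if (up) "group1"
      else if (dn) "group2" else "neither"
  }
  out
}

# distorted box mesh (2x2x2 hexes) dressed as a minimal lv_mesh for the
# solver; no pressure faces, constraints supplied by the caller
make_box_mesh <- function(distort = 0.15, seed = 3) {
  g <- 0:2
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))[, 1:3]
  set.seed(seed)
  jit <- matrix(runif(length(nodes), -distort, distort), nrow(nodes), 3)
  nodes <- nodes + jit   # distort all nodes; keeps hexes valid at 0.15
  nid <- function(i, j, k) i + 3 * j + 9 * k + 1
  elems <- NULL
  for (k in 0:1) for (j in 0:1) for (i in 0:1)
    elems <- rbind(elems, c(nid(i, j, k), nid(i + 1, j, k),
                            nid(i + 1, j + 1, k), nid(i, j + 1, k),
                            nid(i, j, k + 1), nid(i + 1, j, k + 1),
                            nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1)))
  structure(list(nodes = nodes, elems = elems,
                 region = rep("infarct", nrow(elems)),
                 node_ijk = NULL, elem_ijk = NULL,
                 endo_faces = matrix(0L, 0, 4), endo_face_elem = integer(0),
                 epi_faces = matrix(0L, 0, 4), epi_face_elem = integer(0),
                 base_faces = matrix(0L, 0, 4), base_nodes = integer(0),
                 resolution = c(2, 2, 2), param = NULL,
                 preset = list(name = "box"), patch = NULL),
            class = "lv_mesh")
}

# uniform fiber field for non-LV meshes
uniform_fibers <- function(mesh, f0 = c(1, 0, 0), s0 = c(0, 1, 0)) {
  ne <- nrow(mesh$elems)
  structure(list(f0 = matrix(f0, ne * 8, 3, byrow = TRUE),
                 s0 = matrix(s0, ne * 8, 3, byrow = TRUE),
                 n0 = matrix(c(0, 0, 1), ne * 8, 3, byrow = TRUE),
                 helix_deg = rep(NA_real_, ne * 8), n_elem = ne),
            class = "fiber_field")
}

# thick-sphere (hemisphere) fixture for the Lame benchmark
sphere_preset <- function(resolution) {
  lv_preset(name = "sphere", endo_semi_axes = c(10, 10),
            wall_thickness_base = 5, infarct_thickness = 5,
            truncation_height = 0.5, apex_cap_radius = 1,
            resolution = resolution)
}

# Lame thick-walled sphere: radial displacement at radius r under internal
# pressure p (linear elasticity closed form)
lame_u <- function(r, a, b, p, E, nu) {
  (p * a^3 / (b^3 - a^3)) / E *
    ((1 - 2 * nu) * r + (1 + nu) * b^3 / (2 * r^2))
}

# relative errors of the three-mesh Lame benchmark, shared across files
lame_errors <- function() cached("lame_errors", {
  exact <- lame_u(10, 10, 15, 0.01, 50, 0.49)
  vapply(list(c(8, 6, 2), c(12, 9, 3), c(16, 12, 4)), function(res)
    abs(solve_lame_sphere(res)$u_inner / exact - 1), numeric(1))
})

solve_lame_sphere <- function(resolution, p = 0.01, E = 50, nu = 0.49) {
  mesh <- build_idealized_lv(sphere_preset(resolution))
  fib <- assign_fiber_field(mesh)
  nc <- mesh$resolution[1]
  # symmetry: base plane moves only radially; pin rotation about z on the
  # theta = 0 and theta = 90 degree node columns (true zeros of the radial
  # solution, so no artificial stiffness)
  pin_y <- which(mesh$node_ijk[, 1] == 0)
  pin_x <- which(mesh$node_ijk[, 1] == nc / 4)
  cons <- rbind(data.frame(node = pin_y, dof = 2, value = 0),
                data.frame(node = pin_x, dof = 1, value = 0))
  mm <- material_map(healthy = iso_params(E = E, nu = nu))
  sim <- solve_inflation(mesh, fib, mm,
                         load_protocol(p, 1, residual_rtol = 1e-10),
                         base_fix = "normal", constraints = cons)
  # radial displacement on the endocardium, away from the apex cap
  sel <- mesh$node_ijk[, 3] == 0 & mesh$node_ijk[, 2] <= mesh$resolution[2] / 2
  X <- mesh$nodes[sel, ]
  rr <- sqrt(rowSums(X^2))
  ur <- rowSums(sim$u[sel, ] * X) / rr
  list(u_inner = mean(ur), sim = sim)
}

# desk-scale ICM simulations shared by efficacy and stress-ratio tests
icm_resolution <- c(24, 14, 2)
icm_protocol <- load_protocol(1, 10, max_newton_iters = 50)

icm_unpatched <- function() cached("icm_unpatched", {
  mesh <- build_idealized_lv(make_lv_presets("icm"), icm_resolution)
  fib <- assign_fiber_field(mesh)
  sim <- solve_inflation(mesh, fib, material_map(), icm_protocol)
  list(mesh = mesh, sim = sim)
})

icm_patched <- function() cached("icm_patched", {
  base <- icm_unpatched()
  pm <- attach_patch(base$mesh, patch_spec(20, 0.3))
  fib <- assign_fiber_field(pm)
  sim <- solve_inflation(pm, fib, material_map(), icm_protocol)
  list(mesh = pm, sim = sim)
})

healthy_sim <- function() cached("healthy_sim", {
  mesh <- build_idealized_lv(make_lv_presets("healthy"), c(24, 14, 2))
  fib <- assign_fiber_field(mesh)
  sim <- solve_inflation(mesh, fib, material_map(), load_protocol(1, 10))
  list(mesh = mesh, sim = sim)
})
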