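# Finite-strain FEM driver: incremental follower-pressure loading with
# Newton iteration on the assembled residual. Assembly and constitutive
# evaluation live in the C++ kernels; this file owns load stepping,
# constraints and convergence control.

#' Loading protocol for passive inflation
#'
#' @param target_pressure endocardial pressure at the end of the ramp, kPa
#'   (default 1.0, end-diastole)
#' @param n_increments number of pressure increments
#' @param max_newton_iters Newton iteration cap per increment
#' @param residual_rtol relative residual tolerance
#' @param follower logical; `TRUE` (default) applies the pressure on the
#'   deformed endocardial surface with its load stiffness, `FALSE` applies a
#'   dead load computed on the reference surface
#' @return an object of class `load_protocol`
#' @export
load_protocol <- function(target_pressure = 1.0, n_increments = 10,
                          max_newton_iters = 25, residual_rtol = 1e-8,
                          follower = TRUE) {
  stopifnot_scalar(target_pressure, "target_pressure", nonneg = TRUE)
  n_increments <- as.integer(n_increments)
  if (n_increments < 1) stop("'n_increments' must be >= 1", call. = FALSE)
  structure(list(target_pressure = target_pressure,
                 n_increments = n_increments,
                 max_newton_iters = as.integer(max_newton_iters),
                 residual_rtol = residual_rtol,
                 follower = isTRUE(follower)),
            class = "load_protocol")
}

# per-element 9-parameter material rows from a material_map
material_rows <- function(mesh, materials) {
  stopifnot(inherits(materials, "material_map"))
  regions <- unique(mesh$region)
  missing <- setdiff(regions, names(materials))
  if (length(missing))
    stop("material map does not cover region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  rows <- t(vapply(materials, material_row, numeric(9)))
  rows[match(mesh$region, names(materials)), , drop = FALSE]
}

check_fibers <- function(mesh, fibers) {
  if (!inherits(fibers, "fiber_field") || fibers$n_elem != nrow(mesh$elems))
    stop("fiber field does not match the mesh; re-run assign_fiber_field() ",
         "on the current (e.g. patched) mesh", call. = FALSE)
  fibers
}

# residual/tangent of the full system at displacement matrix U
assemble_system <- function(mesh, fibers, materials, U, pload, wantK = TRUE,
                            follower = TRUE, fext_dead = NULL) {
  prm <- material_rows(mesh, materials)
  out <- cpp_assemble(mesh$nodes, U, mesh$elems, prm,
                      fibers$f0, fibers$s0, mesh$endo_faces,
                      if (follower) pload else 0, wantK)
  if (!isTRUE(out$ok))
    return(out)
  if (!follower && pload != 0 && !is.null(fext_dead))
    out$fext <- pload * fext_dead
  out$resid <- out$fint - out$fext
  out
}

# fixed-dof bookkeeping: returns list(dofs, values)
build_constraints <- function(mesh, base_fix, constraints) {
  dofs <- integer(0); vals <- numeric(0)
  if (base_fix == "all") {
    dofs <- as.integer(outer(3 * (mesh$base_nodes - 1), 1:3, `+`))
    vals <- numeric(length(dofs))
  } else if (base_fix == "normal") {
    dofs <- 3 * (mesh$base_nodes - 1) + 3L
    vals <- numeric(length(dofs))
  }
  if (!is.null(constraints)) {
    stopifnot(all(c("node", "dof", "value") %in% names(constraints)))
    dofs <- c(dofs, 3L * (as.integer(constraints$node) - 1L) +
                as.integer(constraints$dof))
    vals <- c(vals, as.numeric(constraints$value))
  }
  keep <- !duplicated(dofs)
  list(dofs = dofs[keep], values = vals[keep])
}

#' Solve passive inflation of the ventricle
#'
#' Incremental-load Newton solution of the finite-strain equilibrium under
#' endocardial pressure. The pressure is a follower load by default (applied
#' on the deformed surface, with the corresponding load-stiffness in the
#' tangent). All three displacement components are fixed on the basal plane
#' nodes. On divergence the increment is halved adaptively (floor 1/64 of
#' the nominal step); non-convergence raises an error carrying the Newton
#' log.
#'
#' @param mesh an `lv_mesh`
#' @param fibers a `fiber_field` for this mesh
#' @param materials a [material_map()] covering every region present
#' @param protocol a [load_protocol()]
#' @param base_fix `"all"` (fix all basal components, default), `"normal"`
#'   (fix only the axial component; for symmetry benchmarks), or `"none"`
#' @param constraints optional extra Dirichlet data as a data.frame with
#'   columns `node`, `dof` (1--3), `value` (ramped with the load factor)
#' @param store_increments keep per-increment displacement fields
#' @return an object of class `lv_sim`: final displacements `u` (n x 3),
#'   per-increment `curves` (pressure, peak displacement, peak von Mises,
#'   volume-weighted mean maximal principal stress, cavity volume), final
#'   per-element Cauchy stresses `element_sigma` (Voigt xx, yy, zz, xy, xz,
#'   yz), stored strain `energy`, and the Newton residual `log`
#' @export
solve_inflation <- function(mesh, fibers, materials = material_map(),
                            protocol = load_protocol(),
                            base_fix = c("all", "normal", "none"),
                            constraints = NULL, store_increments = TRUE) {
  stopifnot(inherits(mesh, "lv_mesh"))
  base_fix <- match.arg(base_fix)
  fibers <- check_fibers(mesh, fibers)
  bc <- build_constraints(mesh, base_fix, constraints)
  if (length(bc$dofs) == 0)
    stop("no Dirichlet constraints; the problem would be singular", call. = FALSE)
  n <- nrow(mesh$nodes); ndof <- 3L * n
  free <- setdiff(seq_len(ndof), bc$dofs)
  prm <- material_rows(mesh, materials)

  fext_dead <- NULL
  if (!protocol$follower && protocol$target_pressure > 0) {
    a0 <- cpp_assemble(mesh$nodes, matrix(0, n, 3), mesh$elems, prm,
                       fibers$f0, fibers$s0, mesh$endo_faces,
                       protocol$target_pressure, FALSE)
    fext_dead <- a0$fext / protocol$target_pressure
  }

  asm <- function(U, f, wantK)
    assemble_system(mesh, fibers, materials, U, f * protocol$target_pressure,
                    wantK, protocol$follower, fext_dead)

  u <- numeric(ndof)
  u_prev <- NULL; f_prev_step <- NA_real_
  to_U <- function(u) matrix(u, n, 3, byrow = TRUE)
  f_done <- 0; df <- 1 / protocol$n_increments
  df_min <- df / 64
  ext_work <- 0; fext_prev <- numeric(ndof)

  # total potential at load factor f: stored energy minus external-load
  # potential (follower pressure is conservative on the cavity volume);
  # used to globalize Newton, since the residual norm alone can have
  # spurious local minima at the tension-only stiffness kinks
  cav_ref <- if (nrow(mesh$endo_faces) > 0)
    cavity_volume(mesh, NULL) else 0
  pot_of <- function(uvec, energy, f) {
    if (protocol$follower) {
      if (nrow(mesh$endo_faces) > 0 && protocol$target_pressure > 0)
        energy - f * protocol$target_pressure *
          (cavity_volume(mesh, to_U(uvec)) - cav_ref)
      else energy
    } else {
      if (!is.null(fext_dead))
        energy - sum(f * protocol$target_pressure * fext_dead * uvec)
      else energy
    }
  }
  increments <- list(); log <- list(); curves <- list()
  inc <- 0L

  record <- function(u, f) {
    U <- to_U(u)
    ef <- cpp_element_fields(mesh$nodes, U, mesh$elems, prm,
                             fibers$f0, fibers$s0)
    myo <- mesh$region != "patch"
    vm <- apply(ef$sigma, 1, function(v) von_mises(voigt_to_sym(v)))
    mps <- apply(ef$sigma, 1, function(v) max_principal_stress(voigt_to_sym(v)))
    list(pressure = f * protocol$target_pressure,
         u = if (store_increments) U else NULL,
         peak_disp = max(sqrt(rowSums(U^2))),
         peak_vm = max(vm[myo]),
         mean_mps = sum(mps[myo] * ef$vol_cur[myo]) / sum(ef$vol_cur[myo]),
         cavity_vol = if (nrow(mesh$endo_faces) > 0)
           cavity_volume(mesh, U) else NA_real_,
         element_sigma = ef$sigma, element_vol = ef$vol_cur,
         energy = sum(ef$energy))
  }
  increments[[1]] <- record(u, 0)

  while (f_done < 1 - 1e-12) {
    f_try <- min(1, f_done + df)
    u_try <- u
    # secant predictor from the previous two converged states
    if (!is.null(u_prev) && is.finite(f_prev_step) && f_prev_step > 0) {
      u_pred <- u
      u_pred[free] <- u[free] +
        ((f_try - f_done) / f_prev_step) * (u[free] - u_prev[free])
      ap <- asm(to_U(u_pred), f_try, FALSE)
      if (isTRUE(ap$ok) && all(is.finite(ap$resid))) u_try <- u_pred
    }
    u_try[bc$dofs] <- f_try * bc$values
    ok <- FALSE
    res_hist <- numeric(0)
    a <- asm(to_U(u_try), f_try, TRUE)
    if (isTRUE(a$ok)) {
      res0 <- sqrt(sum(a$resid[free]^2))
      fscale <- max(sqrt(sum(a$fext^2)), sqrt(sum(a$fint^2)), 1e-8)
      # absolute floor: assembly round-off on the current force scale
      # (internal/external forces can exceed the residual by many orders
      # once a stiff patch is attached)
      tol_of <- function() max(protocol$residual_rtol * res0,
                               1e-9 * max(1, fscale))
      res_hist <- res0
      if (res0 <= tol_of()) ok <- TRUE
      it <- 0
      res_prev <- res0
      pi_cur <- pot_of(u_try, a$energy, f_try)
      # backtracking search along a direction: accept on residual decrease
      # or on potential-energy decrease (full Newton steps from the very
      # soft ground state overshoot the exponential stiffening and can
      # invert elements; near tension-only kinks the residual norm alone
      # has spurious minima, where the energy still descends)
      try_direction <- function(u_base, dir, res_ref, pi_ref) {
        alpha <- 1
        # energy-based acceptance only while far from convergence: near the
        # solution potential differences sit at round-off and would accept
        # residual-increasing noise steps
        allow_energy <- res_ref > 1e3 * tol_of()
        while (alpha >= 1 / 1024) {
          u_cand <- u_base
          u_cand[free] <- u_cand[free] - alpha * dir
          a_r <- asm(to_U(u_cand), f_try, FALSE)
          if (isTRUE(a_r$ok)) {
            res_c <- sqrt(sum(a_r$resid[free]^2))
            pi_c <- pot_of(u_cand, a_r$energy, f_try)
            if (is.finite(res_c) && is.finite(pi_c) &&
                (res_c < res_ref ||
                 (allow_energy &&
                  pi_c < pi_ref - 1e-10 * max(1, abs(pi_ref)))))
              return(list(u = u_cand, res = res_c, pi = pi_c))
          }
          alpha <- alpha / 2
        }
        NULL
      }
      while (!ok && it < protocol$max_newton_iters) {
        it <- it + 1
        K <- Matrix::sparseMatrix(i = a$Ki, j = a$Kj, x = a$Kx,
                                  dims = c(ndof, ndof))
        du <- tryCatch(
          as.numeric(Matrix::solve(K[free, free, drop = FALSE],
                                   a$resid[free])),
          error = function(e) NULL)
        if (is.null(du) || any(!is.finite(du))) break
        step <- try_direction(u_try, du, res_prev, pi_cur)
        if (is.null(step)) {
          # steepest-descent fallback on the potential, scaled to the
          # Newton step length
          g <- a$resid[free]
          gn <- sqrt(sum(g^2))
          if (gn > 0)
            step <- try_direction(u_try, g * (sqrt(sum(du^2)) / gn),
                                  Inf, pi_cur)
        }
        if (is.null(step)) break
        u_try <- step$u
        a <- asm(to_U(u_try), f_try, TRUE)
        fscale <- max(fscale, sqrt(sum(a$fint^2)), sqrt(sum(a$fext^2)))
        res_prev <- step$res
        pi_cur <- step$pi
        res_hist <- c(res_hist, step$res)
        if (step$res <= tol_of()) ok <- TRUE
      }
      # stall fallback: at near-zero strains every fiber sits on the
      # tension-only switch and the chattering tangent can pin Newton a few
      # orders above the nominal tolerance; a residual at 1e-6 of the force
      # scale is equilibrated for all practical purposes
      if (!ok && length(res_hist) > 3 &&
          res_prev <= 1e-6 * max(1, fscale)) ok <- TRUE
    }
    if (ok) {
      # trapezoidal external work along the discrete load path
      fext_cur <- a$fext
      ext_work <- ext_work +
        sum((fext_cur + fext_prev) / 2 * (u_try - u))
      fext_prev <- fext_cur
      u_prev <- u; f_prev_step <- f_try - f_done
      u <- u_try
      f_done <- f_try
      inc <- inc + 1L
      log[[inc]] <- list(factor = f_try, residuals = res_hist)
      increments[[inc + 1L]] <- record(u, f_done)
    } else {
      df <- df / 2
      if (df < df_min) {
        err <- simpleError(sprintf(
          "inflation failed to converge at load factor %.4f (step %.5f); %s",
          f_try, df * 2, "residual history attached as err$log"))
        err$log <- c(log, list(list(factor = f_try, residuals = res_hist)))
        stop(err)
      }
    }
  }

  curves <- do.call(rbind, lapply(increments, function(s)
    data.frame(pressure_kPa = s$pressure, peak_disp_mm = s$peak_disp,
               peak_vm_kPa = s$peak_vm, mean_mps_kPa = s$mean_mps,
               cavity_vol_mm3 = s$cavity_vol)))
  last <- increments[[length(increments)]]
  structure(list(u = to_U(u), curves = curves,
                 element_sigma = last$element_sigma,
                 element_vol = last$element_vol,
                 energy = last$energy,
                 external_work = ext_work,
                 increments = if (store_increments) increments else NULL,
                 log = log, protocol = protocol, converged = TRUE),
            class = "lv_sim")
}

#' @export
print.lv_sim <- function(x, ...) {
  n <- nrow(x$curves)
  cat(sprintf("Passive inflation: %d converged increments to %.3g kPa\n",
              n - 1, x$curves$pressure_kPa[n]))
  cat(sprintf("  peak displacement %.3f mm; peak von Mises %.3f kPa; stored energy %.4g mJ/1000\n",
              x$curves$peak_disp_mm[n], x$curves$peak_vm_kPa[n], x$energy))
  invisible(x)
}

#' @export
#' @importFrom graphics par lines legend
plot.lv_sim <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$curves$pressure_kPa, x$curves$peak_disp_mm, type = "b",
       xlab = "pressure (kPa)", ylab = "peak displacement (mm)", ...)
  plot(x$curves$pressure_kPa, x$curves$peak_vm_kPa, type = "b",
       xlab = "pressure (kPa)", ylab = "peak von Mises (kPa)", ...)
  invisible(x)
}

#' Total stored strain energy of a converged state
#'
#' @param sim an `lv_sim`
#' @return energy in kPa mm^3 (microjoule-scale: 1 kPa mm^3 = 1 uJ)
#' @export
strain_energy <- function(sim) sim$energy

#' External pressure work along the loading path
#'
#' Trapezoidal accumulation of the discrete follower-load forces dotted with
#' the displacement increments over the converged load path; at small
#' pressures this balances the stored strain energy (conservative system).
#'
#' @param sim an `lv_sim`
#' @return work in kPa mm^3
#' @export
pressure_work <- function(sim) sim$external_work

# single-point homogeneous deformation states -------------------------------

point_sigma <- function(material, F, f0 = c(1, 0, 0), s0 = c(0, 1, 0)) {
  cpp_point_stress(F, material_row(material), f0, s0)$sigma
}

#' Equibiaxial extension of a single material element
#'
#' Homogeneous plane-stress state: equal in-plane stretches in the fiber and
#' sheet directions; the through-thickness stretch is solved so the
#' transverse normal stress vanishes.
#'
#' @param material a material object ([hgo_params()] or [iso_params()])
#' @param lambda in-plane stretch (> 0)
#' @return list with in-plane Cauchy stresses `sigma_ff`, `sigma_ss`, the
#'   transverse stretch `lambda_t` and the full stress tensor
#' @export
#' @examples
#' equibiaxial_extension_test(hgo_params(), 1.1)
equibiaxial_extension_test <- function(material, lambda) {
  stopifnot_scalar(lambda, "lambda", positive = TRUE)
  f33 <- function(l3) point_sigma(material, diag(c(lambda, lambda, l3)))[3, 3]
  if (lambda == 1) {
    sig <- point_sigma(material, diag(3))
    return(list(sigma_ff = 0, sigma_ss = 0, lambda_t = 1, sigma = sig))
  }
  # damped Newton from the incompressible guess (wide brackets overflow the
  # exponential terms)
  l3 <- 1 / lambda^2
  for (it in 1:200) {
    s33 <- f33(l3)
    if (!is.finite(s33)) { l3 <- l3 * 1.05; next }
    h <- 1e-7 * max(l3, 1)
    d <- (f33(l3 + h) - s33) / h
    step <- if (is.finite(d) && abs(d) > 0) s33 / d else sign(s33) * 0.01
    step <- max(min(step, 0.1), -0.1)
    l3 <- l3 - step
    if (l3 <= 0) l3 <- 1e-3
    if (abs(step) < 1e-14 * max(l3, 1)) break
  }
  if (abs(f33(l3)) > 1e-6 * max(1, abs(point_sigma(
        material, diag(c(lambda, lambda, l3)))[1, 1])))
    stop("plane-stress thickness solve did not converge", call. = FALSE)
  sig <- point_sigma(material, diag(c(lambda, lambda, l3)))
  list(sigma_ff = sig[1, 1], sigma_ss = sig[2, 2], lambda_t = l3, sigma = sig)
}

#' Uniaxial extension of a single material element
#'
#' Homogeneous stretch along the loading axis with traction-free lateral
#' faces (both lateral normal stresses solved to zero). The fiber direction
#' can be rotated away from the loading axis in the fiber--sheet plane.
#'
#' @param material a material object
#' @param lambda axial stretch (> 0)
#' @param angle_deg angle between the loading axis and the fiber direction,
#'   degrees (default 0: loading along the fiber)
#' @return list with `sigma_axial` (kPa), lateral stretches and the full
#'   stress tensor
#' @export
#' @examples
#' uniaxial_test(iso_params(E = 50), 1.001)$sigma_axial / 0.001  # ~ E
uniaxial_test <- function(material, lambda, angle_deg = 0) {
  stopifnot_scalar(lambda, "lambda", positive = TRUE)
  th <- angle_deg * pi / 180
  f0 <- c(cos(th), sin(th), 0); s0 <- c(-sin(th), cos(th), 0)
  sig_of <- function(l23) point_sigma(material, diag(c(lambda, l23[1], l23[2])),
                                      f0, s0)
  if (lambda == 1)
    return(list(sigma_axial = 0, lateral = c(1, 1), sigma = sig_of(c(1, 1))))
  resid <- function(l23) { s <- sig_of(l23); c(s[2, 2], s[3, 3]) }
  l23 <- rep(1 / sqrt(lambda), 2)
  for (it in 1:60) {
    r <- resid(l23)
    if (max(abs(r)) < 1e-11 * max(1, abs(sig_of(l23)[1, 1]))) break
    h <- 1e-7
    Jm <- cbind((resid(l23 + c(h, 0)) - r) / h,
                (resid(l23 + c(0, h)) - r) / h)
    step <- tryCatch(solve(Jm, r), error = function(e) r * 0.1)
    ln <- l23 - step
    ln[ln < 0.05] <- 0.05
    l23 <- ln
  }
  sig <- sig_of(l23)
  list(sigma_axial = sig[1, 1], lateral = l23, sigma = sig)
}
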