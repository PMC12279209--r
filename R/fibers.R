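# Rule-based myofiber architecture: helix angle +60 deg at the basal
# endocardium, -60 deg at the basal epicardium, varying linearly across the
# wall, with the angle magnitude tapering linearly to 0 toward the apex.

# Gauss-point corner signs, matching the C++ kernel ordering
QP_SIGNS <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                  c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))

# the helix-angle rule itself: xi transmural in [0,1] (0 = endo, 1 = epi),
# lambda longitudinal in [0,1] (1 = base, 0 = apex)
helix_angle <- function(xi, lambda, angle_endo = 60, angle_epi = -60) {
  lambda * (angle_endo + xi * (angle_epi - angle_endo))
}

#' Assign the rule-based fiber field
#'
#' Builds per-quadrature-point orthonormal (fiber, sheet, sheet-normal)
#' triads. The helix angle is
#' \deqn{\alpha(\xi, \lambda) = \lambda\,[\alpha_{endo} + \xi\,(\alpha_{epi} -
#' \alpha_{endo})],}
#' where \eqn{\xi \in [0, 1]} is the transmural coordinate (0 = endo, 1 =
#' epi) and \eqn{\lambda} the normalized longitudinal coordinate (1 at the
#' base, 0 at the apex), so the angle interpolates linearly from +60 to -60
#' degrees across the basal wall and tapers to 0 at the apex. The fiber
#' direction is the circumferential direction rotated by \eqn{\alpha} about
#' the transmural axis; the sheet direction is transmural; the sheet-normal
#' completes the triad.
#'
#' Patch elements (isotropic) receive placeholder triads and `NA` helix
#' angles.
#'
#' @param mesh an `lv_mesh`
#' @param angle_endo,angle_epi helix angles at the basal endocardium and
#'   epicardium, degrees
#' @return an object of class `fiber_field` with per-quadrature-point unit
#'   vectors `f0`, `s0`, `n0` (rows ordered element-major, 8 Gauss points per
#'   element) and `helix_deg`
#' @export
#' @examples
#' mesh <- build_idealized_lv(make_lv_presets("healthy"),
#'                            resolution = c(16, 12, 2))
#' fib <- assign_fiber_field(mesh)
#' range(fib$helix_deg, na.rm = TRUE)
assign_fiber_field <- function(mesh, angle_endo = 60, angle_epi = -60) {
  stopifnot(inherits(mesh, "lv_mesh"))
  pm <- mesh$param
  nt <- mesh$resolution[3]
  ne <- nrow(mesh$elems)
  g <- 1 / sqrt(3)
  nq <- ne * 8L
  f0 <- matrix(0, nq, 3); s0 <- matrix(0, nq, 3); n0 <- matrix(0, nq, 3)
  helix <- rep(NA_real_, nq)
  dth <- 2 * pi / mesh$resolution[1]
  for (e in seq_len(ne)) {
    rows <- (e - 1) * 8 + 1:8
    if (mesh$region[e] == "patch") {
      f0[rows, ] <- matrix(c(1, 0, 0), 8, 3, byrow = TRUE)
      s0[rows, ] <- matrix(c(0, 1, 0), 8, 3, byrow = TRUE)
      n0[rows, ] <- matrix(c(0, 0, 1), 8, 3, byrow = TRUE)
      next
    }
    ijk <- mesh$elem_ijk[e, ]
    th0 <- pm$theta[ijk[1] + 1]; ph0 <- pm$phi[ijk[2] + 1]
    dph <- pm$phi[ijk[2] + 2] - ph0
    for (q in 1:8) {
      sg <- QP_SIGNS[q, ]
      # local (xi, eta, zeta) = (phi-, theta-, transmural-direction)
      ph <- ph0 + (sg[1] * g + 1) / 2 * dph
      th <- th0 + (sg[2] * g + 1) / 2 * dth
      xi_t <- (ijk[3] + (sg[3] * g + 1) / 2) / nt
      lam <- (pm$phi_a - ph) / (pm$phi_a - pm$phi_b)
      alpha <- helix_angle(xi_t, lam, angle_endo, angle_epi) * pi / 180
      nh <- drop(ellipsoid_normal(th, ph, pm$a_r, pm$a_z))
      ch <- c(-sin(th), cos(th), 0)
      lh <- c(nh[2] * ch[3] - nh[3] * ch[2],
              nh[3] * ch[1] - nh[1] * ch[3],
              nh[1] * ch[2] - nh[2] * ch[1])
      lh <- lh / sqrt(sum(lh^2))
      fv <- cos(alpha) * ch + sin(alpha) * lh
      r <- rows[q]
      f0[r, ] <- fv
      s0[r, ] <- nh
      n0[r, ] <- c(fv[2] * nh[3] - fv[3] * nh[2],
                   fv[3] * nh[1] - fv[1] * nh[3],
                   fv[1] * nh[2] - fv[2] * nh[1])
      helix[r] <- alpha * 180 / pi
    }
  }
  structure(list(f0 = f0, s0 = s0, n0 = n0, helix_deg = helix, n_elem = ne),
            class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  cat(sprintf("Fiber field: %d elements x 8 quadrature points\n", x$n_elem))
  if (any(!is.na(x$helix_deg)))
    cat(sprintf("  helix angle range: %.1f to %.1f deg\n",
                min(x$helix_deg, na.rm = TRUE), max(x$helix_deg, na.rm = TRUE)))
  invisible(x)
}
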