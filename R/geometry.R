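# Idealized truncated-ellipsoid LV shell mesh: structured tri-linear
# hexahedra parameterized by (circumferential theta, longitudinal phi,
# transmural xi). Conventions: LV long axis = z, base plane z = 0, apex at
# z < 0. The degenerate apex pole is excluded by a small apex cap.

# ellipsoid helpers ---------------------------------------------------------

endo_point <- function(theta, phi, a_r, a_z) {
  cbind(a_r * sin(phi) * cos(theta),
        a_r * sin(phi) * sin(theta),
        a_z * cos(phi))
}

# outward unit normal of the endocardial ellipsoid (also the transmural
# direction); exactly orthogonal to the circumferential direction
ellipsoid_normal <- function(theta, phi, a_r, a_z) {
  n <- cbind(sin(phi) * cos(theta) / a_r,
             sin(phi) * sin(theta) / a_r,
             cos(phi) / a_z)
  n / sqrt(rowSums(n^2))
}

wrap_angle <- function(x) atan2(sin(x), cos(x))

# normalized elliptical sector coordinate: <=1 inside the infarct core,
# ramping to m_out at the outer border edge; Inf when no infarct
sector_m <- function(theta, s, preset, L) {
  ext <- preset$infarct_extent
  if (ext[1] <= 0) return(rep(Inf, length(theta)))
  th0 <- preset$infarct_center[1] * pi / 180
  s_c <- preset$infarct_center[2] * L
  half_th <- (ext[1] / 2) * pi / 180
  half_s <- ext[2] / 2
  sqrt((wrap_angle(theta - th0) / half_th)^2 + ((s - s_c) / half_s)^2)
}

# thickness weight: 1 in the core, C1 smoothstep to 0 across the border
# (a C0 linear ramp kinks the epicardial surface at the annulus edges,
# which distorts conforming patch extrusion)
sector_weight <- function(m, preset) {
  if (preset$border_width <= 0) return(as.numeric(m <= 1))
  m_out <- 1 + preset$border_width / (preset$infarct_extent[2] / 2)
  u <- pmin(1, pmax(0, (m - 1) / (m_out - 1)))
  1 - u * u * (3 - 2 * u)
}

local_thickness <- function(theta, s, preset, L) {
  w <- sector_weight(sector_m(theta, s, preset, L), preset)
  preset$wall_thickness_base +
    (preset$infarct_thickness - preset$wall_thickness_base) * w
}

# mesh construction ---------------------------------------------------------

#' Build the idealized left-ventricle hexahedral mesh
#'
#' Structured shell mesh of a truncated-ellipsoid LV: `n_circ x n_long x
#' n_trans` tri-linear hexahedra between the endocardial ellipsoid and an
#' epicardial surface offset along the outward normal by the local wall
#' thickness. Wall thinning across the infarct border annulus is linear.
#' Element region labels (`healthy`, `border`, `infarct`), boundary face sets
#' (`endocardium`, `epicardium`, `base`) and the fixed basal node set are
#' populated. Basal nodes are projected onto the plane z = 0.
#'
#' @param preset an [lv_preset()]
#' @param resolution optional `c(n_circ, n_long, n_trans)` override
#' @return an object of class `lv_mesh`
#' @export
#' @examples
#' mesh <- build_idealized_lv(make_lv_presets("healthy"),
#'                            resolution = c(16, 12, 2))
#' mesh
build_idealized_lv <- function(preset, resolution = NULL) {
  stopifnot(inherits(preset, "lv_preset"))
  res <- if (is.null(resolution)) preset$resolution else as.integer(resolution)
  if (length(res) != 3L || any(res < 1))
    stop("'resolution' must be three positive integers", call. = FALSE)
  nc <- res[1]; nl <- res[2]; nt <- res[3]
  if (nc < 8) stop("n_circ must be at least 8 for a closed shell", call. = FALSE)
  a_r <- preset$endo_semi_axes[[1]]; a_z <- preset$endo_semi_axes[[2]]
  phi_b <- acos(2 * preset$truncation_height - 1)
  phi_a <- pi - asin(preset$apex_cap_radius / a_r)
  z_base <- a_z * (2 * preset$truncation_height - 1)

  # endocardial meridian arc length s(phi), measured from the base
  phg <- seq(phi_b, phi_a, length.out = 2001)
  dsd <- sqrt((a_r * cos(phg))^2 + (a_z * sin(phg))^2)
  svals <- c(0, cumsum((dsd[-1] + dsd[-length(dsd)]) / 2 * diff(phg)))
  L <- svals[length(svals)]
  s_of_phi <- function(phi) approx(phg, svals, phi, rule = 2)$y

  # infarct/border must stay off the basal plane
  if (preset$infarct_extent[1] > 0) {
    s_min <- preset$infarct_center[2] * L - preset$infarct_extent[2] / 2 -
      preset$border_width
    if (s_min <= 0)
      stop("infarct plus border annulus reaches the basal plane", call. = FALSE)
    if (preset$infarct_center[2] * L + preset$infarct_extent[2] / 2 +
        preset$border_width >= L)
      stop("infarct plus border annulus reaches the apex cap", call. = FALSE)
  }

  theta <- 2 * pi * (0:(nc - 1)) / nc
  phi <- seq(phi_b, phi_a, length.out = nl + 1)
  nid <- function(i, j, k) (i %% nc) + nc * j + nc * (nl + 1) * k + 1L

  nnod <- nc * (nl + 1) * (nt + 1)
  nodes <- matrix(0, nnod, 3)
  node_ijk <- matrix(0L, nnod, 3)
  for (k in 0:nt) for (j in 0:nl) {
    ph <- phi[j + 1]
    s <- s_of_phi(ph)
    t_loc <- local_thickness(theta, s, preset, L)
    E <- endo_point(theta, ph, a_r, a_z)
    nh <- ellipsoid_normal(theta, ph, a_r, a_z)
    # thinning is realized on the endocardial side: the cavity bulges
    # outward into the thinned sector (infarct expansion) while the
    # epicardial surface remains the smooth offset ellipsoid the patch
    # bonds to
    offset <- (preset$wall_thickness_base - t_loc) + (k / nt) * t_loc
    P <- E + offset * nh
    P[, 3] <- P[, 3] - z_base
    if (j == 0) P[, 3] <- 0          # project basal layer onto z = 0
    idx <- nid(0:(nc - 1), j, k)
    nodes[idx, ] <- P
    node_ijk[idx, ] <- cbind(0:(nc - 1), j, k)
  }

  ne <- nc * nl * nt
  elems <- matrix(0L, ne, 8)
  elem_ijk <- matrix(0L, ne, 3)
  region <- character(ne)
  e <- 0L
  for (k in 0:(nt - 1)) for (j in 0:(nl - 1)) for (i in 0:(nc - 1)) {
    e <- e + 1L
    elems[e, ] <- c(nid(i, j, k),     nid(i, j + 1, k),
                    nid(i + 1, j + 1, k), nid(i + 1, j, k),
                    nid(i, j, k + 1), nid(i, j + 1, k + 1),
                    nid(i + 1, j + 1, k + 1), nid(i + 1, j, k + 1))
    elem_ijk[e, ] <- c(i, j, k)
    th_c <- theta[i + 1] + pi / nc
    s_c <- s_of_phi((phi[j + 1] + phi[j + 2]) / 2)
    m <- sector_m(th_c, s_c, preset, L)
    m_out <- if (preset$border_width > 0)
      1 + preset$border_width / (preset$infarct_extent[2] / 2) else 1
    region[e] <- if (m <= 1) "infarct" else if (m <= m_out) "border" else "healthy"
  }

  storage.mode(elems) <- "integer"
  eid <- function(i, j, k) i + nc * j + nc * nl * k + 1L
  endo_faces <- matrix(0L, nc * nl, 4); endo_face_elem <- integer(nc * nl)
  epi_faces <- matrix(0L, nc * nl, 4); epi_face_elem <- integer(nc * nl)
  f <- 0L
  for (j in 0:(nl - 1)) for (i in 0:(nc - 1)) {
    f <- f + 1L
    # face quads ordered [(-,-), (+,-), (+,+), (-,+)] in (phi, theta) so that
    # t_phi x t_theta points along the outward transmural direction
    endo_faces[f, ] <- c(nid(i, j, 0), nid(i, j + 1, 0),
                         nid(i + 1, j + 1, 0), nid(i + 1, j, 0))
    endo_face_elem[f] <- eid(i, j, 0)
    epi_faces[f, ] <- c(nid(i, j, nt), nid(i, j + 1, nt),
                        nid(i + 1, j + 1, nt), nid(i + 1, j, nt))
    epi_face_elem[f] <- eid(i, j, nt - 1)
  }
  base_faces <- matrix(0L, nc * nt, 4)
  f <- 0L
  for (k in 0:(nt - 1)) for (i in 0:(nc - 1)) {
    f <- f + 1L
    base_faces[f, ] <- c(nid(i, 0, k), nid(i + 1, 0, k),
                         nid(i + 1, 0, k + 1), nid(i, 0, k + 1))
  }
  base_nodes <- sort(unique(as.integer(outer(nid(0:(nc - 1), 0, 0) - 1,
                                             nc * (nl + 1) * (0:nt), `+`) + 1L)))

  mesh <- structure(list(
    nodes = nodes, elems = elems, region = region,
    node_ijk = node_ijk, elem_ijk = elem_ijk,
    n_myo = ne,
    endo_faces = endo_faces, endo_face_elem = endo_face_elem,
    epi_faces = epi_faces, epi_face_elem = epi_face_elem,
    base_faces = base_faces, base_nodes = base_nodes,
    resolution = c(n_circ = nc, n_long = nl, n_trans = nt),
    param = list(a_r = a_r, a_z = a_z, phi_b = phi_b, phi_a = phi_a,
                 z_base = z_base, L = L, phg = phg, svals = svals,
                 theta = theta, phi = phi),
    preset = preset, patch = NULL), class = "lv_mesh")
  mesh
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("LV hexahedral mesh ('%s' preset): %d nodes, %d elements\n",
              x$preset$name, nrow(x$nodes), nrow(x$elems)))
  cat("  regions:", paste(sprintf("%s=%d", names(table(x$region)),
                                  table(x$region)), collapse = ", "), "\n")
  cat(sprintf("  faces: endo %d, epi %d, base %d; fixed basal nodes: %d\n",
              nrow(x$endo_faces), nrow(x$epi_faces), nrow(x$base_faces),
              length(x$base_nodes)))
  if (!is.null(x$patch))
    cat(sprintf("  patch: %d elements, footprint %.1f mm^2\n",
                length(x$patch$patch_elems), x$patch$footprint_area))
  invisible(x)
}

# quadrature over a bilinear quad face; returns list(area, integral of x.n)
face_quadrature <- function(P) {
  s4 <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  g <- 1 / sqrt(3)
  area <- 0; xdotn <- 0; cen <- colMeans(P)
  for (qa in c(-g, g)) for (qb in c(-g, g)) {
    N <- 0.25 * (1 + s4[, 1] * qa) * (1 + s4[, 2] * qb)
    dN1 <- 0.25 * s4[, 1] * (1 + s4[, 2] * qb)
    dN2 <- 0.25 * (1 + s4[, 1] * qa) * s4[, 2]
    t1 <- drop(t(P) %*% dN1); t2 <- drop(t(P) %*% dN2)
    cr <- c(t1[2] * t2[3] - t1[3] * t2[2],
            t1[3] * t2[1] - t1[1] * t2[3],
            t1[1] * t2[2] - t1[2] * t2[1])
    xq <- drop(t(P) %*% N)
    area <- area + sqrt(sum(cr^2))
    xdotn <- xdotn + sum(xq * cr)
  }
  list(area = area, xdotn = xdotn)
}

#' Cavity volume of the meshed ventricle
#'
#' Volume enclosed by the endocardial surface, the basal plane and a flat cap
#' over the small apex opening, by the divergence theorem. With a
#' displacement field the deformed cavity volume is returned.
#'
#' @param mesh an `lv_mesh`
#' @param u optional nodal displacement matrix (n x 3)
#' @return volume in mm^3
#' @export
cavity_volume <- function(mesh, u = NULL) {
  X <- mesh$nodes
  if (!is.null(u)) X <- X + u
  tot <- 0
  for (f in seq_len(nrow(mesh$endo_faces)))
    tot <- tot + face_quadrature(X[mesh$endo_faces[f, ], ])$xdotn
  # apex cap: fan from the rim centroid (endocardial ring at the apex cut)
  nl <- mesh$resolution[2]
  rim <- X[mesh$node_ijk[, 2] == nl & mesh$node_ijk[, 3] == 0, , drop = FALSE]
  # order rim nodes by theta
  rim <- rim[order(atan2(rim[, 2], rim[, 1])), , drop = FALSE]
  cen <- colMeans(rim)
  nr <- nrow(rim)
  for (t in seq_len(nr)) {
    p <- rim[t, ]; q <- rim[t %% nr + 1, ]
    # oriented outward (away from the cavity interior, through the apex)
    tot <- tot + sum(cen * c((p[2] - cen[2]) * (q[3] - cen[3]) - (p[3] - cen[3]) * (q[2] - cen[2]),
                             (p[3] - cen[3]) * (q[1] - cen[1]) - (p[1] - cen[1]) * (q[3] - cen[3]),
                             (p[1] - cen[1]) * (q[2] - cen[2]) - (p[2] - cen[2]) * (q[1] - cen[1])))
  }
  tot / 3
}

#' Analytic cavity volume of the truncated ellipsoid
#'
#' Closed-form volume of the endocardial ellipsoid between the apex and the
#' basal cut plane; oracle for [cavity_volume()] on a freshly built mesh.
#'
#' @param preset an [lv_preset()]
#' @return volume in mm^3
#' @export
analytic_cavity_volume <- function(preset) {
  a_r <- preset$endo_semi_axes[[1]]; a_z <- preset$endo_semi_axes[[2]]
  zb <- a_z * (2 * preset$truncation_height - 1)
  f <- function(z) z - z^3 / (3 * a_z^2)
  pi * a_r^2 * (f(zb) - f(-a_z))
}

# reference volumes of all elements (2x2x2 Gauss)
element_volumes <- function(mesh, u = NULL) {
  X <- mesh$nodes
  if (!is.null(u)) X <- X + u
  sg <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
              c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  g <- 1 / sqrt(3)
  ne <- nrow(mesh$elems)
  vol <- numeric(ne)
  for (e in seq_len(ne)) {
    P <- X[mesh$elems[e, ], ]
    v <- 0
    for (q in 1:8) {
      xi <- sg[q, ] * g
      dN <- matrix(0, 8, 3)
      for (a in 1:8) {
        s <- sg[a, ]
        dN[a, 1] <- 0.125 * s[1] * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3])
        dN[a, 2] <- 0.125 * (1 + s[1] * xi[1]) * s[2] * (1 + s[3] * xi[3])
        dN[a, 3] <- 0.125 * (1 + s[1] * xi[1]) * (1 + s[2] * xi[2]) * s[3]
      }
      v <- v + det(t(P) %*% dN)
    }
    vol[e] <- v
  }
  vol
}

#' Total myocardial wall volume of the mesh
#'
#' Sum of reference element volumes over non-patch elements.
#'
#' @param mesh an `lv_mesh`
#' @return volume in mm^3
#' @export
wall_volume <- function(mesh) {
  sum(element_volumes(mesh)[mesh$region != "patch"])
}

# patch ---------------------------------------------------------------------

#' Epicardial patch specification
#'
#' @param diameter patch diameter, mm (default 20)
#' @param thickness patch thickness, mm (default 0.3)
#' @param n_layers number of element layers through the patch thickness
#' @param center optional `c(theta_deg, s_frac)` epicardial center; by
#'   default the patch is centered over the infarct centroid
#' @return an object of class `patch_spec`
#' @export
patch_spec <- function(diameter = 20, thickness = 0.3, n_layers = 1,
                       center = NULL) {
  stopifnot_scalar(diameter, "diameter", positive = TRUE)
  stopifnot_scalar(thickness, "thickness", positive = TRUE)
  n_layers <- as.integer(n_layers)
  if (n_layers < 1) stop("'n_layers' must be >= 1", call. = FALSE)
  if (!is.null(center) && length(center) != 2L)
    stop("'center' must be c(theta_deg, s_frac)", call. = FALSE)
  structure(list(diameter = diameter, thickness = thickness,
                 n_layers = n_layers, center = center),
            class = "patch_spec")
}

#' Bond an epicardial patch over the infarct
#'
#' Selects the epicardial faces whose centers lie within the patch footprint
#' (a disc of the given diameter by Euclidean distance from the center point
#' on the epicardium) and extrudes them outward along the epicardial normals
#' into `n_layers` of hexahedra labeled `"patch"`. Interface nodes are
#' shared: the bond is conforming (perfectly adherent), with no contact or
#' friction. Original element labels are unchanged. Re-attaching to an
#' already patched mesh is an error.
#'
#' @param mesh an `lv_mesh`
#' @param spec a [patch_spec()]
#' @return the patched `lv_mesh`
#' @export
#' @examples
#' mesh <- build_idealized_lv(make_lv_presets("icm"), resolution = c(16, 12, 2))
#' patched <- attach_patch(mesh, patch_spec(20, 0.3))
attach_patch <- function(mesh, spec = patch_spec()) {
  stopifnot(inherits(mesh, "lv_mesh"), inherits(spec, "patch_spec"))
  if (!is.null(mesh$patch))
    stop("mesh already carries a patch; re-attaching is not allowed", call. = FALSE)
  pm <- mesh$param
  pr <- mesh$preset
  # center point on the epicardium
  if (is.null(spec$center)) {
    inf_e <- which(mesh$region == "infarct")
    if (length(inf_e) == 0)
      stop("no infarct region to center the patch on; give spec$center", call. = FALSE)
    cen_idx <- mesh$elem_ijk[inf_e, , drop = FALSE]
    th_c <- atan2(mean(sin(pm$theta[cen_idx[, 1] + 1] + pi / mesh$resolution[1])),
                  mean(cos(pm$theta[cen_idx[, 1] + 1] + pi / mesh$resolution[1])))
    ph_c <- mean((pm$phi[cen_idx[, 2] + 1] + pm$phi[cen_idx[, 2] + 2]) / 2)
  } else {
    th_c <- spec$center[1] * pi / 180
    ph_c <- approx(pm$svals, pm$phg, spec$center[2] * pm$L, rule = 2)$y
  }
  s_c <- approx(pm$phg, pm$svals, ph_c, rule = 2)$y
  t_c <- local_thickness(th_c, s_c, pr, pm$L)
  cen_pt <- drop(endo_point(th_c, ph_c, pm$a_r, pm$a_z)) +
    t_c * drop(ellipsoid_normal(th_c, ph_c, pm$a_r, pm$a_z))
  cen_pt[3] <- cen_pt[3] - pm$z_base

  # footprint faces
  fc <- t(vapply(seq_len(nrow(mesh$epi_faces)),
                 function(f) colMeans(mesh$nodes[mesh$epi_faces[f, ], ]),
                 numeric(3)))
  d <- sqrt(rowSums((fc - matrix(cen_pt, nrow(fc), 3, byrow = TRUE))^2))
  sel <- which(d <= spec$diameter / 2)
  if (length(sel) == 0)
    stop("patch footprint selects no epicardial faces", call. = FALSE)
  nl <- mesh$resolution[2]
  jf <- mesh$elem_ijk[mesh$epi_face_elem[sel], 2]
  if (any(jf == 0) || any(jf == nl - 1))
    stop("patch footprint exceeds the epicardial surface (reaches base or apex rim)",
         call. = FALSE)
  # the footprint must cover the infarct centroid (partial coverage of a
  # large infarct is the reference configuration)
  if (any(mesh$region == "infarct")) {
    inf_faces <- which(mesh$region[mesh$epi_face_elem] == "infarct")
    inf_cent <- colMeans(fc[inf_faces, , drop = FALSE])
    if (!(which.min(sqrt(rowSums((fc - matrix(inf_cent, nrow(fc), 3,
                                              byrow = TRUE))^2))) %in% sel))
      stop("patch footprint does not cover the infarct centroid", call. = FALSE)
  }

  # footprint area (reference epicardial surface)
  area <- sum(vapply(sel, function(f)
    face_quadrature(mesh$nodes[mesh$epi_faces[f, ], ])$area, numeric(1)))

  # extrude footprint nodes along the true epicardial surface normals
  # (area-weighted average of adjacent epicardial face normals; over the
  # border-zone thickness ramp the surface is tilted relative to the
  # transmural direction)
  fnodes <- sort(unique(as.integer(mesh$epi_faces[sel, ])))
  nh <- matrix(0, length(fnodes), 3)
  for (f in seq_len(nrow(mesh$epi_faces))) {
    quad <- mesh$epi_faces[f, ]
    hit <- match(quad, fnodes)
    if (all(is.na(hit))) next
    P <- mesh$nodes[quad, ]
    t1 <- (P[3, ] + P[2, ] - P[1, ] - P[4, ]) / 2
    t2 <- (P[4, ] + P[3, ] - P[1, ] - P[2, ]) / 2
    cr <- c(t1[2] * t2[3] - t1[3] * t2[2],
            t1[3] * t2[1] - t1[1] * t2[3],
            t1[1] * t2[2] - t1[2] * t2[1])
    for (a in which(!is.na(hit)))
      nh[hit[a], ] <- nh[hit[a], ] + cr
  }
  nh <- nh / sqrt(rowSums(nh^2))
  n0 <- nrow(mesh$nodes)
  nodes <- mesh$nodes
  layer_ids <- matrix(0L, length(fnodes), spec$n_layers + 1)
  layer_ids[, 1] <- fnodes
  for (l in seq_len(spec$n_layers)) {
    new_ids <- n0 + (l - 1) * length(fnodes) + seq_along(fnodes)
    nodes <- rbind(nodes,
                   mesh$nodes[fnodes, ] + (l / spec$n_layers) * spec$thickness * nh)
    layer_ids[, l + 1] <- new_ids
  }
  lookup <- integer(nrow(nodes)); lookup[fnodes] <- seq_along(fnodes)

  elems <- mesh$elems; region <- mesh$region; elem_ijk <- mesh$elem_ijk
  patch_elems <- integer(0)
  for (l in seq_len(spec$n_layers)) for (f in sel) {
    quad <- lookup[mesh$epi_faces[f, ]]
    elems <- rbind(elems, c(layer_ids[quad, l], layer_ids[quad, l + 1]))
    region <- c(region, "patch")
    elem_ijk <- rbind(elem_ijk, c(NA_integer_, NA_integer_, NA_integer_))
    patch_elems <- c(patch_elems, nrow(elems))
  }
  mesh$nodes <- nodes
  mesh$elems <- elems
  mesh$region <- region
  mesh$elem_ijk <- elem_ijk
  mesh$patch <- list(spec = spec, center_point = cen_pt,
                     footprint_faces = sel,
                     footprint_elems = mesh$epi_face_elem[sel],
                     patch_elems = patch_elems,
                     footprint_area = area)
  mesh
}

#' Volume of the attached patch layer
#'
#' @param mesh a patched `lv_mesh`
#' @return reference volume of the patch elements, mm^3
#' @export
patch_volume <- function(mesh) {
  if (is.null(mesh$patch)) stop("mesh has no patch", call. = FALSE)
  sum(element_volumes(mesh)[mesh$patch$patch_elems])
}
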