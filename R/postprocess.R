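# Derived stress fields and scalar endpoints.

#' von Mises stress
#'
#' \eqn{\sqrt{3/2\,\mathrm{dev}(\sigma):\mathrm{dev}(\sigma)}} of a symmetric
#' Cauchy stress tensor.
#'
#' @param sigma 3x3 symmetric matrix or length-6 Voigt vector
#'   (xx, yy, zz, xy, xz, yz), kPa
#' @return scalar, kPa
#' @export
#' @examples
#' von_mises(diag(c(5, 0, 0)))  # uniaxial: returns 5
von_mises <- function(sigma) {
  s <- check_sym3(sigma)
  d <- s - diag(mean(diag(s)), 3)
  sqrt(1.5 * sum(d * d))
}

#' Maximal principal stress
#'
#' Largest eigenvalue of a symmetric Cauchy stress tensor.
#'
#' @inheritParams von_mises
#' @return scalar, kPa
#' @export
#' @examples
#' max_principal_stress(diag(c(3, 1, -2)))  # 3
max_principal_stress <- function(sigma) {
  s <- check_sym3(sigma)
  max(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
}

#' Percent reduction of a scalar endpoint
#'
#' `100 * (baseline - treated) / baseline`.
#'
#' @param baseline untreated value (> 0)
#' @param treated treated value
#' @return percent
#' @export
percent_reduction <- function(baseline, treated) {
  stopifnot_scalar(baseline, "baseline")
  stopifnot_scalar(treated, "treated")
  if (baseline <= 0) stop("'baseline' must be > 0", call. = FALSE)
  100 * (baseline - treated) / baseline
}

#' Recovery Percentage
#'
#' Normalizes a treatment outcome between the MI (0\%) and Sham (100\%)
#' anchors: `(treatment - mi) / (sham - mi) * 100`. The sign is preserved, so
#' values can exceed 100\% or be negative.
#'
#' @param sham,mi,treatment scalar outcome values; `sham` must differ from
#'   `mi`
#' @return percent
#' @export
#' @examples
#' recovery_percentage(sham = 60, mi = 40, treatment = 50)  # 50
recovery_percentage <- function(sham, mi, treatment) {
  stopifnot_scalar(sham, "sham"); stopifnot_scalar(mi, "mi")
  stopifnot_scalar(treatment, "treatment")
  if (sham == mi)
    stop("recovery percentage is undefined when sham == mi", call. = FALSE)
  100 * (treatment - mi) / (sham - mi)
}

# epicardial nodes adjacent to elements of the given regions
region_epi_nodes <- function(mesh, regions = c("infarct")) {
  sel <- mesh$region[mesh$epi_face_elem] %in% regions
  sort(unique(as.integer(mesh$epi_faces[sel, , drop = FALSE])))
}

# epicardium-adjacent myocardial elements, optionally restricted to the
# patch footprint faces
epi_adjacent_elems <- function(mesh, footprint_faces = NULL) {
  faces <- seq_len(nrow(mesh$epi_faces))
  if (!is.null(footprint_faces)) faces <- footprint_faces
  unique(mesh$epi_face_elem[faces])
}

#' Scalar endpoints of a converged inflation
#'
#' Computes the endpoints behind the displacement/stress comparisons:
#' volume-weighted mean maximal principal stress over the myocardial wall
#' (patch excluded), peak displacement over infarct-zone epicardial nodes,
#' and peak von Mises stress in epicardium-adjacent myocardial elements
#' (optionally restricted to the patch footprint, so that reductions measure
#' shielding of the tissue rather than stress carried by the patch).
#'
#' @param sim an `lv_sim`
#' @param mesh the `lv_mesh` the simulation was run on
#' @param footprint_faces optional epicardial face indices further
#'   restricting the von Mises endpoint (e.g. `mesh$patch$footprint_faces`)
#' @param displacement `"radial"` (default: displacement component along the
#'   outward transmural direction, the bulge the patch is meant to
#'   suppress) or `"magnitude"`
#' @return list of class `endpoint_report`: `mean_max_principal_stress`,
#'   `peak_transmural_displacement`, `peak_vonMises_epi` and the
#'   per-increment `curves`
#' @export
endpoint_report <- function(sim, mesh, footprint_faces = NULL,
                            displacement = c("radial", "magnitude")) {
  displacement <- match.arg(displacement)
  stopifnot(inherits(sim, "lv_sim"), inherits(mesh, "lv_mesh"))
  myo <- mesh$region != "patch"
  mps <- apply(sim$element_sigma, 1, function(v)
    max_principal_stress(voigt_to_sym(v)))
  vm <- apply(sim$element_sigma, 1, function(v) von_mises(voigt_to_sym(v)))
  mean_mps <- sum(mps[myo] * sim$element_vol[myo]) / sum(sim$element_vol[myo])

  nodes <- region_epi_nodes(mesh, "infarct")
  if (length(nodes) == 0) nodes <- region_epi_nodes(mesh, c("healthy", "border"))
  if (displacement == "magnitude") {
    disp <- sqrt(rowSums(sim$u[nodes, , drop = FALSE]^2))
  } else {
    ijk <- mesh$node_ijk[nodes, , drop = FALSE]
    nh <- ellipsoid_normal(mesh$param$theta[ijk[, 1] + 1],
                           mesh$param$phi[ijk[, 2] + 1],
                           mesh$param$a_r, mesh$param$a_z)
    disp <- abs(rowSums(sim$u[nodes, , drop = FALSE] * nh))
  }
  # stress endpoint over the infarct-zone epicardium (patch-rim bond-line
  # concentrations in border/remote elements are not part of it)
  elems <- epi_adjacent_elems(mesh, footprint_faces)
  elems <- elems[mesh$region[elems] != "patch"]
  if (any(mesh$region[elems] == "infarct"))
    elems <- elems[mesh$region[elems] == "infarct"]
  rep <- list(mean_max_principal_stress = mean_mps,
              peak_transmural_displacement = max(disp),
              peak_vonMises_epi = max(vm[elems]),
              n_infarct_epi_nodes = length(nodes),
              curves = sim$curves)
  class(rep) <- "endpoint_report"
  rep
}

#' @export
print.endpoint_report <- function(x, ...) {
  cat("Endpoints at final pressure:\n")
  cat(sprintf("  mean maximal principal stress (wall): %.3f kPa\n",
              x$mean_max_principal_stress))
  cat(sprintf("  peak transmural displacement (infarct epi): %.3f mm\n",
              x$peak_transmural_displacement))
  cat(sprintf("  peak von Mises (epi-adjacent myocardium): %.3f kPa\n",
              x$peak_vonMises_epi))
  invisible(x)
}

#' Write an endpoint report to JSON and curves to CSV
#'
#' @param report an `endpoint_report`
#' @param json,csv output paths (either may be `NULL` to skip)
#' @return `report`, invisibly
#' @export
write_endpoint_report <- function(report, json = NULL, csv = NULL) {
  if (!is.null(json))
    jsonlite::write_json(report[c("mean_max_principal_stress",
                                  "peak_transmural_displacement",
                                  "peak_vonMises_epi")],
                         json, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv))
    write.csv(report$curves, csv, row.names = FALSE)
  invisible(report)
}

#' Patch modulus--thickness sweep
#'
#' Re-solves the patched ventricle over a grid of patch Young's moduli and
#' thicknesses and reports, per grid point, the percent reduction (vs the
#' unpatched model) of infarct-zone peak epicardial displacement and of peak
#' sub-patch epicardial von Mises stress. Solver failures are recorded per
#' grid point, not dropped.
#'
#' @param preset an [lv_preset()] (typically the ICM preset)
#' @param E_MPa patch moduli in MPa (the study range spans 0.05--100)
#' @param thickness_mm patch thicknesses in mm
#' @param resolution mesh resolution override
#' @param protocol a [load_protocol()]
#' @param diameter patch diameter, mm
#' @return data.frame of class `patch_sweep` with columns `E_MPa`,
#'   `thickness_mm`, `red_peak_disp_pct`, `red_vm_pct`, `converged`
#' @export
run_patch_sweep <- function(preset, E_MPa = c(0.05, 5, 50, 100),
                            thickness_mm = c(0.1, 0.3, 0.6),
                            resolution = NULL, protocol = load_protocol(),
                            diameter = 20) {
  mesh <- build_idealized_lv(preset, resolution)
  fib <- assign_fiber_field(mesh)
  base <- solve_inflation(mesh, fib, material_map(), protocol)
  ep0 <- endpoint_report(base, mesh)
  grid <- expand.grid(E_MPa = E_MPa, thickness_mm = thickness_mm,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    E <- grid$E_MPa[g]; th <- grid$thickness_mm[g]
    pm <- attach_patch(mesh, patch_spec(diameter, th))
    fibp <- assign_fiber_field(pm)
    mm <- material_map(patch = iso_params(E = E * 1000, nu = 0.49))
    sim <- tryCatch(solve_inflation(pm, fibp, mm, protocol),
                    error = function(e) e)
    if (inherits(sim, "error"))
      return(data.frame(E_MPa = E, thickness_mm = th,
                        red_peak_disp_pct = NA_real_, red_vm_pct = NA_real_,
                        converged = FALSE))
    ep <- endpoint_report(sim, pm)
    data.frame(E_MPa = E, thickness_mm = th,
               red_peak_disp_pct = percent_reduction(
                 ep0$peak_transmural_displacement,
                 ep$peak_transmural_displacement),
               red_vm_pct = percent_reduction(ep0$peak_vonMises_epi,
                                              ep$peak_vonMises_epi),
               converged = TRUE)
  })
  out <- do.call(rbind, res)
  attr(out, "baseline") <- ep0
  class(out) <- c("patch_sweep", class(out))
  out
}

#' Write a sweep grid as TSV
#'
#' @param sweep a `patch_sweep`
#' @param file output path
#' @return `file`, invisibly
#' @export
write_sweep_tsv <- function(sweep, file) {
  write.table(as.data.frame(sweep), file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(file)
}
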