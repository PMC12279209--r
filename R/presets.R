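#' Idealized left-ventricle geometry presets
#'
#' A preset parameterizes a truncated-ellipsoid LV shell: endocardial
#' semi-axes, wall thickness, basal truncation, and (for the ischemic
#' ventricle) a thinned infarct sector with a border annulus. Presets are
#' surrogates for patient anatomy at physiologic human scale, not
#' reconstructions.
#'
#' `make_lv_presets()` returns the two study presets:
#' \describe{
#' \item{healthy}{endocardial radius 25 mm, long semi-axis 40 mm, uniform
#'   10 mm wall, truncation keeping 70\% of the long axis.}
#' \item{icm}{dilated cavity (endocardial radius 32 mm), 9 mm remote wall,
#'   5 mm infarct wall; elliptical infarct sector 90 degrees
#'   (circumferential) by 25 mm (longitudinal) on the free wall toward the
#'   apex, with a 5 mm border annulus across which thickness ramps
#'   smoothly. Thinning is realized on the endocardial side (the cavity
#'   bulges into the thinned sector), keeping the epicardial surface smooth
#'   for patch bonding. The reference 20 mm patch covers the central
#'   infarct; efficacy endpoints measure the whole infarct-zone
#'   epicardium, covered and surrounding.}
#' }
#'
#' @param kind `"healthy"` or `"icm"`
#' @return an object of class `lv_preset`
#' @export
#' @examples
#' p <- make_lv_presets("icm")
#' p$infarct_thickness / p$wall_thickness_base  # thinning ratio <= 0.6
make_lv_presets <- function(kind = c("healthy", "icm")) {
  kind <- match.arg(kind)
  if (kind == "healthy")
    lv_preset(name = "healthy",
              endo_semi_axes = c(a_r = 25, a_z = 40),
              wall_thickness_base = 10, infarct_thickness = 10,
              truncation_height = 0.7,
              infarct_extent = c(deg = 0, mm = 0), border_width = 0,
              resolution = c(n_circ = 24, n_long = 16, n_trans = 3))
  else
    lv_preset(name = "icm",
              endo_semi_axes = c(a_r = 32, a_z = 40),
              wall_thickness_base = 9, infarct_thickness = 5,
              truncation_height = 0.7,
              infarct_extent = c(deg = 90, mm = 25), border_width = 5,
              resolution = c(n_circ = 24, n_long = 16, n_trans = 3))
}

#' @rdname make_lv_presets
#' @param name label for the preset
#' @param endo_semi_axes endocardial semi-axes `c(a_r, a_z)` in mm (short and
#'   long); the full long axis is `2 * a_z`
#' @param wall_thickness_base remote (non-infarct) wall thickness, mm
#' @param infarct_thickness wall thickness at the infarct core, mm
#' @param truncation_height fraction of the long axis kept from the apex;
#'   the basal cut plane is at ellipsoid height `a_z * (2 * fraction - 1)`
#' @param infarct_extent `c(deg, mm)`: full circumferential extent in degrees
#'   and full longitudinal extent in mm of the elliptical infarct sector
#' @param border_width width of the border annulus, mm
#' @param infarct_center `c(theta_deg, s_frac)`: circumferential position and
#'   fractional meridian position (from base toward apex) of the sector center
#' @param apex_cap_radius radius of the excluded apex cap, mm (avoids the
#'   degenerate pole)
#' @param resolution mesh resolution `c(n_circ, n_long, n_trans)`
#' @export
lv_preset <- function(name, endo_semi_axes, wall_thickness_base,
                      infarct_thickness, truncation_height,
                      infarct_extent = c(deg = 0, mm = 0), border_width = 0,
                      infarct_center = c(theta_deg = 180, s_frac = 0.55),
                      apex_cap_radius = 2,
                      resolution = c(n_circ = 24, n_long = 16, n_trans = 3)) {
  stopifnot_scalar(wall_thickness_base, "wall_thickness_base", positive = TRUE)
  stopifnot_scalar(infarct_thickness, "infarct_thickness", positive = TRUE)
  stopifnot_scalar(truncation_height, "truncation_height", positive = TRUE)
  stopifnot_scalar(border_width, "border_width", nonneg = TRUE)
  stopifnot_scalar(apex_cap_radius, "apex_cap_radius", positive = TRUE)
  if (length(endo_semi_axes) != 2L || any(endo_semi_axes <= 0))
    stop("'endo_semi_axes' must be two positive lengths (a_r, a_z)", call. = FALSE)
  if (truncation_height < 0.5 || truncation_height >= 1)
    stop("'truncation_height' must lie in [0.5, 1): the base cut must not fall below the equator", call. = FALSE)
  if (infarct_thickness > wall_thickness_base)
    stop("'infarct_thickness' must not exceed 'wall_thickness_base'", call. = FALSE)
  if (length(infarct_extent) != 2L || any(infarct_extent < 0))
    stop("'infarct_extent' must be c(deg, mm), both >= 0", call. = FALSE)
  if (xor(infarct_extent[1] == 0, infarct_extent[2] == 0))
    stop("'infarct_extent' components must be both zero or both positive", call. = FALSE)
  res <- as.integer(resolution)
  if (length(res) != 3L || any(res < 1))
    stop("'resolution' must be three positive integers", call. = FALSE)
  if (apex_cap_radius >= endo_semi_axes[1])
    stop("'apex_cap_radius' must be smaller than the short semi-axis", call. = FALSE)
  structure(list(name = name,
                 endo_semi_axes = setNames(as.numeric(endo_semi_axes), c("a_r", "a_z")),
                 wall_thickness_base = wall_thickness_base,
                 infarct_thickness = infarct_thickness,
                 truncation_height = truncation_height,
                 infarct_extent = setNames(as.numeric(infarct_extent), c("deg", "mm")),
                 border_width = border_width,
                 infarct_center = setNames(as.numeric(infarct_center),
                                           c("theta_deg", "s_frac")),
                 apex_cap_radius = apex_cap_radius,
                 resolution = setNames(res, c("n_circ", "n_long", "n_trans"))),
            class = "lv_preset")
}

#' @export
print.lv_preset <- function(x, ...) {
  cat(sprintf("LV geometry preset '%s'\n", x$name))
  cat(sprintf("  endo semi-axes: a_r=%g mm, a_z=%g mm; truncation %g of long axis\n",
              x$endo_semi_axes[1], x$endo_semi_axes[2], x$truncation_height))
  cat(sprintf("  wall: remote %g mm, infarct %g mm; infarct %g deg x %g mm, border %g mm\n",
              x$wall_thickness_base, x$infarct_thickness,
              x$infarct_extent[1], x$infarct_extent[2], x$border_width))
  cat(sprintf("  resolution: %d x %d x %d (circ x long x trans)\n",
              x$resolution[1], x$resolution[2], x$resolution[3]))
  invisible(x)
}

#' Read or write a geometry preset as YAML
#'
#' @param x an `lv_preset`
#' @param file path to a YAML file
#' @return `write_preset_yaml` returns `file` invisibly; `read_preset_yaml`
#'   returns an `lv_preset`.
#' @export
write_preset_yaml <- function(x, file) {
  stopifnot(inherits(x, "lv_preset"))
  yaml::write_yaml(lapply(unclass(x), function(v)
    if (is.numeric(v)) as.numeric(v) else v), file)
  invisible(file)
}

#' @rdname write_preset_yaml
#' @export
read_preset_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  lv_preset(name = y$name, endo_semi_axes = y$endo_semi_axes,
            wall_thickness_base = y$wall_thickness_base,
            infarct_thickness = y$infarct_thickness,
            truncation_height = y$truncation_height,
            infarct_extent = y$infarct_extent,
            border_width = y$border_width,
            infarct_center = y$infarct_center,
            apex_cap_radius = y$apex_cap_radius,
            resolution = y$resolution)
}
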