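#' Holzapfel--Gasser--Ogden material parameters
#'
#' Four-term anisotropic hyperelastic law for passive myocardium with
#' exponential isotropic, fiber, sheet and fiber--sheet coupling terms and a
#' quadratic volumetric penalty enforcing near-incompressibility,
#' \deqn{\Psi = \frac{a}{2b}\{e^{b(\bar I_1-3)}-1\}
#'  + \sum_{i\in\{f,s\}} \frac{a_i}{2b_i}\{e^{b_i\langle\bar I_{4i}-1\rangle^2}-1\}
#'  + \frac{a_{fs}}{2b_{fs}}\{e^{b_{fs}\bar I_{8fs}^2}-1\}
#'  + \frac{\kappa}{2}(J-1)^2,}
#' with isochoric invariants (\eqn{\bar C = J^{-2/3}C}) and tension-only
#' fiber/sheet terms (\eqn{\langle x\rangle = \max(x,0)}).
#'
#' Defaults are the Holzapfel--Ogden human-myocardium fit commonly used for
#' passive diastolic mechanics; stress-like moduli in kPa, exponents
#' dimensionless. \code{kappa} defaults to \code{1000 * a}.
#'
#' @param a,b isotropic matrix modulus (kPa) and exponent
#' @param a_f,b_f fiber term modulus (kPa) and exponent
#' @param a_s,b_s sheet term modulus (kPa) and exponent
#' @param a_fs,b_fs fiber--sheet coupling modulus (kPa) and exponent
#' @param kappa volumetric penalty modulus (kPa)
#' @param scale multiplicative factor applied to the four stress-like moduli
#'   (and, through `a`, to the default `kappa`); exponents are unchanged.
#'   See [myocardium_params()] for the calibrated ventricular default.
#' @return an object of class \code{c("hgo_material", "material")}
#' @export
#' @examples
#' m <- hgo_params()
#' hgo_stress(diag(3), m)  # zero at the reference state
hgo_params <- function(a = 0.059, b = 8.023, a_f = 18.472, b_f = 16.026,
                       a_s = 2.481, b_s = 11.120, a_fs = 0.216, b_fs = 11.436,
                       scale = 1, kappa = 1000 * a * scale) {
  stopifnot_scalar(scale, "scale", positive = TRUE)
  a <- a * scale; a_f <- a_f * scale; a_s <- a_s * scale; a_fs <- a_fs * scale
  for (nm in c("a", "b", "a_f", "b_f", "a_s", "b_s", "a_fs", "b_fs", "kappa"))
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  structure(list(a = a, b = b, a_f = a_f, b_f = b_f, a_s = a_s, b_s = b_s,
                 a_fs = a_fs, b_fs = b_fs, kappa = kappa),
            class = c("hgo_material", "material"))
}

#' Calibrated passive-myocardium default
#'
#' The Holzapfel--Ogden shear-test fit has a very soft ground state; used
#' literally in a ventricular inflation it over-dilates the LV by roughly
#' fivefold relative to the end-diastolic displacement scale reported for
#' patient-specific models (peak transmural displacements of order 1--2 mm
#' at 1 kPa). As is common for diastolic FE models, the package therefore
#' scales the four stress-like moduli by a single factor, calibrated once so
#' that the synthetic ICM ventricle's peak infarct-zone epicardial
#' displacement at 1 kPa end-diastolic pressure is about 1.9 mm. Exponents
#' (strain-stiffening shape) are untouched.
#'
#' @param scale the calibrated stiffness factor
#' @return an `hgo_material`
#' @export
myocardium_params <- function(scale = MYO_STIFFNESS_SCALE) {
  hgo_params(scale = scale)
}

#' @rdname myocardium_params
#' @format `MYO_STIFFNESS_SCALE` is the calibrated scalar.
#' @export
MYO_STIFFNESS_SCALE <- 75

#' Isotropic material parameters
#'
#' Nearly incompressible compressible neo-Hookean law parameterized by small-
#' strain Young's modulus and Poisson ratio; used for the infarct zone
#' (default E = 50 kPa) and the epicardial patch. In the small-strain limit
#' the uniaxial stress--strain slope equals \code{E}.
#'
#' @param E Young's modulus (kPa)
#' @param nu Poisson ratio in \[0, 0.5)
#' @return an object of class \code{c("iso_material", "material")}
#' @export
#' @examples
#' infarct <- iso_params(E = 50)
#' patch <- iso_params(E = 50e3)  # 50 MPa in kPa
iso_params <- function(E = 50, nu = 0.49) {
  stopifnot_scalar(E, "E", positive = TRUE)
  stopifnot_scalar(nu, "nu", nonneg = TRUE)
  if (nu >= 0.5) stop("'nu' must be < 0.5", call. = FALSE)
  structure(list(E = E, nu = nu,
                 mu = E / (2 * (1 + nu)),
                 kappa = E / (3 * (1 - 2 * nu))),
            class = c("iso_material", "material"))
}

#' @export
print.hgo_material <- function(x, ...) {
  cat("Holzapfel-Gasser-Ogden material (kPa):\n")
  cat(sprintf("  a=%g b=%g | a_f=%g b_f=%g | a_s=%g b_s=%g | a_fs=%g b_fs=%g | kappa=%g\n",
              x$a, x$b, x$a_f, x$b_f, x$a_s, x$b_s, x$a_fs, x$b_fs, x$kappa))
  invisible(x)
}

#' @export
print.iso_material <- function(x, ...) {
  cat(sprintf("Isotropic neo-Hookean material: E=%g kPa, nu=%g (mu=%g, kappa=%g kPa)\n",
              x$E, x$nu, x$mu, x$kappa))
  invisible(x)
}

# 9-parameter row consumed by the C++ kernels:
# (a, b, a_f, b_f, a_s, b_s, a_fs, b_fs, kappa); an isotropic material is the
# fiber-free degenerate case (a = mu, b -> 0)
material_row <- function(m) {
  if (inherits(m, "hgo_material"))
    c(m$a, m$b, m$a_f, m$b_f, m$a_s, m$b_s, m$a_fs, m$b_fs, m$kappa)
  else if (inherits(m, "iso_material"))
    c(m$mu, 0, 0, 0, 0, 0, 0, 0, m$kappa)
  else stop("not a material object", call. = FALSE)
}

check_F <- function(F) {
  if (!is.matrix(F) || !all(dim(F) == c(3L, 3L)) || !all(is.finite(F)))
    stop("'F' must be a finite 3x3 deformation gradient", call. = FALSE)
  if (det(F) <= 0)
    stop("deformation gradient has non-positive determinant (inverted state)",
         call. = FALSE)
  F
}

unitize <- function(v) v / sqrt(sum(v^2))

#' Strain-energy density of the HGO law
#'
#' @param F 3x3 deformation gradient
#' @param params an [hgo_params()] object
#' @param f0,s0 unit fiber and sheet directions in the reference configuration
#' @return energy density in kPa (per unit reference volume)
#' @export
hgo_energy <- function(F, params = hgo_params(),
                       f0 = c(1, 0, 0), s0 = c(0, 1, 0)) {
  check_F(F)
  cpp_point_stress(F, material_row(params), unitize(f0), unitize(s0))$psi
}

#' Cauchy stress of the HGO law
#'
#' Push-forward of \eqn{2\,\partial\Psi/\partial C}; the volumetric penalty
#' contributes the pressure \eqn{\kappa(J-1)\,I}.
#'
#' @inheritParams hgo_energy
#' @return 3x3 Cauchy stress (kPa)
#' @export
hgo_stress <- function(F, params = hgo_params(),
                       f0 = c(1, 0, 0), s0 = c(0, 1, 0)) {
  check_F(F)
  cpp_point_stress(F, material_row(params), unitize(f0), unitize(s0))$sigma
}

#' Cauchy stress of the isotropic law
#'
#' @param F 3x3 deformation gradient
#' @param params an [iso_params()] object
#' @return 3x3 Cauchy stress (kPa)
#' @export
iso_stress <- function(F, params = iso_params()) {
  check_F(F)
  cpp_point_stress(F, material_row(params), c(1, 0, 0), c(0, 1, 0))$sigma
}

#' Strain-energy density of the isotropic law
#' @inheritParams iso_stress
#' @return energy density (kPa)
#' @export
iso_energy <- function(F, params = iso_params()) {
  check_F(F)
  cpp_point_stress(F, material_row(params), c(1, 0, 0), c(0, 1, 0))$psi
}

#' Region-to-material assignment
#'
#' Maps mesh region labels to constitutive laws. Every region present in a
#' mesh must be covered when solving.
#'
#' @param healthy,border,infarct,patch material objects (or `NULL` for patch
#'   when no patch is present)
#' @return a named list of materials, class `material_map`
#' @export
#' @examples
#' mm <- material_map()  # calibrated HGO myocardium, 50 kPa infarct, 50 MPa patch
material_map <- function(healthy = myocardium_params(),
                         border = myocardium_params(),
                         infarct = iso_params(E = 50, nu = 0.49),
                         patch = iso_params(E = 50e3, nu = 0.49)) {
  mm <- list(healthy = healthy, border = border, infarct = infarct,
             patch = patch)
  mm <- mm[!vapply(mm, is.null, logical(1))]
  for (m in mm) if (!inherits(m, "material"))
    stop("all entries must be material objects", call. = FALSE)
  structure(mm, class = "material_map")
}

#' Read or write a material map as YAML
#'
#' Format: one entry per region with `model: hgo` or `model: isotropic` and
#' the parameter fields of [hgo_params()] / [iso_params()]. Units are fixed
#' to mm--kPa--mN and validated on load.
#'
#' @param x a `material_map`
#' @param file path to a YAML file
#' @return `write_material_yaml` returns `file` invisibly;
#'   `read_material_yaml` returns a `material_map`.
#' @export
write_material_yaml <- function(x, file) {
  stopifnot(inherits(x, "material_map"))
  out <- lapply(x, function(m) {
    if (inherits(m, "hgo_material"))
      c(list(model = "hgo"), unclass(m))
    else c(list(model = "isotropic"), list(E = m$E, nu = m$nu))
  })
  yaml::write_yaml(c(list(units = "mm-kPa-mN"), out), file)
  invisible(file)
}

#' @rdname write_material_yaml
#' @export
read_material_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  if (!identical(y$units, "mm-kPa-mN"))
    stop("material YAML must declare units: mm-kPa-mN", call. = FALSE)
  y$units <- NULL
  mm <- lapply(y, function(e) {
    switch(e$model,
      hgo = hgo_params(a = e$a, b = e$b, a_f = e$a_f, b_f = e$b_f,
                       a_s = e$a_s, b_s = e$b_s, a_fs = e$a_fs,
                       b_fs = e$b_fs, kappa = e$kappa),
      isotropic = iso_params(E = e$E, nu = e$nu),
      stop("unknown material model: ", e$model, call. = FALSE))
  })
  structure(mm, class = "material_map")
}
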