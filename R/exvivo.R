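# Ex vivo marker-grid mechanics: local strain fields from fiducial marker
# quadrilaterals, sample stress from load and cross-section, and the
# composite (secant) modulus of the layered tissue+patch sample.

#' Synthetic marker-grid dataset with known ground truth
#'
#' Emulates a fluorescent microneedle marker grid on a myocardial sample
#' stretched uniaxially along the circumferential (Y) direction: a regular
#' reference grid, deformed by the affine map
#' `diag(1 - lateral_ratio * applied_strain, 1 + applied_strain)` plus
#' i.i.d. Gaussian jitter on the deformed positions (digitization noise).
#'
#' @param truth a [marker_truth()] object
#' @return a `marker_grid`: data.frame with columns `marker_id`, `x_ref`,
#'   `y_ref`, `x_def`, `y_def` (mm) plus grid attributes
#' @export
#' @examples
#' g <- make_marker_dataset(marker_truth(noise_sd = 0))
#' r <- local_strain_field(g)
#' c(r$mean_strain_x, r$mean_strain_y)  # -0.093, 0.100
make_marker_dataset <- function(truth = marker_truth()) {
  stopifnot(inherits(truth, "marker_truth"))
  nr <- truth$grid_dims[1]; nc <- truth$grid_dims[2]
  gx <- (seq_len(nc) - (nc + 1) / 2) * truth$spacing
  gy <- (seq_len(nr) - (nr + 1) / 2) * truth$spacing
  ref <- cbind(x = rep(gx, each = nr), y = rep(gy, nc))
  Fm <- diag(c(1 - truth$lateral_ratio * truth$applied_strain,
               1 + truth$applied_strain))
  def <- ref %*% t(Fm)
  def <- with_seed(truth$seed,
                   def + matrix(rnorm(length(def), 0, truth$noise_sd),
                                nrow(def), 2))
  out <- data.frame(marker_id = seq_len(nrow(ref)),
                    x_ref = ref[, 1], y_ref = ref[, 2],
                    x_def = def[, 1], y_def = def[, 2])
  structure(out, grid_dims = truth$grid_dims, truth = truth,
            class = c("marker_grid", "data.frame"))
}

#' @rdname make_marker_dataset
#' @param grid_dims `c(rows, cols)` of the marker grid
#' @param spacing marker spacing, mm
#' @param applied_strain imposed engineering strain along Y (default 0.10,
#'   the 10\% stretch protocol)
#' @param lateral_ratio transverse contraction per unit axial stretch
#' @param noise_sd isotropic in-plane Gaussian jitter SD, mm
#' @param seed integer seed for the jitter
#' @export
marker_truth <- function(grid_dims = c(21, 21), spacing = 1,
                         applied_strain = 0.10, lateral_ratio = 0.93,
                         noise_sd = 0.02, seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 2L || any(grid_dims < 2L))
    stop("'grid_dims' must be two integers >= 2", call. = FALSE)
  stopifnot_scalar(spacing, "spacing", positive = TRUE)
  stopifnot_scalar(applied_strain, "applied_strain", nonneg = TRUE)
  if (applied_strain >= 1) stop("'applied_strain' must be < 1", call. = FALSE)
  stopifnot_scalar(lateral_ratio, "lateral_ratio")
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(grid_dims = grid_dims, spacing = spacing,
                 applied_strain = applied_strain,
                 lateral_ratio = lateral_ratio,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "marker_truth")
}

#' Read or write a marker grid as CSV
#'
#' Columns `marker_id, x_ref, y_ref, x_def, y_def`, coordinates in mm.
#'
#' @param grid a `marker_grid` (or compatible data.frame)
#' @param file path
#' @param grid_dims `c(rows, cols)`; required on read if the file has no
#'   square grid
#' @return `write_marker_csv` returns `file` invisibly; `read_marker_csv`
#'   returns a `marker_grid`.
#' @export
write_marker_csv <- function(grid, file) {
  write.csv(as.data.frame(grid), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_marker_csv
#' @export
read_marker_csv <- function(file, grid_dims = NULL) {
  d <- read.csv(file)
  need <- c("marker_id", "x_ref", "y_ref", "x_def", "y_def")
  if (!all(need %in% names(d)))
    stop("marker CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(grid_dims)) {
    n <- sqrt(nrow(d))
    if (n != round(n))
      stop("non-square marker grid: give 'grid_dims'", call. = FALSE)
    grid_dims <- c(n, n)
  }
  structure(d, grid_dims = as.integer(grid_dims),
            class = c("marker_grid", "data.frame"))
}

# least-squares 2D deformation gradient of one marker quad;
# NULL when the reference markers are (near-)collinear
quad_defgrad <- function(ref, def) {
  rc <- sweep(ref, 2, colMeans(ref)); dc <- sweep(def, 2, colMeans(def))
  A <- t(rc) %*% rc
  if (abs(det(A)) < 1e-10 * (sum(rc^2) / 2 + 1e-30)^2) return(NULL)
  t(solve(A, t(rc) %*% dc))
}

#' Local strain field from a marker grid
#'
#' For every grid quadrilateral a local 2D deformation gradient is fitted by
#' least squares from the reference to the deformed marker positions; the
#' engineering strains along X (longitudinal) and Y (circumferential) are
#' taken from the rotation-free right stretch,
#' \eqn{\epsilon_X = \sqrt{C_{11}} - 1}, \eqn{\epsilon_Y = \sqrt{C_{22}} - 1}
#' with \eqn{C = F^T F}, so rigid motions leave the strains unchanged and
#' affine deformations are recovered exactly. Quads with collinear reference
#' markers are skipped (counted in `n_skipped`).
#'
#' @param grid a `marker_grid`
#' @param roi optional polygon (two-column matrix, mm) restricting the
#'   region-of-interest means to quads whose centroids fall inside
#' @return a `strain_report` list: per-quad data.frame `quads` (centroid,
#'   strain_x, strain_y), ROI means `mean_strain_x`, `mean_strain_y`,
#'   `n_skipped`
#' @export
local_strain_field <- function(grid, roi = NULL) {
  dims <- attr(grid, "grid_dims")
  if (is.null(dims)) stop("grid lacks 'grid_dims' attribute", call. = FALSE)
  nr <- dims[1]; nc <- dims[2]
  if (nr < 2 || nc < 2 || nrow(grid) != nr * nc)
    stop("need at least a 2x2 marker grid matching grid_dims", call. = FALSE)
  idx <- function(r, c) (c - 1L) * nr + r
  rows <- list(); skipped <- 0L
  for (c in seq_len(nc - 1)) for (r in seq_len(nr - 1)) {
    ii <- c(idx(r, c), idx(r + 1, c), idx(r + 1, c + 1), idx(r, c + 1))
    ref <- cbind(grid$x_ref[ii], grid$y_ref[ii])
    def <- cbind(grid$x_def[ii], grid$y_def[ii])
    Fq <- quad_defgrad(ref, def)
    if (is.null(Fq)) { skipped <- skipped + 1L; next }
    C <- t(Fq) %*% Fq
    rows[[length(rows) + 1L]] <- data.frame(
      row = r, col = c,
      cx = mean(ref[, 1]), cy = mean(ref[, 2]),
      strain_x = sqrt(C[1, 1]) - 1, strain_y = sqrt(C[2, 2]) - 1)
  }
  if (skipped > 0)
    warning(sprintf("%d degenerate marker quad(s) skipped", skipped),
            call. = FALSE)
  quads <- do.call(rbind, rows)
  keep <- rep(TRUE, nrow(quads))
  if (!is.null(roi))
    keep <- point_in_polygon(quads$cx, quads$cy, roi)
  structure(list(quads = quads,
                 mean_strain_x = mean(quads$strain_x[keep]),
                 mean_strain_y = mean(quads$strain_y[keep]),
                 n_roi = sum(keep), n_skipped = skipped),
            class = "strain_report")
}

#' @export
print.strain_report <- function(x, ...) {
  cat(sprintf("Marker-grid strain field: %d quads (%d in ROI, %d skipped)\n",
              nrow(x$quads), x$n_roi, x$n_skipped))
  cat(sprintf("  mean strain X: %+.2f%%  Y: %+.2f%%\n",
              100 * x$mean_strain_x, 100 * x$mean_strain_y))
  invisible(x)
}

#' @export
#' @importFrom grDevices png hcl.colors dev.off
#' @importFrom graphics image
plot.strain_report <- function(x, component = c("y", "x"), file = NULL, ...) {
  component <- match.arg(component)
  v <- if (component == "y") x$quads$strain_y else x$quads$strain_x
  nr <- max(x$quads$row); nc <- max(x$quads$col)
  z <- matrix(NA_real_, nr, nc)
  z[cbind(x$quads$row, x$quads$col)] <- v
  if (!is.null(file)) { png(file, 480, 480); on.exit(dev.off()) }
  image(t(z), col = hcl.colors(64, "RdYlBu", rev = TRUE),
        main = sprintf("strain %s", toupper(component)), axes = FALSE, ...)
  invisible(x)
}

# ray-casting point-in-polygon
point_in_polygon <- function(px, py, poly) {
  nx <- poly[, 1]; ny <- poly[, 2]; n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  crossings <- matrix(FALSE, length(px), 1)
  for (i in seq_len(n)) {
    cond <- ((ny[i] > py) != (ny[j] > py)) &
      (px < (nx[j] - nx[i]) * (py - ny[i]) / (ny[j] - ny[i]) + nx[i])
    inside <- xor(inside, cond)
    j <- i
  }
  inside
}

#' Nominal sample stress from load and cross-section
#'
#' `stress = load / (width * thickness)`; with load in N and lengths in mm
#' this is N/mm^2 = MPa, converted to kPa (factor 1000) in one place.
#'
#' @param load force, N
#' @param width,thickness sample cross-section, mm
#' @return stress, kPa
#' @export
#' @examples
#' sample_stress(0.1, 10, 1)  # 10 kPa
sample_stress <- function(load, width, thickness) {
  stopifnot_scalar(load, "load")
  stopifnot_scalar(width, "width", positive = TRUE)
  stopifnot_scalar(thickness, "thickness", positive = TRUE)
  load / (width * thickness) * 1000
}

#' Composite (secant) modulus
#'
#' Stress divided by strain at the applied strain level; for a layered
#' tissue-plus-patch sample this is the effective modulus of the composite.
#'
#' @param stress nominal stress, kPa
#' @param strain engineering strain (> 0), dimensionless
#' @return modulus, kPa
#' @export
#' @examples
#' composite_modulus(10, 0.10)  # 100 kPa
composite_modulus <- function(stress, strain) {
  stopifnot_scalar(stress, "stress")
  stopifnot_scalar(strain, "strain")
  if (strain <= 0) stop("'strain' must be > 0", call. = FALSE)
  stress / strain
}

#' Rule-of-mixtures modulus of parallel layers
#'
#' Thickness-weighted mean \eqn{(\sum E_i t_i)/(\sum t_i)} for layers
#' strained equally in parallel; independent oracle for the composite
#' modulus of a tissue+patch sandwich.
#'
#' @param E layer moduli, kPa
#' @param t layer thicknesses, mm
#' @return effective modulus, kPa
#' @export
#' @examples
#' rule_of_mixtures_modulus(c(50, 50e3), c(2, 0.3))  # ~6.57 MPa
rule_of_mixtures_modulus <- function(E, t) {
  if (length(E) != length(t) || any(t <= 0) || any(E <= 0))
    stop("'E' and 't' must be positive vectors of equal length", call. = FALSE)
  sum(E * t) / sum(t)
}
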