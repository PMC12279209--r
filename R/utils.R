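# internal helpers

# run code with a temporary RNG state so generators are deterministic
# under `seed` without clobbering the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# symmetric 3x3 from Voigt (xx, yy, zz, xy, xz, yz)
voigt_to_sym <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

check_sym3 <- function(sigma, tol = 1e-8) {
  if (is.numeric(sigma) && length(sigma) == 6L) sigma <- voigt_to_sym(sigma)
  if (!is.matrix(sigma) || !all(dim(sigma) == c(3L, 3L)))
    stop("stress must be a 3x3 matrix or a length-6 Voigt vector", call. = FALSE)
  sc <- max(abs(sigma), 1)
  if (max(abs(sigma - t(sigma))) > tol * sc)
    stop("stress tensor is not symmetric", call. = FALSE)
  (sigma + t(sigma)) / 2
}
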