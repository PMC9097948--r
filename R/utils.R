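# Small geometry helpers shared across modules.

vec_norm <- function(v) sqrt(sum(v * v))

#' Normalize a 3-vector to unit length
#'
#' @param v numeric 3-vector.
#' @param tol vectors with norm below `tol` raise an error.
#' @return unit-norm 3-vector.
#' @keywords internal
unit_vector <- function(v, tol = 1e-12) {
  n <- vec_norm(v)
  if (!is.finite(n) || n < tol) {
    stop("cannot normalize a (near-)zero vector", call. = FALSE)
  }
  v / n
}

is_unit <- function(v, tol = 1e-9) {
  length(v) == 3L && all(is.finite(v)) && abs(vec_norm(v) - 1) <= tol
}

#' Any unit vector orthogonal to `v`
#' @keywords internal
orthogonal_unit <- function(v) {
  v <- unit_vector(v)
  # cross with the axis v is least aligned with
  e <- diag(3)[, which.min(abs(v))]
  unit_vector(cross3(v, e))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Draw points uniformly on the unit sphere
#' @param n number of points.
#' @return n x 3 matrix of unit rows.
#' @keywords internal
runif_sphere <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
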