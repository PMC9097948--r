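#' @title Cell-division direction model
#'
#' @description
#' The division axis of a cell is modeled as the normalized weighted sum of
#' three unit 3-vectors: the dominant cell polarity `p`, the composite
#' cell-cell squeeze direction `s` from contacting neighbors, and the
#' cell-eggshell squeeze direction `e` (zero when the cell is off the
#' shell). Each component carries a non-negative coefficient; the
#' coefficient vector `K = (K_p, K_s, K_e)` is fitted to observed division
#' axes by minimizing the sum of angular differences. Division axes are
#' undirected lines, so all angles are computed sign-invariantly.
#'
#' @name division_direction
NULL

#' Division-direction coefficient model
#'
#' @param K numeric 3-vector `(K_p, K_s, K_e)`, all `>= 0`, not all zero;
#'   normalized so that `sum(K) == 1` (the composed direction is invariant
#'   to positive rescaling of `K`, so the L1 gauge fixes identifiability).
#' @param objective optional fitted objective value (radians).
#' @param n_obs optional number of observations used in fitting.
#' @return a `division_direction_model`.
#' @export
division_direction_model <- function(K, objective = NA_real_,
                                     n_obs = NA_integer_) {
  stopifnot(length(K) == 3L, all(is.finite(K)))
  if (any(K < 0) || sum(K) <= 0) {
    stop("`K` must be non-negative with a positive sum", call. = FALSE)
  }
  structure(list(K = as.numeric(K) / sum(K), objective = objective,
                 n_obs = n_obs),
            class = "division_direction_model")
}

#' @export
print.division_direction_model <- function(x, ...) {
  cat(sprintf(
    "<division_direction_model> K = (%.4f, %.4f, %.4f) [polarity, cell-cell, eggshell]\n",
    x$K[1], x$K[2], x$K[3]))
  if (is.finite(x$objective)) {
    cat(sprintf("  fitted on %d observations, objective %.6g rad\n",
                x$n_obs, x$objective))
  }
  invisible(x)
}

#' Composite cell-cell squeeze direction
#'
#' Overlap-weighted repulsion: each neighbor whose sphere overlaps the cell
#' pushes it along the centre-centre line with weight equal to the overlap
#' depth `max(0, (r + r_j) - d_j)`; the weighted sum is normalized. Returns
#' the zero vector when no neighbor overlaps.
#'
#' @param cell one-row cell data frame.
#' @param neighbors cell data frame of neighbor cells (may be empty).
#' @return unit 3-vector, or `c(0,0,0)`.
#' @export
neighbor_squeeze_vector <- function(cell, neighbors) {
  if (is.null(neighbors) || nrow(neighbors) == 0L) return(c(0, 0, 0))
  x0 <- as.numeric(cell[1, c("x", "y", "z")])
  dx <- sweep(as.matrix(neighbors[, c("x", "y", "z")]), 2, x0, "-")
  d <- sqrt(rowSums(dx^2))
  if (any(d < 1e-9)) {
    stop("degeneracy error: neighbor coincident with cell", call. = FALSE)
  }
  w <- pmax(0, (cell$radius[1] + neighbors$radius) - d)
  v <- as.numeric(colSums((-dx / d) * w))
  if (vec_norm(v) < 1e-12) return(c(0, 0, 0))
  unit_vector(v)
}

#' Cell-eggshell squeeze direction
#'
#' The inward surface normal of the ellipsoid at the cell's radial
#' projection, when the cell presses against the shell
#' (`g(x) + r_norm > contact_threshold`); the zero vector otherwise, and at
#' the exact shell centre where the normal is undefined.
#'
#' @param cell one-row cell data frame.
#' @param shell an [eggshell()].
#' @param contact_threshold normalized contact level above which the shell
#'   is felt (default 1: touching the surface).
#' @return unit 3-vector pointing inward, or `c(0,0,0)`.
#' @export
eggshell_squeeze_vector <- function(cell, shell, contact_threshold = 1) {
  rel <- matrix(as.numeric(cell[1, c("x", "y", "z")]) - shell$center, 1, 3)
  sr <- shell_reach(rel, shell$semi_axes, cell$radius[1])
  if (sr$g[1] < 1e-12) return(c(0, 0, 0))
  if (sr$g[1] + sr$reach[1] <= contact_threshold) return(c(0, 0, 0))
  outward <- rel[1, ] / shell$semi_axes^2   # gradient direction of g
  -unit_vector(outward)
}

#' Compose the three direction components into a division axis
#'
#' @param model a [division_direction_model()].
#' @param p,s,e the polarity, cell-cell squeeze, and eggshell squeeze
#'   components; unit 3-vectors or zero vectors.
#' @return unit 3-vector `normalize(K_p p + K_s s + K_e e)`.
#' @export
compose_direction <- function(model, p, s = c(0, 0, 0), e = c(0, 0, 0)) {
  K <- model$K
  v <- K[1] * p + K[2] * s + K[3] * e
  if (vec_norm(v) < 1e-12) {
    stop("degeneracy error: composed direction is zero", call. = FALSE)
  }
  unit_vector(v)
}

#' Angle between two undirected axes
#'
#' `acos(|d1 . d2|)`, in `[0, pi/2]`: flipping the sign of either axis
#' leaves the angle unchanged, matching the sign ambiguity of an observed
#' division axis.
#'
#' @param d_pred,d_obs unit 3-vectors.
#' @return angle in radians.
#' @export
angle_error <- function(d_pred, d_obs) {
  if (!is_unit(d_pred, 1e-6) || !is_unit(d_obs, 1e-6)) {
    stop("`d_pred` and `d_obs` must be unit vectors", call. = FALSE)
  }
  acos(min(1, abs(sum(d_pred * d_obs))))
}

# Observation table columns (components + observed axis).
OBS_COLS <- c("name", "px", "py", "pz", "sx", "sy", "sz",
              "ex", "ey", "ez", "dx", "dy", "dz")

obs_matrices <- function(obs) {
  list(P = as.matrix(obs[, c("px", "py", "pz")]),
       S = as.matrix(obs[, c("sx", "sy", "sz")]),
       E = as.matrix(obs[, c("ex", "ey", "ez")]),
       D = as.matrix(obs[, c("dx", "dy", "dz")]))
}

# Vectorized objective: sum of sign-invariant angles between composed
# directions and observed axes. Rows whose composition vanishes contribute
# the maximal angle pi/2.
divdir_objective <- function(K, m) {
  V <- K[1] * m$P + K[2] * m$S + K[3] * m$E
  nv <- sqrt(rowSums(V^2))
  cosang <- abs(rowSums(V * m$D)) / pmax(nv, 1e-300)
  cosang[nv < 1e-12] <- 0
  sum(acos(pmin(1, cosang)))
}

#' Fit the division-direction coefficients
#'
#' Minimizes the summed sign-invariant angle between composed and observed
#' axes over the 2-simplex `{K >= 0, sum(K) = 1}`. The simplex is
#' parametrized by squared coordinates (`K = v^2 / sum(v^2)`) and searched
#' by multi-start Nelder-Mead: the three pure strategies plus seeded random
#' simplex points, followed by restart polishing of the best solution (the
#' objective is cone-shaped, not smooth, at an exact fit).
#'
#' @param observations data frame in the observation-table layout
#'   `name,px,py,pz,sx,sy,sz,ex,ey,ez,dx,dy,dz`, or a path to such a file.
#' @param n_starts number of random starts (in addition to the three pure
#'   strategies).
#' @param seed integer seed for the start points.
#' @return a [division_direction_model()] with the attained objective.
#' @export
fit_coefficients <- function(observations, n_starts = 16, seed = 1) {
  if (is.character(observations)) {
    observations <- read_observations(observations)
  }
  obs <- as.data.frame(observations)
  missing_cols <- setdiff(OBS_COLS, names(obs))
  if (length(missing_cols)) {
    stop("observation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(obs) == 0L) stop("no observations to fit", call. = FALSE)
  m <- obs_matrices(obs)
  allzero <- rowSums(abs(m$P)) + rowSums(abs(m$S)) + rowSums(abs(m$E)) == 0
  if (any(allzero)) {
    warning(sum(allzero), " observation(s) with all-zero components rejected")
    obs <- obs[!allzero, , drop = FALSE]
    if (nrow(obs) == 0L) stop("no usable observations", call. = FALSE)
    m <- obs_matrices(obs)
  }
  if (nrow(obs) < 3L) {
    warning("fewer than 3 observations: the fit is underdetermined")
  }

  obj_v <- function(v) divdir_objective(v^2 / sum(v^2), m)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  starts <- rbind(diag(3),
                  matrix(stats::rexp(3 * n_starts), n_starts, 3))
  starts <- starts / rowSums(starts)
  best <- list(value = Inf, par = c(1, 1, 1))
  for (i in seq_len(nrow(starts))) {
    v0 <- sqrt(starts[i, ]) + 1e-3   # nudge off exact zeros for Nelder-Mead
    fit <- stats::optim(v0, obj_v, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-14))
    if (fit$value < best$value) best <- fit
  }
  # restart polishing: rebuilds the simplex around the incumbent
  for (round in 1:8) {
    fit <- stats::optim(best$par, obj_v, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-15))
    if (fit$value >= best$value - 1e-13) {
      if (fit$value < best$value) best <- fit
      break
    }
    best <- fit
  }
  K <- best$par^2 / sum(best$par^2)
  # snap negligible components to the simplex boundary when that helps
  snap <- K
  snap[snap < 1e-9] <- 0
  if (sum(snap) > 0) {
    snap <- snap / sum(snap)
    if (divdir_objective(snap, m) <= best$value) K <- snap
  }
  # pure strategies are always candidate solutions
  for (k in 1:3) {
    pure <- as.numeric(1:3 == k)
    if (divdir_objective(pure, m) < divdir_objective(K, m)) K <- pure
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  division_direction_model(K, objective = divdir_objective(K / sum(K), m),
                           n_obs = nrow(obs))
}

#' Predict the division axis of a cell in its current geometry
#'
#' Computes the polarity, cell-cell squeeze, and eggshell squeeze components
#' from the cell's surroundings and composes them with the model
#' coefficients.
#'
#' @param model a [division_direction_model()].
#' @param cell one-row cell data frame; its polarity columns must be set.
#' @param neighbors cell data frame of neighboring cells (may be empty).
#' @param shell an [eggshell()] or `NULL`.
#' @return unit 3-vector division axis.
#' @export
predict_axis <- function(model, cell, neighbors = NULL, shell = NULL) {
  p <- as.numeric(cell[1, c("px", "py", "pz")])
  if (anyNA(p)) stop("cell has no polarity", call. = FALSE)
  s <- neighbor_squeeze_vector(cell, neighbors)
  e <- if (is.null(shell)) c(0, 0, 0) else eggshell_squeeze_vector(cell, shell)
  compose_direction(model, p, s, e)
}

#' Read and write observed-division tables
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return `read_observations`: data frame with the observation columns.
#' @export
read_observations <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(OBS_COLS, names(df))
  if (length(missing_cols)) {
    stop("observation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df[OBS_COLS]
}

#' @rdname read_observations
#' @param obs observation data frame.
#' @export
write_observations <- function(obs, path, sep = ",") {
  stopifnot(all(OBS_COLS %in% names(obs)))
  utils::write.table(obs[OBS_COLS], path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted model as JSON
#'
#' @param model a [division_direction_model()].
#' @param path JSON file path.
#' @export
write_divdir_model <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, objective = model$objective, n_obs = model$n_obs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_divdir_model
#' @export
read_divdir_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  division_direction_model(x$K,
                           objective = if (is.null(x$objective)) NA_real_ else x$objective,
                           n_obs = if (is.null(x$n_obs)) NA_integer_ else x$n_obs)
}
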