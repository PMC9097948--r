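#' @title Quasi-equilibrium spring-mass mechanics
#'
#' @description
#' Cells are point masses; contacting neighbors are joined by harmonic
#' springs with rest length equal to the sum of the two cell radii; the
#' rigid eggshell is a one-sided quadratic penalty on the normalized
#' ellipsoid coordinate. Because mechanical relaxation is fast relative to
#' the 1-minute observation cadence (inertia and damping are negligible
#' against the spring forces), positions at every observation step are
#' obtained by minimizing the total potential energy.
#'
#' Cell tables are plain data frames with columns `name`, `x`, `y`, `z`,
#' `radius` and optional polarity columns `px`, `py`, `pz`.
#'
#' @name mechanics
NULL

#' Construct a cell record
#'
#' @param name cell name.
#' @param position numeric 3-vector, micrometres.
#' @param radius cell radius, micrometres (> 0).
#' @param polarity optional unit 3-vector.
#' @return one-row cell data frame.
#' @export
cell <- function(name, position, radius, polarity = NULL) {
  stopifnot_scalar(radius, "radius", positive = TRUE)
  stopifnot(length(position) == 3L, all(is.finite(position)))
  if (is.null(polarity)) {
    polarity <- c(NA_real_, NA_real_, NA_real_)
  } else if (!is_unit(polarity)) {
    stop("`polarity` must be a unit 3-vector", call. = FALSE)
  }
  data.frame(name = name, x = position[1], y = position[2], z = position[3],
             radius = radius, px = polarity[1], py = polarity[2],
             pz = polarity[3], stringsAsFactors = FALSE)
}

cell_positions <- function(cells) {
  m <- as.matrix(cells[, c("x", "y", "z")])
  rownames(m) <- cells$name
  m
}

cell_polarity <- function(cells, name) {
  i <- match(name, cells$name)
  p <- as.numeric(cells[i, c("px", "py", "pz")])
  if (anyNA(p)) NULL else p
}

#' Ellipsoidal eggshell
#'
#' @param semi_axes numeric 3-vector `(a, b, c)` of semi-axes in micrometres,
#'   `a >= b >= c > 0`. Default matches an embryo roughly 50 um long with a
#'   30 um diameter.
#' @param center centre, micrometres.
#' @return an `eggshell` object.
#' @export
eggshell <- function(semi_axes = c(25, 15, 15), center = c(0, 0, 0)) {
  stopifnot(length(semi_axes) == 3L, length(center) == 3L)
  if (!(semi_axes[1] >= semi_axes[2] && semi_axes[2] >= semi_axes[3] &&
        semi_axes[3] > 0)) {
    stop("eggshell semi-axes must satisfy a >= b >= c > 0", call. = FALSE)
  }
  structure(list(semi_axes = as.numeric(semi_axes),
                 center = as.numeric(center)),
            class = "eggshell")
}

#' @export
print.eggshell <- function(x, ...) {
  cat(sprintf("<eggshell> semi-axes (%g, %g, %g) um at (%g, %g, %g)\n",
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# Normalized ellipsoid coordinate g(x) = sqrt((x/a)^2 + (y/b)^2 + (z/c)^2):
# 1 on the shell surface, < 1 inside. `rel` is an n x 3 matrix of positions
# relative to the shell centre.
shell_g <- function(rel, semi) {
  sqrt(rowSums(sweep(rel, 2, semi, "/")^2))
}

# Effective normalized radius: a step of delta um along the radial direction
# changes g by delta * g / |x|, so a cell of radius r occupies r * g / |x|
# in normalized units. At the centre (g = 0) fall back to r / min(semi).
shell_reach <- function(rel, semi, radius, eps = 1e-9) {
  rho <- sqrt(rowSums(rel^2))
  g <- shell_g(rel, semi)
  reach <- ifelse(rho > eps, radius * g / rho, radius / min(semi))
  list(g = g, rho = rho, reach = reach, h = g + reach - 1)
}

#' Build the contact spring network
#'
#' Two cells are neighbors (joined by a spring) iff their centre distance is
#' at most `contact_factor * (r_i + r_j)`; the spring rest length is
#' `r_i + r_j` and all springs share one stiffness.
#'
#' @param cells cell data frame (see [cell()]).
#' @param contact_factor dimensionless contact threshold (> 0).
#' @param stiffness spring constant, energy per um^2.
#' @return a `spring_network`: list with `cells` and an edge data frame
#'   `(i, j, k, L0)`.
#' @export
build_neighbor_graph <- function(cells, contact_factor = 1.2, stiffness = 1) {
  stopifnot_scalar(contact_factor, "contact_factor", positive = TRUE)
  stopifnot_scalar(stiffness, "stiffness", positive = TRUE)
  n <- nrow(cells)
  if (n < 1L) stop("need at least one cell", call. = FALSE)
  pos <- cell_positions(cells)
  d <- as.matrix(stats::dist(pos))
  if (n > 1L) {
    off <- d[upper.tri(d)]
    if (any(off < 1e-9)) {
      stop("degeneracy error: coincident cell positions", call. = FALSE)
    }
  }
  rsum <- outer(cells$radius, cells$radius, "+")
  hit <- which(upper.tri(d) & d <= contact_factor * rsum, arr.ind = TRUE)
  edges <- data.frame(i = hit[, 1], j = hit[, 2],
                      k = rep(stiffness, nrow(hit)),
                      L0 = rsum[hit])
  structure(list(cells = cells, edges = edges,
                 contact_factor = contact_factor),
            class = "spring_network")
}

#' @export
print.spring_network <- function(x, ...) {
  cat(sprintf("<spring_network> %d cells, %d springs\n",
              nrow(x$cells), nrow(x$edges)))
  invisible(x)
}

# Total potential energy and its gradient. pos: n x 3; returns list(E, grad).
energy_gradient <- function(pos, edges, radii, shell = NULL, shell_k = 10) {
  n <- nrow(pos)
  grad <- matrix(0, n, 3)
  E <- 0
  if (nrow(edges)) {
    dvec <- pos[edges$i, , drop = FALSE] - pos[edges$j, , drop = FALSE]
    len <- sqrt(rowSums(dvec^2))
    stretch <- len - edges$L0
    E <- E + sum(0.5 * edges$k * stretch^2)
    coef <- edges$k * stretch / pmax(len, 1e-300)
    gvec <- dvec * coef
    for (col in 1:3) {
      grad[, col] <- grad[, col] +
        tabulate_add(edges$i, gvec[, col], n) -
        tabulate_add(edges$j, gvec[, col], n)
    }
  }
  if (!is.null(shell)) {
    rel <- sweep(pos, 2, shell$center)
    sr <- shell_reach(rel, shell$semi_axes, radii)
    act <- which(sr$h > 0)
    if (length(act)) {
      E <- E + sum(0.5 * shell_k * sr$h[act]^2)
      semi2 <- shell$semi_axes^2
      for (i in act) {
        g <- sr$g[i]; rho <- sr$rho[i]; r <- radii[i]
        if (g < 1e-12 || rho < 1e-12) next  # zero-gradient centre, documented
        dg <- rel[i, ] / semi2 / g
        dh <- (1 + r / rho) * dg - (g * r / rho^3) * rel[i, ]
        grad[i, ] <- grad[i, ] + shell_k * sr$h[i] * dh
      }
    }
  }
  list(E = E, grad = grad)
}

tabulate_add <- function(idx, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Potential energy of a spring network inside the eggshell
#'
#' `E = sum_edges 1/2 k (|x_i - x_j| - L0)^2 +
#'  sum_cells 1/2 k_shell max(0, g(x) + r_norm - 1)^2`, where `g` is the
#' normalized ellipsoid coordinate and `r_norm` the cell radius expressed in
#' normalized units along the local radial direction.
#'
#' @param net a `spring_network`.
#' @param shell an [eggshell()], or `NULL` for no confinement.
#' @param positions optional n x 3 matrix overriding the cells' positions.
#' @param shell_k eggshell penalty stiffness.
#' @return scalar energy (>= 0).
#' @export
potential_energy <- function(net, shell = NULL, positions = NULL,
                             shell_k = 10) {
  if (is.null(positions)) positions <- cell_positions(net$cells)
  stopifnot(all(is.finite(positions)))
  energy_gradient(positions, net$edges, net$cells$radius, shell, shell_k)$E
}

#' Relax a spring network to mechanical equilibrium
#'
#' Minimizes [potential_energy()] over the free cell positions with L-BFGS-B
#' and the analytic gradient, until the gradient max-norm over free
#' coordinates is at most `tol_grad`. Frozen cells do not move. When no
#' eggshell is present the energy is invariant under rigid motions, so the
#' first free cell is pinned and the second restricted to the line joining
#' it to the first (gauge fixing; disable with `gauge = FALSE`).
#'
#' @param net a `spring_network`.
#' @param shell an [eggshell()] or `NULL`.
#' @param frozen character vector of cell names that must not move.
#' @param shell_k eggshell penalty stiffness.
#' @param tol_grad gradient max-norm tolerance, energy per um.
#' @param max_iter iteration cap for the minimizer.
#' @param gauge pin rigid-body freedom when no shell is active.
#' @return list with `positions` (n x 3, named rows), `energy`,
#'   `initial_energy`, and `grad_max`.
#' @export
relax_to_equilibrium <- function(net, shell = NULL, frozen = character(0),
                                 shell_k = 10, tol_grad = 1e-6,
                                 max_iter = 10000, gauge = is.null(shell)) {
  cells <- net$cells
  n <- nrow(cells)
  pos0 <- cell_positions(cells)
  is_frozen <- cells$name %in% frozen
  if (all(is_frozen)) stop("at least one cell must be unfrozen", call. = FALSE)

  # per-cell basis of allowed displacement directions (3 x m_i)
  basis <- vector("list", n)
  free_idx <- which(!is_frozen)
  for (i in free_idx) basis[[i]] <- diag(3)
  if (gauge && length(free_idx) >= 1L) {
    basis[free_idx[1]] <- list(NULL)               # pin first free cell
    if (length(free_idx) >= 2L) {
      axis <- pos0[free_idx[2], ] - pos0[free_idx[1], ]
      if (vec_norm(axis) > 1e-12) {
        basis[[free_idx[2]]] <- matrix(unit_vector(axis), 3, 1)
      }
    }
  }
  m <- vapply(basis, function(b) if (is.null(b)) 0L else ncol(b), 0L)
  offs <- c(0L, cumsum(m))
  npar <- offs[n + 1L]
  radii <- cells$radius
  edges <- net$edges

  to_pos <- function(theta) {
    pos <- pos0
    for (i in which(m > 0L)) {
      pos[i, ] <- pos0[i, ] + as.numeric(basis[[i]] %*%
                                           theta[(offs[i] + 1L):offs[i + 1L]])
    }
    pos
  }
  fn <- function(theta) {
    energy_gradient(to_pos(theta), edges, radii, shell, shell_k)$E
  }
  gr <- function(theta) {
    g <- energy_gradient(to_pos(theta), edges, radii, shell, shell_k)$grad
    out <- numeric(npar)
    for (i in which(m > 0L)) {
      out[(offs[i] + 1L):offs[i + 1L]] <- crossprod(basis[[i]], g[i, ])
    }
    out
  }

  e0 <- fn(numeric(npar))
  if (npar == 0L) {
    return(list(positions = pos0, energy = e0, initial_energy = e0,
                grad_max = 0))
  }
  theta <- numeric(npar)
  gmax <- Inf
  for (round in 1:6) {
    fit <- stats::optim(theta, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter,
                                       pgtol = tol_grad / 10, factr = 10))
    theta <- fit$par
    gmax <- max(abs(gr(theta)))
    if (gmax <= tol_grad) break
  }
  pos <- to_pos(theta)
  e1 <- fn(theta)
  if (gmax > tol_grad) {
    stop(errorCondition(
      sprintf("relaxation did not reach gradient tolerance (%.3g > %.3g)",
              gmax, tol_grad),
      class = "embryosim_convergence_error",
      positions = pos, energy = e1, grad_max = gmax))
  }
  list(positions = pos, energy = min(e1, e0), initial_energy = e0,
       grad_max = gmax)
}

#' Split a mother cell into two daughters
#'
#' Daughters are placed at `mother_position +/- offset_fraction * radius *
#' direction`, each with radius `r / 2^(1/3)` so the two daughters together
#' conserve the mother's volume exactly. Daughters inherit the mother's
#' polarity unless `polarity` overrides it (the simulator passes the chosen
#' division axis).
#'
#' @param mother one-row cell data frame.
#' @param direction unit 3-vector along the division axis.
#' @param offset_fraction fraction of the mother radius separating each
#'   daughter from the mother centre, in (0, 1].
#' @param names character 2-vector of daughter names, `(plus, minus)` along
#'   `+direction` / `-direction`; defaults to `name + c("1","2")`.
#' @param polarity optional unit 3-vector overriding inherited polarity.
#' @return two-row cell data frame (daughter on `+direction` first).
#' @export
place_daughters <- function(mother, direction, offset_fraction = 0.5,
                            names = NULL, polarity = NULL) {
  direction <- unit_vector(direction)
  stopifnot_scalar(offset_fraction, "offset_fraction", positive = TRUE)
  if (offset_fraction > 1) stop("`offset_fraction` must be <= 1", call. = FALSE)
  if (is.null(names)) names <- paste0(mother$name, c("1", "2"))
  x0 <- as.numeric(mother[1, c("x", "y", "z")])
  r <- mother$radius[1]
  rd <- r / 2^(1 / 3)
  pol <- if (!is.null(polarity)) {
    unit_vector(polarity)
  } else {
    as.numeric(mother[1, c("px", "py", "pz")])
  }
  off <- offset_fraction * r * direction
  rbind(
    data.frame(name = names[1], x = x0[1] + off[1], y = x0[2] + off[2],
               z = x0[3] + off[3], radius = rd, px = pol[1], py = pol[2],
               pz = pol[3], stringsAsFactors = FALSE),
    data.frame(name = names[2], x = x0[1] - off[1], y = x0[2] - off[2],
               z = x0[3] - off[3], radius = rd, px = pol[1], py = pol[2],
               pz = pol[3], stringsAsFactors = FALSE))
}

#' Read and write nuclei time-series tables
#'
#' The interchange format for tracked nuclei positions: delimiter-separated
#' text with header `time,name,x,y,z,radius` (micrometres), one row per live
#' cell per time point. The reader tolerates extra columns.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return `read_nuclei_table`: data frame with the six canonical columns
#'   first.
#' @export
read_nuclei_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("time", "name", "x", "y", "z", "radius")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("nuclei table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df[c(req, setdiff(names(df), req))]
}

#' @rdname read_nuclei_table
#' @param df data frame with columns `time,name,x,y,z,radius`.
#' @export
write_nuclei_table <- function(df, path, sep = ",") {
  req <- c("time", "name", "x", "y", "z", "radius")
  stopifnot(all(req %in% names(df)))
  utils::write.table(format(df[req], digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
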