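#' @title Synthetic fixtures: lineages, observed divisions, scenarios
#'
#' @description
#' Stand-ins for the predefined observation datasets: complete binary
#' lineages with uniform division intervals, observed-division tables
#' generated from a known coefficient vector with controlled angular noise
#' (the oracle for coefficient recovery), and migration scenarios including
#' a Cpaaa-like intercalation field with four ordered sub-goals. Every
#' generator is a pure function of its parameters and seed.
#'
#' @name synthetic_data
NULL

#' Generate a complete binary lineage
#'
#' @param generations number of division rounds (0 = a single terminal
#'   root).
#' @param division_interval minutes between successive divisions.
#' @param root_name name of the root cell.
#' @param birth_time birth time of the root, minutes.
#' @return a [lineage_tree()] with `2^(generations+1) - 1` cells; fates are
#'   assigned cyclically over the five tissue labels plus "other".
#' @export
synth_lineage <- function(generations = 4, division_interval = 10,
                          root_name = "R", birth_time = 0) {
  stopifnot(generations >= 0, division_interval > 0)
  rows <- list(list(name = root_name, parent = NA_character_,
                    birth = birth_time, gen = 0L))
  out <- list()
  k <- 0L
  while (length(rows)) {
    nd <- rows[[1]]; rows <- rows[-1]
    divides <- nd$gen < generations
    k <- k + 1L
    out[[k]] <- data.frame(
      name = nd$name, parent = nd$parent, birth_time = nd$birth,
      division_time = if (divides) nd$birth + division_interval else NA_real_,
      fate = FATE_LEVELS[(k - 1L) %% 6L + 1L],
      stringsAsFactors = FALSE)
    if (divides) {
      for (sfx in c("a", "p")) {
        rows[[length(rows) + 1L]] <- list(
          name = paste0(nd$name, sfx), parent = nd$name,
          birth = nd$birth + division_interval, gen = nd$gen + 1L)
      }
    }
  }
  lineage_tree(do.call(rbind, out))
}

# Rotate unit vector d by `angle` about a unit axis u orthogonal to d:
# d' = d cos(angle) + (u x d) sin(angle).
rotate_about_transverse <- function(d, u, angle) {
  d * cos(angle) + cross3(u, d) * sin(angle)
}

#' Generate observed divisions from known coefficients
#'
#' Direction components are drawn uniformly on the sphere (the squeeze
#' components are zeroed independently with probability `p_zero` to mimic
#' cells without overlap or shell contact); the observed axis is the
#' composed direction perturbed by a rotation about a random transverse
#' axis. The rotation angle is half-normal with mean `noise_angle_deg`
#' degrees, so `noise_angle_deg` is the expected angular deviation.
#'
#' @param K_true coefficient 3-vector on the simplex.
#' @param n number of observations.
#' @param noise_angle_deg mean angular deviation, degrees.
#' @param seed integer seed.
#' @param p_zero probability that each squeeze component is absent.
#' @return observation data frame (see [read_observations()] for the
#'   layout).
#' @export
synth_divisions <- function(K_true, n, noise_angle_deg = 0, seed = 1,
                            p_zero = 0.3) {
  stopifnot(n >= 1, noise_angle_deg >= 0)
  model <- division_direction_model(K_true)
  set.seed(seed)
  P <- runif_sphere(n)
  S <- runif_sphere(n) * (stats::runif(n) >= p_zero)
  E <- runif_sphere(n) * (stats::runif(n) >= p_zero)
  # half-normal with mean noise_angle_deg: scale = mean * sqrt(pi/2)
  ang <- abs(stats::rnorm(n, 0, noise_angle_deg * sqrt(pi / 2))) * pi / 180
  D <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    d <- compose_direction(model, P[i, ], S[i, ], E[i, ])
    u <- orthogonal_unit_random(d)
    D[i, ] <- rotate_about_transverse(d, u, ang[i])
  }
  data.frame(name = sprintf("obs%03d", seq_len(n)),
             px = P[, 1], py = P[, 2], pz = P[, 3],
             sx = S[, 1], sy = S[, 2], sz = S[, 3],
             ex = E[, 1], ey = E[, 2], ez = E[, 3],
             dx = D[, 1], dy = D[, 2], dz = D[, 3],
             stringsAsFactors = FALSE)
}

# Uniformly random unit vector orthogonal to d.
orthogonal_unit_random <- function(d) {
  v <- stats::rnorm(3)
  v <- v - sum(v * d) * d
  while (vec_norm(v) < 1e-9) {
    v <- stats::rnorm(3)
    v <- v - sum(v * d) * d
  }
  unit_vector(v)
}

#' Generate a migration scenario
#'
#' Four kinds:
#' * `corridor`: a 1 x `length` free lane, destination at the far end.
#' * `open_grid`: an empty `size` x `size` grid, corner to corner.
#' * `detour`: a `size` x `size` grid with a wall forcing a detour.
#' * `cpaaa_like`: a band of occupied cells with a single intercalation
#'   channel; four ordered sub-goals sit along the channel before the
#'   destination, mirroring the rosette way-points of the Cpaaa path.
#'
#' @param kind scenario kind.
#' @param seed integer seed (kept for interface uniformity; layouts are
#'   deterministic).
#' @param length corridor length (free sites).
#' @param size grid edge for `open_grid` / `detour`.
#' @return a [migration_env()]; destination reachability is checked on
#'   construction by breadth-first search.
#' @export
synth_migration_scenario <- function(kind = c("corridor", "open_grid",
                                              "detour", "cpaaa_like"),
                                     seed = 1, length = 5, size = 7) {
  kind <- match.arg(kind)
  env <- switch(kind,
    corridor = migration_env(
      dims = c(length, 1), occupied = NULL,
      start = c(1, 1), goals = list(c(length, 1))),
    open_grid = migration_env(
      dims = c(size, size), occupied = NULL,
      start = c(1, 1), goals = list(c(size, size))),
    detour = {
      # vertical wall through the middle with no opening except the top row
      wall_x <- (size + 1) %/% 2
      occ <- cbind(wall_x, seq_len(size - 1))
      migration_env(dims = c(size, size), occupied = occ,
                    start = c(1, (size + 1) %/% 2),
                    goals = list(c(size, (size + 1) %/% 2)))
    },
    cpaaa_like = {
      # two rows of neighbor cells flanking one open channel (row 4);
      # the migrating cell intercalates anteriorly through it
      occ <- rbind(cbind(4:10, 3L), cbind(4:10, 5L))
      migration_env(dims = c(13, 7), occupied = occ,
                    start = c(2, 4),
                    goals = list(c(4, 4), c(6, 4), c(8, 4), c(10, 4),
                                 c(12, 4)),
                    max_steps = 300)
    })
  check_reachable(env)
  env
}
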