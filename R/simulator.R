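#' @title The agent-based embryo simulation engine
#'
#' @description
#' Advances the embryo in 1-minute observation steps. At each step, cells
#' whose scheduled division time has arrived divide (in lexicographic name
#' order): the division axis is composed by the division-direction model
#' from the mother's polarity and the current squeeze geometry, daughters
#' are named by the Sulston convention against the AP axis and placed along
#' the axis, and the contact network is rebuilt. The broken mechanical
#' equilibrium is then restored by potential-energy minimization before the
#' step is recorded.
#'
#' @name simulator
NULL

#' Simulation configuration
#'
#' @param eggshell_semi_axes eggshell semi-axes `(a, b, c)`, micrometres.
#' @param ap_axis unit 3-vector pointing anterior.
#' @param time_step observation cadence, minutes.
#' @param spring_k spring stiffness, energy per um^2.
#' @param shell_k eggshell penalty stiffness.
#' @param contact_factor neighbor contact threshold (see
#'   [build_neighbor_graph()]).
#' @param offset_fraction daughter placement offset (see
#'   [place_daughters()]).
#' @param division_K coefficient 3-vector for the division-direction model,
#'   or a fitted [division_direction_model()].
#' @param initial_radius root-cell radius, micrometres. The default (15)
#'   makes the 16-cell stage fill about 60% of the default shell volume.
#' @param seed integer seed (daughter-placement jitter of degenerate
#'   configurations).
#' @param end_time final simulated minute; default runs one step past the
#'   last scheduled division.
#' @param tol_grad,max_iter relaxation controls (see
#'   [relax_to_equilibrium()]).
#' @return a `sim_config`.
#' @export
sim_config <- function(eggshell_semi_axes = c(25, 15, 15),
                       ap_axis = c(1, 0, 0), time_step = 1,
                       spring_k = 1, shell_k = 10, contact_factor = 1.2,
                       offset_fraction = 0.5,
                       division_K = c(0.6, 0.3, 0.1),
                       initial_radius = 15, seed = 1, end_time = NULL,
                       tol_grad = 1e-6, max_iter = 10000) {
  model <- if (inherits(division_K, "division_direction_model")) {
    division_K
  } else {
    division_direction_model(division_K)
  }
  structure(list(eggshell_semi_axes = eggshell_semi_axes,
                 ap_axis = unit_vector(ap_axis), time_step = time_step,
                 spring_k = spring_k, shell_k = shell_k,
                 contact_factor = contact_factor,
                 offset_fraction = offset_fraction,
                 division_model = model,
                 initial_radius = initial_radius, seed = seed,
                 end_time = end_time, tol_grad = tol_grad,
                 max_iter = max_iter),
            class = "sim_config")
}

#' Read / write a simulation configuration (YAML)
#'
#' @param path file path.
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_config, x)
}

#' @rdname read_sim_config
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$division_K <- x$division_model$K
  x$division_model <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

neighbors_of <- function(cells, name, contact_factor) {
  i <- match(name, cells$name)
  pos <- cell_positions(cells)
  d <- sqrt(colSums((t(pos) - pos[i, ])^2))
  hit <- d <= contact_factor * (cells$radius[i] + cells$radius) &
    seq_len(nrow(cells)) != i
  cells[hit, , drop = FALSE]
}

# De-duplicate coincident positions with a tiny seeded jitter (logged);
# exact coincidences make spring directions undefined.
jitter_coincident <- function(cells, eps = 1e-6) {
  if (nrow(cells) < 2L) return(cells)
  repeat {
    d <- stats::dist(cell_positions(cells))
    if (all(d >= 1e-9)) return(cells)
    message("jittering coincident cell positions by ", eps, " um")
    hit <- which(as.matrix(d) < 1e-9, arr.ind = TRUE)
    i <- hit[hit[, 1] < hit[, 2], 1][1]
    cells[i, c("x", "y", "z")] <- cells[i, c("x", "y", "z")] +
      eps * runif_sphere(1)[1, ]
  }
}

#' Run the embryo simulation
#'
#' @param config a [sim_config()].
#' @param lineage a [lineage_tree()]; fate and division times come from it.
#' @param initial_state optional cell data frame for the cells alive at the
#'   start time; by default a single root cell is placed at the shell
#'   centre with `config$initial_radius` and polarity along the AP axis.
#' @return an `embryo_trajectory`: list with `snapshots` (data frame
#'   `time,name,x,y,z,radius`), `events` (one row per division: time,
#'   mother, daughters, chosen axis), and the `config`.
#' @export
run_simulation <- function(config, lineage, initial_state = NULL) {
  validate_lineage(lineage)
  shell <- eggshell(config$eggshell_semi_axes)
  t0 <- min(lineage$birth_time)
  tend <- config$end_time
  if (is.null(tend)) {
    tend <- if (all(is.na(lineage$division_time))) {
      t0 + 10 * config$time_step
    } else {
      max(lineage$division_time, na.rm = TRUE) + config$time_step
    }
  }
  if (tend < t0) stop("end time precedes the lineage start", call. = FALSE)

  alive0 <- cells_alive_at(lineage, t0)
  if (is.null(initial_state)) {
    if (length(alive0) != 1L) {
      stop("supply `initial_state` when more than one cell is alive at the ",
           "start time", call. = FALSE)
    }
    cells <- cell(alive0, shell$center, config$initial_radius,
                  polarity = config$ap_axis)
  } else {
    cells <- initial_state
    if (!setequal(cells$name, alive0)) {
      stop("consistency error: initial_state cells do not match the ",
           "lineage cells alive at the start time", call. = FALSE)
    }
  }

  set.seed(config$seed)
  model <- config$division_model
  snapshots <- list()
  events <- list()
  for (t in seq(t0, tend, by = config$time_step)) {
    due <- lineage$name[!is.na(lineage$division_time) &
                          lineage$division_time == t]
    for (mother_name in sort(due)) {
      if (!(mother_name %in% cells$name)) {
        stop(sprintf("consistency error at t=%g: dividing cell %s not present",
                     t, mother_name), call. = FALSE)
      }
      mother <- cells[cells$name == mother_name, , drop = FALSE]
      nbrs <- neighbors_of(cells, mother_name, config$contact_factor)
      # highly symmetric geometries can cancel the composition exactly;
      # fall back to the mother's polarity axis
      axis <- tryCatch(predict_axis(model, mother, nbrs, shell),
                       error = function(e) {
                         message(sprintf(
                           "t=%g: degenerate axis composition for %s; using polarity",
                           t, mother_name))
                         unit_vector(as.numeric(mother[1, c("px", "py", "pz")]))
                       })
      kid_names <- resolve_daughter_names(lineage, mother_name, axis,
                                          config$ap_axis)
      # kid_names is (anterior, posterior); anterior sits at +axis iff the
      # axis points anterior
      plus_first <- if (anterior_sign(axis, config$ap_axis) > 0) {
        kid_names
      } else {
        rev(kid_names)
      }
      daughters <- place_daughters(mother, axis, config$offset_fraction,
                                   names = plus_first, polarity = axis)
      cells <- rbind(cells[cells$name != mother_name, , drop = FALSE],
                     daughters)
      events[[length(events) + 1L]] <- data.frame(
        time = t, mother = mother_name,
        daughter_a = kid_names[1], daughter_p = kid_names[2],
        axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
        stringsAsFactors = FALSE)
    }
    cells <- jitter_coincident(cells)
    net <- build_neighbor_graph(cells, config$contact_factor,
                                config$spring_k)
    rel <- relax_to_equilibrium(net, shell, shell_k = config$shell_k,
                                tol_grad = config$tol_grad,
                                max_iter = config$max_iter)
    cells[, c("x", "y", "z")] <- rel$positions
    snapshots[[length(snapshots) + 1L]] <- data.frame(
      time = t, name = cells$name, x = cells$x, y = cells$y, z = cells$z,
      radius = cells$radius, stringsAsFactors = FALSE)
  }
  snap <- do.call(rbind, snapshots)
  rownames(snap) <- NULL
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), mother = character(0),
               daughter_a = character(0), daughter_p = character(0),
               axis_x = numeric(0), axis_y = numeric(0),
               axis_z = numeric(0), stringsAsFactors = FALSE)
  structure(list(snapshots = snap, events = ev, config = config,
                 final_cells = cells),
            class = "embryo_trajectory")
}

# Daughter names: the lineage tree is authoritative; daughter_names()
# resolves which child is anterior. Children that do not follow the a/p
# suffix convention (founder cells, arbitrary synthetic names) are matched
# by the founder table or, failing that, lexicographically.
resolve_daughter_names <- function(lineage, mother, axis, ap_axis) {
  kids <- children_of(lineage, mother)
  conv <- daughter_names(mother, axis, ap_axis)
  if (setequal(kids, conv)) return(conv)
  kids  # sorted: first lexicographic child is anterior
}

#' @export
print.embryo_trajectory <- function(x, ...) {
  times <- unique(x$snapshots$time)
  cat(sprintf(
    "<embryo_trajectory> t = [%g, %g] (%d steps), %d division(s), final %d cells\n",
    min(times), max(times), length(times), nrow(x$events),
    sum(x$snapshots$time == max(times))))
  invisible(x)
}

#' Cell counts per recorded time point
#'
#' @param traj an `embryo_trajectory`.
#' @return data frame `time`, `n_cells`.
#' @export
cell_counts <- function(traj) {
  tab <- table(traj$snapshots$time)
  data.frame(time = as.numeric(names(tab)), n_cells = as.integer(tab))
}

#' Write / read a trajectory as a nuclei time-series table
#'
#' @param traj an `embryo_trajectory` (or its `snapshots` data frame).
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- if (inherits(traj, "embryo_trajectory")) traj$snapshots else traj
  write_nuclei_table(df, path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read_nuclei_table(path)
}
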