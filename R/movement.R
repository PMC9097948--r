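#' @title Directed single-cell migration by tabular reinforcement learning
#'
#' @description
#' Directed migration (the anterior intercalation of Cpaaa is the motivating
#' case) is framed as a path-optimization problem on a bounded integer
#' lattice: neighboring cells are static occupied sites, the eggshell is
#' the lattice boundary, and the migrating cell must visit an ordered list
#' of sub-goals (rosette way-points) before its destination. A tabular
#' Q-learner is trained over states `(site - current goal, local occupancy
#' mask, goal index)` with axis-aligned unit moves plus "stay".
#'
#' @name movement
NULL

# Axis-aligned moves (+x, -x, +y, -y[, +z, -z]) then "stay"; greedy
# tie-breaks take the lowest action index.
action_moves <- function(d) {
  mv <- matrix(0L, 2L * d + 1L, d)
  for (ax in seq_len(d)) {
    mv[2L * ax - 1L, ax] <- 1L
    mv[2L * ax, ax] <- -1L
  }
  mv
}

site_key <- function(site) paste(site, collapse = ",")

#' Construct a migration environment
#'
#' @param dims integer vector (length 2 or 3) of lattice extents; sites are
#'   `1..dims[k]` along axis `k`.
#' @param occupied integer matrix (rows are sites) of obstacle cells; may
#'   have zero rows.
#' @param start integer site of the migrating cell.
#' @param goals list (or matrix rows) of integer sites: sub-goals in order,
#'   destination last.
#' @param spacing lattice spacing in micrometres.
#' @param step_cost,collision_penalty,goal_reward reward constants.
#' @param max_steps episode cap.
#' @return a `migration_env`.
#' @export
migration_env <- function(dims, occupied, start, goals, spacing = 1,
                          step_cost = 1, collision_penalty = 5,
                          goal_reward = 100, max_steps = 200) {
  dims <- as.integer(dims)
  d <- length(dims)
  stopifnot(d %in% c(2L, 3L), all(dims >= 1L))
  occupied <- if (is.null(occupied) || NROW(occupied) == 0L) {
    matrix(integer(0), 0, d)
  } else {
    matrix(as.integer(as.matrix(occupied)), ncol = d)
  }
  if (is.matrix(goals)) goals <- lapply(seq_len(nrow(goals)), function(i) goals[i, ])
  goals <- lapply(goals, as.integer)
  start <- as.integer(start)
  stopifnot(length(start) == d, all(lengths(goals) == d), length(goals) >= 1L)
  occ_keys <- apply(occupied, 1, site_key)
  if (length(occ_keys) == 0L) occ_keys <- character(0)
  for (s in c(list(start), goals)) {
    if (any(s < 1L) || any(s > dims)) stop("site off-lattice", call. = FALSE)
    if (site_key(s) %in% occ_keys) {
      stop("start and goals must be unoccupied", call. = FALSE)
    }
  }
  if (anyDuplicated(vapply(goals, site_key, ""))) {
    stop("goals must be distinct", call. = FALSE)
  }
  stopifnot_scalar(step_cost, "step_cost")
  stopifnot_scalar(collision_penalty, "collision_penalty")
  stopifnot_scalar(goal_reward, "goal_reward", positive = TRUE)
  structure(list(dims = dims, d = d, occupied = occupied,
                 occ_keys = occ_keys, start = start, goals = goals,
                 spacing = spacing, step_cost = step_cost,
                 collision_penalty = collision_penalty,
                 goal_reward = goal_reward,
                 max_steps = as.integer(max_steps),
                 moves = action_moves(d)),
            class = "migration_env")
}

#' @export
print.migration_env <- function(x, ...) {
  cat(sprintf(
    "<migration_env> %s lattice, %d occupied, %d goal(s), start (%s)\n",
    paste(x$dims, collapse = "x"), nrow(x$occupied), length(x$goals),
    paste(x$start, collapse = ",")))
  invisible(x)
}

env_blocked <- function(env, site) {
  any(site < 1L) || any(site > env$dims) || site_key(site) %in% env$occ_keys
}

#' Initial state of a migration episode
#'
#' Goals already satisfied at the start site are consumed immediately.
#'
#' @param env a [migration_env()].
#' @return state list `(site, goal_idx, steps, done)`.
#' @export
env_reset <- function(env) {
  st <- list(site = env$start, goal_idx = 1L, steps = 0L, done = FALSE)
  while (!st$done && identical(st$site, env$goals[[st$goal_idx]])) {
    st$goal_idx <- st$goal_idx + 1L
    if (st$goal_idx > length(env$goals)) st$done <- TRUE
  }
  st
}

#' One environment transition
#'
#' The move is blocked (agent stays, collision penalty applied) if the
#' target site is occupied or off-lattice. Reward is
#' `-step_cost - collision_penalty * blocked + goal_reward * reached_goal`;
#' reaching a sub-goal advances the goal index; the episode ends when the
#' final destination is reached or `max_steps` is exceeded.
#'
#' @param env a [migration_env()].
#' @param state state list from [env_reset()] or a previous step.
#' @param action action index in `1..nrow(env$moves)` (last = stay).
#' @return list `(state, reward, done)`.
#' @export
env_step <- function(env, state, action) {
  if (!(action %in% seq_len(nrow(env$moves)))) {
    stop("unknown action index", call. = FALSE)
  }
  target <- state$site + env$moves[action, ]
  blocked <- env_blocked(env, target)
  site <- if (blocked) state$site else target
  reward <- -env$step_cost - if (blocked) env$collision_penalty else 0
  goal_idx <- state$goal_idx
  done <- FALSE
  if (identical(as.integer(site), env$goals[[goal_idx]])) {
    reward <- reward + env$goal_reward
    goal_idx <- goal_idx + 1L
    if (goal_idx > length(env$goals)) done <- TRUE
  }
  steps <- state$steps + 1L
  if (steps >= env$max_steps) done <- TRUE
  list(state = list(site = as.integer(site), goal_idx = goal_idx,
                    steps = steps, done = done),
       reward = reward, done = done)
}

# State key for the Q-table: position relative to the current goal, the
# occupancy mask of the adjacent sites, and the goal index.
state_key <- function(env, site, goal_idx) {
  gi <- min(goal_idx, length(env$goals))
  rel <- site - env$goals[[gi]]
  mask <- apply(env$moves[-nrow(env$moves), , drop = FALSE], 1,
                function(mv) env_blocked(env, site + mv))
  paste(c(rel, as.integer(mask), gi), collapse = ",")
}

# Breadth-first distance between two free sites (internal reachability
# check; tests use an independent graph library as the oracle).
bfs_distance <- function(env, from, to) {
  if (identical(as.integer(from), as.integer(to))) return(0L)
  frontier <- list(as.integer(from))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(site_key(from), TRUE, seen)
  dist <- 0L
  while (length(frontier)) {
    dist <- dist + 1L
    nxt <- list()
    for (s in frontier) {
      for (a in seq_len(nrow(env$moves) - 1L)) {
        t <- s + env$moves[a, ]
        if (env_blocked(env, t)) next
        k <- site_key(t)
        if (exists(k, seen, inherits = FALSE)) next
        if (identical(t, as.integer(to))) return(dist)
        assign(k, TRUE, seen)
        nxt[[length(nxt) + 1L]] <- t
      }
    }
    frontier <- nxt
  }
  NA_integer_
}

check_reachable <- function(env) {
  legs <- c(list(env$start), env$goals)
  for (i in seq_len(length(legs) - 1L)) {
    if (is.na(bfs_distance(env, legs[[i]], legs[[i + 1L]]))) {
      stop(sprintf("configuration error: goal %d unreachable", i),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Train a migration policy by tabular Q-learning
#'
#' Epsilon-greedy Q-learning over the discretized state space. Training is
#' bit-reproducible for a fixed seed and configuration. An unreachable goal
#' sequence is rejected up front by a breadth-first connectivity check.
#'
#' @param env a [migration_env()].
#' @param episodes number of training episodes.
#' @param alpha learning rate in (0, 1].
#' @param gamma discount factor, at least 0 and below 1.
#' @param epsilon_schedule function(episode) -> exploration rate, or a
#'   numeric vector of length `episodes`; default decays linearly from 1 to
#'   0.05 over the first 80% of episodes.
#' @param seed integer RNG seed.
#' @return a `migration_policy`: the action-value table (named list of
#'   per-state action values), action count, and the per-episode return
#'   curve in `$episode_returns`.
#' @export
train_q_learning <- function(env, episodes = 600, alpha = 0.5, gamma = 0.95,
                             epsilon_schedule = NULL, seed = 1) {
  stopifnot(episodes >= 1, alpha > 0, alpha <= 1, gamma >= 0, gamma < 1)
  check_reachable(env)
  if (is.null(epsilon_schedule)) {
    epsilon_schedule <- function(ep) {
      max(0.05, 1 - (ep - 1) / max(1, 0.8 * episodes))
    }
  }
  eps_at <- if (is.function(epsilon_schedule)) {
    epsilon_schedule
  } else {
    function(ep) epsilon_schedule[[ep]]
  }
  n_actions <- nrow(env$moves)
  Q <- new.env(hash = TRUE, parent = emptyenv())
  q_get <- function(key) {
    if (exists(key, Q, inherits = FALSE)) get(key, Q) else numeric(n_actions)
  }
  set.seed(seed)
  returns <- numeric(episodes)
  for (ep in seq_len(episodes)) {
    eps <- eps_at(ep)
    st <- env_reset(env)
    total <- 0
    while (!st$done) {
      key <- state_key(env, st$site, st$goal_idx)
      qv <- q_get(key)
      a <- if (stats::runif(1) < eps) {
        sample.int(n_actions, 1L)
      } else {
        which.max(qv)
      }
      tr <- env_step(env, st, a)
      total <- total + tr$reward
      target <- tr$reward +
        if (tr$done) 0 else gamma * max(q_get(state_key(env, tr$state$site,
                                                        tr$state$goal_idx)))
      qv[a] <- qv[a] + alpha * (target - qv[a])
      assign(key, qv, Q)
      st <- tr$state
    }
    returns[ep] <- total
  }
  keys <- sort(ls(Q))
  table <- stats::setNames(lapply(keys, q_get), keys)
  structure(list(table = table, n_actions = n_actions,
                 episode_returns = returns,
                 config = list(episodes = episodes, alpha = alpha,
                               gamma = gamma, seed = seed)),
            class = "migration_policy")
}

#' @export
print.migration_policy <- function(x, ...) {
  cat(sprintf("<migration_policy> %d states x %d actions (%d episodes)\n",
              length(x$table), x$n_actions, x$config$episodes))
  invisible(x)
}

#' Greedy rollout of a trained policy
#'
#' Follows the greedy action (lowest index on ties) from the start site;
#' with `epsilon > 0` a random action is taken with that probability (the
#' protocol for averaging a migration path over repeated seeded runs).
#' In a fully greedy rollout, revisiting a (site, goal index) pair
#' indicates a policy loop; the rollout then stops and is reported as
#' failed.
#'
#' @param env a [migration_env()].
#' @param policy a trained `migration_policy`.
#' @param epsilon exploration rate during the rollout.
#' @param seed optional RNG seed for `epsilon > 0`.
#' @return list with `path` (matrix of visited sites, one row per time
#'   point, starting site included), `moves` (number of transitions),
#'   `reward` (total return), `success`, and `goal_times` (path row index
#'   at which each goal was reached).
#' @export
greedy_rollout <- function(env, policy, epsilon = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- env_reset(env)
  path <- matrix(st$site, 1, env$d)
  total <- 0
  goal_times <- rep(NA_integer_, length(env$goals))
  if (st$done) {  # start coincides with all goals
    goal_times[] <- 1L
    return(list(path = path, moves = 0L, reward = 0, success = TRUE,
                goal_times = goal_times))
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  repeat {
    if (epsilon == 0) {
      loop_key <- paste(site_key(st$site), st$goal_idx, sep = "|")
      if (exists(loop_key, seen, inherits = FALSE)) {
        warning("rollout failure: state revisited under the same goal")
        return(list(path = path, moves = nrow(path) - 1L, reward = total,
                    success = FALSE, goal_times = goal_times))
      }
      assign(loop_key, TRUE, seen)
    }
    qv <- policy$table[[state_key(env, st$site, st$goal_idx)]]
    if (is.null(qv)) qv <- numeric(policy$n_actions)
    a <- if (epsilon > 0 && stats::runif(1) < epsilon) {
      sample.int(policy$n_actions, 1L)
    } else {
      which.max(qv)
    }
    prev_goal <- st$goal_idx
    tr <- env_step(env, st, a)
    total <- total + tr$reward
    st <- tr$state
    path <- rbind(path, st$site)
    if (st$goal_idx > prev_goal) goal_times[prev_goal] <- nrow(path)
    if (st$done) break
  }
  reached_all <- st$goal_idx > length(env$goals)
  list(path = path, moves = nrow(path) - 1L, reward = total,
       success = reached_all, goal_times = goal_times)
}

#' Per-time-step statistics over a set of migration paths
#'
#' Paths of different lengths are padded with their final position (a cell
#' that has arrived stays put). This mirrors the standard presentation of
#' simulated migration paths: a mean trajectory over repeated runs with a
#' one-standard-deviation band.
#'
#' @param paths list of path matrices (rows = time points, columns =
#'   lattice coordinates).
#' @return list with `mean` and `sd` matrices (time points x coordinates)
#'   and `n`, the number of paths.
#' @export
path_statistics <- function(paths) {
  if (!length(paths)) stop("`paths` must be non-empty", call. = FALSE)
  d <- ncol(paths[[1]])
  tmax <- max(vapply(paths, nrow, 0L))
  padded <- lapply(paths, function(p) {
    if (nrow(p) < tmax) {
      p <- rbind(p, matrix(p[nrow(p), ], tmax - nrow(p), d, byrow = TRUE))
    }
    p
  })
  arr <- array(unlist(padded), dim = c(tmax, d, length(paths)))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  if (length(paths) == 1L) sdv[] <- 0
  list(mean = mu, sd = sdv, n = length(paths))
}

#' Save / load migration scenarios as YAML
#'
#' @param env a [migration_env()].
#' @param path file path.
#' @export
write_scenario <- function(env, path) {
  yaml::write_yaml(list(
    dims = as.integer(env$dims),
    occupied = if (nrow(env$occupied)) {
      apply(env$occupied, 1, function(s) as.integer(s), simplify = FALSE)
    } else {
      list()
    },
    start = as.integer(env$start),
    goals = lapply(env$goals, as.integer),
    spacing = env$spacing, step_cost = env$step_cost,
    collision_penalty = env$collision_penalty,
    goal_reward = env$goal_reward, max_steps = env$max_steps), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  occ <- if (length(x$occupied)) {
    do.call(rbind, lapply(x$occupied, as.integer))
  } else {
    NULL
  }
  migration_env(dims = x$dims, occupied = occ, start = x$start,
                goals = x$goals, spacing = x$spacing,
                step_cost = x$step_cost,
                collision_penalty = x$collision_penalty,
                goal_reward = x$goal_reward, max_steps = x$max_steps)
}
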