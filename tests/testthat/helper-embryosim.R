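# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops, independent of the vectorized package internals.

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

random_cells <- function(n, seed, box = 10, rmin = 0.5, rmax = 1.5) {
  set.seed(seed)
  data.frame(name = sprintf("c%02d", seq_len(n)),
             x = runif(n, -box, box), y = runif(n, -box, box),
             z = runif(n, -box, box),
             radius = runif(n, rmin, rmax),
             px = NA_real_, py = NA_real_, pz = NA_real_,
             stringsAsFactors = FALSE)
}

# Straight-line potential-energy oracle: explicit per-edge and per-cell
# summation, including the one-sided eggshell penalty.
oracle_energy <- function(net, shell = NULL, positions = NULL, shell_k = 10) {
  pos <- if (is.null(positions)) as.matrix(net$cells[, c("x", "y", "z")]) else positions
  E <- 0
  ed <- net$edges
  for (r in seq_len(nrow(ed))) {
    d <- sqrt(sum((pos[ed$i[r], ] - pos[ed$j[r], ])^2))
    E <- E + 0.5 * ed$k[r] * (d - ed$L0[r])^2
  }
  if (!is.null(shell)) {
    for (i in seq_len(nrow(pos))) {
      rel <- pos[i, ] - shell$center
      g <- sqrt(sum((rel / shell$semi_axes)^2))
      rho <- sqrt(sum(rel^2))
      reach <- if (rho > 1e-9) net$cells$radius[i] * g / rho else
        net$cells$radius[i] / min(shell$semi_axes)
      h <- g + reach - 1
      if (h > 0) E <- E + 0.5 * shell_k * h^2
    }
  }
  E
}

# All-pairs brute-force neighbor scan.
oracle_neighbor_edges <- function(cells, contact_factor) {
  n <- nrow(cells)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((as.numeric(cells[i, c("x", "y", "z")]) -
                       as.numeric(cells[j, c("x", "y", "z")]))^2))
      if (d <= contact_factor * (cells$radius[i] + cells$radius[j])) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

# Breadth-first shortest-path oracle over free lattice sites (igraph).
oracle_bfs_length <- function(env) {
  dims <- env$dims
  d <- length(dims)
  coords <- as.matrix(expand.grid(lapply(dims, seq_len)))
  keys <- apply(coords, 1, function(s) paste(s, collapse = ","))
  free <- !(keys %in% env$occ_keys)
  idx <- stats::setNames(seq_along(keys), keys)
  edges <- NULL
  for (ax in seq_len(d)) {
    shifted <- coords
    shifted[, ax] <- shifted[, ax] + 1L
    ok <- shifted[, ax] <= dims[ax]
    k2 <- apply(shifted[ok, , drop = FALSE], 1, paste, collapse = ",")
    a <- idx[keys[ok]]
    b <- idx[k2]
    keep <- free[a] & free[b]
    edges <- rbind(edges, cbind(a[keep], b[keep]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  legs <- c(list(env$start), env$goals)
  total <- 0
  for (i in seq_len(length(legs) - 1)) {
    from <- idx[paste(legs[[i]], collapse = ",")]
    to <- idx[paste(legs[[i + 1]], collapse = ",")]
    total <- total + igraph::distances(g, from, to)[1, 1]
  }
  total
}

expect_unit <- function(v, tol = 1e-9) {
  expect_equal(sqrt(sum(v^2)), 1, tolerance = tol)
}
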