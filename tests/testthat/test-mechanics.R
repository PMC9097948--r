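test_that("contact springs follow the distance-threshold rule", {
  near <- rbind(cell("a", c(0, 0, 0), 1), cell("b", c(1.9 * 2, 0, 0), 1))
  expect_equal(nrow(build_neighbor_graph(near, contact_factor = 2)$edges), 1L)
  far <- rbind(cell("a", c(0, 0, 0), 1), cell("b", c(2.1 * 2, 0, 0), 1))
  expect_equal(nrow(build_neighbor_graph(far, contact_factor = 2)$edges), 0L)
  same <- rbind(cell("a", c(0, 0, 0), 1), cell("b", c(0, 0, 0), 1))
  expect_error(build_neighbor_graph(same), "degeneracy")
  # spring rest length is the sum of the two radii
  net <- build_neighbor_graph(near, contact_factor = 2)
  expect_equal(net$edges$L0, 2)
})

test_that("neighbor graph equals the all-pairs brute-force scan", {
  cells <- random_cells(20, seed = 11, box = 4)
  net <- build_neighbor_graph(cells, contact_factor = 1.2)
  oracle <- oracle_neighbor_edges(cells, 1.2)
  got <- as.matrix(net$edges[, c("i", "j")])
  dimnames(got) <- NULL
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE])
})

test_that("potential energy matches closed forms and the term-by-term oracle", {
  rest <- build_neighbor_graph(
    rbind(cell("a", c(0, 0, 0), 1), cell("b", c(2, 0, 0), 1)),
    contact_factor = 1.2)
  expect_equal(potential_energy(rest, eggshell()), 0)

  # one spring, k = 2, L0 = 1, stretched to distance 2: E = 1/2*2*(2-1)^2
  one <- list(cells = rbind(cell("a", c(0, 0, 0), 0.5),
                            cell("b", c(2, 0, 0), 0.5)),
              edges = data.frame(i = 1L, j = 2L, k = 2, L0 = 1))
  class(one) <- "spring_network"
  expect_equal(potential_energy(one), 1)

  shell <- eggshell(c(6, 5, 4))
  for (seed in 1:5) {
    cells <- random_cells(10, seed = seed, box = 5)
    net <- build_neighbor_graph(cells, contact_factor = 1.5)
    expect_equal(potential_energy(net, shell),
                 oracle_energy(net, shell), tolerance = 1e-12)
  }
})

test_that("energy is invariant under rigid motion when no shell is active", {
  cells <- random_cells(8, seed = 3, box = 3)
  net <- build_neighbor_graph(cells, contact_factor = 1.5)
  pos <- as.matrix(cells[, c("x", "y", "z")])
  e0 <- potential_energy(net, positions = pos)
  # rotation about z by 40 degrees plus a translation
  th <- 40 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pos2 <- pos %*% t(R) + matrix(c(3, -2, 7), nrow(pos), 3, byrow = TRUE)
  expect_equal(potential_energy(net, positions = pos2), e0, tolerance = 1e-9)
})

test_that("relaxation reaches analytic minima for small systems", {
  two <- build_neighbor_graph(
    rbind(cell("a", c(0, 0, 0), 1), cell("b", c(4, 0, 0), 1)),
    contact_factor = 3)
  r <- relax_to_equilibrium(two)
  expect_lt(abs(as.numeric(dist(r$positions)) - 2), 1e-6)
  expect_lte(r$energy, r$initial_energy)
  expect_lte(r$grad_max, 1e-6)

  tri <- build_neighbor_graph(
    rbind(cell("a", c(0, 0, 0), 1), cell("b", c(3, 0, 0), 1),
          cell("c", c(1.5, 2.8, 0), 1)),
    contact_factor = 2)
  expect_equal(nrow(tri$edges), 3L)
  r3 <- relax_to_equilibrium(tri)
  expect_true(all(abs(as.numeric(dist(r3$positions)) - 2) < 1e-5))
})

test_that("a cell outside the shell is pushed back to the surface", {
  shell <- eggshell()
  out <- build_neighbor_graph(cell("x", c(30, 4, -3), 2))
  r <- relax_to_equilibrium(out, shell)
  rel <- r$positions[1, ] - shell$center
  g <- sqrt(sum((rel / shell$semi_axes)^2))
  h <- g + 2 * g / sqrt(sum(rel^2)) - 1
  expect_lt(abs(h), 1e-4)

  # on a spherical shell the penalty gradient is radial, so the relaxed
  # radius must match a 1-D bisection along the radial line
  sph <- eggshell(c(10, 10, 10))
  start <- c(30, 4, -3)
  r2 <- relax_to_equilibrium(build_neighbor_graph(cell("x", start, 2)), sph)
  u <- start / sqrt(sum(start^2))
  f <- function(t) {
    p <- t * u
    gg <- sqrt(sum((p / sph$semi_axes)^2))
    gg + 2 * gg / t - 1
  }
  lo <- 1; hi <- 40
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(sqrt(sum(r2$positions[1, ]^2)), (lo + hi) / 2,
               tolerance = 1e-4)
  # and the relaxed point stays on the original radial line
  expect_equal(as.numeric(r2$positions[1, ] / sqrt(sum(r2$positions[1, ]^2))),
               u, tolerance = 1e-6)
})

test_that("frozen cells stay put and relaxation never raises the energy", {
  cells <- random_cells(6, seed = 8, box = 2)
  net <- build_neighbor_graph(cells, contact_factor = 2)
  r <- relax_to_equilibrium(net, frozen = c("c01", "c02"), gauge = FALSE)
  expect_equal(r$positions["c01", ], unlist(cells[1, c("x", "y", "z")]))
  expect_equal(r$positions["c02", ], unlist(cells[2, c("x", "y", "z")]))
  expect_lte(r$energy, r$initial_energy)
})

test_that("daughter placement conserves volume and copies polarity", {
  mom <- cell("AB", c(0, 0, 0), 1, polarity = c(0, 1, 0))
  kids <- place_daughters(mom, c(1, 0, 0), 0.5, names = c("ABa", "ABp"))
  expect_equal(kids$x, c(0.5, -0.5))
  expect_equal(kids$radius, rep(2^(-1 / 3), 2))
  expect_equal(sum(kids$radius^3), mom$radius^3, tolerance = 1e-9)
  expect_equal(unlist(kids[1, c("px", "py", "pz")], use.names = FALSE),
               c(0, 1, 0))
  # override replaces inherited polarity (the simulator passes the axis)
  kids2 <- place_daughters(mom, c(1, 0, 0), 0.5, polarity = c(0, 0, 1))
  expect_equal(kids2$pz, c(1, 1))
  expect_error(place_daughters(mom, c(0, 0, 0)), "zero")
})

test_that("nuclei tables round-trip and the reader tolerates extra columns", {
  df <- data.frame(time = c(0, 0, 1), name = c("a", "b", "a"),
                   x = c(0.123456, -4, 2), y = c(1, 2, 3), z = c(0, 0, -1),
                   radius = c(1, 1.5, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_nuclei_table(df, path)
  back <- read_nuclei_table(path)
  expect_equal(back$x, df$x, tolerance = 1e-9)
  # extra columns pass through
  extra <- cbind(df, note = "q")
  utils::write.table(extra, path, sep = ",", row.names = FALSE, quote = FALSE)
  back2 <- read_nuclei_table(path)
  expect_equal(back2$radius, df$radius)
})
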