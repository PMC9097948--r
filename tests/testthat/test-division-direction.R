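test_that("neighbor squeeze is overlap-weighted repulsion", {
  me <- cell("m", c(0, 0, 0), 1)
  # one overlapping neighbor on the -x side pushes along +x
  nb <- cell("n", c(-1.5, 0, 0), 1)
  expect_equal(neighbor_squeeze_vector(me, nb), c(1, 0, 0))
  # two symmetric overlapping neighbors cancel
  sym <- rbind(cell("n1", c(0, 1.5, 0), 1), cell("n2", c(0, -1.5, 0), 1))
  expect_equal(neighbor_squeeze_vector(me, sym), c(0, 0, 0))
  # non-overlapping neighbors contribute nothing
  expect_equal(neighbor_squeeze_vector(me, cell("f", c(5, 0, 0), 1)),
               c(0, 0, 0))
  expect_error(neighbor_squeeze_vector(me, cell("n", c(0, 0, 0), 1)),
               "degeneracy")

  # 5 random neighbors against an explicit summation oracle
  set.seed(4)
  nbrs <- random_cells(5, seed = 4, box = 1.5, rmin = 0.8, rmax = 1.2)
  v <- c(0, 0, 0)
  for (i in 1:5) {
    dx <- as.numeric(nbrs[i, c("x", "y", "z")])
    d <- sqrt(sum(dx^2))
    w <- max(0, (1 + nbrs$radius[i]) - d)
    v <- v - w * dx / d
  }
  v <- v / sqrt(sum(v^2))
  expect_equal(neighbor_squeeze_vector(me, nbrs), v, tolerance = 1e-12)
})

test_that("eggshell squeeze is the inward ellipsoid normal on contact", {
  shell <- eggshell(c(25, 15, 15))
  pressed <- cell("x", c(25, 0, 0), 1)
  expect_equal(eggshell_squeeze_vector(pressed, shell), c(-1, 0, 0))
  centre <- cell("x", c(0, 0, 0), 1)
  expect_equal(eggshell_squeeze_vector(centre, shell), c(0, 0, 0))
  deep <- cell("x", c(2, 1, -1), 1)
  expect_equal(eggshell_squeeze_vector(deep, shell), c(0, 0, 0))

  # random boundary point: matches the finite-difference gradient of g
  set.seed(9)
  u <- c(1, 2, -1.5); u <- u / sqrt(sum(u^2))
  g1 <- sqrt(sum((u / shell$semi_axes)^2))
  p <- u / g1                       # point exactly on the surface
  onshell <- cell("x", p, 1)
  got <- eggshell_squeeze_vector(onshell, shell)
  eps <- 1e-6
  num <- vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- eps
    gp <- sqrt(sum(((p + e) / shell$semi_axes)^2))
    gm <- sqrt(sum(((p - e) / shell$semi_axes)^2))
    (gp - gm) / (2 * eps)
  }, 0)
  expect_equal(got, -num / sqrt(sum(num^2)), tolerance = 1e-6)
})

test_that("direction composition and angle error behave as stated", {
  m1 <- division_direction_model(c(1, 0, 0))
  expect_equal(compose_direction(m1, c(0, 1, 0)), c(0, 1, 0))
  m2 <- division_direction_model(c(0.5, 0.5, 0))
  expect_equal(compose_direction(m2, c(1, 0, 0), c(0, 1, 0)),
               c(1, 1, 0) / sqrt(2))
  expect_error(compose_direction(m2, c(1, 0, 0), c(-1, 0, 0)), "degeneracy")
  # composed directions are unit vectors for random inputs
  set.seed(2)
  for (i in 1:20) {
    K <- rexp(3); K <- K / sum(K)
    m <- division_direction_model(K)
    p <- rnorm(3); p <- p / sqrt(sum(p^2))
    s <- rnorm(3); s <- s / sqrt(sum(s^2))
    expect_equal(sqrt(sum(compose_direction(m, p, s)^2)), 1,
                 tolerance = 1e-12)
  }

  d <- c(0, 0, 1)
  expect_equal(angle_error(d, d), 0)
  expect_equal(angle_error(d, -d), 0)           # axes are undirected
  expect_equal(angle_error(d, c(1, 0, 0)), pi / 2)
  expect_error(angle_error(d, c(1, 1, 0)), "unit")
})

test_that("coefficients are recovered exactly from noiseless observations", {
  K_true <- c(0.6, 0.3, 0.1)
  obs <- synth_divisions(K_true, n = 100, noise_angle_deg = 0, seed = 21)
  fit <- fit_coefficients(obs, n_starts = 16, seed = 1)
  expect_gte(cosine_sim(fit$K, K_true), 0.999)
  expect_lte(fit$objective, 1e-6)
  expect_equal(sum(fit$K), 1)
  expect_true(all(fit$K >= 0))
})

test_that("polarity-only observations drive K_p toward one", {
  set.seed(5)
  n <- 60
  obs <- synth_divisions(c(1, 0, 0), n = n, noise_angle_deg = 0, seed = 5)
  fit <- fit_coefficients(obs, seed = 2)
  expect_gte(fit$K[1], 0.95)
})

test_that("a single observation is fit exactly with a warning", {
  obs <- synth_divisions(c(0.5, 0.25, 0.25), n = 1, noise_angle_deg = 0,
                         seed = 3)
  expect_warning(fit <- fit_coefficients(obs, seed = 1), "underdetermined")
  expect_lte(fit$objective, 1e-6)
})

test_that("the objective is invariant to observed-axis sign flips", {
  obs <- synth_divisions(c(0.4, 0.4, 0.2), n = 50, noise_angle_deg = 10,
                         seed = 7)
  flipped <- obs
  flip <- seq(1, 50, by = 2)
  flipped[flip, c("dx", "dy", "dz")] <- -flipped[flip, c("dx", "dy", "dz")]
  f1 <- fit_coefficients(obs, n_starts = 8, seed = 1)
  f2 <- fit_coefficients(flipped, n_starts = 8, seed = 1)
  expect_equal(f2$objective, f1$objective, tolerance = 1e-9)
  expect_equal(f2$K, f1$K, tolerance = 1e-6)
})

test_that("the fit dominates every pure single-component strategy", {
  obs <- synth_divisions(c(0.5, 0.3, 0.2), n = 80, noise_angle_deg = 15,
                         seed = 13)
  fit <- fit_coefficients(obs, n_starts = 8, seed = 4)
  m <- obs
  for (k in 1:3) {
    pure <- division_direction_model(as.numeric(1:3 == k))
    pure_obj <- 0
    for (i in seq_len(nrow(m))) {
      p <- as.numeric(m[i, c("px", "py", "pz")])
      s <- as.numeric(m[i, c("sx", "sy", "sz")])
      e <- as.numeric(m[i, c("ex", "ey", "ez")])
      d <- as.numeric(m[i, c("dx", "dy", "dz")])
      v <- pure$K[1] * p + pure$K[2] * s + pure$K[3] * e
      ang <- if (sqrt(sum(v^2)) < 1e-12) pi / 2 else
        acos(min(1, abs(sum(v * d)) / sqrt(sum(v^2))))
      pure_obj <- pure_obj + ang
    }
    expect_lte(fit$objective, pure_obj + 1e-9)
  }
})

test_that("predict_axis composes the individually computed components", {
  shell <- eggshell()
  model <- division_direction_model(c(0.5, 0.3, 0.2))
  # isolated cell deep in the shell: the axis is the polarity
  iso <- cell("c", c(1, 0, 0), 1, polarity = c(0, 1, 0))
  expect_equal(predict_axis(model, iso, NULL, shell), c(0, 1, 0))
  # pressed on the shell with K = (0,0,1): the inward normal
  pressed <- cell("c", c(25, 0, 0), 1, polarity = c(0, 1, 0))
  shellonly <- division_direction_model(c(0, 0, 1))
  expect_equal(predict_axis(shellonly, pressed, NULL, shell), c(-1, 0, 0))
  # general configuration equals compose_direction of the components
  nbrs <- rbind(cell("n1", c(24, 1.2, 0), 1), cell("n2", c(24.5, -1, 0.5), 1))
  got <- predict_axis(model, pressed, nbrs, shell)
  want <- compose_direction(model, c(0, 1, 0),
                            neighbor_squeeze_vector(pressed, nbrs),
                            eggshell_squeeze_vector(pressed, shell))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(predict_axis(model, cell("c", c(0, 0, 0), 1), NULL, shell),
               "polarity")
})

test_that("fitted models round-trip through JSON", {
  m <- division_direction_model(c(0.6, 0.3, 0.1), objective = 0.123,
                                n_obs = 42L)
  path <- withr::local_tempfile(fileext = ".json")
  write_divdir_model(m, path)
  back <- read_divdir_model(path)
  expect_equal(back$K, m$K)
  expect_equal(back$objective, m$objective)
})
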