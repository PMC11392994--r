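pure_diffusion_params <- function(h = 0.5, dt = 0.01, alpha = 1)
  continuum_params(alpha = alpha, chi = 0, nu = 0, Omega_pq = 0,
                   Omega_qp = 0, D = 0, gamma = 0, A_dep = 0,
                   x0 = c(25, 25), food_sources = list(), Lx = 50, Ly = 50,
                   h = h, dt = dt, delta_width = 1.5)

grid_x <- function(prm) {
  g <- anttrails:::grid_centers(prm)
  outer(g$x, rep(1, prm$ny))
}

axis_variance <- function(f, prm) {
  X <- grid_x(prm)
  m <- sum(f) * prm$h^2
  mx <- sum(X * f) * prm$h^2 / m
  sum((X - mx)^2 * f) * prm$h^2 / m
}

test_that("mollified delta is a normalized, compactly supported bump", {
  prm <- continuum_params(Lx = 20, Ly = 20, x0 = c(10, 10),
                          food_sources = list(), h = 0.5)
  d <- mollified_delta(c(10.3, 9.7), prm)
  expect_true(all(d >= 0))
  expect_equal(sum(d) * prm$h^2, 1, tolerance = 1e-10)
  g <- anttrails:::grid_centers(prm)
  r <- sqrt(outer((g$x - 10.3)^2, (g$y - 9.7)^2, `+`))
  expect_true(all(d[r > prm$delta_width] == 0))
  # symmetric about a grid-aligned centre
  dc <- mollified_delta(c(10, 10), prm)
  expect_equal(dc, dc[nrow(dc):1, ], tolerance = 1e-12)
  # degenerate width: single-cell indicator of height 1/h^2
  prm2 <- continuum_params(Lx = 20, Ly = 20, x0 = c(10, 10),
                           food_sources = list(), h = 1, delta_width = 0.2)
  d2 <- mollified_delta(c(10.5, 10.5), prm2)
  expect_equal(sum(d2 != 0), 1)
  expect_equal(max(d2), 1)
  expect_error(mollified_delta(c(-1, 5), prm), "inside")
})

test_that("ADI diffusion reproduces the heat kernel spread", {
  prm <- pure_diffusion_params()
  f <- continuum_fields(prm)
  v0 <- axis_variance(f$p, prm)
  run <- run_pde(prm, T = 2)
  v1 <- axis_variance(run$snapshots[[1]]$p, prm)
  expect_equal(v1 - v0, 2 * prm$alpha * 2, tolerance = 0.01)
  expect_lt(run$max_mass_drift, 1e-10)
})

test_that("refining h and dt shrinks the error against the heat kernel", {
  # evolve an exact Gaussian and compare the whole profile to the analytic
  # solution; the variance identity alone is exact at any resolution, so a
  # pointwise error functional is needed to see the scheme's order
  err_at <- function(h, dt) {
    prm <- pure_diffusion_params(h = h, dt = dt)
    g <- anttrails:::grid_centers(prm)
    s0 <- 4   # initial variance per axis
    gauss <- function(s2) {
      gx <- exp(-(g$x - 25)^2 / (2 * s2))
      gy <- exp(-(g$y - 25)^2 / (2 * s2))
      outer(gx, gy) / (2 * pi * s2)
    }
    f <- list(p = gauss(s0), q = NULL, u = NULL)
    steps <- round(1 / dt)
    for (i in seq_len(steps))
      f$p <- anttrails:::adi_diffuse(f$p, 1, dt, prm, "neumann")
    max(abs(f$p - gauss(s0 + 2 * 1)))
  }
  e_coarse <- err_at(1, 0.05)
  e_fine <- err_at(0.5, 0.025)
  expect_lt(e_fine, e_coarse / 2)
})

test_that("chemotaxis flux vanishes for spatially constant pheromone", {
  prm <- continuum_params(chi = 5, alpha = 0, nu = 0, Omega_pq = 0,
                          Omega_qp = 0, x0 = c(25, 25),
                          food_sources = list(), dt = 0.01)
  f <- continuum_fields(prm)
  f$u <- matrix(3.7, prm$nx, prm$ny)
  expect_equal(step_p(f, prm), f$p)
})

test_that("conversion exchange is exactly antisymmetric between p and q", {
  prm <- continuum_params(x0 = c(25, 25), food_sources = list(c(40, 25)),
                          dt = 0.01)
  f <- continuum_fields(prm)
  # evolve a little so q is nonzero too
  run <- run_pde(prm, T = 2)
  s <- run$snapshots[[1]]
  f <- list(p = s$p, q = s$q, u = s$u, t = 2, mass0 = run$mass0)
  dq <- sum(step_q(f, prm) - f$q) * prm$h^2
  dp <- sum(step_p(f, prm) - f$p) * prm$h^2
  expect_lt(abs(dp + dq), 1e-12)
})

test_that("carrier advection moves mass toward the nest at speed nu", {
  prm <- continuum_params(alpha = 0, chi = 0, nu = 1, Omega_pq = 0,
                          Omega_qp = 0, D = 0, gamma = 0, A_dep = 0,
                          x0 = c(5, 25), food_sources = list(),
                          Lx = 50, Ly = 50, h = 0.5, dt = 0.02)
  q <- mollified_delta(c(40, 25), prm)
  f <- list(p = q * 0, q = q, u = q * 0, t = 0, mass0 = 0)
  X <- grid_x(prm)
  cent0 <- sum(X * f$q) / sum(f$q)
  for (i in 1:250) f$q <- step_q(f, prm)   # T = 5
  cent1 <- sum(X * f$q) / sum(f$q)
  expect_equal(cent1 - cent0, -5, tolerance = 0.1)
  expect_equal(sum(f$q) * prm$h^2, 1, tolerance = 1e-10)
  # nu = 0: unchanged
  prm0 <- continuum_params(alpha = 0, chi = 0, nu = 0, Omega_pq = 0,
                           Omega_qp = 0, D = 0, gamma = 0, A_dep = 0,
                           x0 = c(5, 25), food_sources = list(),
                           Lx = 50, Ly = 50, h = 0.5, dt = 0.02)
  expect_equal(step_q(list(p = q * 0, q = q, u = q * 0), prm0), q)
})

test_that("pheromone field decays, grows at sources, and stays
           nonnegative", {
  prm <- continuum_params(x0 = c(25, 25), food_sources = list(c(40, 25)),
                          dt = 0.01)
  # pure decay of a uniform interior patch (away from Robin boundary)
  f <- list(p = matrix(0, prm$nx, prm$ny), q = matrix(0, prm$nx, prm$ny),
            u = matrix(1, prm$nx, prm$ny))
  u1 <- step_u(f, prm)
  expect_equal(u1[25, 25], (1 - prm$gamma * prm$dt), tolerance = 1e-8)
  # source-dominated growth: u rises at rate ~ A_dep * q at the source cell
  # (source placed on a cell centre so the deposition kernel is 1 there)
  prms <- continuum_params(x0 = c(25, 25),
                           food_sources = list(c(39.5, 24.5)), dt = 0.01)
  q <- mollified_delta(c(39.5, 24.5), prms)
  f2 <- list(p = q * 0, q = q, u = q * 0)
  u2 <- step_u(f2, prms)
  i <- which.max(q)
  expect_equal(u2[i] / prms$dt, prms$A_dep * q[i], tolerance = 0.01)
  expect_true(all(u2 >= 0))
})

test_that("full runs conserve ants, relax without food, and respect
           mirror symmetry", {
  # no food: p tends to the uniform density 1/(Lx*Ly)
  prm <- continuum_params(chi = 0, nu = 0, Omega_pq = 0, Omega_qp = 0,
                          A_dep = 0, x0 = c(10, 10), food_sources = list(),
                          Lx = 20, Ly = 20, h = 1, dt = 0.05)
  run <- run_pde(prm, T = 150)
  s <- run$snapshots[[1]]
  expect_equal(max(abs(s$p - 1 / 400)), 0, tolerance = 1e-6)
  expect_true(all(s$q == 0) && all(s$u == 0))
  # two equidistant sources: fields symmetric under the swapping reflection
  prm2 <- continuum_params(x0 = c(25, 25),
                           food_sources = list(c(40, 25), c(10, 25)),
                           dt = 0.01)
  run2 <- run_pde(prm2, T = 10)
  s2 <- run2$snapshots[[1]]
  mir <- function(m) m[nrow(m):1, ]
  expect_lt(max(abs(s2$p - mir(s2$p))), 1e-6)
  expect_lt(max(abs(s2$q - mir(s2$q))), 1e-6)
  expect_lt(max(abs(s2$u - mir(s2$u))), 1e-6)
  expect_lt(run2$max_mass_drift, 1e-8)
})

test_that("configuration guards: CFL and geometry", {
  expect_error(continuum_params(nu = 10, dt = 0.2, h = 1), "CFL")
  expect_error(continuum_params(x0 = c(60, 25)), "inside")
  expect_error(continuum_params(food_sources = list(c(55, 25))), "inside")
})
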