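#' Parameters of the macroscopic chemotaxis PDE
#'
#' The continuum model evolves a forager density `p` (diffusion `alpha`,
#' chemotactic drift up the pheromone gradient with sensitivity `chi`), a
#' carrier density `q` (advection at speed `nu` along the unit vector
#' pointing at the nest), and a pheromone field `u` (diffusion `D`, decay
#' `gamma`, source `A_dep * q * exp(-||x - x_f||^2)` summed over sources).
#' Conversions between `p` and `q` act through mollified point masses at the
#' food sources and the nest with rates `Omega_pq`, `Omega_qp`. `p` and `q`
#' carry no-flux (homogeneous Neumann) boundaries so ants are conserved; `u`
#' carries the same Robin (Fourier-type) boundary closure as the lattice
#' field.
#'
#' @param alpha Forager diffusion coefficient.
#' @param chi Chemotactic sensitivity.
#' @param nu Carrier speed.
#' @param Omega_pq,Omega_qp Conversion rate constants.
#' @param D,gamma,A_dep Pheromone parameters.
#' @param x0 Nest location (continuous coordinates inside the domain).
#' @param food_sources List of food-source locations (may be empty).
#' @param Lx,Ly Domain extents.
#' @param h Grid spacing (cell-centred grid).
#' @param dt Time step; the upwind CFL condition `nu*dt/h <= 1` is enforced.
#' @param delta_width Mollifier radius for the point masses (default `2*h`).
#' @return An object of class `continuum_params`.
#' @export
continuum_params <- function(alpha = 1, chi = 1, nu = 1, Omega_pq = 1,
                             Omega_qp = 1, D = 10, gamma = 0.001,
                             A_dep = 1, x0 = c(25, 25),
                             food_sources = list(c(40, 25)),
                             Lx = 50, Ly = 50, h = 1, dt = 0.01,
                             delta_width = 2 * h) {
  stopifnot(alpha >= 0, chi >= 0, nu >= 0, Omega_pq >= 0, Omega_qp >= 0,
            D >= 0, gamma >= 0, A_dep >= 0, h > 0, dt > 0, Lx > 0, Ly > 0,
            delta_width > 0)
  if (nu * dt / h > 1)
    stop("upwind CFL violated: nu*dt/h = ", signif(nu * dt / h, 3),
         " exceeds 1", call. = FALSE)
  fm <- if (length(food_sources)) do.call(rbind, lapply(food_sources,
                                                        as.numeric))
        else matrix(numeric(0), ncol = 2)
  inside <- function(p) p[1] > 0 && p[1] < Lx && p[2] > 0 && p[2] < Ly
  if (!inside(x0)) stop("x0 must lie inside the domain", call. = FALSE)
  if (nrow(fm) > 0 && !all(apply(fm, 1, inside)))
    stop("all food sources must lie inside the domain", call. = FALSE)
  prm <- list(alpha = alpha, chi = chi, nu = nu, Omega_pq = Omega_pq,
              Omega_qp = Omega_qp, D = D, gamma = gamma, A_dep = A_dep,
              x0 = as.numeric(x0), food_sources = fm, Lx = Lx, Ly = Ly,
              h = h, dt = dt, delta_width = delta_width,
              nx = as.integer(round(Lx / h)), ny = as.integer(round(Ly / h)))
  class(prm) <- "continuum_params"
  # cache the grid functions reused every step
  prm$delta_nest <- mollified_delta(prm$x0, prm)
  prm$delta_food <- lapply(seq_len(nrow(fm)), function(k)
    mollified_delta(fm[k, ], prm))
  prm$src_kernel <- source_kernel(prm)
  prm
}

#' @export
print.continuum_params <- function(x, ...) {
  cat("<continuum_params> [0,", x$Lx, "] x [0,", x$Ly, "], h = ", x$h,
      ", dt = ", x$dt, " (", x$nx, "x", x$ny, " cells)\n", sep = "")
  cat("  alpha = ", x$alpha, ", chi = ", x$chi, ", nu = ", x$nu,
      ", Omega_pq = ", x$Omega_pq, ", Omega_qp = ", x$Omega_qp, "\n",
      sep = "")
  cat("  D = ", x$D, ", gamma = ", x$gamma, ", A_dep = ", x$A_dep,
      ", ", nrow(x$food_sources), " food source(s)\n", sep = "")
  invisible(x)
}

# cell-centre coordinates along each axis
grid_centers <- function(params) {
  list(x = (seq_len(params$nx) - 0.5) * params$h,
       y = (seq_len(params$ny) - 0.5) * params$h)
}

#' Mollified point mass on the grid
#'
#' Discretizes a Dirac delta as a raised-cosine bump of radius
#' `delta_width`: nonnegative, symmetric about the centre up to grid
#' truncation, supported strictly inside the radius, and normalized so the
#' discrete integral is exactly 1. If the radius does not cover any cell
#' centre the nearest cell becomes an indicator of height `1/h^2`.
#'
#' @param center Point `(x, y)` inside the domain.
#' @param params A [continuum_params()] (supplies grid and radius).
#' @return An `nx x ny` matrix integrating to 1 (times `h^2`).
#' @export
mollified_delta <- function(center, params) {
  if (center[1] <= 0 || center[1] >= params$Lx ||
      center[2] <= 0 || center[2] >= params$Ly)
    stop("center must lie inside the domain", call. = FALSE)
  g <- grid_centers(params)
  r <- sqrt(outer((g$x - center[1])^2, (g$y - center[2])^2, `+`))
  w <- ifelse(r < params$delta_width,
              1 + cos(pi * r / params$delta_width), 0)
  tot <- sum(w) * params$h^2
  if (tot == 0) {
    i <- which.min(abs(g$x - center[1]))
    j <- which.min(abs(g$y - center[2]))
    w <- matrix(0, params$nx, params$ny)
    w[i, j] <- 1 / params$h^2
    return(w)
  }
  w / tot
}

#' Initial continuum fields
#'
#' Foragers start as a mollified point mass at the nest; carriers and
#' pheromone start at zero, so total ant mass is exactly 1.
#'
#' @param params A [continuum_params()].
#' @return A `continuum_fields` list: matrices `p`, `q`, `u`, clock `t`, and
#'   the initial mass `mass0`.
#' @export
continuum_fields <- function(params) {
  p <- mollified_delta(params$x0, params)
  q <- matrix(0, params$nx, params$ny)
  structure(list(p = p, q = q, u = q, t = 0,
                 mass0 = sum(p) * params$h^2),
            class = "continuum_fields")
}

# One Peaceman-Rachford ADI diffusion step of coefficient `coef`.
# bc = "neumann" (no flux) or "robin" (D du/dn_out = -u, via ghost cell).
adi_diffuse <- function(f, coef, dt, params, bc = "neumann") {
  if (coef == 0) return(f)
  h <- params$h
  r <- coef * dt / (2 * h^2)
  bterm <- if (bc == "robin") h / coef else 0   # extra loss at the boundary
  lap1 <- function(m, along) {
    if (along == 2) m <- t(m)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    out[2:(n - 1), ] <- m[1:(n - 2), ] - 2 * m[2:(n - 1), ] + m[3:n, ]
    out[1, ] <- m[2, ] - m[1, ] - bterm * m[1, ]
    out[n, ] <- m[n - 1, ] - m[n, ] - bterm * m[n, ]
    if (along == 2) t(out) else out
  }
  solve1 <- function(m, along) {
    if (along == 2) m <- t(m)
    n <- nrow(m)
    dg <- rep(1 + 2 * r, n)
    dg[c(1, n)] <- 1 + r + r * bterm
    out <- cpp_tridiag_solve(rep(-r, n - 1), dg, rep(-r, n - 1), m)
    if (along == 2) t(out) else out
  }
  half <- solve1(f + r * lap1(f, 2), 1)
  solve1(half + r * lap1(half, 1), 2)
}

# conversion exchange computed from the *pre-step* p and q; returned as the
# term to add to dp/dt (its negative goes to dq/dt)
conversion_exchange <- function(fields, params) {
  if (nrow(params$food_sources) == 0 ||
      (params$Omega_pq == 0 && params$Omega_qp == 0))
    return(matrix(0, params$nx, params$ny))
  take <- matrix(0, params$nx, params$ny)
  for (k in seq_len(nrow(params$food_sources)))
    take <- take + params$Omega_pq * params$delta_food[[k]] * fields$p
  give <- params$Omega_qp * params$delta_nest * fields$q
  give - take
}

#' One time step of the forager density
#'
#' ADI implicit diffusion (`alpha`), explicit conservative chemotaxis flux
#' `-chi * div((grad u) p)` with zero-flux faces, and the mollified
#' conversion exchange; homogeneous Neumann boundaries.
#'
#' @param fields A `continuum_fields` (supplies `p`, `q`, `u`).
#' @param params A [continuum_params()].
#' @return The updated `p` matrix.
#' @export
step_p <- function(fields, params) {
  h <- params$h; dt <- params$dt
  p <- adi_diffuse(fields$p, params$alpha, dt, params, "neumann")
  if (params$chi > 0) {
    u <- fields$u
    nx <- params$nx; ny <- params$ny
    # face fluxes G = chi * (du/dn) * p_face, zero on the boundary
    gx <- matrix(0, nx + 1, ny)
    gx[2:nx, ] <- params$chi * (u[2:nx, ] - u[1:(nx - 1), ]) / h *
      (p[2:nx, ] + p[1:(nx - 1), ]) / 2
    gy <- matrix(0, nx, ny + 1)
    gy[, 2:ny] <- params$chi * (u[, 2:ny] - u[, 1:(ny - 1)]) / h *
      (p[, 2:ny] + p[, 1:(ny - 1)]) / 2
    p <- p - dt / h * (gx[2:(nx + 1), ] - gx[1:nx, ] +
                       gy[, 2:(ny + 1)] - gy[, 1:ny])
  }
  p + dt * conversion_exchange(fields, params)
}

#' One time step of the carrier density
#'
#' First-order upwind step of the conservative advection
#' `-nu * div(v q)` with `v = (x0 - x)/||x0 - x||` (set to 0 at the nest),
#' zero-flux boundary faces, plus the conversion exchange.
#'
#' @inheritParams step_p
#' @return The updated `q` matrix.
#' @export
step_q <- function(fields, params) {
  q <- fields$q
  h <- params$h; dt <- params$dt
  nx <- params$nx; ny <- params$ny
  if (params$nu > 0) {
    g <- grid_centers(params)
    # velocities at interior x-faces (positions i*h, y centres)
    fx <- g$x[-nx] + h / 2
    dxm <- outer(params$x0[1] - fx, rep(1, ny))
    dym <- outer(rep(1, nx - 1), params$x0[2] - g$y)
    nrm <- sqrt(dxm^2 + dym^2)
    vx <- params$nu * ifelse(nrm < 1e-12, 0, dxm / nrm)
    Fx <- matrix(0, nx + 1, ny)
    Fx[2:nx, ] <- pmax(vx, 0) * q[1:(nx - 1), ] + pmin(vx, 0) * q[2:nx, ]
    fy <- g$y[-ny] + h / 2
    dxm <- outer(params$x0[1] - g$x, rep(1, ny - 1))
    dym <- outer(rep(1, nx), params$x0[2] - fy)
    nrm <- sqrt(dxm^2 + dym^2)
    vy <- params$nu * ifelse(nrm < 1e-12, 0, dym / nrm)
    Fy <- matrix(0, nx, ny + 1)
    Fy[, 2:ny] <- pmax(vy, 0) * q[, 1:(ny - 1)] + pmin(vy, 0) * q[, 2:ny]
    q <- q - dt / h * (Fx[2:(nx + 1), ] - Fx[1:nx, ] +
                       Fy[, 2:(ny + 1)] - Fy[, 1:ny])
  }
  q - dt * conversion_exchange(fields, params)
}

#' One time step of the pheromone field
#'
#' ADI diffusion with the Robin boundary closure, explicit decay
#' `(1 - gamma*dt)`, and the explicit source
#' `A_dep * q * sum_k exp(-||x - x_f^(k)||^2)` (decay length 1, as the
#' continuum source is written).
#'
#' @inheritParams step_p
#' @return The updated `u` matrix.
#' @export
step_u <- function(fields, params) {
  u <- adi_diffuse(fields$u, params$D, params$dt, params, "robin")
  u <- u * (1 - params$gamma * params$dt)
  if (nrow(params$food_sources) > 0 && params$A_dep > 0) {
    u <- u + params$dt * params$A_dep * fields$q * params$src_kernel
  }
  u
}

source_kernel <- function(params) {
  g <- grid_centers(params)
  ker <- matrix(0, params$nx, params$ny)
  for (k in seq_len(nrow(params$food_sources))) {
    xf <- params$food_sources[k, ]
    ker <- ker + exp(-outer((g$x - xf[1])^2, (g$y - xf[2])^2, `+`))
  }
  ker
}

#' Time-march the continuum system
#'
#' Advances the three fields with the update order `u`, then `q`, then `p`
#' per step (so the freshly updated pheromone drives the same step's
#' chemotaxis, and the conversion exchange uses one consistent pre-step
#' `p`, `q` pair, keeping total ant mass conserved to machine precision).
#' Aborts with a diagnostic if any field norm blows up.
#'
#' @param params A [continuum_params()].
#' @param T Final time.
#' @param snapshot_times Times at which to record fields (rounded to steps);
#'   defaults to `T`.
#' @return A `continuum_run`: `params`, `snapshots` (lists of `time`, `p`,
#'   `q`, `u`), `mass0` and `max_mass_drift` (largest observed
#'   `|integral(p+q) - mass0|`).
#' @examples
#' prm <- continuum_params(Lx = 20, Ly = 20, x0 = c(10, 10),
#'                         food_sources = list(c(15, 10)), dt = 0.02)
#' run <- run_pde(prm, T = 1)
#' glance(run)
#' @export
run_pde <- function(params, T, snapshot_times = NULL) {
  if (is.null(snapshot_times)) snapshot_times <- T
  steps <- as.integer(round(T / params$dt))
  snap_steps <- sort(unique(pmin(as.integer(round(snapshot_times /
                                                  params$dt)), steps)))
  if (any(snap_steps < 0)) stop("snapshot times must be >= 0", call. = FALSE)
  fields <- continuum_fields(params)
  h2 <- params$h^2
  snaps <- list()
  if (length(snap_steps) && snap_steps[1] == 0) {
    snaps[[1]] <- list(time = 0, p = fields$p, q = fields$q, u = fields$u)
    snap_steps <- snap_steps[-1]
  }
  max_drift <- 0
  for (s in seq_len(steps)) {
    fields$u <- step_u(fields, params)
    q_new <- step_q(fields, params)
    p_new <- step_p(fields, params)
    fields$p <- p_new; fields$q <- q_new
    fields$t <- s * params$dt
    mass <- sum(fields$p + fields$q) * h2
    drift <- abs(mass - fields$mass0)
    if (drift > max_drift) max_drift <- drift
    if (!all(is.finite(fields$p)) || !all(is.finite(fields$u)) ||
        mass > 100 * fields$mass0)
      stop("continuum solve diverged at t = ", fields$t,
           " (mass = ", signif(mass, 4), "); reduce dt", call. = FALSE)
    if (length(snap_steps) && s == snap_steps[1]) {
      snaps[[length(snaps) + 1]] <- list(time = fields$t, p = fields$p,
                                         q = fields$q, u = fields$u)
      snap_steps <- snap_steps[-1]
    }
  }
  structure(list(params = params, snapshots = snaps,
                 mass0 = fields$mass0, max_mass_drift = max_drift),
            class = "continuum_run")
}

#' @export
print.continuum_run <- function(x, ...) {
  cat("<continuum_run> ", length(x$snapshots), " snapshot(s), mass drift ",
      format(x$max_mass_drift, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a continuum run into a long tibble
#'
#' @param x A `continuum_run`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `x`, `y`, `p`, `q`, `u` (one row
#'   per grid cell per snapshot; `x`, `y` are cell-centre coordinates).
#' @method tidy continuum_run
#' @export
tidy.continuum_run <- function(x, ...) {
  g <- grid_centers(x$params)
  idx <- tidyr::expand_grid(i = seq_len(x$params$nx),
                            j = seq_len(x$params$ny))
  purrr::map_dfr(x$snapshots, function(s) {
    ij <- cbind(idx$i, idx$j)
    tibble::tibble(time = s$time, x = g$x[idx$i], y = g$y[idx$j],
                   p = s$p[ij], q = s$q[ij], u = s$u[ij])
  })
}

#' @method glance continuum_run
#' @export
glance.continuum_run <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  h2 <- x$params$h^2
  tibble::tibble(final_time = last$time,
                 mass0 = x$mass0,
                 max_mass_drift = x$max_mass_drift,
                 forager_mass = sum(last$p) * h2,
                 carrier_mass = sum(last$q) * h2,
                 pheromone_mass = sum(last$u) * h2)
}

#' Plot a continuum-run snapshot
#'
#' Draws `p`, `q` and `u` side by side (facets) at one snapshot time.
#'
#' @param object A `continuum_run`.
#' @param time Snapshot time (default: last recorded).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot continuum_run
#' @export
autoplot.continuum_run <- function(object, time = NULL, ...) {
  d <- tidy(object)
  if (is.null(time)) time <- max(d$time)
  d <- d[d$time == time, ]
  long <- tidyr::pivot_longer(d, c("p", "q", "u"), names_to = "field")
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y,
                                     fill = log1p(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~field) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("continuum fields, t = ", time))
}
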