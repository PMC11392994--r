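#' Configure a lattice foraging scenario
#'
#' Assembles and validates every parameter of the stochastic lattice model:
#' the grid, the colony, the nest/food geometry, and the pheromone
#' reaction-diffusion coefficients. Defaults follow the dimensionless values
#' commonly used for this class of model (pheromone diffusion `D = 10`,
#' evaporation `gamma = 0.001`, deposition amplitude `A_dep = 1`, deposition
#' decay length `sigma_decay = 1`, field time step `dt = 0.001`, lattice
#' spacing `dx = 1`, down-gradient weight `epsilon = 0.001`).
#'
#' @param M,N Lattice dimensions (sites); ants live on `[1, M] x [1, N]`.
#' @param n Number of ants in the colony.
#' @param x0 Nest site, an integer pair.
#' @param food_sources Food-source sites: a list of integer pairs or a
#'   `K x 2` matrix. May be empty (pure random-walk scenario).
#' @param D Pheromone diffusion coefficient (length^2 / time).
#' @param gamma Pheromone evaporation rate (1 / time).
#' @param A_dep Deposition amplitude at a food source (concentration / time).
#' @param sigma_decay Decay length of deposition with distance from the food
#'   source (lattice units).
#' @param epsilon Weight assigned to down-gradient moves, `0 < epsilon < 1`.
#' @param dt Pheromone time step; `round(1/dt)` field steps are interleaved
#'   into each unit of ant time once food has been discovered.
#' @param dx Lattice spacing (fixed to 1 in all shipped scenarios).
#' @param T_max Run length in units of time (one unit = `n` ant-move events).
#' @param seed RNG seed; together with the config it fully determines a run.
#' @param beeline `"adaptive"` (default) recomputes the homing direction
#'   `x0 - pos` each step, which contracts the Chebyshev distance to the nest
#'   by exactly 1 per move; `"fixed"` extends the literal vector `x0 - x_f`
#'   of the visited source.
#' @param deposition `"all_sources"` (default) sums the deposition kernel
#'   over every food source; `"visited"` uses only the source the carrier
#'   last visited.
#'
#' @return An object of class `scenario_config` (a validated named list).
#' @examples
#' cfg <- scenario_config(M = 30, N = 30, n = 100, x0 = c(15, 15),
#'                        food_sources = list(c(25, 15)), T_max = 50)
#' cfg
#' @export
scenario_config <- function(M = 50, N = 50, n = 1000, x0 = c(25, 25),
                            food_sources = list(), D = 10, gamma = 0.001,
                            A_dep = 1, sigma_decay = 1, epsilon = 0.001,
                            dt = 0.001, dx = 1, T_max = 100, seed = 1,
                            beeline = c("adaptive", "fixed"),
                            deposition = c("all_sources", "visited")) {
  cfg <- list(M = as.integer(M), N = as.integer(N), n = as.integer(n),
              x0 = as.integer(x0), food_sources = as_food_matrix(food_sources),
              D = as.numeric(D), gamma = as.numeric(gamma),
              A_dep = as.numeric(A_dep), sigma_decay = as.numeric(sigma_decay),
              epsilon = as.numeric(epsilon), dt = as.numeric(dt),
              dx = as.numeric(dx), T_max = as.integer(T_max),
              seed = as.integer(seed),
              beeline = match.arg(beeline),
              deposition = match.arg(deposition))
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

as_food_matrix <- function(food_sources) {
  if (is.matrix(food_sources)) {
    fm <- matrix(as.integer(food_sources), ncol = 2)
  } else if (length(food_sources) == 0) {
    fm <- matrix(integer(0), ncol = 2)
  } else {
    fm <- do.call(rbind, lapply(food_sources, function(p) as.integer(p[1:2])))
  }
  colnames(fm) <- c("x", "y")
  fm
}

#' Validate a scenario configuration
#'
#' Checks every invariant of the lattice model configuration, including the
#' forward-Euler stability condition `D * dt / dx^2 <= 1/4` for the pheromone
#' field. Called by [scenario_config()]; exported so that configurations read
#' from files are re-validated.
#'
#' @param cfg A `scenario_config`.
#' @return `cfg`, invisibly unchanged, or an error naming the violated field.
#' @export
validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$M < 2 || cfg$N < 2) stop("M and N must both be >= 2", call. = FALSE)
  if (cfg$n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(cfg$x0) != 2 || !site_in_bounds(cfg$x0, cfg))
    stop("x0 must be an integer pair inside [1,M] x [1,N]", call. = FALSE)
  K <- nrow(cfg$food_sources)
  if (K > 0) {
    for (k in seq_len(K)) {
      fk <- cfg$food_sources[k, ]
      if (!site_in_bounds(fk, cfg))
        stop("food_sources[", k, "] lies outside the lattice", call. = FALSE)
      if (all(fk == cfg$x0))
        stop("food_sources[", k, "] coincides with the nest x0", call. = FALSE)
    }
    if (anyDuplicated(cfg$food_sources) > 0)
      stop("food_sources must be pairwise distinct", call. = FALSE)
  }
  if (!(cfg$epsilon > 0 && cfg$epsilon < 1))
    stop("epsilon must satisfy 0 < epsilon < 1", call. = FALSE)
  if (cfg$dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (cfg$dx <= 0) stop("dx must be > 0", call. = FALSE)
  if (cfg$D < 0 || cfg$gamma < 0 || cfg$A_dep < 0)
    stop("D, gamma and A_dep must be >= 0", call. = FALSE)
  if (cfg$sigma_decay <= 0) stop("sigma_decay must be > 0", call. = FALSE)
  if (cfg$T_max < 1) stop("T_max must be >= 1", call. = FALSE)
  mu <- cfg$D * cfg$dt / cfg$dx^2
  if (mu > 0.25)
    stop("forward-Euler stability violated: D*dt/dx^2 = ", signif(mu, 3),
         " exceeds 1/4", call. = FALSE)
  invisible(cfg)
}

site_in_bounds <- function(p, cfg) {
  p[1] >= 1 && p[1] <= cfg$M && p[2] >= 1 && p[2] <= cfg$N
}

#' @export
print.scenario_config <- function(x, ...) {
  K <- nrow(x$food_sources)
  cat("<scenario_config> ", x$M, "x", x$N, " lattice, n = ", x$n,
      ", T_max = ", x$T_max, "\n", sep = "")
  cat("  nest (", x$x0[1], ",", x$x0[2], "), ", K, " food source(s)",
      if (K > 0) paste0(": ", paste(apply(x$food_sources, 1, function(p)
        paste0("(", p[1], ",", p[2], ")")), collapse = " ")), "\n", sep = "")
  cat("  pheromone: D = ", x$D, ", gamma = ", x$gamma, ", A_dep = ", x$A_dep,
      ", sigma = ", x$sigma_decay, ", dt = ", x$dt, "\n", sep = "")
  cat("  epsilon = ", x$epsilon, ", seed = ", x$seed, ", beeline = ",
      x$beeline, ", deposition = ", x$deposition, "\n", sep = "")
  invisible(x)
}

#' Shipped scenario presets
#'
#' Three scaled-down study scenarios on a 50 x 50 lattice with the nest at
#' the centre: `"one_food"` (one source 15 sites from the nest),
#' `"two_equidistant"` (two sources, both 15 sites away on opposite sides),
#' and `"two_unequal"` (sources 10 and 15 sites away in different
#' directions). Override any field through `...`.
#'
#' @param preset One of `"one_food"`, `"two_equidistant"`, `"two_unequal"`.
#' @param ... Field overrides passed to the configuration (e.g. `seed`,
#'   `T_max`, `n`).
#' @return A `scenario_config`.
#' @examples
#' scenario_preset("one_food", T_max = 50, seed = 7)
#' @export
scenario_preset <- function(preset = c("one_food", "two_equidistant",
                                       "two_unequal"), ...) {
  preset <- match.arg(preset)
  path <- system.file("extdata", "presets", paste0(preset, ".json"),
                      package = "anttrails")
  cfg <- read_config(path)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(unclass(cfg)))
    if (length(bad)) stop("unknown scenario field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cfg <- do.call(scenario_config, utils::modifyList(unclass(cfg), dots))
  }
  cfg
}
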