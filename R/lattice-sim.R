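#' Simulate the stochastic lattice foraging model
#'
#' Runs the full event loop. One unit of time consists of `n` ant-move
#' events, each moving one uniformly chosen ant (with replacement): foragers
#' sample their Moore neighbourhood with pheromone-dependent weights (see
#' [forager_move_distribution()]), carriers take one beeline step toward the
#' nest ([carrier_step()]). Once any food source has been discovered,
#' `round(1/dt)` forward-Euler field steps per unit of time are interleaved
#' evenly across the ant events, each executed before the ant event it
#' precedes, so the field always updates first. All ants start at the nest as
#' foragers; mode conversions happen on arrival at a food source or the nest.
#' A given `(config, seed)` pair reproduces the identical trajectory.
#'
#' @param config A [scenario_config()].
#' @param snapshot_times Integer times (in units, `0:T_max`) at which to
#'   record the ant table and pheromone grid. Defaults to the final time.
#' @param record_beeline Record, for every completed carrier trip, the
#'   Chebyshev distance from its conversion site to the nest and the number
#'   of moves it took (used to verify the beeline contraction property).
#' @return A `lattice_run` object: list with `config`, `snapshots` (each a
#'   list of `time`, `ants` tibble with columns `id`, `x`, `y`, `mode`, and
#'   the `field` matrix), `discovery_time` (first forager-food contact in
#'   units of time, `Inf` if never), and `beeline` (tibble of completed-trip
#'   records, if requested).
#' @examples
#' cfg <- scenario_config(M = 21, N = 21, n = 50, x0 = c(11, 11),
#'                        food_sources = list(c(16, 11)), T_max = 20,
#'                        seed = 42)
#' run <- simulate_lattice(cfg, snapshot_times = c(10, 20))
#' glance(run)
#' @export
simulate_lattice <- function(config, snapshot_times = NULL,
                             record_beeline = TRUE) {
  validate_scenario_config(config)
  if (is.null(snapshot_times)) snapshot_times <- config$T_max
  snapshot_times <- sort(unique(as.integer(snapshot_times)))
  if (any(snapshot_times < 0) || any(snapshot_times > config$T_max))
    stop("snapshot_times must lie in [0, T_max]", call. = FALSE)
  set.seed(config$seed)
  raw <- cpp_simulate(config$M, config$N, config$n, config$x0,
                      config$food_sources, config$D, config$gamma,
                      config$A_dep, config$sigma_decay, config$epsilon,
                      config$dt, config$dx, config$T_max, snapshot_times,
                      config$beeline == "adaptive",
                      if (config$deposition == "visited") 1L else 0L,
                      record_beeline)
  snaps <- lapply(raw$snapshots, function(s) {
    a <- s$ants
    list(time = s$time,
         ants = tibble::tibble(
           id = seq_len(nrow(a)), x = a[, 1], y = a[, 2],
           mode = ifelse(a[, 3] == 1L, "carrier", "forager")),
         field = s$field)
  })
  structure(list(
    config = config,
    snapshots = snaps,
    discovery_time = if (is.na(raw$discovery_time)) Inf
                     else raw$discovery_time,
    beeline = tibble::tibble(cheb_distance = raw$beeline_cheb,
                             steps = raw$beeline_steps)),
    class = "lattice_run")
}

#' @export
print.lattice_run <- function(x, ...) {
  cat("<lattice_run> ", x$config$M, "x", x$config$N, " lattice, n = ",
      x$config$n, ", T_max = ", x$config$T_max, "\n", sep = "")
  cat("  snapshots at t = ",
      paste(vapply(x$snapshots, `[[`, 0, "time"), collapse = ", "),
      "\n", sep = "")
  cat("  discovery time: ",
      if (is.finite(x$discovery_time))
        format(round(x$discovery_time, 3)) else "never", "\n", sep = "")
  invisible(x)
}

#' Tidy a lattice run into a long tibble
#'
#' @param x A `lattice_run`.
#' @param what `"ants"` (one row per ant per snapshot) or `"field"` (one row
#'   per lattice cell per snapshot, long form `x`, `y`, `c`).
#' @param ... Unused.
#' @return A tibble with a leading `time` column.
#' @method tidy lattice_run
#' @export
tidy.lattice_run <- function(x, what = c("ants", "field"), ...) {
  what <- match.arg(what)
  purrr::map_dfr(x$snapshots, function(s) {
    if (what == "ants") {
      dplyr::mutate(s$ants, time = s$time, .before = 1)
    } else {
      grid <- tidyr::expand_grid(x = seq_len(nrow(s$field)),
                                 y = seq_len(ncol(s$field)))
      tibble::tibble(time = s$time, x = grid$x, y = grid$y,
                     c = s$field[cbind(grid$x, grid$y)])
    }
  })
}

#' One-row summary of a lattice run
#'
#' @param x A `lattice_run`.
#' @param ... Unused.
#' @return A tibble with colony size, run length, discovery time, the final
#'   carrier fraction, and total pheromone mass at the last snapshot.
#' @method glance lattice_run
#' @export
glance.lattice_run <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  tibble::tibble(
    n = x$config$n,
    T_max = x$config$T_max,
    n_food = nrow(x$config$food_sources),
    discovery_time = x$discovery_time,
    final_time = last$time,
    carrier_fraction = mean(last$ants$mode == "carrier"),
    pheromone_mass = sum(last$field) * x$config$dx^2)
}

#' Plot a lattice-run snapshot
#'
#' Pheromone field as a raster (log1p scale) with ants overlaid, coloured by
#' mode; nest and food sources marked.
#'
#' @param object A `lattice_run`.
#' @param time Snapshot time to draw (default: the last one recorded).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lattice_run
#' @export
autoplot.lattice_run <- function(object, time = NULL, ...) {
  times <- vapply(object$snapshots, `[[`, 0, "time")
  if (is.null(time)) time <- times[length(times)]
  s <- object$snapshots[[match(time, times)]]
  if (is.na(match(time, times)))
    stop("no snapshot recorded at time ", time, call. = FALSE)
  fld <- tidy.lattice_run(object, "field")
  fld <- fld[fld$time == s$time, ]
  cfg <- object$config
  marks <- tibble::tibble(
    x = c(cfg$x0[1], cfg$food_sources[, 1]),
    y = c(cfg$x0[2], cfg$food_sources[, 2]),
    what = c("nest", rep("food", nrow(cfg$food_sources))))
  ggplot2::ggplot(fld, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log1p(.data$c))) +
    ggplot2::geom_point(data = s$ants,
                        ggplot2::aes(colour = .data$mode),
                        size = 0.6, alpha = 0.6) +
    ggplot2::geom_point(data = marks, ggplot2::aes(shape = .data$what),
                        size = 3, colour = "red") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("lattice run, t = ", s$time),
                  fill = "log1p(c)")
}
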