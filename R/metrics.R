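#' Fraction of ants (or mass) inside a nest-source corridor
#'
#' The corridor is the set of points within Euclidean distance `half_width`
#' of the straight segment from the nest to the source — the operational
#' definition of "a trail has formed" used throughout the package (there is
#' no canonical quantitative criterion for a trail; this one is an artifact
#' definition, reported with its half-width).
#'
#' @param data A tibble/data frame with columns `x`, `y` (ant positions or
#'   grid-cell coordinates) and optionally a weight column for density mass.
#' @param nest,source Endpoints of the corridor segment (numeric pairs,
#'   must differ).
#' @param half_width Corridor half-width (default 3 lattice units).
#' @param weight Optional column name (string) holding nonnegative weights;
#'   omitted means every row counts 1.
#' @return A fraction in `[0, 1]`.
#' @examples
#' ants <- tibble::tibble(x = c(5, 10, 30), y = c(5, 10, 40))
#' corridor_occupancy(ants, nest = c(0, 0), source = c(15, 15))
#' @export
corridor_occupancy <- function(data, nest, source, half_width = 3,
                               weight = NULL) {
  if (all(nest == source))
    stop("degenerate corridor: nest and source coincide", call. = FALSE)
  stopifnot(half_width >= 1)
  d <- point_segment_distance(data$x, data$y, nest, source)
  w <- if (is.null(weight)) rep(1, nrow(data)) else data[[weight]]
  if (sum(w) == 0) return(0)
  sum(w[d <= half_width]) / sum(w)
}

point_segment_distance <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  t <- pmin(pmax(((px - a[1]) * abx + (py - a[2]) * aby) / len2, 0), 1)
  sqrt((px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2)
}

#' Per-source carrier fractions (winner index)
#'
#' For each food source, the fraction of carriers (or carrier mass) lying in
#' its nest-source corridor, normalized over the carriers assigned to any
#' corridor; carriers outside every corridor are excluded from the
#' normalization. Under winner-take-all competition the proximal source's
#' fraction approaches 1; for equidistant sources the ensemble mean is
#' symmetric.
#'
#' @param data Carrier positions: tibble with `x`, `y` and optionally a
#'   weight column. For lattice snapshots pass only the rows with
#'   `mode == "carrier"`.
#' @param nest Nest position.
#' @param sources List (or `K x 2` matrix) of at least one source position.
#' @param half_width Corridor half-width.
#' @param weight Optional weight column name.
#' @return A tibble with columns `source` (index), `in_corridor` (count or
#'   mass) and `fraction`. If no carrier falls in any corridor the
#'   fractions are `NA` and the `defined` attribute is `FALSE` (never
#'   `NaN`).
#' @export
winner_index <- function(data, nest, sources, half_width = 3,
                         weight = NULL) {
  if (is.matrix(sources))
    sources <- lapply(seq_len(nrow(sources)), function(k) sources[k, ])
  stopifnot(length(sources) >= 1)
  w <- if (is.null(weight)) rep(1, nrow(data)) else data[[weight]]
  mass <- vapply(sources, function(s) {
    d <- point_segment_distance(data$x, data$y, nest, s)
    sum(w[d <= half_width])
  }, 0)
  tot <- sum(mass)
  out <- tibble::tibble(source = seq_along(sources), in_corridor = mass,
                        fraction = if (tot > 0) mass / tot
                                   else rep(NA_real_, length(sources)))
  attr(out, "defined") <- tot > 0
  out
}

#' Per-axis spread of foragers about the nest
#'
#' Mean squared deviation of positions from the nest along each axis (the
#' second moment about the nest, not about the sample mean). For the
#' pre-discovery Moore random walk this grows as `0.75 * t` per axis, since
#' each of the 8 unit moves contributes `E[dx^2] = 6/8`.
#'
#' @param data Positions: tibble with `x`, `y` (at least 2 rows).
#' @param nest Nest position.
#' @return A tibble with columns `axis` (`"x"`, `"y"`) and `variance`.
#' @export
forager_spread <- function(data, nest) {
  stopifnot(nrow(data) >= 2)
  tibble::tibble(axis = c("x", "y"),
                 variance = c(mean((data$x - nest[1])^2),
                              mean((data$y - nest[2])^2)))
}

#' Time of first forager-food contact
#'
#' @param run A `lattice_run`.
#' @return Discovery time in units of time (event-resolved), or `Inf` if no
#'   food source was ever found.
#' @export
discovery_time <- function(run) {
  stopifnot(inherits(run, "lattice_run"))
  run$discovery_time
}

#' Trail metrics for every snapshot of a run
#'
#' Convenience wrapper applying [corridor_occupancy()] (all ants, per
#' source) and [winner_index()] (carriers) to each recorded snapshot of a
#' lattice run.
#'
#' @param run A `lattice_run` with at least one food source.
#' @param half_width Corridor half-width.
#' @return A tibble with one row per snapshot per source: `time`, `source`,
#'   `occupancy` (all ants in that corridor), `carrier_fraction` (winner
#'   index among carriers; `NA` before any carriers exist).
#' @export
trail_metrics <- function(run, half_width = 3) {
  cfg <- run$config
  K <- nrow(cfg$food_sources)
  stopifnot(K >= 1)
  sources <- lapply(seq_len(K), function(k) cfg$food_sources[k, ])
  purrr::map_dfr(run$snapshots, function(s) {
    carriers <- s$ants[s$ants$mode == "carrier", ]
    wi <- winner_index(carriers, cfg$x0, sources, half_width)
    occ <- vapply(sources, function(src)
      corridor_occupancy(s$ants, cfg$x0, src, half_width), 0)
    tibble::tibble(time = s$time, source = seq_len(K), occupancy = occ,
                   carrier_fraction = wi$fraction)
  })
}
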