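#' Moore neighbourhood of a lattice site
#'
#' Returns the in-bounds subset of the eight surrounding sites in a fixed
#' deterministic order (offsets scanned row-major), never including the site
#' itself. Reflecting boundaries are realized by restriction: a corner site
#' has 3 neighbours, an edge site 5, an interior site 8.
#'
#' @param pos Integer pair, the site.
#' @param config A [scenario_config()] (supplies `M`, `N`).
#' @return A tibble with columns `x`, `y`, one row per neighbour.
#' @examples
#' cfg <- scenario_config(M = 10, N = 10, n = 1, x0 = c(5, 5), T_max = 1)
#' moore_neighborhood(c(1, 1), cfg)
#' @export
moore_neighborhood <- function(pos, config) {
  check_pos(pos, config)
  nb <- cpp_moore_neighbors(as.integer(pos[1]), as.integer(pos[2]),
                            config$M, config$N)
  tibble::tibble(x = nb[, 1], y = nb[, 2])
}

check_pos <- function(pos, config) {
  if (length(pos) != 2 || !site_in_bounds(pos, config))
    stop("pos must be an integer pair inside [1,M] x [1,N]", call. = FALSE)
  invisible(pos)
}

#' Move distribution of a foraging ant
#'
#' Each in-bounds Moore neighbour `a` gets the weight `epsilon` if the
#' pheromone difference `dc = c(a) - c(pos)` is negative, `1` if it is zero,
#' and `1 + dc` if positive; probabilities are the weights normalized over
#' the neighbourhood. On a flat (e.g. all-zero) field, and at a strict local
#' maximum where every difference is negative, the distribution is uniform.
#'
#' @param pos Integer pair, the forager's site.
#' @param field Numeric `M x N` matrix of pheromone concentrations.
#' @param config A [scenario_config()].
#' @return A tibble with columns `x`, `y`, `weight`, `prob`; `prob` sums to 1.
#' @export
forager_move_distribution <- function(pos, field, config) {
  check_pos(pos, config)
  stopifnot(is.matrix(field), nrow(field) == config$M,
            ncol(field) == config$N)
  if (anyNA(field) || any(!is.finite(field)))
    stop("pheromone field contains non-finite values", call. = FALSE)
  nb <- moore_neighborhood(pos, config)
  w <- cpp_move_weights(as.integer(pos[1]), as.integer(pos[2]),
                        field, config$epsilon)
  tibble::tibble(x = nb$x, y = nb$y, weight = w, prob = w / sum(w))
}

#' One beeline step of a carrying ant
#'
#' A carrier moves to the neighbour first entered by the ray cast from the
#' centre of its site in the homing direction. With the default
#' `beeline = "adaptive"` convention the direction is `x0 - pos`, recomputed
#' every step, which decreases the Chebyshev distance to the nest by exactly
#' 1 per move; with `beeline = "fixed"` the literal vector `x0 - x_f` of the
#' visited source is extended instead (`source_index` selects it). Exact
#' 45-degree exits take the diagonal neighbour.
#'
#' @param pos Integer pair, the carrier's site (must not be the nest).
#' @param config A [scenario_config()].
#' @param source_index Which food source the carrier visited (only used for
#'   the `"fixed"` convention).
#' @return Integer pair, the next site.
#' @export
carrier_step <- function(pos, config, source_index = 1L) {
  check_pos(pos, config)
  if (all(pos == config$x0))
    stop("carrier is at the nest; it converts to a forager instead of moving",
         call. = FALSE)
  if (config$beeline == "adaptive") {
    as.integer(cpp_carrier_step(as.integer(pos[1]), as.integer(pos[2]),
                                config$x0[1], config$x0[2]))
  } else {
    xf <- config$food_sources[source_index, ]
    d <- config$x0 - xf
    sx <- sign(d[1]); sy <- sign(d[2])
    step <- if (abs(d[1]) > abs(d[2])) c(sx, 0)
            else if (abs(d[2]) > abs(d[1])) c(0, sy)
            else c(sx, sy)
    out <- as.integer(pos + step)
    if (!site_in_bounds(out, config)) as.integer(pos) else out
  }
}

#' Pheromone deposition rate of an ant
#'
#' Foragers deposit nothing. A carrier at `x` deposits at rate
#' `sum_k A_dep * exp(-(||x - x_f^(k)|| / sigma_decay)^2)` (Euclidean
#' distance), summed over all food sources under the default
#' `deposition = "all_sources"` convention, or over the single visited
#' source under `"visited"`.
#'
#' @param ant A list with elements `pos` (integer pair) and `mode`
#'   (`"forager"` or `"carrier"`), optionally `source` (index of the visited
#'   source, default 1).
#' @param config A [scenario_config()].
#' @return A nonnegative scalar rate.
#' @export
deposition_rate <- function(ant, config) {
  stopifnot(is.list(ant), ant$mode %in% c("forager", "carrier"))
  if (ant$mode == "forager") return(0)
  food <- config$food_sources
  if (config$deposition == "visited") {
    k <- if (is.null(ant$source)) 1L else as.integer(ant$source)
    food <- food[k, , drop = FALSE]
  }
  cpp_deposition_rate(as.integer(ant$pos[1]), as.integer(ant$pos[2]),
                      food, config$A_dep, config$sigma_decay)
}

#' One forward-Euler step of the pheromone field
#'
#' Advances the discretized reaction-diffusion field by one step of length
#' `dt`: diffusion through the 5-point Laplacian, exponential evaporation at
#' rate `gamma`, and deposition by every carrier into its occupied cell
#' (divided by `dx^2`, the discrete point source). Boundary faces close the
#' Laplacian with a ghost cell obeying the Robin (Fourier-type) relation
#' `D * dc/dn_out = -c`, so pheromone keeps flowing with its gradient across
#' the boundary.
#'
#' @param field Numeric `M x N` matrix.
#' @param ants A tibble (or data frame) with columns `x`, `y`, `mode`
#'   (`"forager"`/`"carrier"`), optionally `source`; only carriers deposit.
#' @param config A [scenario_config()] (must satisfy `D*dt/dx^2 <= 1/4`).
#' @return The updated `M x N` matrix.
#' @export
pheromone_step <- function(field, ants, config) {
  stopifnot(is.matrix(field), nrow(field) == config$M,
            ncol(field) == config$N)
  if (is.null(ants) || nrow(ants) == 0) {
    carr <- matrix(integer(0), ncol = 2)
    src <- integer(0)
  } else {
    keep <- ants$mode == "carrier"
    carr <- cbind(as.integer(ants$x[keep]), as.integer(ants$y[keep]))
    src <- if ("source" %in% names(ants)) as.integer(ants$source[keep])
           else rep(1L, sum(keep))
  }
  cpp_field_step(field, carr, config$food_sources, config$D, config$gamma,
                 config$A_dep, config$sigma_decay, config$dt, config$dx,
                 if (config$deposition == "visited") 1L else 0L, src)
}

#' Mode transition of an ant
#'
#' A forager standing on any food source becomes a carrier; a carrier
#' standing on the nest becomes a forager; anything else is unchanged.
#'
#' @param ant A list with `pos` and `mode` (and optionally `source`).
#' @param config A [scenario_config()].
#' @return The (possibly updated) ant.
#' @export
update_mode <- function(ant, config) {
  food <- config$food_sources
  if (ant$mode == "forager" && nrow(food) > 0) {
    hit <- which(food[, 1] == ant$pos[1] & food[, 2] == ant$pos[2])
    if (length(hit)) {
      ant$mode <- "carrier"
      ant$source <- unname(hit[1])
    }
  } else if (ant$mode == "carrier" && all(ant$pos == config$x0)) {
    ant$mode <- "forager"
  }
  ant
}
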