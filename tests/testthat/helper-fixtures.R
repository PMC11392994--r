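# small configurations reused across tests; everything is generated in code
tiny_config <- function(...) {
  args <- list(M = 10, N = 10, n = 5, x0 = c(5, 5),
               food_sources = list(c(8, 5)), T_max = 5, seed = 1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario_config, args)
}

small_trail_config <- function(seed = 1, ...) {
  scenario_config(M = 21, N = 21, n = 100, x0 = c(11, 11),
                  food_sources = list(c(16, 11)), T_max = 40, seed = seed,
                  ...)
}

# random positive parameter draw for the averaged system
random_averaged_params <- function() {
  averaged_params(alpha = runif(1, 0.1, 5), chi = runif(1, 0, 20),
                  nu = runif(1, 0, 5),
                  Omega_pq = runif(1, 0.1, 10), Omega_qp = runif(1, 0.1, 10),
                  D = runif(1, 0.5, 20), gamma = runif(1, 1e-4, 0.1),
                  A_dep = runif(1, 0.1, 10),
                  M = sample(5:40, 1), N = sample(5:40, 1),
                  x0 = c(2, 2), x_f = c(2 + runif(1, 1, 10), 2))
}
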