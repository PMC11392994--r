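#' Parameters of the space-averaged trail-formation system
#'
#' The space-averaged system replaces the point conversion terms of the
#' macroscopic PDE with domain-averaged rates `Omega/(M*N)` and the localized
#' pheromone source with `A_dep * pi/(4*M*N) * E(x_f) * q`, where `E(x_f)`
#' is a product of error-function differences ([erf_factor()]). Its
#' homogeneous equilibrium and linearization yield the dispersion relation
#' used to predict trail onset.
#'
#' Derived quantities are computed on construction: the unit homing vector
#' `e_hat = (x0 - x_f)/||x0 - x_f||`, the composite constant
#' `Gamma = (M*N)^-2 * (1/Omega_pq + 1/Omega_qp)^-1`, and `E_val = E(x_f)`.
#'
#' Default rates place the system in the trail-forming (linearly unstable)
#' regime on a 15 x 15 domain: the destabilizing chemotactic feedback must
#' beat forager diffusion and pheromone evaporation at low wavenumbers,
#' which holds here for `chi = 10`, `A_dep = 5` with the standard pheromone
#' parameters `D = 10`, `gamma = 0.001`.
#'
#' @param alpha Forager diffusion coefficient.
#' @param chi Chemotactic sensitivity of foragers to the pheromone.
#' @param nu Carrier (returner) speed.
#' @param Omega_pq,Omega_qp Forager-to-carrier and carrier-to-forager
#'   conversion rate constants.
#' @param D,gamma,A_dep Pheromone diffusion, evaporation and deposition
#'   parameters.
#' @param M,N Domain dimensions.
#' @param x0,x_f Nest and food-source positions (continuous pairs).
#' @return An object of class `averaged_params`.
#' @examples
#' ap <- averaged_params()
#' homogeneous_equilibrium(ap)
#' @export
averaged_params <- function(alpha = 1, chi = 10, nu = 1, Omega_pq = 1,
                            Omega_qp = 1, D = 10, gamma = 0.001, A_dep = 5,
                            M = 15, N = 15, x0 = c(8, 8), x_f = c(12, 8)) {
  stopifnot(alpha >= 0, chi >= 0, nu >= 0, Omega_pq > 0, Omega_qp > 0,
            D >= 0, gamma > 0, A_dep >= 0, M > 0, N > 0,
            length(x0) == 2, length(x_f) == 2)
  d <- x0 - x_f
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("x0 and x_f must differ", call. = FALSE)
  p <- list(alpha = alpha, chi = chi, nu = nu, Omega_pq = Omega_pq,
            Omega_qp = Omega_qp, D = D, gamma = gamma, A_dep = A_dep,
            M = M, N = N, x0 = x0, x_f = x_f,
            e_hat = d / nd,
            Gamma = (1 / (M * N)^2) / (1 / Omega_pq + 1 / Omega_qp),
            E_val = erf_factor(x_f, M, N))
  class(p) <- "averaged_params"
  p
}

#' @export
print.averaged_params <- function(x, ...) {
  cat("<averaged_params> ", x$M, "x", x$N, " domain\n", sep = "")
  cat("  alpha = ", x$alpha, ", chi = ", x$chi, ", nu = ", x$nu,
      ", Omega_pq = ", x$Omega_pq, ", Omega_qp = ", x$Omega_qp, "\n",
      sep = "")
  cat("  D = ", x$D, ", gamma = ", x$gamma, ", A_dep = ", x$A_dep,
      "\n  Gamma = ", format(x$Gamma), ", E(x_f) = ", format(x$E_val),
      "\n", sep = "")
  invisible(x)
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Error-function factor of the averaged pheromone source
#'
#' Evaluates
#' `E(x_f) = (erf(x_f1) - erf(x_f1 - N)) * (erf(x_f2) - erf(x_f2 - M))`,
#' the exact space average of the Gaussian deposition kernel over the
#' rectangular domain (up to the `pi/4` factor carried separately). For a
#' source well inside a large domain the factor approaches 4; it tends to 0
#' as the source leaves the domain.
#'
#' @param x_f Food-source position, a pair `(x_f1, x_f2)`.
#' @param M,N Domain dimensions.
#' @return A scalar in `[0, 4]`.
#' @export
erf_factor <- function(x_f, M, N) {
  (erf(x_f[1]) - erf(x_f[1] - N)) * (erf(x_f[2]) - erf(x_f[2] - M))
}

#' Homogeneous equilibrium of the averaged system
#'
#' Returns `p_h = Gamma*M*N/Omega_pq`, `q_h = Gamma*M*N/Omega_qp`, and
#' `u_h = Gamma*A_dep*pi*E(x_f) / (4*gamma*Omega_qp)`. These make the
#' spatially homogeneous right-hand side vanish identically and satisfy the
#' normalization `M*N*(p_h + q_h) = 1`. In the limits `Omega_pq -> 0`,
#' `Omega_qp -> Inf`, `E -> 0` the no-food equilibrium
#' `(1/(M*N), 0, 0)` is recovered.
#'
#' @param params An [averaged_params()].
#' @return A named list with `p_h`, `q_h`, `u_h`.
#' @export
homogeneous_equilibrium <- function(params) {
  MN <- params$M * params$N
  list(p_h = params$Gamma * MN / params$Omega_pq,
       q_h = params$Gamma * MN / params$Omega_qp,
       u_h = params$Gamma * params$A_dep * pi * params$E_val /
             (4 * params$gamma * params$Omega_qp))
}

#' Right-hand side of the averaged system for homogeneous states
#'
#' With all gradients zero the averaged dynamics reduce to the conversion
#' exchange and the pheromone balance; used to verify that
#' [homogeneous_equilibrium()] is an exact fixed point.
#'
#' @param params An [averaged_params()].
#' @param p,q,u Homogeneous field values.
#' @return Numeric vector `c(dp, dq, du)`.
#' @export
averaged_rhs_homogeneous <- function(params, p, q, u) {
  MN <- params$M * params$N
  ex <- params$Omega_pq / MN * p - params$Omega_qp / MN * q
  c(dp = -ex,
    dq = ex,
    du = -params$gamma * u +
      params$A_dep * pi / (4 * MN) * params$E_val * q)
}

#' Linearization matrix of the averaged system
#'
#' Assembles the 3x3 complex matrix whose singularity condition
#' `det(A) = 0` defines the dispersion relation for plane-wave perturbations
#' `exp(i k.x + lambda t)` about the homogeneous equilibrium. Rows
#' correspond to the forager, carrier and pheromone perturbations.
#'
#' @param k Wavevector, a pair `(k1, k2)`.
#' @param lambda Complex growth rate at which to evaluate the matrix.
#' @param params An [averaged_params()].
#' @return A 3x3 complex matrix.
#' @export
assemble_matrix <- function(k, lambda, params) {
  lambda * diag(3) + linearization_part(k, params)
}

# The lambda-independent part B, so that A = lambda*I + B and the dispersion
# roots are the eigenvalues of -B.
linearization_part <- function(k, params) {
  MN <- params$M * params$N
  k2 <- sum(k^2)
  a <- params$Omega_pq / MN
  b <- params$Omega_qp / MN
  ek <- sum(params$e_hat * k)
  matrix(c(
    params$alpha * k2 + a, -b,
    -params$Gamma * params$chi * MN / params$Omega_pq * k2,
    -a, -1i * params$nu * ek + b, 0,
    0, -params$A_dep * pi / (4 * MN) * params$E_val,
    params$gamma + params$D * k2),
    nrow = 3, byrow = TRUE)
}

#' Dispersion roots at one wavevector
#'
#' Expands `det(lambda*I + B) = 0` as a monic cubic in `lambda` (trace,
#' second invariant, determinant of `B`) and returns its three roots via
#' [polyroot()]; if the polynomial residual at any root is poor the roots
#' are recomputed as eigenvalues of `-B`. At `k = (0, 0)` the cubic factors
#' in closed form with roots `0`, `-(Omega_pq + Omega_qp)/(M*N)` and
#' `-gamma`.
#'
#' @param k Wavevector `(k1, k2)`.
#' @param params An [averaged_params()].
#' @return Complex vector of length 3, ordered by decreasing real part.
#' @export
dispersion_roots <- function(k, params) {
  B <- linearization_part(k, params)
  # char poly of -B: det(lambda*I + B) = lambda^3 + c2 lambda^2 + c1 lambda + c0
  c2 <- B[1, 1] + B[2, 2] + B[3, 3]
  c1 <- B[1, 1] * B[2, 2] - B[1, 2] * B[2, 1] +
        B[1, 1] * B[3, 3] - B[1, 3] * B[3, 1] +
        B[2, 2] * B[3, 3] - B[2, 3] * B[3, 2]
  c0 <- B[1, 1] * (B[2, 2] * B[3, 3] - B[2, 3] * B[3, 2]) -
        B[1, 2] * (B[2, 1] * B[3, 3] - B[2, 3] * B[3, 1]) +
        B[1, 3] * (B[2, 1] * B[3, 2] - B[2, 2] * B[3, 1])
  r <- polyroot(c(c0, c1, c2, 1))
  scale <- max(1, Mod(c(c0, c1, c2)))
  resid <- Mod(r^3 + c2 * r^2 + c1 * r + c0) / scale
  if (any(!is.finite(resid)) || max(resid) > 1e-8)
    r <- eigen(-B, only.values = TRUE)$values
  r[order(-Re(r))]
}

#' Rectangular wavevector grid
#'
#' Uniform grid over `[-k_max, k_max]^2`. The trail-forming instability of
#' this system lives at low wavenumbers, so the default extent is small
#' enough to resolve the positive-growth window around the origin.
#'
#' @param k_max Half-extent of the grid.
#' @param nk Number of points per axis.
#' @param drop_origin Remove the `k = (0, 0)` point (where one root is
#'   always exactly 0).
#' @return A tibble with columns `k1`, `k2`.
#' @export
k_grid <- function(k_max = 0.05, nk = 51, drop_origin = FALSE) {
  ks <- seq(-k_max, k_max, length.out = nk)
  g <- tidyr::expand_grid(k1 = ks, k2 = ks)
  if (drop_origin) g <- g[!(g$k1 == 0 & g$k2 == 0), ]
  g
}

#' Maximum growth rate over a wavevector grid
#'
#' Evaluates [dispersion_roots()] at every grid point and reports the
#' largest real part and where it is attained. A positive maximum signals
#' linear instability of the homogeneous state — the onset of trail
#' formation — while a nonpositive maximum over all `k != 0` means
#' perturbations decay.
#'
#' @param params An [averaged_params()].
#' @param grid A tibble with columns `k1`, `k2` (see [k_grid()]).
#' @return A `dispersion_result`: the per-wavevector root table plus the
#'   attained maximum; see [tidy.dispersion_result()].
#' @export
max_growth_rate <- function(params, grid = k_grid()) {
  stopifnot(nrow(grid) > 0)
  roots <- t(vapply(seq_len(nrow(grid)), function(i) {
    dispersion_roots(c(grid$k1[i], grid$k2[i]), params)
  }, complex(3)))
  max_re_k <- apply(Re(roots), 1, max)
  imax <- which.max(max_re_k)
  structure(list(
    k_grid = grid, roots = roots,
    max_re_per_k = max_re_k,
    max_re = max_re_k[imax],
    argmax_k = c(grid$k1[imax], grid$k2[imax]),
    params = params),
    class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("<dispersion_result> ", nrow(x$k_grid), " wavevectors\n", sep = "")
  cat("  max Re(lambda) = ", format(x$max_re), " at k = (",
      format(x$argmax_k[1]), ", ", format(x$argmax_k[2]), ")\n", sep = "")
  cat("  homogeneous state ",
      if (x$max_re > 0) "UNSTABLE (trail onset)" else "stable", "\n",
      sep = "")
  invisible(x)
}

#' Tidy a dispersion result
#'
#' @param x A `dispersion_result`.
#' @param ... Unused.
#' @return A tibble with `k1`, `k2`, the three complex roots split into
#'   `re_l1..re_l3`, `im_l1..im_l3` (ordered by decreasing real part), and
#'   `max_re`.
#' @method tidy dispersion_result
#' @export
tidy.dispersion_result <- function(x, ...) {
  tibble::tibble(
    k1 = x$k_grid$k1, k2 = x$k_grid$k2,
    re_l1 = Re(x$roots[, 1]), im_l1 = Im(x$roots[, 1]),
    re_l2 = Re(x$roots[, 2]), im_l2 = Im(x$roots[, 2]),
    re_l3 = Re(x$roots[, 3]), im_l3 = Im(x$roots[, 3]),
    max_re = x$max_re_per_k)
}

#' @method glance dispersion_result
#' @export
glance.dispersion_result <- function(x, ...) {
  tibble::tibble(max_re = x$max_re,
                 argmax_k1 = x$argmax_k[1], argmax_k2 = x$argmax_k[2],
                 unstable = x$max_re > 0, n_k = nrow(x$k_grid))
}

#' Plot the projected dispersion surface
#'
#' Projects the dispersion surface onto the `k1` axis: for each `k1` the
#' largest real part over `k2` is drawn, the standard way to display the
#' low-wavenumber instability window.
#'
#' @param object A `dispersion_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dispersion_result
#' @export
autoplot.dispersion_result <- function(object, ...) {
  d <- tidy(object)
  proj <- dplyr::summarise(dplyr::group_by(d, .data$k1),
                           max_re = max(.data$re_l1), .groups = "drop")
  ggplot2::ggplot(proj, ggplot2::aes(.data$k1, .data$max_re)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(k[1]),
                  y = expression(max~Re~lambda))
}

#' Sweep one parameter of the averaged system
#'
#' Re-evaluates [max_growth_rate()] for each value of one rate parameter,
#' holding the rest fixed — the standard way to read off which parameters
#' stabilize (pheromone diffusion, evaporation) or destabilize (deposition
#' amount) the homogeneous state, and that returner speed barely matters.
#'
#' @param param_name One of `"alpha"`, `"chi"`, `"nu"`, `"Omega_pq"`,
#'   `"Omega_qp"`, `"D"`, `"gamma"`, `"A_dep"`.
#' @param values Numeric vector of parameter values.
#' @param params Baseline [averaged_params()].
#' @param grid Wavevector grid (see [k_grid()]).
#' @return A tibble with columns `param`, `value`, `max_re`, `argmax_k1`,
#'   `argmax_k2`.
#' @export
parameter_sweep <- function(param_name, values, params = averaged_params(),
                            grid = k_grid()) {
  allowed <- c("alpha", "chi", "nu", "Omega_pq", "Omega_qp", "D", "gamma",
               "A_dep")
  if (!param_name %in% allowed)
    stop("unknown parameter: ", param_name, call. = FALSE)
  purrr::map_dfr(values, function(v) {
    args <- unclass(params)[c(allowed, "M", "N", "x0", "x_f")]
    args[[param_name]] <- v
    res <- max_growth_rate(do.call(averaged_params, args), grid)
    tibble::tibble(param = param_name, value = v, max_re = res$max_re,
                   argmax_k1 = res$argmax_k[1], argmax_k2 = res$argmax_k[2])
  })
}
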