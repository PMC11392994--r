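test_that("erf factor matches its limiting values", {
  # source deep inside a large domain: both differences tend to 2
  expect_equal(erf_factor(c(50, 50), 100, 100), 4, tolerance = 1e-10)
  # source at the origin corner of a large domain
  expect_equal(erf_factor(c(0, 0), 100, 100), 1, tolerance = 1e-10)
  expect_equal(erf_factor(c(-30, -30), 100, 100), 0, tolerance = 1e-12)
})

test_that("homogeneous equilibrium annihilates the averaged dynamics", {
  set.seed(101)
  for (i in 1:20) {
    ap <- random_averaged_params()
    eq <- homogeneous_equilibrium(ap)
    rhs <- averaged_rhs_homogeneous(ap, eq$p_h, eq$q_h, eq$u_h)
    expect_lt(max(abs(rhs)), 1e-12)
    expect_equal(ap$M * ap$N * (eq$p_h + eq$q_h), 1, tolerance = 1e-14)
  }
  # equal conversion rates: p_h = q_h = 1/(2MN)
  ap <- averaged_params(Omega_pq = 3, Omega_qp = 3, M = 10, N = 20)
  eq <- homogeneous_equilibrium(ap)
  expect_equal(eq$p_h, 1 / (2 * 200))
  expect_equal(eq$q_h, 1 / (2 * 200))
  # no-food limits recover (1/MN, 0, 0)
  ap0 <- averaged_params(Omega_pq = 1e-10, Omega_qp = 1e10,
                         x_f = c(-50, -50), M = 10, N = 10)
  eq0 <- homogeneous_equilibrium(ap0)
  expect_equal(eq0$p_h, 1 / 100, tolerance = 1e-10)
  expect_equal(eq0$q_h, 0, tolerance = 1e-12)
  expect_equal(eq0$u_h, 0, tolerance = 1e-12)
})

test_that("linearization matrix has the printed structure", {
  ap <- averaged_params()
  MN <- ap$M * ap$N
  A <- assemble_matrix(c(1, 0), 0 + 0i, ap)
  expect_equal(A[1, 3], -ap$Gamma * ap$chi * MN / ap$Omega_pq + 0i)
  expect_equal(A[2, 3], 0 + 0i)
  expect_equal(A[3, 1], 0 + 0i)
  expect_equal(A[3, 2], -ap$A_dep * pi / (4 * MN) * ap$E_val + 0i)
  # k = 0: no k-dependence left
  A0 <- assemble_matrix(c(0, 0), 0.5 + 0i, ap)
  expect_equal(A0[1, 1], 0.5 + ap$Omega_pq / MN + 0i)
  expect_equal(A0[3, 3], 0.5 + ap$gamma + 0i)
  # k -> -k conjugates the advection entry and nothing else
  k <- c(0.3, 0.1)
  Ap <- assemble_matrix(k, 0 + 0i, ap)
  Am <- assemble_matrix(-k, 0 + 0i, ap)
  expect_equal(Am[2, 2], Conj(Ap[2, 2]))
  expect_equal(Am[1, 1], Ap[1, 1])
})

test_that("dispersion roots solve det(A) = 0 and respect k -> -k
           conjugation", {
  set.seed(7)
  for (i in 1:10) {
    ap <- random_averaged_params()
    k <- runif(2, -1, 1)
    det3 <- function(A) {
      A[1, 1] * (A[2, 2] * A[3, 3] - A[2, 3] * A[3, 2]) -
      A[1, 2] * (A[2, 1] * A[3, 3] - A[2, 3] * A[3, 1]) +
      A[1, 3] * (A[2, 1] * A[3, 2] - A[2, 2] * A[3, 1])
    }
    r <- dispersion_roots(k, ap)
    for (lam in r)
      expect_lt(Mod(det3(assemble_matrix(k, lam, ap))), 1e-8)
    # independent oracle: eigenvalues of the negated linear part
    ev <- eigen(-anttrails:::linearization_part(k, ap),
                only.values = TRUE)$values
    expect_equal(sort(Re(r)), sort(Re(ev)), tolerance = 1e-8)
    expect_equal(sort(Im(r)), sort(Im(ev)), tolerance = 1e-8)
    # conjugate symmetry
    rm <- dispersion_roots(-k, ap)
    expect_equal(sort(Re(rm)), sort(Re(r)), tolerance = 1e-8)
    expect_equal(sort(Im(rm)), sort(-Im(r)), tolerance = 1e-8)
  }
})

test_that("high-wavenumber perturbations always decay", {
  ap <- averaged_params()
  r <- dispersion_roots(c(100, 0), ap)
  expect_true(all(Re(r) < 0))
  r <- dispersion_roots(c(70, -70), ap)
  expect_true(all(Re(r) < 0))
})

test_that("default parameters sit in the trail-forming window at low k", {
  res <- max_growth_rate(averaged_params(), k_grid(0.05, 41))
  expect_gt(res$max_re, 0)
  expect_lt(sqrt(sum(res$argmax_k^2)), 0.02)
  d <- tidy(res)
  expect_equal(nrow(d), 41^2)
  # the k = 0 root set contains 0
  expect_equal(d$re_l1[d$k1 == 0 & d$k2 == 0], 0, tolerance = 1e-10)
})

test_that("parameter sweeps reduce to direct calls and validate names", {
  ap <- averaged_params()
  g <- k_grid(0.05, 21)
  sw <- parameter_sweep("D", 10, ap, g)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$max_re, max_growth_rate(ap, g)$max_re)
  sw3 <- parameter_sweep("gamma", c(1e-3, 2e-3, 4e-3), ap, g)
  expect_equal(nrow(sw3), 3)
  expect_error(parameter_sweep("bogus", 1, ap, g), "unknown")
})
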