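test_that("Moore neighbourhood restricts to in-bounds sites", {
  cfg <- tiny_config()
  expect_equal(nrow(moore_neighborhood(c(5, 5), cfg)), 8)
  corner <- moore_neighborhood(c(1, 1), cfg)
  expect_equal(nrow(corner), 3)
  expect_setequal(paste(corner$x, corner$y),
                  c("1 2", "2 1", "2 2"))
  expect_equal(nrow(moore_neighborhood(c(1, 5), cfg)), 5)
  expect_error(moore_neighborhood(c(0, 5), cfg), "pos")
  # never contains the site itself
  nb <- moore_neighborhood(c(5, 5), cfg)
  expect_false(any(nb$x == 5 & nb$y == 5))
})

test_that("forager move weights follow the gradient rule", {
  cfg <- tiny_config()
  zero <- matrix(0, 10, 10)
  d <- forager_move_distribution(c(5, 5), zero, cfg)
  expect_equal(d$prob, rep(1 / 8, 8))
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)

  # strict local maximum: all differences negative, uniform again
  f <- matrix(0, 10, 10); f[5, 5] <- 1
  d <- forager_move_distribution(c(5, 5), f, cfg)
  expect_equal(d$weight, rep(cfg$epsilon, 8))
  expect_equal(d$prob, rep(1 / 8, 8))

  # one up-gradient (+0.5), one down-gradient (-0.2), six flat
  f <- matrix(0, 10, 10); f[6, 5] <- 0.5; f[4, 5] <- -0.2
  d <- forager_move_distribution(c(5, 5), f, cfg)
  expect_equal(sum(d$weight), 7.501)
  expect_equal(d$prob[d$x == 6 & d$y == 5], 1.5 / 7.501)
  expect_equal(d$prob[d$x == 4 & d$y == 5], 0.001 / 7.501)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)

  f[3, 3] <- NaN
  expect_error(forager_move_distribution(c(5, 5), f, cfg), "non-finite")
})

test_that("beeline step tracks the ray to the nest", {
  cfg <- scenario_config(M = 10, N = 10, n = 1, x0 = c(1, 1), T_max = 1)
  expect_equal(carrier_step(c(5, 5), cfg), c(4L, 4L))   # exact diagonal
  expect_equal(carrier_step(c(2, 1), cfg), c(1L, 1L))   # adjacent
  expect_equal(carrier_step(c(7, 3), cfg), c(6L, 3L))   # shallow ray, x face
  expect_error(carrier_step(c(1, 1), cfg), "nest")
  # Chebyshev distance contracts by exactly 1 from any site
  cheb <- function(p) max(abs(p - cfg$x0))
  for (p in list(c(9, 2), c(2, 9), c(10, 10), c(1, 7), c(6, 2))) {
    s <- carrier_step(p, cfg)
    expect_equal(cheb(s), cheb(p) - 1)
  }
})

test_that("deposition decays with distance from the food and is
           carrier-only", {
  cfg <- tiny_config()  # one source at (8, 5), A_dep = 1, sigma = 1
  expect_equal(deposition_rate(list(pos = c(8, 5), mode = "carrier"), cfg),
               1.0)
  expect_equal(deposition_rate(list(pos = c(6, 5), mode = "carrier"), cfg),
               exp(-4))
  expect_equal(deposition_rate(list(pos = c(8, 5), mode = "forager"), cfg),
               0)
  # printed form: sum over all sources
  cfg2 <- tiny_config(food_sources = list(c(8, 5), c(2, 5)))
  expect_equal(deposition_rate(list(pos = c(8, 5), mode = "carrier"), cfg2),
               1 + exp(-36))
  cfg3 <- tiny_config(food_sources = list(c(8, 5), c(2, 5)),
                      deposition = "visited")
  expect_equal(deposition_rate(list(pos = c(8, 5), mode = "carrier",
                                    source = 2), cfg3), exp(-36))
})

test_that("field step: decay, point deposition, and the zero fixed point", {
  cfg <- tiny_config()
  none <- tibble::tibble(x = integer(), y = integer(), mode = character())
  # uniform field, no carriers: pure decay in the interior
  f1 <- pheromone_step(matrix(1, 10, 10), none, cfg)
  expect_equal(f1[5, 5], 1 - cfg$gamma * cfg$dt)
  # zero field, one carrier on the source: c = dt * A_dep there
  carr <- tibble::tibble(x = 8L, y = 5L, mode = "carrier")
  f2 <- pheromone_step(matrix(0, 10, 10), carr, cfg)
  expect_equal(f2[8, 5], cfg$dt * cfg$A_dep)
  expect_equal(sum(f2 != 0), 1)
  # zero field, no carriers: fixed point
  expect_equal(pheromone_step(matrix(0, 10, 10), none, cfg),
               matrix(0, 10, 10))
})

test_that("mode transitions happen only at food sources and the nest", {
  cfg <- tiny_config()
  a <- update_mode(list(pos = c(8, 5), mode = "forager"), cfg)
  expect_equal(a$mode, "carrier")
  expect_equal(a$source, 1)
  b <- update_mode(list(pos = c(5, 5), mode = "carrier"), cfg)
  expect_equal(b$mode, "forager")
  c3 <- update_mode(list(pos = c(3, 3), mode = "forager"), cfg)
  expect_equal(c3$mode, "forager")
  c4 <- update_mode(list(pos = c(8, 5), mode = "carrier"), cfg)
  expect_equal(c4$mode, "carrier")
})
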