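test_that("growth saturates in food with the Monod half-saturation", {
  p <- growth_params()
  expect_equal(growth_rate(1e12, 0, 0, "juvenile", FALSE, p),
               p$g0 + p$a1, tolerance = 1e-9)
  expect_equal(growth_rate(p$a2, 0, 0, "juvenile", FALSE, p),
               p$g0 + p$a1 / 2)
  # monotone increasing and concave in food
  f <- seq(0, 5, length.out = 200)
  g <- growth_rate(f, 0, 0, "juvenile", FALSE, p)
  expect_true(all(diff(g) > 0))
  expect_true(all(diff(diff(g)) <= 1e-12))
  # decreasing in density and light
  expect_true(growth_rate(1, 10, 0, p = p) < growth_rate(1, 0, 0, p = p))
  expect_true(growth_rate(1, 0, 100, p = p) < growth_rate(1, 0, 0, p = p))
})

test_that("light hampers adult growth more than juvenile growth", {
  p <- growth_params(u = 0.02)
  light <- 50
  pen_j <- growth_rate(1, 0, 0, "juvenile", p = p) -
    growth_rate(1, 0, light, "juvenile", p = p)
  pen_a <- growth_rate(1, 0, 0, "adult", p = p) -
    growth_rate(1, 0, light, "adult", p = p)
  expect_gt(pen_a, pen_j)
  expect_equal(pen_a - pen_j, p$u * log10(1 + light))
})

test_that("reaction distance responds to light, prey size and spectrum", {
  p <- rd_params(r0 = 0, k = 4, l = 0.5, alpha = 0.4, phi = 1)
  expect_equal(reaction_distance(0, c(0, 1, 0), "juvenile", p), 0)
  red <- reaction_distance(50, c(1, 0, 0), "juvenile", p)
  green <- reaction_distance(50, c(0, 1, 0), "juvenile", p)
  blue <- reaction_distance(50, c(0, 0, 1), "juvenile", p)
  expect_equal(red, p$alpha * green)
  expect_lt(red, green)
  expect_equal(blue, green)      # phi = 1: blue and green equivalent
  # adult-juvenile difference is l times the band factor
  bands <- c(0.2, 0.5, 0.3)
  d <- reaction_distance(50, bands, "adult", p) -
    reaction_distance(50, bands, "juvenile", p)
  expect_equal(d, p$l * sum(bands * c(p$alpha, 1, p$phi)))
  # non-decreasing in light
  rd <- reaction_distance(seq(0, 100, by = 1), c(0, 1, 0), "juvenile", p)
  expect_true(all(diff(rd) >= 0))
})

test_that("attack rate is the cylindrical search volume per day", {
  expect_equal(attack_rate(0, 5.62), 0)
  expect_equal(attack_rate(1, 5.62), pi * 1^2 * 5.62 * 86.4)
  expect_equal(attack_rate(2, 3), 4 * attack_rate(1, 3))
})

test_that("threshold-disc consumption matches Holling's disc equation when
           the threshold vanishes", {
  # independent oracle: direct evaluation of a*N/(1+a*h*N)
  holling_II <- function(N, a, h) a * N / (1 + a * h * N)
  p <- fr_params(attack = 1.3, handling = 0.004, gamma = 0, n = 1)
  N <- seq(0, 100, length.out = 1000)
  expect_equal(consumption_rate(N, p),
               holling_II(N, 1.3, 0.004), tolerance = 1e-12)
})

test_that("consumption respects the foraging-initiation threshold and the
           handling plateau", {
  p3 <- fr_params(attack = 1.2, handling = 0.002, gamma = 3.4158, n = 2)
  expect_equal(consumption_rate(c(0, 1, 3.4158), p3), c(0, 0, 0))
  p1 <- fr_params(attack = 2, handling = 0, gamma = 0, n = 1)
  expect_equal(consumption_rate(c(1, 5, 10), p1), 2 * c(1, 5, 10))
  p2 <- fr_params(attack = 2, handling = 0.01, gamma = 0, n = 1)
  expect_equal(consumption_rate(1e9, p2), 1 / 0.01, tolerance = 1e-6)
})

test_that("per-capita risk is decreasing for type II and unimodal with a
           low-density refuge for type III", {
  p2 <- fr_params(attack = 1.2, handling = 0.002, gamma = 0, n = 1)
  N <- seq(0.01, 100, length.out = 500)
  r2 <- per_capita_fish_mortality(N, p2, predator_density = 1)
  expect_true(all(diff(r2) < 0))
  expect_equal(per_capita_fish_mortality(0, p2, 1), 1.2)  # N -> 0+ limit
  # handling 0: constant risk
  p0 <- fr_params(attack = 2, handling = 0, gamma = 0, n = 1)
  expect_equal(per_capita_fish_mortality(c(1, 10, 50), p0, 3), rep(6, 3))
  # type III: zero below gamma, interior maximum (brute-force grid)
  p3 <- fr_params(attack = 1.2, handling = 0.002, gamma = 3.4158, n = 2)
  r3 <- per_capita_fish_mortality(N, p3, predator_density = 1)
  expect_true(all(r3[N <= 3.4158] == 0))
  expect_equal(per_capita_fish_mortality(0, p3, 1), 0)
  imax <- which.max(r3)
  expect_gt(imax, 1); expect_lt(imax, length(N))
  expect_gt(N[imax], 3.4158)
})

test_that("total mortality adds a constant background term", {
  p <- mortality_params(longevity = 50)
  expect_equal(total_mortality(0, p), 0.02)
  expect_equal(total_mortality(0.07, p) - total_mortality(0, p), 0.07)
  expect_true(all(total_mortality(runif(20), p) >= 1 / 50))
})

test_that("fitness ranks positive growth by the Werner-Gilliam ratio and
           non-positive growth strictly below it", {
  expect_equal(fitness(0.1, 0.02), 5)
  expect_lt(fitness(0.1, 0.05), fitness(0.1, 0.02))
  expect_equal(fitness(0, 0.02), 0)
  expect_gt(fitness(1e-9, 10), fitness(0, 0.001))
  expect_gt(fitness(-0.01, 0.001), fitness(-0.02, 0.001))
  expect_lt(fitness(-1e-9, 0.001), fitness(1e-9, 10))
  expect_error(fitness(0.1, 0), "invalid rate")
})

test_that("rates stay finite on finite inputs", {
  p <- growth_params(); f3 <- fr_params(gamma = 2, n = 3)
  grid <- expand.grid(food = c(0, 0.5, 100), dens = c(0, 60, 600),
                      light = c(0, 1, 1e4))
  g <- with(grid, growth_rate(food, dens, light, p = p))
  expect_true(all(is.finite(g)))
  expect_true(all(is.finite(consumption_rate(c(0, 1, 1e6), f3))))
  expect_true(all(is.finite(
    per_capita_fish_mortality(c(0, 1, 1e6), f3, 1))))
})
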