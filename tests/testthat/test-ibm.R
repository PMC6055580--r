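test_that("identical seed and configuration give bit-identical runs", {
  cfg <- simulation_config(40, "juvenile", "both", "III",
                           n_replicates = 2, seed = 11)
  r1 <- run_replicates(cfg)
  r2 <- run_replicates(cfg)
  expect_identical(r1$mean_distribution, r2$mean_distribution)
  expect_identical(r1$final_sectors, r2$final_sectors)
})

test_that("occupancy is conserved and agents move at most one sector per
           sweep", {
  env <- treatment_environment("both")
  vr <- default_vital_rates("juvenile", "II")
  set.seed(5)
  state <- list(agent_sectors = rep(5L, 25))
  for (i in 1:30) {
    prev <- state$agent_sectors
    state <- ibm_step(state, env, vr)
    expect_equal(sum(state$occupancy), 25)
    expect_equal(state$occupancy,
                 tabulate(state$agent_sectors, nbins = 10))
    expect_true(all(abs(state$agent_sectors - prev) <= 1))
  }
  expect_equal(state$step, 30L)
})

test_that("a lone forager climbs a strict food gradient greedily", {
  col <- sector_column()
  env <- build_environment(col,
                           make_profile("exponential-top", 2, 2, col),
                           make_profile("uniform", 1, column = col))
  vr <- vr_growth_only()
  set.seed(1)
  state <- list(agent_sectors = 10L)
  for (i in 1:9) state <- ibm_step(state, env, vr)
  expect_equal(state$agent_sectors, 1L)
})

test_that("a lone agent in a uniform column performs an unbiased lazy
           random walk", {
  env <- treatment_environment("none")
  vr <- default_vital_rates("juvenile", "II")
  cfg <- simulation_config(1, "juvenile", "none", "II", n_steps = 10000,
                           burn_in = 100, n_replicates = 1, seed = 99)
  res <- run_simulation(cfg, env = env, params = vr,
                        keep_trajectory = TRUE)
  moves <- diff(as.integer(res$agent_sectors))
  up <- sum(moves == -1); down <- sum(moves == 1)
  expect_gt(up + down, 1000)   # it does move
  expect_gt(stats::binom.test(up, up + down)$p.value, 0.001)
})

test_that("replicate aggregation is consistent with single runs", {
  cfg <- simulation_config(30, "juvenile", "food", "II",
                           n_replicates = 5, seed = 21)
  agg <- run_replicates(cfg)
  expect_equal(agg$grand_mean_depth, mean(agg$per_replicate_mean_depth))
  expect_equal(sum(agg$mean_distribution), 1, tolerance = 1e-9)
  # n_replicates = 1 equals run_simulation at the derived seed
  cfg1 <- cfg; cfg1$n_replicates <- 1L
  one <- run_replicates(cfg1)
  cfg_direct <- cfg; cfg_direct$seed <- derive_seed(cfg$seed, 1)
  direct <- run_simulation(cfg_direct)
  expect_identical(one$per_replicate_mean_depth,
                   direct$per_replicate_mean_depth)
  expect_identical(one$mean_distribution, direct$mean_distribution)
})

test_that("derived replicate seeds are deterministic 32-bit integers", {
  s <- vapply(1:200, function(r) derive_seed(123, r), integer(1))
  expect_true(all(s == vapply(1:200, function(r) derive_seed(123, r),
                              integer(1))))
  expect_true(all(s >= 0 & s < 2^31))
  expect_equal(length(unique(s)), 200L)
})

test_that("the no-gradient treatment spreads agents uniformly", {
  cfg <- simulation_config(60, "juvenile", "none", "II",
                           n_replicates = 100, seed = 31)
  res <- run_replicates(cfg)
  counts <- res$mean_distribution * 60 * 100
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
  expect_equal(res$grand_mean_depth, 0.5, tolerance = 0.02)
})

test_that("perceived fitness blurs sub-threshold differences and counts
           the mover in the candidate sector", {
  col <- sector_column()
  # adjacent sectors differ in food by 10%: invisible to a juvenile with
  # ae_F = 0.19, visible to an adult with ae_F = 0.08
  food <- 1.0 * 1.1^(9:0)
  env <- build_environment(col, food, make_profile("uniform", 1, column = col))
  vr_j <- default_vital_rates("juvenile", "II", predator_density = 0)
  vr_a <- default_vital_rates("adult", "II", predator_density = 0)
  occ <- rep(1L, 10)
  up_j <- perceived_fitness(5, 4, occ, env, vr_j)
  stay_j <- perceived_fitness(5, 5, occ, env, vr_j)
  # juvenile: food blurred, but candidate density includes the mover, so
  # the move looks strictly worse than staying
  dens_pen <- growth_rate(env$food[5], 1 / 0.6, 1, "juvenile",
                          p = vr_j$growth) -
    growth_rate(env$food[5], 2 / 0.6, 1, "juvenile", p = vr_j$growth)
  expect_equal(stay_j - up_j, dens_pen / 0.02, tolerance = 1e-9)
  # adult: the 10% food difference is visible
  up_a <- perceived_fitness(5, 4, occ, env, vr_a)
  gr_true <- growth_rate(env$food[4], 2 / 0.6, 1, "adult", p = vr_a$growth)
  expect_equal(up_a, gr_true / 0.02, tolerance = 1e-9)
  # zero thresholds perceive truth
  vr0 <- vr_growth_only()
  up0 <- perceived_fitness(5, 4, occ, env, vr0)
  gr0 <- growth_rate(env$food[4], 2 / 0.6, 1, "juvenile", p = vr0$growth)
  expect_equal(up0, gr0 / 0.02, tolerance = 1e-9)
  expect_error(perceived_fitness(2, 5, occ, env, vr0), "adjacent")
})

test_that("equilibrium gain is zero on a flat landscape without
           interference", {
  col <- sector_column()
  env <- build_environment(col, rep(0.8, 10), rep(1, 10))
  vr <- vr_growth_only()
  vr$growth$b <- 0
  for (sec in list(rep(3L, 7), 1:10, c(1L, 1L, 10L))) {
    expect_equal(equilibrium_check(sec, env, vr), 0)
  }
  # a single agent at the global optimum has nothing to gain
  env2 <- build_environment(col, make_profile("exponential-top", 2, 2, col),
                            rep(1, 10))
  expect_lte(equilibrium_check(1L, env2, vr_growth_only()), 0)
})
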