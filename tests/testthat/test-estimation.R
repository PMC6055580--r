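truth_III <- fr_params(attack = 1.2, handling = 0.002, gamma = 3.4158, n = 2)
truth_II <- fr_params(attack = 1.2, handling = 0.002, gamma = 0, n = 1)

test_that("noiseless functional-response data are refit exactly", {
  d2 <- gen_consumption(truth_II, noise_sd = 0, seed = 1)
  f2 <- fit_functional_response(d2, "II")
  expect_equal(f2$params$attack, 1.2, tolerance = 1e-6)
  expect_equal(f2$params$handling, 0.002, tolerance = 1e-6)

  d3 <- gen_consumption(truth_III, noise_sd = 0, seed = 1)
  f3 <- fit_functional_response(d3, "III")
  expect_equal(f3$params$attack, 1.2, tolerance = 1e-6)
  expect_equal(f3$params$handling, 0.002, tolerance = 1e-6)
  expect_equal(f3$params$gamma, 3.4158, tolerance = 1e-6)
  expect_equal(f3$params$n, 2, tolerance = 1e-6)
  # the all-zero rows below the threshold force a positive gamma
  expect_gt(f3$params$gamma, 1)
  # refitting threshold data as type II leaves residual error (nesting)
  f2on3 <- fit_functional_response(d3, "II")
  expect_gt(f2on3$sse, f3$sse)
})

test_that("type III never fits worse than type II on the same data", {
  for (s in 1:5) {
    d <- gen_consumption(truth_II, noise_sd = 15, seed = s)
    f2 <- fit_functional_response(d, "II")
    f3 <- fit_functional_response(d, "III")
    expect_lte(f3$sse, f2$sse + 1e-8 * (1 + f2$sse))
  }
})

test_that("model selection prefers parsimony at equal fit and detects a
           real threshold", {
  d2 <- gen_consumption(truth_II, noise_sd = 0, seed = 2)
  sel0 <- compare_response_types(fit_functional_response(d2, "II"),
                                 fit_functional_response(d2, "III"))
  expect_equal(sel0$F, 0)
  expect_equal(sel0$selected, "II")

  d3 <- gen_consumption(truth_III, noise_sd = 15, seed = 2)
  sel3 <- compare_response_types(fit_functional_response(d3, "II"),
                                 fit_functional_response(d3, "III"))
  expect_equal(sel3$selected, "III")
  expect_lt(sel3$aic_III, sel3$aic_II)

  d_other <- gen_consumption(truth_III, noise_sd = 15, seed = 3)
  expect_error(
    compare_response_types(fit_functional_response(d3, "II"),
                           fit_functional_response(d_other, "III")),
    "identical data")
})

test_that("insufficient consumption data raise data errors", {
  d <- gen_consumption(truth_II, densities = c(1, 5, 20), n_rep = 1,
                       noise_sd = 0, seed = 1)
  expect_error(fit_functional_response(d, "II"), "at least 4 rows")
  d2 <- gen_consumption(truth_II, densities = c(1, 5), n_rep = 3,
                        noise_sd = 0, seed = 1)
  expect_error(fit_functional_response(d2, "II"), "distinct")
})

test_that("the per-capita transformation exposes the response shape", {
  d <- data.frame(prey_density = 10, consumption = 5)
  expect_equal(to_per_capita_risk(d)$risk, 0.5)
  N <- seq(0.5, 80, length.out = 200)
  d2 <- data.frame(prey_density = N,
                   consumption = consumption_rate(N, truth_II))
  expect_true(all(diff(to_per_capita_risk(d2)$risk) < 0))
  d3 <- data.frame(prey_density = N,
                   consumption = consumption_rate(N, truth_III))
  r3 <- to_per_capita_risk(d3)$risk
  expect_true(all(r3[N <= truth_III$gamma] == 0))
  imax <- which.max(r3)
  expect_true(imax > 1 && imax < length(N))
  dz <- data.frame(prey_density = c(0, 5), consumption = c(0, 2))
  expect_warning(out <- to_per_capita_risk(dz), "zero-density")
  expect_equal(nrow(out), 1L)
})

test_that("the age-scaled threshold reproduces the printed adult value", {
  expect_identical(scale_gamma_for_age(3.4158, 2), 0.0342)
  expect_equal(scale_gamma_for_age(1.23, 0), 1.23)
  expect_equal(scale_gamma_for_age(0, 5), 0)
})

test_that("noiseless growth trials are refit exactly and the design's
           identifiability is tracked", {
  gt <- growth_params()
  d0 <- gen_growth(gt, noise_sd = 0, seed = 1)
  fit <- fit_growth_model(d0)
  expect_equal(unlist(fit$params), unlist(gt), tolerance = 1e-6)
  expect_length(fit$fixed, 0)
  # food-only design: only g0, a1, a2 identifiable, the rest flagged
  des <- expand.grid(food = c(0.1, 0.2, 0.4, 0.8, 1.6), density = 1,
                     light = 1, age = "juvenile", kairomone = FALSE,
                     stringsAsFactors = FALSE)
  dfo <- gen_growth(gt, design = des, n_rep = 3, noise_sd = 0, seed = 2)
  ffo <- fit_growth_model(dfo)
  expect_setequal(ffo$fixed, c("b", "c", "u", "kappa"))
  expect_setequal(names(ffo$se), c("g0", "a1", "a2"))
  expect_error(fit_growth_model(dfo[dfo$food < 0.2, ]), "food levels")
})

test_that("a planted age-by-light interaction is detected", {
  hits <- vapply(1:20, function(s)
    fit_growth_model(gen_growth(growth_params(), seed = s))$p[["u"]] < 0.05,
    logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("noiseless reaction-distance trials are refit exactly and band
           contrasts behave", {
  rt <- rd_params(r0 = 0.5, k = 4, l = 0.5, alpha = 0.6, phi = 1)
  d0 <- gen_rd(rt, noise_sd = 0, seed = 1)
  fit <- fit_reaction_distance_model(d0)
  expect_equal(unlist(fit$params), unlist(rt), tolerance = 1e-6)
  # with noise: the red-green contrast is significant, blue-green is not
  dn <- gen_rd(rt, noise_sd = 0.3, seed = 3)
  fn <- fit_reaction_distance_model(dn)
  ctr <- fn$contrasts
  expect_lt(ctr$p[ctr$contrast == "red_vs_green"], 0.05)
  expect_gt(ctr$p[ctr$contrast == "blue_vs_green"], 0.05)
  # light-independent data: the light slope CI covers zero
  d_flat <- gen_rd(rd_params(r0 = 5, k = 0, l = 0.5, alpha = 0.6),
                   noise_sd = 0.3, seed = 4)
  f_flat <- fit_reaction_distance_model(d_flat)
  expect_gt(f_flat$p[["k"]], 0.01)
})

test_that("the perception-cost estimator recovers planted slowdowns and
           the gradient arm is more variable", {
  same <- data.frame(arm = rep(c("homogeneous", "gradient"), each = 10),
                     growth = rep(seq(0.2, 0.29, by = 0.01), 2))
  expect_equal(estimate_perception_cost(same)$percent_slowdown, 0)

  planted <- gen_paired_growth("juvenile", target_deficit = 9.2, seed = 5)
  pc <- estimate_perception_cost(planted)
  expect_true(pc$ci[1] < 9.2 && 9.2 < pc$ci[2])
  expect_equal(pc$percent_slowdown, 9.2, tolerance = 0.25)

  # location-dependent intake inflates the gradient-arm SD
  hold <- vapply(1:10, function(s) {
    p <- estimate_perception_cost(gen_paired_growth("juvenile", seed = s))
    p$sd_gradient > p$sd_homogeneous
  }, logical(1))
  expect_gte(mean(hold), 0.9)
})

test_that("the Poisson-deviance loss improves the deviance of the OLS
           solution it starts from", {
  tr <- fr_params(attack = 1.2, handling = 0.002, gamma = 0, n = 1)
  d <- gen_consumption(tr, noise_sd = 10, seed = 6)
  f_ols <- fit_functional_response(d, "II")
  f_poi <- fit_functional_response(d, "II", loss = "poisson")
  expect_s3_class(f_poi, "fr_fit")
  dev <- function(p) {
    mu <- pmax(consumption_rate(d$prey_density, p), 1e-9)
    2 * sum(mu - d$consumption * log(mu))
  }
  expect_lte(f_poi$deviance, dev(f_ols$params) + 1e-8)
  # on noiseless data both losses agree on the truth
  d0 <- gen_consumption(tr, noise_sd = 0, seed = 6)
  f0 <- fit_functional_response(d0, "II", loss = "poisson")
  expect_equal(f0$params$attack, 1.2, tolerance = 1e-3)
  expect_equal(f0$params$handling, 0.002, tolerance = 1e-3)
})
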