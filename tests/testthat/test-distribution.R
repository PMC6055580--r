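col10 <- sector_column()

test_that("mean depth is the midpoint-weighted average", {
  expect_equal(mean_depth(rep(0.1, 10), col10), 0.5)
  expect_equal(mean_depth(c(1, rep(0, 9)), col10), 0.05)
  expect_equal(mean_depth(c(rep(0, 9), 1), col10), 0.95)
  expect_error(mean_depth(rep(0.2, 10), col10), "sum to 1")
  # consistent permutation of sectors and fractions leaves it unchanged
  fr <- c(0.4, 0.1, 0, 0.2, 0, 0, 0.05, 0.15, 0.1, 0)
  perm <- sample(10)
  expect_equal(sum(fr[perm] * col10$midpoints[perm]),
               mean_depth(fr, col10))
})

test_that("density regression recovers exact lines and translation only
           shifts the intercept", {
  rec <- data.frame(density = c(1, 5, 10, 20, 40),
                    mean_depth = 0.3 + 0.004 * c(1, 5, 10, 20, 40))
  fit <- density_regression(rec)
  expect_equal(fit$slope, 0.004)
  expect_equal(fit$intercept, 0.3)
  rec2 <- rec; rec2$mean_depth <- rec2$mean_depth + 0.1
  fit2 <- density_regression(rec2)
  expect_equal(fit2$slope, fit$slope)
  expect_equal(fit2$intercept, fit$intercept + 0.1)
  expect_error(density_regression(rec[1:2, ]), "3 records")
})

test_that("the regression slope is null-calibrated", {
  set.seed(8)
  rec <- data.frame(density = runif(30, 1, 60),
                    mean_depth = 0.5 + rnorm(30, 0, 0.05))
  fit <- density_regression(rec)
  expect_gt(fit$p, 0.01)
})

test_that("ANCOVA separates slope and intercept differences and
           suppresses the intercept test when slopes differ", {
  dens <- rep(c(2, 8, 15, 30, 50), 4)
  grp <- rep(c("a", "b"), each = 10)
  # identical groups
  same <- data.frame(density = dens, mean_depth = 0.3 + 0.002 * dens,
                     group = grp)
  cmp0 <- compare_groups(same)
  expect_equal(cmp0$slope_test$F, 0, tolerance = 1e-9)
  expect_equal(cmp0$intercept_test$F, 0, tolerance = 1e-9)
  # equal slopes, offset intercepts well beyond the noise
  set.seed(2)
  noise <- rnorm(20, 0, 0.01)
  off <- data.frame(density = dens,
                    mean_depth = 0.3 + 0.002 * dens +
                      0.2 * (grp == "b") + noise,
                    group = grp)
  cmp1 <- compare_groups(off)
  expect_gt(cmp1$slope_test$p, 0.05)
  expect_lt(cmp1$intercept_test$p, 0.001)
  expect_equal(cmp1$intercepts[["b"]] - cmp1$intercepts[["a"]], 0.2,
               tolerance = 0.06)
  # different slopes: the intercept test is suppressed in the report
  diff_slope <- data.frame(density = dens,
                           mean_depth = 0.3 +
                             (0.001 + 0.008 * (grp == "b")) * dens + noise,
                           group = grp)
  cmp2 <- compare_groups(diff_slope)
  expect_lt(cmp2$slope_test$p, 0.05)
  expect_null(cmp2$intercept_test)
  expect_match(cmp2$intercept_suppressed_reason, "slopes differ")
  # degrees of freedom follow the (df; error df) convention
  expect_equal(cmp1$slope_test$df, 1)
  expect_equal(cmp1$slope_test$error_df, 16)
  expect_equal(cmp1$intercept_test$error_df, 17)
  expect_error(compare_groups(same[same$group == "a", ]), "2 levels")
})

test_that("permuted group labels give calibrated p-values", {
  set.seed(77)
  rec <- data.frame(density = runif(24, 1, 60),
                    mean_depth = 0.4 + rnorm(24, 0, 0.08))
  pvals <- replicate(300, {
    rec$group <- sample(rep(c("a", "b"), each = 12))
    compare_groups(rec)$slope_test$p
  })
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.13)
  expect_gt(mean(pvals), 0.35)
})

test_that("Bonferroni levels match the printed family adjustments", {
  expect_identical(bonferroni_alpha(0.05, 12), 0.00417)
  expect_identical(bonferroni_alpha(0.05, 4), 0.0125)
  expect_equal(bonferroni_alpha(0.03, 1), 0.03)
  expect_error(bonferroni_alpha(1.2, 4), "family_alpha")
})

# records with a planted adult-vs-juvenile depth offset only under both
# gradients, everything else exchangeable
planted_records <- function(seed = 4, offset = 0.25, sd = 0.02) {
  set.seed(seed)
  grid <- expand.grid(treatment = c("none", "food", "risk", "both"),
                      age = c("juvenile", "adult"), idx = 1:10,
                      stringsAsFactors = FALSE)
  grid$source <- "experiment"
  grid$column_side <- sample(c("left", "right"), nrow(grid), TRUE)
  grid$density <- runif(nrow(grid), 0.5, 60)
  grid$mean_depth <- 0.5 + rnorm(nrow(grid), 0, sd) +
    ifelse(grid$treatment == "both" & grid$age == "adult", offset, 0)
  grid$idx <- NULL
  grid
}

test_that("the comparison battery flags exactly the planted effect", {
  rec <- planted_records()
  bat <- run_comparison_battery(rec)
  expect_equal(nrow(bat$experiment), 12L)
  expect_equal(bat$alpha12, 0.00417)
  expect_equal(bat$alpha4, 0.0125)
  hit <- bat$experiment$comparison == "juvenile vs adult, both"
  expect_true(bat$experiment$intercept_significant[hit])
  # the two treatment contrasts involving 'both' for adults also see the
  # offset; no other comparison may fire
  allowed <- hit | grepl("adult, .*both", bat$experiment$comparison)
  expect_false(any(bat$experiment$intercept_significant[!allowed]))
  expect_false(any(bat$experiment$slope_significant, na.rm = TRUE))
})

test_that("missing cells yield explicit missing-comparison rows", {
  rec <- planted_records()
  rec <- rec[!(rec$treatment == "risk" & rec$age == "adult"), ]
  bat <- run_comparison_battery(rec)
  miss <- grepl("missing comparison", bat$experiment$note)
  expect_true(any(miss))
  expect_true(all(is.na(bat$experiment$slope_p[miss])))
  expect_equal(nrow(bat$experiment), 12L)
})

test_that("the battery is a pure function of its input records", {
  rec <- planted_records(seed = 9)
  b1 <- run_comparison_battery(rec)
  b2 <- run_comparison_battery(rec)
  expect_identical(b1$experiment, b2$experiment)
})

test_that("experiment-vs-simulation comparisons cover the 16-cell layout", {
  rec <- planted_records()
  sim <- rec[rec$source == "experiment", ]
  sim_II <- sim; sim_II$source <- "simulation-II"
  sim_III <- sim; sim_III$source <- "simulation-III"
  sim_III$mean_depth <- sim_III$mean_depth + 0.3  # simulations run deeper
  bat <- run_comparison_battery(rbind(rec, sim_II, sim_III))
  expect_equal(nrow(bat$simulation), 16L)
  ii <- bat$simulation$response_type == "II"
  expect_false(any(bat$simulation$intercept_significant[ii]))
  expect_true(all(bat$simulation$intercept_significant[!ii] |
                    !is.na(bat$simulation$note[!ii]) &
                    nzchar(bat$simulation$note[!ii])))
})

test_that("records survive a CSV round trip", {
  rec <- planted_records()
  f <- tempfile(fileext = ".csv")
  write_records_csv(rec, f)
  back <- read_records_csv(f)
  expect_equal(back$mean_depth, rec$mean_depth)
  expect_equal(back$treatment, rec$treatment)
  unlink(f)
})
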