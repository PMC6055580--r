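#' Mean depth of a distribution over the column
#'
#' Midpoint-weighted average depth of per-sector occupancy fractions.
#'
#' @param distribution fractions per sector (sum to 1, tolerance 1e-6).
#' @param column a [sector_column()].
#' @return Mean depth in metres.
#' @export
mean_depth <- function(distribution, column) {
  stopifnot(inherits(column, "sector_column"))
  if (length(distribution) != column$n_sectors)
    stop("distribution length does not match the column")
  if (abs(sum(distribution) - 1) > 1e-6)
    stop("distribution fractions must sum to 1")
  sum(distribution * column$midpoints)
}

#' Regression of mean depth on population density
#'
#' Ordinary least squares of per-experiment mean depth on overall
#' population density, the density-dependence test applied to each
#' treatment-by-age group.
#'
#' @param records data frame with columns `density` (ind L^-1, > 0) and
#'   `mean_depth` (m); typically one treatment-by-age cell of a record set.
#' @return A list with `slope`, `intercept`, `F`, `df`, `error_df`, `p`,
#'   `r_squared`, `n` and the fitted `model`.
#' @export
density_regression <- function(records) {
  check_records(records, need = c("density", "mean_depth"))
  if (nrow(records) < 3L)
    stop("need at least 3 records for a density regression")
  if (length(unique(records$density)) < 2L)
    stop("need at least 2 distinct densities")
  fit <- lm(mean_depth ~ density, data = records)
  an <- suppressWarnings(anova(fit))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       F = an$`F value`[1], df = an$Df[1], error_df = an$Df[2],
       p = an$`Pr(>F)`[1],
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = nrow(records), model = fit)
}

# one row of a sequential anova as (F, df, error df, p); a term whose sum
# of squares is numerically zero (e.g. perfectly coincident groups, where
# the residual variance may be zero too and F would be 0/0) is reported as
# F = 0, p = 1
clean_anova_row <- function(an, term) {
  ss <- an[term, "Sum Sq"]
  tot <- sum(an[, "Sum Sq"])
  Fv <- an[term, "F value"]; p <- an[term, "Pr(>F)"]
  if (is.na(Fv) || !is.finite(Fv) || ss <= 1e-12 * max(tot, 1e-300)) {
    Fv <- 0; p <- 1
  }
  list(F = Fv, df = an[term, "Df"], error_df = an["Residuals", "Df"],
       p = p)
}

check_records <- function(records, need) {
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (any(records$density <= 0)) stop("densities must be positive")
  invisible(TRUE)
}

#' ANCOVA comparison of two groups of depth records
#'
#' Implements the two-stage slope/intercept comparison: (1) an F-test of
#' slope homogeneity (the density-by-group interaction in the full model);
#' (2) only when slopes are homogeneous at `alpha`, an F-test of the group
#' intercept under the common-slope model. Degrees of freedom are reported
#' as (df; error df). When the slopes differ the intercept test is
#' suppressed (reported as `NULL` with a reason), mirroring standard
#' ANCOVA reporting practice.
#'
#' @param records data frame with `density`, `mean_depth` and the grouping
#'   column.
#' @param grouping name of a two-level factor column in `records`.
#' @param alpha level at which a slope difference suppresses the intercept
#'   test.
#' @return An object of class `ancova_comparison`: `slope_test` and
#'   `intercept_test` (each `F`, `df`, `error_df`, `p`; the latter `NULL`
#'   when suppressed, with `intercept_suppressed_reason`), `slopes` and
#'   `intercepts` per group, `groups`, `n`.
#' @export
compare_groups <- function(records, grouping = "group", alpha = 0.05) {
  check_records(records, need = c("density", "mean_depth", grouping))
  g <- factor(records[[grouping]])
  if (nlevels(g) != 2L)
    stop("grouping factor must have exactly 2 levels, got ", nlevels(g))
  for (lev in levels(g)) {
    sub <- records[g == lev, ]
    if (nrow(sub) < 3L || length(unique(sub$density)) < 2L)
      stop("degenerate group '", lev,
           "': need >= 3 records and >= 2 distinct densities")
  }
  d <- data.frame(density = records$density,
                  mean_depth = records$mean_depth, group = g)
  full <- lm(mean_depth ~ density * group, data = d)
  an_full <- suppressWarnings(anova(full))
  slope_test <- clean_anova_row(an_full, "density:group")
  # per-group lines
  cf <- coef(full)
  slopes <- c(cf[["density"]], cf[["density"]] + cf[[4]])
  intercepts <- c(cf[["(Intercept)"]], cf[["(Intercept)"]] + cf[[3]])
  names(slopes) <- names(intercepts) <- levels(g)
  if (is.na(slope_test$p) || slope_test$p >= alpha) {
    common <- lm(mean_depth ~ density + group, data = d)
    intercept_test <- clean_anova_row(suppressWarnings(anova(common)), "group")
    reason <- NULL
  } else {
    intercept_test <- NULL
    reason <- sprintf("slopes differ (p = %.4g < %.4g); intercepts not compared",
                      slope_test$p, alpha)
  }
  structure(list(slope_test = slope_test, intercept_test = intercept_test,
                 intercept_suppressed_reason = reason,
                 slopes = slopes, intercepts = intercepts,
                 groups = levels(g), n = nrow(d)),
            class = "ancova_comparison")
}

#' @export
print.ancova_comparison <- function(x, ...) {
  st <- x$slope_test
  cat(sprintf("<ancova_comparison> %s vs %s (n = %d)\n",
              x$groups[1], x$groups[2], x$n))
  cat(sprintf("  slopes:     F_%d;%d = %.3f, p = %.4g\n",
              st$df, st$error_df, st$F, st$p))
  if (is.null(x$intercept_test)) {
    cat("  intercepts:", x$intercept_suppressed_reason, "\n")
  } else {
    it <- x$intercept_test
    cat(sprintf("  intercepts: F_%d;%d = %.3f, p = %.4g\n",
                it$df, it$error_df, it$F, it$p))
  }
  invisible(x)
}

#' Bonferroni-adjusted per-comparison significance level
#'
#' `family_alpha / m`, reported at 3 significant figures: 0.00417 for a
#' family of 12 comparisons at 0.05, 0.0125 for 4.
#'
#' @param family_alpha family-wise error rate, in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return Per-comparison alpha.
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  if (family_alpha <= 0 || family_alpha >= 1)
    stop("'family_alpha' must lie in (0, 1)")
  if (m < 1) stop("'m' must be at least 1")
  signif(family_alpha / m, 3)
}

# the 12 within-experiment comparisons: juveniles vs adults in each
# treatment, and the 4 treatment contrasts within each age class
battery_plan_experiment <- function() {
  treatments <- c("none", "food", "risk", "both")
  plan <- lapply(treatments, function(tr)
    list(label = paste0("juvenile vs adult, ", tr),
         type = "age", treatment = tr))
  pairs <- list(c("none", "food"), c("none", "risk"),
                c("food", "both"), c("risk", "both"))
  for (age in c("juvenile", "adult"))
    for (pr in pairs)
      plan[[length(plan) + 1L]] <-
        list(label = paste0(age, ", ", pr[1], " vs ", pr[2]),
             type = "treatment", age = age, pair = pr)
  plan
}

run_one_comparison <- function(sub, grouping, alpha) {
  tryCatch({
    cmp <- compare_groups(sub, grouping = grouping, alpha = alpha)
    st <- cmp$slope_test; it <- cmp$intercept_test
    data.frame(slope_F = st$F, slope_df = st$df, slope_edf = st$error_df,
               slope_p = st$p,
               intercept_F = if (is.null(it)) NA_real_ else it$F,
               intercept_df = if (is.null(it)) NA_integer_ else it$df,
               intercept_edf = if (is.null(it)) NA_integer_ else it$error_df,
               intercept_p = if (is.null(it)) NA_real_ else it$p,
               note = if (is.null(it)) "intercepts suppressed (slopes differ)"
                      else "")
  }, error = function(e)
    data.frame(slope_F = NA_real_, slope_df = NA_integer_,
               slope_edf = NA_integer_, slope_p = NA_real_,
               intercept_F = NA_real_, intercept_df = NA_integer_,
               intercept_edf = NA_integer_, intercept_p = NA_real_,
               note = paste("missing comparison:", conditionMessage(e))))
}

#' Run the full slope/intercept comparison battery
#'
#' Executes (i) the 12 within-experiment comparisons (juveniles vs adults
#' in each treatment; the four treatment contrasts none-food, none-risk,
#' food-both, risk-both within each age class), flagged at the
#' Bonferroni-adjusted level for 12 comparisons, and (ii) when simulation
#' records are present, the 16 experiment-vs-simulation comparisons
#' (2 ages x 4 treatments x 2 response-type scenarios), flagged at the
#' level for 4 comparisons per age-by-treatment family. Each comparison
#' also reports the per-group density-regression slope. Missing cells
#' produce an explicit missing-comparison row rather than an error.
#'
#' @param records data frame with columns `source` (`"experiment"`,
#'   `"simulation-II"`, `"simulation-III"`), `treatment`, `age`, `density`,
#'   `mean_depth` (and optionally `column_side`, carried but not tested).
#' @param alpha family-wise error rate.
#' @return A list of class `comparison_battery`: `experiment` (12-row data
#'   frame), `simulation` (16-row data frame or `NULL`), `alpha12`,
#'   `alpha4`.
#' @export
run_comparison_battery <- function(records, alpha = 0.05) {
  check_records(records,
                need = c("source", "treatment", "age", "density",
                         "mean_depth"))
  a12 <- bonferroni_alpha(alpha, 12)
  a4 <- bonferroni_alpha(alpha, 4)
  exp_rec <- records[records$source == "experiment", ]

  rows <- lapply(battery_plan_experiment(), function(cmp) {
    if (cmp$type == "age") {
      sub <- exp_rec[exp_rec$treatment == cmp$treatment, ]
      sub$group <- sub$age
    } else {
      sub <- exp_rec[exp_rec$age == cmp$age &
                       exp_rec$treatment %in% cmp$pair, ]
      sub$group <- sub$treatment
    }
    cbind(data.frame(comparison = cmp$label), run_one_comparison(sub, "group", a12))
  })
  tab1 <- do.call(rbind, rows)
  tab1$slope_significant <- !is.na(tab1$slope_p) & tab1$slope_p < a12
  tab1$intercept_significant <- !is.na(tab1$intercept_p) &
    tab1$intercept_p < a12

  sims <- intersect(c("simulation-II", "simulation-III"),
                    unique(records$source))
  tab2 <- NULL
  if (length(sims) > 0) {
    rows2 <- list()
    for (age in c("juvenile", "adult"))
      for (type in c("II", "III"))
        for (tr in c("none", "food", "risk", "both")) {
          src <- paste0("simulation-", type)
          sub <- records[records$age == age & records$treatment == tr &
                           records$source %in% c("experiment", src), ]
          sub$group <- ifelse(sub$source == "experiment",
                              "experiment", "simulation")
          rows2[[length(rows2) + 1L]] <- cbind(
            data.frame(age = age, response_type = type, treatment = tr),
            run_one_comparison(sub, "group", a4))
        }
    tab2 <- do.call(rbind, rows2)
    tab2$slope_significant <- !is.na(tab2$slope_p) & tab2$slope_p < a4
    tab2$intercept_significant <- !is.na(tab2$intercept_p) &
      tab2$intercept_p < a4
  }
  structure(list(experiment = tab1, simulation = tab2,
                 alpha12 = a12, alpha4 = a4),
            class = "comparison_battery")
}

#' @export
print.comparison_battery <- function(x, ...) {
  cat("<comparison_battery>\n")
  cat(sprintf("Within-experiment comparisons (per-comparison alpha %.3g):\n",
              x$alpha12))
  print(x$experiment[, c("comparison", "slope_p", "intercept_p",
                         "slope_significant", "intercept_significant")],
        row.names = FALSE)
  if (!is.null(x$simulation)) {
    cat(sprintf("\nExperiment vs simulation (per-comparison alpha %.3g):\n",
                x$alpha4))
    print(x$simulation[, c("age", "response_type", "treatment", "slope_p",
                           "intercept_p", "slope_significant",
                           "intercept_significant")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Read / write experiment records as CSV
#'
#' Columns: `source`, `treatment`, `age`, `column_side`, `density`,
#' `mean_depth` (plus any extra columns such as `provenance`).
#'
#' @param records a records data frame.
#' @param file path.
#' @export
write_records_csv <- function(records, file) {
  write.csv(records, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(file) {
  df <- read.csv(file)
  need <- c("source", "treatment", "age", "density", "mean_depth")
  if (!all(need %in% names(df)))
    stop("records CSV must have columns: ", paste(need, collapse = ", "))
  df
}
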