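# Seeded generators for every dataset the pipeline consumes. Noise is
# Gaussian, truncated at zero where the response is non-negative;
# changing only the seed changes only the noise.

trunc_noise <- function(mu, sd) {
  if (sd <= 0) return(mu)
  pmax(0, mu + rnorm(length(mu), 0, sd))
}

#' Generate consumption-rate trials
#'
#' Saturating (optionally threshold-initiated) consumption over a density
#' grid with truncated Gaussian observation noise, emulating per-session
#' feeding trials. The default truth is a type III response with the
#' fitted threshold `gamma = 3.4158` ind L^-1 and shape `n = 2`; rows below
#' the threshold have zero consumption before noise.
#'
#' @param true_params an [fr_params()] truth.
#' @param densities prey densities, ind L^-1.
#' @param n_rep feeding sessions per density.
#' @param noise_sd observation noise SD, prey predator^-1 day^-1.
#' @param seed integer seed.
#' @return Data frame with `prey_density` and `consumption`.
#' @export
gen_consumption <- function(true_params = fr_params(attack = 1.2,
                                                    handling = 0.002,
                                                    gamma = 3.4158, n = 2),
                            densities = c(0.166, 0.5, 1, 2, 3, 5, 8, 12,
                                          20, 30, 45, 62),
                            n_rep = 2L, noise_sd = 15, seed = 1L) {
  if (any(densities < 0)) stop("densities must be non-negative")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  set.seed(seed)
  N <- rep(densities, each = n_rep)
  mu <- consumption_rate(N, true_params)
  data.frame(prey_density = N, consumption = trunc_noise(mu, noise_sd))
}

#' Generate factorial growth trials
#'
#' Growth rates from the [growth_rate()] surface over a full factorial of
#' food, density, light, age and kairomone, plus Gaussian noise on the
#' response. The default design (five food levels bracketing the incipient
#' level, three densities, three light decades, both ages, both kairomone
#' states, two replicates per cell) gives comfortable power for the
#' age-by-light interaction at the default effect and noise sizes.
#'
#' @param true_params a [growth_params()] truth.
#' @param design optional data frame with columns `food`, `density`,
#'   `light`, `age`, `kairomone`; defaults to the factorial above.
#' @param n_rep replicates per design cell.
#' @param noise_sd response noise SD, day^-1.
#' @param seed integer seed.
#' @return Data frame ready for [fit_growth_model()].
#' @export
gen_growth <- function(true_params = growth_params(),
                       design = NULL, n_rep = 2L, noise_sd = 0.02,
                       seed = 1L) {
  if (is.null(design))
    design <- expand.grid(food = c(0.1, 0.2, 0.4, 0.8, 1.6),
                          density = c(1, 30, 60),
                          light = c(1, 10, 100),
                          age = c("juvenile", "adult"),
                          kairomone = c(FALSE, TRUE),
                          stringsAsFactors = FALSE)
  set.seed(seed)
  d <- design[rep(seq_len(nrow(design)), each = n_rep), , drop = FALSE]
  rownames(d) <- NULL
  mu <- mapply(function(f, dd, l, a, k)
    growth_rate(f, dd, l, a, k, true_params),
    d$food, d$density, d$light, d$age, d$kairomone)
  d$growth <- mu + if (noise_sd > 0) rnorm(nrow(d), 0, noise_sd) else 0
  d
}

#' Generate reaction-distance trials
#'
#' Reaction distances from the [reaction_distance()] form with one pure
#' spectral band per trial and truncated Gaussian noise.
#'
#' @param true_params an [rd_params()] truth.
#' @param lights light levels, relative units.
#' @param bands spectral bands used.
#' @param ages age classes used.
#' @param n_rep trials per cell.
#' @param noise_sd noise SD, cm.
#' @param seed integer seed.
#' @return Data frame ready for [fit_reaction_distance_model()].
#' @export
gen_rd <- function(true_params = rd_params(),
                   lights = c(1, 10, 100),
                   bands = c("red", "green", "blue"),
                   ages = c("juvenile", "adult"),
                   n_rep = 4L, noise_sd = 0.3, seed = 1L) {
  set.seed(seed)
  d <- expand.grid(light = lights, band = bands, age = ages,
                   rep = seq_len(n_rep), stringsAsFactors = FALSE)
  d$rep <- NULL
  w <- list(red = c(1, 0, 0), green = c(0, 1, 0), blue = c(0, 0, 1))
  mu <- mapply(function(l, b, a)
    reaction_distance(l, w[[b]], a, true_params),
    d$light, d$band, d$age)
  d$rd <- trunc_noise(mu, noise_sd)
  d
}

# one noisy count: each individual's observed sector is its true sector
# (drawn from the time-averaged distribution) with probability 1 - epsilon,
# otherwise an adjacent one; with epsilon = 0 the count is exact
observe_count <- function(dist, n, column, epsilon) {
  if (epsilon == 0) return(sum(dist * column$midpoints))
  S <- column$n_sectors
  true_sec <- sample.int(S, n, replace = TRUE, prob = dist)
  err <- runif(n) < epsilon
  shift <- ifelse(runif(n) < 0.5, -1L, 1L)
  obs <- true_sec + ifelse(err, shift, 0L)
  obs <- pmin(pmax(obs, 1L), S)
  mean(column$midpoints[obs])
}

#' Generate synthetic verification-experiment records
#'
#' For each treatment-by-age cell, draws densities spanning the
#' experimental range (0.166--62 ind L^-1, i.e. 1--360 individuals in the
#' 6-L column), runs one column simulation per record, and converts the
#' post-burn-in distribution into an observed mean depth by two noisy
#' counts (each individual observed in its true sector with probability
#' `1 - epsilon`, otherwise an adjacent one) whose mean depths are
#' averaged — mirroring the "mean of two counts" protocol. Records carry a
#' `provenance = "synthetic"` column.
#'
#' @param treatments,ages cells to generate.
#' @param n_per_cell experiments per cell (the study ran 8--11).
#' @param density_range overall densities, ind L^-1; log-uniform draws.
#' @param epsilon per-individual miscount probability.
#' @param response_type functional-response scenario for the generating
#'   simulations.
#' @param column a [sector_column()].
#' @param n_steps,burn_in simulation protocol per record.
#' @param seed integer seed.
#' @return A records data frame (`source = "experiment"`) for
#'   [run_comparison_battery()].
#' @export
gen_experiment_records <- function(treatments = c("none", "food", "risk",
                                                  "both"),
                                   ages = c("juvenile", "adult"),
                                   n_per_cell = 9L,
                                   density_range = c(0.166, 62),
                                   epsilon = 0.05,
                                   response_type = "III",
                                   column = sector_column(),
                                   n_steps = 200L, burn_in = 100L,
                                   seed = 1L) {
  if (epsilon < 0 || epsilon > 1) stop("'epsilon' must lie in [0, 1]")
  set.seed(seed)
  rows <- list()
  rec_id <- 0L
  for (tr in treatments) {
    env <- treatment_environment(tr, column)
    for (age in ages) {
      dens <- exp(runif(n_per_cell, log(density_range[1]),
                        log(density_range[2])))
      side <- sample(rep(c("left", "right"), length.out = n_per_cell))
      for (i in seq_len(n_per_cell)) {
        rec_id <- rec_id + 1L
        n_ind <- max(1L, min(360L, round(dens[i] * column$total_volume)))
        cfg <- simulation_config(n_ind, age = age, treatment = tr,
                                 response_type = response_type,
                                 n_steps = n_steps, burn_in = burn_in,
                                 n_replicates = 1L,
                                 seed = derive_seed(seed, rec_id))
        res <- run_simulation(cfg, env = env)
        md <- mean(c(observe_count(res$mean_distribution, n_ind, column,
                                   epsilon),
                     observe_count(res$mean_distribution, n_ind, column,
                                   epsilon)))
        rows[[rec_id]] <- data.frame(
          source = "experiment", treatment = tr, age = age,
          column_side = side[i],
          density = n_ind / column$total_volume,
          mean_depth = md, provenance = "synthetic")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate simulation-side records for the battery
#'
#' For each treatment-by-age cell and each density of a grid, runs the
#' replicate set of the column simulation under one response-type scenario
#' and records the grand mean depth, producing the `simulation-II` /
#' `simulation-III` rows consumed by [run_comparison_battery()].
#'
#' @param response_type `"II"` or `"III"`.
#' @param densities overall densities, ind L^-1.
#' @param n_replicates replicates per density.
#' @inheritParams gen_experiment_records
#' @return A records data frame with `source = "simulation-<type>"`.
#' @export
gen_simulation_records <- function(response_type = c("II", "III"),
                                   treatments = c("none", "food", "risk",
                                                  "both"),
                                   ages = c("juvenile", "adult"),
                                   densities = c(0.166, 1, 5, 15, 35, 60),
                                   n_replicates = 20L,
                                   column = sector_column(),
                                   n_steps = 200L, burn_in = 100L,
                                   seed = 1L) {
  response_type <- match.arg(response_type)
  rows <- list()
  idx <- 0L
  for (tr in treatments) {
    env <- treatment_environment(tr, column)
    for (age in ages) {
      params <- default_vital_rates(age, response_type)
      for (dens in densities) {
        idx <- idx + 1L
        n_ind <- max(1L, min(360L, round(dens * column$total_volume)))
        cfg <- simulation_config(n_ind, age = age, treatment = tr,
                                 response_type = response_type,
                                 n_steps = n_steps, burn_in = burn_in,
                                 n_replicates = n_replicates,
                                 seed = derive_seed(seed, idx))
        res <- run_replicates(cfg, env = env, params = params)
        rows[[idx]] <- data.frame(
          source = paste0("simulation-", response_type), treatment = tr,
          age = age, column_side = NA_character_,
          density = n_ind / column$total_volume,
          mean_depth = res$grand_mean_depth, provenance = "synthetic")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate paired growth data: gradient vs homogeneous food column
#'
#' The homogeneous arm grows at the gradient's maximum food concentration
#' (the omniscient benchmark); the gradient arm grows at the food levels
#' each individual actually experiences in a column simulation run with
#' the age class's perception thresholds, so both the mean deficit and the
#' larger between-individual spread arise from imperfect assessment of the
#' gradient. The default gradient is gentle (`gradient_attenuation = 1.5`
#' m^-1, adjacent-sector food steps of 14--16%): such steps fall below the
#' juvenile detection threshold (0.19), so juveniles drift through the
#' gradient instead of fine-tuning their position — which is exactly the
#' location-dependent-intake mechanism that depresses mean growth and
#' inflates its between-individual spread. Measurement noise is added to
#' both arms. When `target_deficit` is supplied the gradient arm is
#' rescaled to that expected percent deficit (a planted truth for
#' estimator checks).
#'
#' @param age age class (sets the perception thresholds).
#' @param n_individuals individuals per arm.
#' @param true_params a [growth_params()] truth.
#' @param target_deficit optional planted percent slowdown.
#' @param window number of terminal steps over which each individual's
#'   realised growth is averaged; a short window keeps the between-
#'   individual positional differences that make the gradient arm more
#'   variable (long windows mix positions away).
#' @param noise_sd measurement noise SD, day^-1.
#' @param gradient_attenuation decay (m^-1) of the gradient-arm food
#'   profile; the homogeneous arm uses the same surface concentration
#'   everywhere.
#' @param opts environment magnitudes ([environment_options()]); only the
#'   food surface value and light level are used.
#' @param column a [sector_column()].
#' @param n_steps,burn_in simulation protocol.
#' @param seed integer seed.
#' @return Data frame with `arm`, `individual`, `age`, `growth`, for
#'   [estimate_perception_cost()].
#' @export
gen_paired_growth <- function(age = c("juvenile", "adult"),
                              n_individuals = 24L,
                              true_params = growth_params(),
                              target_deficit = NULL,
                              window = 10L,
                              noise_sd = 0.01,
                              gradient_attenuation = 1.5,
                              opts = environment_options(),
                              column = sector_column(),
                              n_steps = 200L, burn_in = 100L, seed = 1L) {
  age <- match.arg(age)
  vr <- default_vital_rates(age, "II", opts = opts)
  vr$growth <- true_params
  grad_opts <- opts
  grad_opts$food_attenuation <- gradient_attenuation
  env <- treatment_environment("food", column, grad_opts)
  cfg <- simulation_config(n_individuals, age = age, treatment = "food",
                           response_type = "II", n_steps = n_steps,
                           burn_in = burn_in, n_replicates = 1L,
                           seed = derive_seed(seed, 1L))
  res <- run_simulation(cfg, env = env, params = vr, keep_trajectory = TRUE)
  window <- min(as.integer(window), n_steps - burn_in)
  post <- (n_steps - window + 1L):n_steps
  asec <- res$agent_sectors[post, , drop = FALSE]
  occ <- res$occupancy[post, , drop = FALSE]
  vol <- column$sector_volume
  # realised growth of each individual: average over its post-burn-in path
  grad_gr <- vapply(seq_len(n_individuals), function(a) {
    s <- asec[, a]
    dens <- occ[cbind(seq_along(s), s)] / vol
    mean(growth_rate(env$food[s], dens, env$light[s], age,
                     env$kairomone, true_params))
  }, numeric(1))
  d0 <- n_individuals / column$total_volume
  hom_mu <- growth_rate(opts$food_surface, d0, opts$light_uniform, age,
                        FALSE, true_params)
  if (!is.null(target_deficit)) {
    target_mean <- hom_mu * (1 - target_deficit / 100)
    grad_gr <- grad_gr * target_mean / mean(grad_gr)
  }
  set.seed(derive_seed(seed, 2L))
  data.frame(
    arm = rep(c("homogeneous", "gradient"), each = n_individuals),
    individual = rep(seq_len(n_individuals), 2),
    age = age,
    growth = c(rep(hom_mu, n_individuals), grad_gr) +
      if (noise_sd > 0) rnorm(2 * n_individuals, 0, noise_sd) else 0)
}
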