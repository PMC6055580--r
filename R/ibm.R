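#' Simulation configuration
#'
#' The protocol of a single simulated experiment: all individuals start in
#' the fifth sector from the top, a run lasts 200 asynchronous time steps
#' of which only the last 100 enter the summaries (burn-in discards the
#' approach to equilibrium), and each configuration is repeated 100 times.
#'
#' @param n_individuals number of agents (1--360 for the default 6-L column).
#' @param age `"juvenile"` or `"adult"`.
#' @param treatment preset name, see [treatment_environment()].
#' @param response_type `"II"` or `"III"` functional-response scenario.
#' @param n_steps total sweeps per replicate.
#' @param burn_in sweeps discarded before averaging (`burn_in < n_steps`).
#' @param n_replicates replicate simulations per configuration.
#' @param seed root seed; per-replicate streams are derived from it.
#' @param initial_sector 1-based release sector (default 5, fifth from top).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals, age = c("juvenile", "adult"),
                              treatment = c("none", "food", "risk", "both"),
                              response_type = c("II", "III"),
                              n_steps = 200L, burn_in = 100L,
                              n_replicates = 100L, seed = 1L,
                              initial_sector = 5L) {
  age <- match.arg(age)
  treatment <- match.arg(treatment)
  response_type <- match.arg(response_type)
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L)
    stop("'n_individuals' must be at least 1")
  n_steps <- as.integer(n_steps); burn_in <- as.integer(burn_in)
  if (burn_in >= n_steps) stop("'burn_in' must be smaller than 'n_steps'")
  if (burn_in < 0L) stop("'burn_in' must be non-negative")
  if (n_replicates < 1L) stop("'n_replicates' must be at least 1")
  structure(list(n_individuals = n_individuals, age = age,
                 treatment = treatment, response_type = response_type,
                 n_steps = n_steps, burn_in = burn_in,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 initial_sector = as.integer(initial_sector)),
            class = "simulation_config")
}

#' Derive a replicate seed from a root seed
#'
#' Deterministic stream derivation: `(seed + r * 1000003) mod (2^31 - 1)`.
#'
#' @param seed root seed (integer).
#' @param r replicate index (1-based).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, r) {
  as.integer((as.double(seed) %% 2147483647 + as.double(r) * 1000003) %%
               2147483647)
}

# flat parameter list consumed by the compiled kernel
ibm_par_list <- function(vr, env) {
  g <- vr$growth; r <- vr$rd; f <- vr$fr; m <- vr$mortality
  p <- vr$perception
  list(g0 = g$g0, a1 = g$a1, a2 = g$a2, b = g$b, c = g$c, u = g$u,
       kappa = g$kappa, r0 = r$r0, k = r$k, l = r$l,
       handling = f$handling, gamma = f$gamma, n = f$n,
       longevity = m$longevity, predator_density = m$predator_density,
       swim_speed = m$swim_speed, ae_food = p$ae_food, ae_light = p$ae_light,
       adult = vr$age == "adult", kairomone = env$kairomone,
       sector_volume = env$column$sector_volume)
}

resolve_env <- function(config, env) {
  if (is.null(env)) treatment_environment(config$treatment) else env
}

resolve_params <- function(config, params) {
  if (is.null(params))
    default_vital_rates(config$age, config$response_type)
  else params
}

#' Run a single replicate of the column simulation
#'
#' Seeds the RNG with `config$seed`, releases all agents in the initial
#' sector and performs `n_steps` asynchronous sweeps. The mean distribution
#' is the per-sector occupancy fraction averaged over the post-burn-in
#' steps; mean depth is its midpoint-weighted average.
#'
#' @param config a [simulation_config()].
#' @param env optional `environment_profile`; defaults to the config's
#'   treatment preset.
#' @param params optional [vital_rates()] bundle; defaults to
#'   [default_vital_rates()] for the config's age and response type.
#' @param keep_trajectory keep the full occupancy (and agent) trajectory.
#' @return An object of class `occupancy_result` with `mean_distribution`
#'   (fractions per sector), `per_replicate_mean_depth`, `grand_mean_depth`,
#'   `final_sectors` (1-based agent positions at the last step) and, when
#'   requested, `occupancy` (steps x sectors counts) and `agent_sectors`.
#' @export
run_simulation <- function(config, env = NULL, params = NULL,
                           keep_trajectory = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  env <- resolve_env(config, env)
  params <- resolve_params(config, params)
  S <- env$column$n_sectors
  if (config$initial_sector < 1L || config$initial_sector > S)
    stop("'initial_sector' outside the column")
  set.seed(config$seed)
  bf <- band_factor(env$band_weights, params$rd)
  raw <- ibm_run_cpp(rep(config$initial_sector - 1L, config$n_individuals),
                     config$n_steps, env$food, env$light, bf,
                     ibm_par_list(params, env), keep_trajectory)
  post <- raw$occupancy[(config$burn_in + 1L):config$n_steps, , drop = FALSE]
  dist <- colMeans(post) / config$n_individuals
  md <- sum(dist * env$column$midpoints)
  out <- list(mean_distribution = dist,
              per_replicate_mean_depth = md,
              grand_mean_depth = md,
              final_sectors = as.integer(raw$sectors) + 1L,
              column = env$column, config = config)
  if (keep_trajectory) {
    out$occupancy <- raw$occupancy
    out$agent_sectors <- raw$agent_sectors + 1L
  }
  structure(out, class = "occupancy_result")
}

#' Run the full replicate set of a configuration
#'
#' Replicate `r` is seeded with `derive_seed(config$seed, r)`; the grand
#' mean distribution averages the replicate mean distributions and the
#' grand mean depth equals the mean of the per-replicate mean depths.
#'
#' @inheritParams run_simulation
#' @return An `occupancy_result`; `final_sectors` is a list with one
#'   integer vector per replicate.
#' @export
run_replicates <- function(config, env = NULL, params = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  env <- resolve_env(config, env)
  params <- resolve_params(config, params)
  reps <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, r)
    reps[[r]] <- run_simulation(cfg_r, env = env, params = params)
  }
  dists <- vapply(reps, `[[`, numeric(env$column$n_sectors),
                  "mean_distribution")
  md <- vapply(reps, `[[`, numeric(1), "per_replicate_mean_depth")
  structure(list(mean_distribution = rowMeans(dists),
                 per_replicate_mean_depth = md,
                 grand_mean_depth = mean(md),
                 final_sectors = lapply(reps, `[[`, "final_sectors"),
                 column = env$column, config = config),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  nr <- length(x$per_replicate_mean_depth)
  cat(sprintf("<occupancy_result> %d individuals, treatment '%s', %s, type %s\n",
              x$config$n_individuals, x$config$treatment, x$config$age,
              x$config$response_type))
  cat(sprintf("  grand mean depth %.3f m over %d replicate%s\n",
              x$grand_mean_depth, nr, if (nr == 1) "" else "s"))
  cat("  mean distribution:", paste(sprintf("%.3f", x$mean_distribution),
                                    collapse = " "), "\n")
  invisible(x)
}

#' One asynchronous sweep over all agents
#'
#' Advances a simulation state by a single time step using the current RNG
#' state (seed beforehand for reproducibility). A fresh random permutation
#' of agents is swept; each agent moves to the strict perceived-fitness
#' maximiser among stay/up/down, ties broken uniformly at random, and
#' occupancy updates immediately within the sweep.
#'
#' @param state list with `agent_sectors` (1-based) and optionally `step`.
#' @param env an `environment_profile`.
#' @param params a [vital_rates()] bundle.
#' @return The updated state (`agent_sectors`, `occupancy`, `step`).
#' @export
ibm_step <- function(state, env, params) {
  sec <- as.integer(state$agent_sectors)
  S <- env$column$n_sectors
  if (any(sec < 1L) || any(sec > S)) stop("agent sectors outside the column")
  bf <- band_factor(env$band_weights, params$rd)
  raw <- ibm_run_cpp(sec - 1L, 1L, env$food, env$light, bf,
                     ibm_par_list(params, env), FALSE)
  newsec <- as.integer(raw$sectors) + 1L
  list(agent_sectors = newsec,
       occupancy = tabulate(newsec, nbins = S),
       step = (if (is.null(state$step)) 0L else state$step) + 1L)
}

#' Perceived fitness of a candidate sector
#'
#' Evaluates what an agent in `current` believes a move to `candidate`
#' (equal or adjacent) is worth. Food and light of the candidate are
#' replaced by the current sector's values whenever their relative
#' difference is below the detection thresholds; the candidate's density
#' counts the mover itself (`(occupancy + 1) / sector_volume`) while the
#' current sector's density is `occupancy / sector_volume`.
#'
#' @param current 1-based current sector of the agent.
#' @param candidate 1-based candidate sector (`|candidate - current| <= 1`).
#' @param occupancy integer counts per sector (including the focal agent).
#' @param env an `environment_profile`.
#' @param params a [vital_rates()] bundle.
#' @return A fitness score (see [fitness()]).
#' @export
perceived_fitness <- function(current, candidate, occupancy, env, params) {
  S <- env$column$n_sectors
  if (current < 1 || current > S || candidate < 1 || candidate > S)
    stop("sector index outside the column")
  if (abs(candidate - current) > 1)
    stop("invalid move: candidate sector is not adjacent")
  vol <- env$column$sector_volume
  ae_f <- params$perception$ae_food
  ae_i <- params$perception$ae_light
  if (candidate == current) {
    food <- env$food[current]; light <- env$light[current]
    dens <- occupancy[current] / vol
  } else {
    food <- perceive_value(env$food[current], env$food[candidate], ae_f)
    light <- perceive_value(env$light[current], env$light[candidate], ae_i)
    dens <- (occupancy[candidate] + 1) / vol
  }
  sector_fitness_r(food, light,
                   band_factor(env$band_weights[candidate, ], params$rd),
                   dens, params, env$kairomone)
}

# R mirrors of the compiled kernel's perception and fitness rules
perceive_value <- function(cur, cand, ae) {
  if (ae <= 0) return(cand)
  rel <- if (cur > 0) abs(cand - cur) / cur else if (cand == cur) 0 else Inf
  if (rel < ae) cur else cand
}

sector_fitness_r <- function(food, light, bandfac, dens, vr, kairomone) {
  gr <- growth_rate(food, dens, light, vr$age, kairomone, vr$growth)
  base <- vr$rd$r0 + vr$rd$k * log10(1 + light) +
    if (vr$age == "adult") vr$rd$l else 0
  rd <- max(0, base * bandfac)
  a <- attack_rate(rd, vr$mortality$swim_speed)
  frx <- vr$fr; frx$attack <- max(a, .Machine$double.xmin)
  fm <- if (dens <= 0) {
    if (frx$gamma > 0 || frx$n > 1) 0
    else vr$mortality$predator_density * a
  } else {
    vr$mortality$predator_density * consumption_rate(dens, frx) / dens
  }
  fitness(gr, fm + 1 / vr$mortality$longevity, vr$mortality$longevity)
}

#' Maximum unilateral perceivable fitness gain
#'
#' IFD/Nash diagnostic: the maximum over agents of (best adjacent perceived
#' fitness minus current perceived fitness). A value `<= 0` means no agent
#' believes it could do better by moving, i.e. the configuration is a
#' perceived ideal free distribution.
#'
#' @param state an `occupancy_result` (its final replicate state is used),
#'   or a list with `agent_sectors`, or a plain integer vector of 1-based
#'   agent sectors.
#' @param env an `environment_profile`.
#' @param params a [vital_rates()] bundle.
#' @return The maximum gain (dimensionless fitness units).
#' @export
equilibrium_check <- function(state, env, params) {
  sec <- if (inherits(state, "occupancy_result")) {
    fs <- state$final_sectors
    if (is.list(fs)) fs[[length(fs)]] else fs
  } else if (is.list(state)) state$agent_sectors else state
  sec <- as.integer(sec)
  S <- env$column$n_sectors
  occ <- tabulate(sec, nbins = S)
  gains <- vapply(sec, function(i) {
    stay <- perceived_fitness(i, i, occ, env, params)
    best <- -Inf
    for (j in c(i - 1L, i + 1L)) {
      if (j < 1L || j > S) next
      best <- max(best, perceived_fitness(i, j, occ, env, params))
    }
    best - stay
  }, numeric(1))
  max(gains)
}

#' Export occupancy trajectories and replicate summaries as CSV
#'
#' `export_occupancy_csv()` writes long-format counts (`replicate`, `step`,
#' `sector`, `count`) for a result kept with `keep_trajectory = TRUE`;
#' `export_mean_depth_csv()` writes one row per replicate (`replicate`,
#' `mean_depth_m`).
#'
#' @param result an `occupancy_result`.
#' @param file output path.
#' @param replicate replicate label for the trajectory export.
#' @export
export_occupancy_csv <- function(result, file, replicate = 1L) {
  if (is.null(result$occupancy))
    stop("no trajectory stored; rerun with keep_trajectory = TRUE")
  occ <- result$occupancy
  df <- data.frame(replicate = replicate,
                   step = rep(seq_len(nrow(occ)), times = ncol(occ)),
                   sector = rep(seq_len(ncol(occ)), each = nrow(occ)),
                   count = as.vector(occ))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname export_occupancy_csv
#' @export
export_mean_depth_csv <- function(result, file) {
  df <- data.frame(replicate = seq_along(result$per_replicate_mean_depth),
                   mean_depth_m = result$per_replicate_mean_depth)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
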