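#' Default pipeline configuration
#'
#' The fully resolved configuration consumed by [run_pipeline()]: column
#' geometry, gradient magnitudes, per-age vital-rate parameters, the
#' simulation protocol grid, generator settings and analysis settings.
#' A user configuration file only needs a `seed`; everything else defaults
#' to the values below. The default simulation grid is deliberately
#' reduced (20 replicates, six densities) so the demonstration pipeline
#' runs quickly; raise `simulation$n_replicates` to 100 for full-protocol
#' runs.
#'
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = NULL,
    column = list(n_sectors = 10L, total_depth = 1.0, sector_volume = 0.6),
    environment = list(food_uniform = 0.8, food_surface = 1.6,
                       food_attenuation = 2.3, light_uniform = 1.0,
                       light_surface = 100, light_attenuation = 4.6,
                       band_weights = c(1, 1, 1) / 3),
    vital_rates = list(
      juvenile = list(ae_food = 0.19, ae_light = 0.10),
      adult = list(ae_food = 0.08, ae_light = 0.10),
      growth = list(g0 = 0.05, a1 = 0.5, a2 = 0.4, b = 0.003,
                    c = 0.005, u = 0.08, kappa = 0.02),
      rd = list(r0 = 0.5, k = 4, l = 0.5, alpha = 0.4, phi = 1),
      fr = list(handling = 3e-9, gamma_juvenile = 3.4158,
                gamma_orders_adult = 2, n = 2),
      mortality = list(longevity = 50, swim_speed = 5.62,
                       predator_density = NULL)),
    simulation = list(n_steps = 200L, burn_in = 100L, n_replicates = 20L,
                      initial_sector = 5L,
                      densities = c(0.166, 1, 5, 15, 35, 60),
                      treatments = c("none", "food", "risk", "both"),
                      ages = c("juvenile", "adult")),
    generators = list(
      consumption = list(attack = 1.2, handling = 0.002, gamma = 3.4158,
                         n = 2, n_rep = 2L, noise_sd = 15),
      growth = list(n_rep = 2L, noise_sd = 0.02),
      rd = list(n_rep = 4L, noise_sd = 0.3),
      records = list(n_per_cell = 9L, epsilon = 0.05),
      paired_growth = list(n_individuals = 24L, noise_sd = 0.01)),
    analysis = list(alpha = 0.05)),
    class = "pipeline_config")
}

# recursive merge with unknown-key detection; paths are reported in errors
merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: '", here, "'")
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key '", here, "' must be a mapping")
      base[[key]] <- merge_config(base[[key]], user[[key]], here)
    } else {
      base[key] <- list(user[[key]])  # keeps explicit NULLs in place
    }
  }
  base
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed))
    stop("configuration error: 'seed' is required")
  if (cfg$column$sector_volume <= 0)
    stop("configuration error: 'column$sector_volume' must be positive")
  if (cfg$column$total_depth <= 0)
    stop("configuration error: 'column$total_depth' must be positive")
  if (cfg$column$n_sectors < 2)
    stop("configuration error: 'column$n_sectors' must be at least 2")
  if (cfg$simulation$burn_in >= cfg$simulation$n_steps)
    stop("configuration error: 'simulation$burn_in' must be below ",
         "'simulation$n_steps'")
  bad <- setdiff(cfg$simulation$treatments,
                 c("none", "food", "risk", "both"))
  if (length(bad))
    stop("configuration error: unknown treatment preset(s): ",
         paste(bad, collapse = ", "))
  if (any(cfg$simulation$densities <= 0))
    stop("configuration error: 'simulation$densities' must be positive")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, deep-merges it into [default_config()] (unknown keys
#' are an error naming the offending path), validates the result and
#' returns the fully resolved configuration. `seed` is the only required
#' key.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(merge_config(default_config(), user))
}

#' Save a resolved configuration as YAML
#'
#' @param config a `pipeline_config`.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  writeLines(yaml::as.yaml(cfg, precision = 15), path)
  invisible(path)
}

# materialise helper objects from the configuration
config_column <- function(cfg) {
  sector_column(cfg$column$n_sectors, cfg$column$total_depth,
                cfg$column$sector_volume)
}

config_env_opts <- function(cfg) {
  e <- cfg$environment
  environment_options(food_uniform = e$food_uniform,
                      food_surface = e$food_surface,
                      food_attenuation = e$food_attenuation,
                      light_uniform = e$light_uniform,
                      light_surface = e$light_surface,
                      light_attenuation = e$light_attenuation,
                      band_weights = e$band_weights)
}

config_vital_rates <- function(cfg, age, response_type) {
  v <- cfg$vital_rates
  g <- do.call(growth_params, v$growth)
  r <- do.call(rd_params, v$rd)
  gamma <- if (response_type == "II") 0
           else if (age == "juvenile") v$fr$gamma_juvenile
           else scale_gamma_for_age(v$fr$gamma_juvenile,
                                    v$fr$gamma_orders_adult)
  fr <- fr_params(attack = 1, handling = v$fr$handling, gamma = gamma,
                  n = if (response_type == "II") 1 else v$fr$n)
  perc <- perception_params(ae_food = v[[age]]$ae_food,
                            ae_light = v[[age]]$ae_light)
  mort <- mortality_params(longevity = v$mortality$longevity,
                           swim_speed = v$mortality$swim_speed)
  vr <- vital_rates(age = age, growth = g, rd = r, fr = fr,
                    mortality = mort, perception = perc)
  ref <- vr; ref$age <- "juvenile"  # shared exposure, juvenile-calibrated
  vr$mortality$predator_density <-
    if (is.null(v$mortality$predator_density))
      calibrate_predator_density(ref, opts = config_env_opts(cfg))
    else v$mortality$predator_density
  vr
}
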