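#' Discrete vertical water column
#'
#' Builds the one-dimensional stack of sectors that discretises the
#' experimental column. Sector 1 is the top sector; sector midpoint depths
#' are `(i - 0.5) * total_depth / n_sectors`.
#'
#' The defaults (10 sectors, 1 m, 0.6 L per sector, i.e. 6 L total) mirror
#' the twin-column apparatus: counts of 1--360 individuals then correspond
#' to overall densities of about 0.166--60 individuals per litre.
#'
#' @param n_sectors number of stacked sectors (>= 2).
#' @param total_depth column height in metres.
#' @param sector_volume volume of one sector in litres.
#' @return An object of class `sector_column` with fields `n_sectors`,
#'   `total_depth`, `sector_volume`, `midpoints` (metres, top first) and
#'   `total_volume` (litres).
#' @examples
#' col <- sector_column()
#' col$midpoints   # 0.05, 0.15, ..., 0.95
#' @export
sector_column <- function(n_sectors = 10L, total_depth = 1.0,
                          sector_volume = 0.6) {
  n_sectors <- as.integer(n_sectors)
  if (is.na(n_sectors) || n_sectors < 2L)
    stop("invalid geometry: 'n_sectors' must be an integer >= 2")
  if (!is.finite(total_depth) || total_depth <= 0)
    stop("invalid geometry: 'total_depth' must be positive")
  if (!is.finite(sector_volume) || sector_volume <= 0)
    stop("invalid geometry: 'sector_volume' must be positive")
  h <- total_depth / n_sectors
  structure(
    list(n_sectors = n_sectors,
         total_depth = total_depth,
         sector_volume = sector_volume,
         total_volume = sector_volume * n_sectors,
         midpoints = (seq_len(n_sectors) - 0.5) * h),
    class = "sector_column")
}

#' @export
print.sector_column <- function(x, ...) {
  cat(sprintf("<sector_column> %d sectors, %.3g m deep, %.3g L/sector (%.3g L total)\n",
              x$n_sectors, x$total_depth, x$sector_volume, x$total_volume))
  invisible(x)
}

#' Per-sector gradient profile
#'
#' Evaluates a gradient shape at the sector midpoints. `"exponential-top"`
#' gives `surface_value * exp(-attenuation * depth)` (maximum at the top, the
#' physically expected shape for light attenuation); `"exponential-bottom"`
#' mirrors it; `"uniform"` repeats `surface_value`.
#'
#' @param kind profile shape.
#' @param surface_value value at (or extrapolated to) the surface; >= 0.
#' @param attenuation exponential decay rate per metre; >= 0.
#' @param column a [sector_column()].
#' @return Numeric vector of per-sector values, top sector first.
#' @export
make_profile <- function(kind = c("uniform", "exponential-top",
                                  "exponential-bottom"),
                         surface_value, attenuation = 0, column) {
  kind <- match.arg(kind)
  if (!is.finite(surface_value) || surface_value < 0)
    stop("invalid profile: 'surface_value' must be non-negative")
  if (!is.finite(attenuation) || attenuation < 0)
    stop("invalid profile: 'attenuation' must be non-negative")
  stopifnot(inherits(column, "sector_column"))
  top <- surface_value * exp(-attenuation * column$midpoints)
  switch(kind,
         "uniform" = rep(surface_value, column$n_sectors),
         "exponential-top" = top,
         "exponential-bottom" = rev(top))
}

#' Assemble a column environment
#'
#' Bundles the per-sector food and light profiles, the spectral band
#' weights and the kairomone flag into a validated environment object.
#' Kairomones are treated as evenly mixed, so the flag is a single boolean
#' for the whole column.
#'
#' @param column a [sector_column()].
#' @param food per-sector food concentration, mg C L^-1.
#' @param light per-sector light intensity, relative units.
#' @param band_weights either a length-3 vector `c(red, green, blue)`
#'   applied to every sector, or an `n_sectors` x 3 matrix; each row must
#'   sum to 1 (tolerance 1e-9).
#' @param kairomone logical; predator chemical cue present (uniform).
#' @return An object of class `environment_profile`.
#' @export
build_environment <- function(column, food, light,
                              band_weights = c(1, 1, 1) / 3,
                              kairomone = FALSE) {
  stopifnot(inherits(column, "sector_column"))
  S <- column$n_sectors
  if (length(food) != S || length(light) != S)
    stop("profile length does not match the column (", S, " sectors)")
  if (any(!is.finite(food)) || any(food < 0))
    stop("food profile must be finite and non-negative")
  if (any(!is.finite(light)) || any(light < 0))
    stop("light profile must be finite and non-negative")
  if (is.null(dim(band_weights))) {
    if (length(band_weights) != 3L)
      stop("band_weights must have 3 components (red, green, blue)")
    band_weights <- matrix(band_weights, nrow = S, ncol = 3, byrow = TRUE)
  }
  band_weights <- as.matrix(band_weights)
  if (!all(dim(band_weights) == c(S, 3)))
    stop("band_weights must be a length-3 vector or an n_sectors x 3 matrix")
  if (any(band_weights < 0) || any(band_weights > 1))
    stop("band weights must lie in [0, 1]")
  if (any(abs(rowSums(band_weights) - 1) > 1e-9))
    stop("band weights must sum to 1 in every sector (tolerance 1e-9)")
  dimnames(band_weights) <- list(NULL, c("red", "green", "blue"))
  structure(
    list(column = column, food = as.numeric(food), light = as.numeric(light),
         band_weights = band_weights, kairomone = isTRUE(kairomone)),
    class = "environment_profile")
}

#' @export
print.environment_profile <- function(x, ...) {
  cat(sprintf("<environment_profile> %d sectors; food %.3g-%.3g mg C/L; light %.3g-%.3g; kairomone %s\n",
              x$column$n_sectors, min(x$food), max(x$food),
              min(x$light), max(x$light), x$kairomone))
  invisible(x)
}

#' Default gradient magnitudes for the four treatments
#'
#' The apparatus profiles are not tabulated anywhere, so these are
#' configurable lake-epilimnion-like placeholders: the uniform food level is
#' the incipient limiting concentration 0.8 mg C L^-1; the food gradient
#' peaks at twice that at the surface and decays at 2.3 m^-1 (adjacent
#' sectors then differ by 21--26%, resolvable by both age classes'
#' perception thresholds); light spans two orders of magnitude over the
#' 1-m column in the risk treatments and is uniformly dim otherwise.
#'
#' @param food_uniform uniform food concentration, mg C L^-1.
#' @param food_surface surface food concentration of the gradient.
#' @param food_attenuation food gradient decay, m^-1.
#' @param light_uniform uniform (dim) light level, relative units.
#' @param light_surface surface light of the risk gradient.
#' @param light_attenuation light decay, m^-1.
#' @param band_weights spectral weights `c(red, green, blue)`.
#' @return A list of options consumed by [treatment_environment()].
#' @export
environment_options <- function(food_uniform = 0.8,
                                food_surface = 1.6,
                                food_attenuation = 2.3,
                                light_uniform = 1.0,
                                light_surface = 100,
                                light_attenuation = 4.6,
                                band_weights = c(1, 1, 1) / 3) {
  list(food_uniform = food_uniform, food_surface = food_surface,
       food_attenuation = food_attenuation, light_uniform = light_uniform,
       light_surface = light_surface, light_attenuation = light_attenuation,
       band_weights = band_weights)
}

#' Canonical treatment environments
#'
#' Builds one of the four treatments crossed in the verification
#' experiments: `"none"` (no gradients), `"food"` (algal gradient alone),
#' `"risk"` (light gradient plus kairomone), `"both"`.
#'
#' @param treatment preset name.
#' @param column a [sector_column()].
#' @param opts gradient magnitudes, see [environment_options()].
#' @return An `environment_profile`.
#' @export
treatment_environment <- function(treatment = c("none", "food", "risk", "both"),
                                  column = sector_column(),
                                  opts = environment_options()) {
  treatment <- match.arg(treatment)
  food_grad <- treatment %in% c("food", "both")
  risk_grad <- treatment %in% c("risk", "both")
  food <- if (food_grad)
    make_profile("exponential-top", opts$food_surface, opts$food_attenuation,
                 column)
  else make_profile("uniform", opts$food_uniform, column = column)
  light <- if (risk_grad)
    make_profile("exponential-top", opts$light_surface, opts$light_attenuation,
                 column)
  else make_profile("uniform", opts$light_uniform, column = column)
  build_environment(column, food, light, band_weights = opts$band_weights,
                    kairomone = risk_grad)
}

#' Write / read an environment profile as CSV
#'
#' Columns: `sector_index`, `depth_m`, `food_mgC_L`, `light`, `w_red`,
#' `w_green`, `w_blue`. The kairomone flag is not part of the tabular
#' schema; supply it when reading.
#'
#' @param env an `environment_profile`.
#' @param file path to the CSV file.
#' @export
write_profile_csv <- function(env, file) {
  stopifnot(inherits(env, "environment_profile"))
  df <- data.frame(sector_index = seq_len(env$column$n_sectors),
                   depth_m = env$column$midpoints,
                   food_mgC_L = env$food,
                   light = env$light,
                   w_red = env$band_weights[, "red"],
                   w_green = env$band_weights[, "green"],
                   w_blue = env$band_weights[, "blue"])
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_profile_csv
#' @param sector_volume sector volume (litres) for the rebuilt column.
#' @param kairomone kairomone flag for the rebuilt environment.
#' @export
read_profile_csv <- function(file, sector_volume = 0.6, kairomone = FALSE) {
  df <- read.csv(file)
  need <- c("sector_index", "depth_m", "food_mgC_L", "light",
            "w_red", "w_green", "w_blue")
  if (!all(need %in% names(df)))
    stop("profile CSV must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$sector_index), ]
  h <- df$depth_m[1] * 2
  col <- sector_column(nrow(df), total_depth = h * nrow(df),
                       sector_volume = sector_volume)
  build_environment(col, df$food_mgC_L, df$light,
                    band_weights = as.matrix(df[, c("w_red", "w_green", "w_blue")]),
                    kairomone = kairomone)
}
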