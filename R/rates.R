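#' Individual growth rate
#'
#' Monod-saturating response to food, linear interference cost of density,
#' log-light predation-information cost (steeper for adults via the
#' age-by-light interaction `u`) and a constant kairomone cost:
#' `g0 + a1*F/(a2+F) - b*D - (c + u*[adult])*log10(1+I) - kappa*[kairomone]`.
#' Vectorised over `food`, `density` and `light`.
#'
#' @param food food concentration, mg C L^-1 (>= 0).
#' @param density population density, ind L^-1 (>= 0).
#' @param light light intensity, relative units (>= 0).
#' @param age `"juvenile"` or `"adult"`.
#' @param kairomone logical, predator chemical cue present.
#' @param p a [growth_params()].
#' @return Growth rate, day^-1.
#' @export
growth_rate <- function(food, density = 0, light = 0,
                        age = c("juvenile", "adult"), kairomone = FALSE,
                        p = growth_params()) {
  age <- match.arg(age)
  stopifnot(inherits(p, "growth_params"))
  if (any(food < 0) || any(density < 0) || any(light < 0))
    stop("food, density and light must be non-negative")
  lightcost <- (p$c + if (age == "adult") p$u else 0) * log10(1 + light)
  p$g0 + p$a1 * food / (p$a2 + food) - p$b * density - lightcost -
    if (isTRUE(kairomone)) p$kappa else 0
}

#' Visual reaction distance of the fish
#'
#' `max(0, (r0 + k*log10(1+I) + l*[adult]) * (w_red*alpha + w_green +
#' w_blue*phi))`; non-decreasing in light, larger for adult (larger) prey,
#' reduced in red light.
#'
#' @param light light intensity, relative units (>= 0).
#' @param bands spectral weights: a length-3 vector `c(red, green, blue)`
#'   summing to 1, or a matrix with one row per light value.
#' @param age `"juvenile"` or `"adult"` (prey age class).
#' @param p an [rd_params()].
#' @return Reaction distance, cm.
#' @export
reaction_distance <- function(light, bands = c(1, 1, 1) / 3,
                              age = c("juvenile", "adult"),
                              p = rd_params()) {
  age <- match.arg(age)
  stopifnot(inherits(p, "rd_params"))
  if (any(light < 0)) stop("light must be non-negative")
  fac <- band_factor(bands, p)
  base <- p$r0 + p$k * log10(1 + light) + if (age == "adult") p$l else 0
  pmax(0, base * fac)
}

# spectral multiplier w_red*alpha + w_green + w_blue*phi
band_factor <- function(bands, p) {
  if (is.null(dim(bands))) {
    if (length(bands) != 3L) stop("band weights must have 3 components")
    sum(bands * c(p$alpha, 1, p$phi))
  } else {
    as.numeric(as.matrix(bands) %*% c(p$alpha, 1, p$phi))
  }
}

#' Attack coefficient from reaction distance and swimming speed
#'
#' Cylindrical search volume per day: `pi * rd^2 * v` in cm^3 s^-1,
#' converted to litres day^-1 (`* 86400 / 1000`). Links the measured
#' reaction distance and foraging swimming speed to the disc equation's
#' attack coefficient.
#'
#' @param rd reaction distance, cm (>= 0).
#' @param v swimming speed, cm s^-1 (>= 0).
#' @return Attack coefficient, L predator^-1 day^-1.
#' @export
attack_rate <- function(rd, v = 5.62) {
  if (any(rd < 0) || any(v < 0)) stop("'rd' and 'v' must be non-negative")
  pi * rd^2 * v * 86.4
}

#' Threshold-disc consumption rate
#'
#' With `M = max(N - gamma, 0)`, consumption is
#' `attack * M^n / (1 + attack * handling * M^n)`: zero at or below the
#' foraging-initiation threshold, exactly Holling's type II disc equation
#' when `gamma = 0` and `n = 1`, and saturating at `1 / handling`.
#'
#' @param N prey density, ind L^-1 (>= 0).
#' @param p an [fr_params()].
#' @return Consumption, prey predator^-1 day^-1. Vectorised over `N`.
#' @export
consumption_rate <- function(N, p = fr_params()) {
  stopifnot(inherits(p, "fr_params"))
  if (any(N < 0)) stop("prey density must be non-negative")
  M <- pmax(N - p$gamma, 0)
  Mn <- M^p$n
  p$attack * Mn / (1 + p$attack * p$handling * Mn)
}

#' Per-capita fish mortality
#'
#' `predator_density * consumption_rate(N) / N`. Strictly decreasing in `N`
#' for a type II response (safety in numbers); for type III it is zero up
#' to the threshold, peaks at an intermediate density and declines, giving
#' both a low- and a high-density refuge. At `N = 0` the `N -> 0+` limit is
#' used: `predator_density * attack` for type II, 0 for any threshold
#' response.
#'
#' @param N prey density, ind L^-1 (>= 0). Vectorised.
#' @param p an [fr_params()].
#' @param predator_density predators L^-1.
#' @return Mortality rate, day^-1.
#' @export
per_capita_fish_mortality <- function(N, p = fr_params(),
                                      predator_density = 1) {
  stopifnot(inherits(p, "fr_params"))
  if (any(N < 0)) stop("prey density must be non-negative")
  out <- numeric(length(N))
  pos <- N > 0
  out[pos] <- predator_density * consumption_rate(N[pos], p) / N[pos]
  if (any(!pos))
    out[!pos] <- if (p$gamma > 0 || p$n > 1) 0
                 else predator_density * p$attack
  out
}

#' Total per-capita mortality
#'
#' Fish-caused mortality plus constant background mortality `1/longevity`
#' (independent of light, density and age).
#'
#' @param fish_mort fish-caused mortality, day^-1 (>= 0).
#' @param p a [mortality_params()].
#' @return Total mortality, day^-1.
#' @export
total_mortality <- function(fish_mort, p = mortality_params()) {
  stopifnot(inherits(p, "mortality_params"))
  if (any(fish_mort < 0)) stop("fish mortality must be non-negative")
  fish_mort + 1 / p$longevity
}

#' Growth-to-mortality fitness score
#'
#' The Werner-Gilliam criterion: maximise growth rate over mortality rate.
#' For non-positive growth the ratio is misleading (a higher mortality
#' would "improve" it), so such states are ranked by growth alone, scaled
#' by longevity (`gr * longevity`), strictly below every positive-growth
#' state.
#'
#' @param gr growth rate, day^-1.
#' @param mort total mortality, day^-1 (> 0).
#' @param longevity days, used to scale the non-positive branch.
#' @return Dimensionless fitness score; higher is better. Vectorised.
#' @export
fitness <- function(gr, mort, longevity = 50) {
  if (any(mort <= 0)) stop("invalid rate: mortality must be positive")
  ifelse(gr > 0, gr / mort, gr * longevity)
}
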