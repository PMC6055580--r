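#' Growth-model parameters
#'
#' Coefficients of the per-sector growth rate
#' `g0 + a1 * F / (a2 + F) - b * D - (c + u * adult) * log10(1 + I) -
#' kappa * kairomone` (day^-1), with food `F` in mg C L^-1, density `D` in
#' ind L^-1 and light `I` in relative units. The saturating food term is a
#' Monod ("asymptote") function; density interference and the log-light
#' predation-information cost enter linearly.
#'
#' Defaults are field-plausible placeholders: half-saturation `a2` below the
#' incipient limiting level 0.8 mg C L^-1, an interference slope that costs
#' about 0.18 day^-1 at the top of the density range (60 ind L^-1), and an
#' adult-by-light interaction `u` that dominates the juvenile light cost `c`
#' (in the growth trials only food and the age-by-light interaction had
#' clear effects).
#'
#' @param g0 intercept, day^-1.
#' @param a1 asymptote scale, day^-1 (>= 0).
#' @param a2 half-saturation food concentration, mg C L^-1 (> 0).
#' @param b interference slope, day^-1 per (ind L^-1) (>= 0).
#' @param c juvenile light-cost slope, day^-1 per log10-light unit.
#' @param u additional adult light-cost slope (age-by-light interaction).
#' @param kappa kairomone growth cost, day^-1.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(g0 = 0.05, a1 = 0.5, a2 = 0.4, b = 0.003,
                          c = 0.005, u = 0.08, kappa = 0.02) {
  if (!is.finite(a2) || a2 <= 0) stop("'a2' must be positive")
  if (a1 < 0) stop("'a1' must be non-negative")
  if (b < 0) stop("'b' must be non-negative")
  structure(list(g0 = g0, a1 = a1, a2 = a2, b = b, c = c, u = u,
                 kappa = kappa), class = "growth_params")
}

#' Reaction-distance parameters
#'
#' The visual reaction distance of the fish (cm) is
#' `max(0, (r0 + k * log10(1 + I) + l * adult) * (w_red * alpha + w_green +
#' w_blue * phi))`. `alpha <= 1` encodes the shorter reaction distance in
#' red light relative to green; `phi` defaults to 1 because detection is
#' similar in the green and blue bands.
#'
#' @param r0 baseline distance, cm.
#' @param k slope per log10-light unit, cm.
#' @param l adult (large-prey) increment, cm.
#' @param alpha red-band multiplier, in (0, 1].
#' @param phi blue-vs-green multiplier (default 1).
#' @return An object of class `rd_params`.
#' @export
rd_params <- function(r0 = 0.5, k = 4, l = 0.5, alpha = 0.4, phi = 1) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]")
  if (phi < 0) stop("'phi' must be non-negative")
  structure(list(r0 = r0, k = k, l = l, alpha = alpha, phi = phi),
            class = "rd_params")
}

#' Functional-response parameters
#'
#' Threshold-disc consumption `attack * M^n / (1 + attack * handling * M^n)`
#' with `M = max(N - gamma, 0)`. The foraging-initiation threshold
#' `gamma = 0` together with `n = 1` recovers Holling's type II disc
#' equation; `gamma > 0` (or `n > 1`) gives a type III response with a
#' low-density prey refuge.
#'
#' @param attack attack coefficient, litres cleared predator^-1 day^-1 (> 0).
#' @param handling handling time, days per prey (>= 0).
#' @param gamma threshold prey density, ind L^-1 (>= 0).
#' @param n shape exponent (>= 1).
#' @return An object of class `fr_params`.
#' @seealso [classify_response()]
#' @export
fr_params <- function(attack = 1.2, handling = 0.002, gamma = 0, n = 1) {
  if (!is.finite(attack) || attack <= 0) stop("'attack' must be positive")
  if (handling < 0) stop("'handling' must be non-negative")
  if (gamma < 0) stop("'gamma' must be non-negative")
  if (n < 1) stop("'n' must be >= 1")
  structure(list(attack = attack, handling = handling, gamma = gamma, n = n),
            class = "fr_params")
}

#' Classify a functional response as type II or III
#'
#' Type II if and only if `gamma == 0` and `n == 1`; any positive threshold
#' or shape exponent above 1 makes the response type III.
#'
#' @param p an [fr_params()] object.
#' @return `"II"` or `"III"`.
#' @export
classify_response <- function(p) {
  stopifnot(inherits(p, "fr_params"))
  if (p$gamma == 0 && p$n == 1) "II" else "III"
}

#' Mortality parameters
#'
#' Background mortality is `1 / longevity` (0.02 day^-1 at the default
#' 50-day longevity) and is independent of light, density and age.
#' `predator_density` scales fish-caused mortality; it is a free exposure
#' parameter (risk was conveyed by light and kairomone cues, with no fish
#' physically present in the columns) and is usually set by
#' [calibrate_predator_density()].
#'
#' @param longevity days (> 0).
#' @param predator_density predators L^-1 (>= 0).
#' @param swim_speed foraging swimming speed of the fish, cm s^-1
#'   (measured mean 5.62).
#' @return An object of class `mortality_params`.
#' @export
mortality_params <- function(longevity = 50, predator_density = 0,
                             swim_speed = 5.62) {
  if (!is.finite(longevity) || longevity <= 0)
    stop("'longevity' must be positive")
  if (predator_density < 0) stop("'predator_density' must be non-negative")
  structure(list(longevity = longevity, predator_density = predator_density,
                 swim_speed = swim_speed), class = "mortality_params")
}

#' Perception thresholds
#'
#' Relative differences in food concentration and light intensity below
#' which an individual cannot distinguish an adjacent sector from its
#' current one. The food thresholds were derived from the growth-slowdown
#' experiments: 0.19 for juveniles and 0.08 for adults. The light
#' threshold default (0.10) is a literature-style placeholder.
#'
#' @param ae_food relative food-difference detection threshold (>= 0).
#' @param ae_light relative light-difference detection threshold (>= 0).
#' @return An object of class `perception_params`.
#' @export
perception_params <- function(ae_food = 0.19, ae_light = 0.10) {
  if (ae_food < 0 || ae_light < 0)
    stop("perception thresholds must be non-negative")
  structure(list(ae_food = ae_food, ae_light = ae_light),
            class = "perception_params")
}

#' Bundle of vital-rate parameters for one age class
#'
#' @param age `"juvenile"` or `"adult"`.
#' @param growth a [growth_params()].
#' @param rd an [rd_params()].
#' @param fr an [fr_params()].
#' @param mortality a [mortality_params()].
#' @param perception a [perception_params()].
#' @return An object of class `vital_rates`.
#' @export
vital_rates <- function(age = c("juvenile", "adult"),
                        growth = growth_params(), rd = rd_params(),
                        fr = fr_params(), mortality = mortality_params(),
                        perception = perception_params()) {
  age <- match.arg(age)
  stopifnot(inherits(growth, "growth_params"), inherits(rd, "rd_params"),
            inherits(fr, "fr_params"), inherits(mortality, "mortality_params"),
            inherits(perception, "perception_params"))
  structure(list(age = age, growth = growth, rd = rd, fr = fr,
                 mortality = mortality, perception = perception),
            class = "vital_rates")
}

#' @export
print.vital_rates <- function(x, ...) {
  cat(sprintf("<vital_rates> %s, type %s response (gamma=%.4g, n=%.3g), ae_F=%.3g\n",
              x$age, classify_response(x$fr), x$fr$gamma, x$fr$n,
              x$perception$ae_food))
  invisible(x)
}

#' Default vital rates for an age class and response-type scenario
#'
#' Encodes the study conditions: the type III threshold is the fitted
#' juvenile value `gamma = 3.4158` ind L^-1 with shape `n = 2`; the adult
#' threshold is that value reduced by two orders of magnitude (0.0342, see
#' [scale_gamma_for_age()]); type II sets `gamma = 0`, `n = 1`. Food
#' perception thresholds are 0.19 (juvenile) and 0.08 (adult). The in-column
#' handling time is short (3e-9 d) so that the light-driven attack gradient
#' dominates adjacent-sector differences in per-capita risk while its
#' density dependence (risk dilution under type II) still expresses across
#' the 1--360 individual range; `predator_density`, unless supplied, is
#' calibrated once against the juvenile reference bundle so that type II
#' fish mortality equals background mortality at mid-column light of the
#' risk treatment and a reference density of 10 ind L^-1.
#'
#' @param age `"juvenile"` or `"adult"`.
#' @param response_type `"II"` or `"III"`.
#' @param predator_density optional override of the calibrated exposure.
#' @param opts environment magnitudes used for the calibration.
#' @return A `vital_rates` bundle.
#' @export
default_vital_rates <- function(age = c("juvenile", "adult"),
                                response_type = c("II", "III"),
                                predator_density = NULL,
                                opts = environment_options()) {
  age <- match.arg(age)
  response_type <- match.arg(response_type)
  gamma_juv <- 3.4158
  fr <- if (response_type == "II")
    fr_params(attack = 1, handling = 3e-9, gamma = 0, n = 1)
  else
    fr_params(attack = 1, handling = 3e-9,
              gamma = if (age == "juvenile") gamma_juv
                      else scale_gamma_for_age(gamma_juv, 2),
              n = 2)
  perc <- perception_params(ae_food = if (age == "juvenile") 0.19 else 0.08,
                            ae_light = 0.10)
  mort <- mortality_params()
  vr <- vital_rates(age = age, growth = growth_params(), rd = rd_params(),
                    fr = fr, mortality = mort, perception = perc)
  # one shared exposure level: calibrated against the juvenile reference
  # prey so the adult's larger reaction distance raises (not cancels) its
  # risk relative to juveniles
  ref <- vr; ref$age <- "juvenile"
  vr$mortality$predator_density <-
    if (is.null(predator_density))
      calibrate_predator_density(ref, opts = opts)
    else predator_density
  vr
}

#' Calibrate the predator-exposure scaling
#'
#' Returns the predator density (predators L^-1) at which type II
#' fish-caused mortality equals background mortality `1 / longevity` at the
#' light level of the central sector of the risk-treatment gradient and at
#' `reference_density`. This anchors the free exposure parameter to the
#' model's own mortality scale; it is deterministic given the options.
#'
#' @param vr a [vital_rates()] bundle (reaction-distance, handling and
#'   mortality parameters are used).
#' @param reference_density ind L^-1 at which to match.
#' @param opts environment magnitudes, see [environment_options()].
#' @return Predator density, predators L^-1.
#' @export
calibrate_predator_density <- function(vr, reference_density = 10,
                                       opts = environment_options()) {
  stopifnot(inherits(vr, "vital_rates"))
  col <- sector_column()
  mid <- col$midpoints[ceiling(col$n_sectors / 2)]
  light_mid <- opts$light_surface * exp(-opts$light_attenuation * mid)
  w <- opts$band_weights
  rd <- reaction_distance(light_mid, w, vr$age, vr$rd)
  a <- attack_rate(rd, vr$mortality$swim_speed)
  fr2 <- fr_params(attack = a, handling = vr$fr$handling, gamma = 0, n = 1)
  per_cap_per_pred <- consumption_rate(reference_density, fr2) /
    reference_density
  (1 / vr$mortality$longevity) / per_cap_per_pred
}
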