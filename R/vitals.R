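#' Draw the growth coefficient k for a new individual
#'
#' `k = exp(intercept + slope * l_inf + N(0, resid_sd))`, drawn once at
#' birth from the ln(k) on asymptotic-length regression.
#'
#' @param l_inf Asymptotic lengths (cm), positive.
#' @param reg An [lk_regression()].
#' @return Growth coefficients (per year), same length as `l_inf`.
#' @examples
#' lk <- lk_regression(resid_sd = 0)
#' draw_k(14.6, lk) # 0.534
#' @export
draw_k <- function(l_inf, reg = lk_regression()) {
  stopifnot(all(l_inf > 0), inherits(reg, "lk_regression"))
  mu <- reg$intercept + reg$slope * l_inf
  if (reg$resid_sd > 0) mu <- mu + rnorm(length(l_inf), 0, reg$resid_sd)
  exp(mu)
}

#' Advance length along the individual growth curve
#'
#' One year of growth compressed into the density-dependent growth time
#' `g` in [0, 1]: `length' = l_inf - (l_inf - length) * exp(-k * g)`.
#' Length never decreases and never exceeds `l_inf`.
#'
#' @param length Current lengths (cm).
#' @param l_inf Asymptotic lengths (cm).
#' @param k Growth coefficients (per year).
#' @param growth_time Fraction of the year available for growth, in [0, 1].
#' @return Updated lengths (cm).
#' @export
grow_length <- function(length, l_inf, k, growth_time) {
  stopifnot(growth_time >= 0, growth_time <= 1)
  l_inf - (l_inf - length) * exp(-k * growth_time)
}

#' Maturation check
#'
#' An individual matures when it is at least `min_age` years old and at
#' least `fraction` of its own asymptotic length — but never before its
#' second autumn.
#'
#' @param age Ages (years).
#' @param length Lengths (cm).
#' @param l_inf Asymptotic lengths (cm).
#' @param mature Current maturity flags.
#' @param fraction Maturation threshold as a fraction of `l_inf` (0.67).
#' @param min_age Minimum maturation age (2).
#' @return Logical vector: newly mature this year?
#' @export
check_maturation <- function(age, length, l_inf, mature,
                             fraction = 0.67, min_age = 2) {
  !mature & age >= min_age & length >= fraction * l_inf
}

#' Egg production of mature females
#'
#' `eggs = (intercept + slope * weight) * factor[age] * density_factor`,
#' with weight from the length-weight fit (length converted cm to mm).
#' The age-specific factor implements reproductive senescence; the density
#' factor implements crowding-reduced egg production.
#'
#' @param length_cm Female lengths (cm).
#' @param age Female ages (years); ages beyond the factor table use its
#'   last entry.
#' @param factors Fecundity-factor vector (see [gsi_to_factors()]).
#' @param lw A [length_weight_fit()].
#' @param fec A [fecundity_model()].
#' @param density_factor Shared density multiplier in [0, 1].
#' @param mature,alive Contract flags; all must be `TRUE`.
#' @return Expected egg numbers (non-negative reals).
#' @export
eggs_produced <- function(length_cm, age, factors, lw = length_weight_fit(),
                          fec = fecundity_model(), density_factor = 1,
                          mature = TRUE, alive = TRUE) {
  if (!all(mature)) stop("eggs_produced called on an immature female")
  if (!all(alive)) stop("eggs_produced called on a dead female")
  stopifnot(density_factor >= 0, density_factor <= 1)
  w <- predict_weight(10 * length_cm, lw)
  f <- factors[pmin(age, length(factors))]
  pmax(fecundity(w, fec) * f * density_factor, 0)
}

#' Instantaneous natural mortality rate for an adult
#'
#' Looks up the age-specific rate from the schedule (ages beyond 6 use the
#' 6+ rate) and adds the survival cost of maturation for individuals that
#' matured this year. Applies to ages 2--7 only; all earlier mortality is
#' folded into the single egg-to-age-2 survival probability.
#'
#' @param age Ages in years, all within 2..7.
#' @param sched A [mortality_schedule()].
#' @param newly_mature Logical: did the individual mature this year?
#' @return Instantaneous rates (per year).
#' @export
natural_mortality_rate <- function(age, sched = mortality_schedule(),
                                   newly_mature = FALSE) {
  stopifnot(inherits(sched, "mortality_schedule"))
  if (length(age) == 0) return(numeric(0))
  if (any(age < 2) || any(age > 7))
    stop("natural mortality applies to ages 2..7 only")
  rate <- unname(sched$rates[pmin(age, 6) - 1L])
  rate + sched$maturation_cost * newly_mature
}

#' Survival under an instantaneous mortality rate
#'
#' One Bernoulli draw per individual with survival probability
#' `exp(-rate)`.
#'
#' @param rate Instantaneous rates (per year), >= 0.
#' @return Logical vector: survived?
#' @export
survive_natural <- function(rate) {
  stopifnot(all(rate >= 0))
  runif(length(rate)) < exp(-rate)
}
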