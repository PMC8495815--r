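#' Regression of ln(k) on asymptotic length
#'
#' The von Bertalanffy intrinsic growth coefficient `k` of an individual is
#' tied to its asymptotic length through a linear regression on the log
#' scale, `ln(k) = intercept + slope * l_inf`, with normally distributed
#' residuals. Defaults are the empirical fit for the studied vendace
#' population: `ln(k) = 1.27 - 0.13 * L_inf` (L_inf in cm), residual SD 0.30.
#'
#' @param intercept Intercept on the ln(k) scale.
#' @param slope Slope per cm of asymptotic length (negative: larger-growing
#'   fish approach their asymptote more slowly).
#' @param resid_sd Residual standard deviation on the ln(k) scale.
#' @return An object of class `lk_regression`.
#' @seealso [fit_k_on_linf()], [draw_k()]
#' @export
lk_regression <- function(intercept = 1.27, slope = -0.13, resid_sd = 0.30) {
  stopifnot(is.numeric(intercept), is.numeric(slope), is.numeric(resid_sd),
            resid_sd >= 0)
  structure(list(intercept = intercept, slope = slope, resid_sd = resid_sd),
            class = "lk_regression")
}

#' Length-weight power law W = a * L^b
#'
#' Fresh weight in grams as a power function of total length in millimetres.
#' Defaults `a = 7e-6`, `b = 2.943` are the empirical vendace fit; with
#' these constants a 146 mm fish weighs 16.4 g.
#'
#' @param a Scaling coefficient (g per mm^b).
#' @param b Allometric exponent (dimensionless).
#' @return An object of class `length_weight_fit`.
#' @export
length_weight_fit <- function(a = 7e-6, b = 2.943) {
  stopifnot(a > 0, b >= 0)
  structure(list(a = a, b = b), class = "length_weight_fit")
}

#' Predict fresh weight from length
#'
#' @param length_mm Length in millimetres.
#' @param lw A [length_weight_fit()].
#' @return Weight in grams.
#' @export
predict_weight <- function(length_mm, lw = length_weight_fit()) {
  stopifnot(inherits(lw, "length_weight_fit"))
  lw$a * length_mm^lw$b
}

#' Linear fecundity model (eggs on body weight)
#'
#' Individual fecundity as a linear function of fresh weight in grams:
#' `eggs = intercept + slope * weight_g`. Defaults are the empirical fit
#' `39.06 + 118.47 * w`.
#'
#' @param intercept Eggs at zero weight (regression intercept).
#' @param slope Eggs per gram body weight.
#' @return An object of class `fecundity_model`.
#' @export
fecundity_model <- function(intercept = 39.06, slope = 118.47) {
  stopifnot(slope > 0)
  structure(list(intercept = intercept, slope = slope),
            class = "fecundity_model")
}

#' Age schedule of instantaneous natural mortality
#'
#' Two modes: `"constant"` applies the same rate (0.257) to all adult age
#' classes; `"senescent"` applies an age-increasing schedule
#' (0.2, 0.258, 0.314, 0.372, 0.428 for ages 2 to 6+). Ages beyond 6 use the
#' 6+ rate. A survival cost of maturation (default 0.058, the age-2 to age-3
#' increment of the senescent schedule) is added to the rate once, in the
#' year an individual matures, in every mode.
#'
#' @param mode `"constant"` or `"senescent"`.
#' @param rates Optional numeric vector of length 5 overriding the rates for
#'   ages 2,3,4,5,6+.
#' @param maturation_cost Additive instantaneous rate applied in the year of
#'   maturation.
#' @return An object of class `mortality_schedule`.
#' @export
mortality_schedule <- function(mode = c("constant", "senescent"),
                               rates = NULL, maturation_cost = 0.058) {
  mode <- match.arg(mode)
  if (is.null(rates)) {
    rates <- if (mode == "constant") rep(0.257, 5)
             else c(0.2, 0.258, 0.314, 0.372, 0.428)
  }
  stopifnot(length(rates) == 5, all(rates >= 0), maturation_cost >= 0)
  if (mode == "senescent" && any(diff(rates) < 0))
    stop("senescent mortality rates must be non-decreasing in age")
  structure(list(mode = mode, rates = setNames(rates, 2:6),
                 maturation_cost = maturation_cost),
            class = "mortality_schedule")
}

#' Genotype-to-phenotype map for asymptotic length
#'
#' Asymptotic length (cm) is expressed once at birth as
#' `linf_at_sum0 + linf_per_allele * allele_sum + N(0, env_sd)`, truncated
#' below at `floor_cm`. With the default map the purely genetic range is
#' 8--18 cm, centred at 13 cm for the founder allele frequency of 0.5; the
#' range reaches low enough that the pristine selection balance between
#' early maturation and size-dependent fecundity lies in the interior of
#' the genetic range, so additive variance persists through the burn-in.
#' The default environmental SD is calibrated so that midparent-offspring
#' heritability falls in the 0.2--0.3 band (see [calibrate_env_sd()]).
#'
#' @param linf_at_sum0 Asymptotic length at allele sum zero (cm).
#' @param linf_per_allele Increment per 1-allele (cm).
#' @param env_sd SD of the environmental (non-heritable) deviation (cm).
#' @param floor_cm Lower truncation keeping growth curves biologically valid.
#' @return An object of class `phenotype_map`.
#' @export
phenotype_map <- function(linf_at_sum0 = 8, linf_per_allele = 0.5,
                          env_sd = 1.72, floor_cm = 8) {
  stopifnot(linf_at_sum0 > 0, linf_per_allele >= 0, env_sd >= 0, floor_cm > 0)
  structure(list(linf_at_sum0 = linf_at_sum0,
                 linf_per_allele = linf_per_allele,
                 env_sd = env_sd, floor_cm = floor_cm),
            class = "phenotype_map")
}

#' Density-dependence configuration
#'
#' Growth time (and egg production) are scaled by a logistic function of
#' relative biomass, `plogis(dd_intercept + dd_slope * BM/CC)`. The
#' intercept is constrained to `-0.85 * dd_slope` so that the factor is
#' exactly 0.5 when biomass is at 85% of carrying capacity. The steepness
#' `dd_slope` is a free model constant, calibrated so that an unfished
#' population equilibrates in the 56--61 unit band (see
#' [calibrate_dd_slope()]); the packaged default comes from that
#' calibration.
#'
#' @param carrying_capacity Carrying capacity in biomass units (1 unit =
#'   1 kg fresh weight).
#' @param dd_slope Logistic steepness, negative.
#' @return An object of class `density_config`.
#' @export
density_config <- function(carrying_capacity = 75, dd_slope = -15) {
  stopifnot(carrying_capacity > 0, dd_slope < 0)
  structure(list(carrying_capacity = carrying_capacity,
                 dd_slope = dd_slope,
                 dd_intercept = -0.85 * dd_slope),
            class = "density_config")
}

#' Bundled simulation configuration
#'
#' Collects every life-history, genetic, density and scenario constant the
#' simulator needs. The two `*_senescence` switches select the fecundity
#' factors (GSI-derived versus flat) and the natural-mortality schedule
#' (age-increasing versus constant).
#'
#' @param reproductive_senescence Use the GSI-derived age-declining
#'   fecundity factors?
#' @param actuarial_senescence Use the age-increasing mortality schedule?
#' @param map Genotype-to-phenotype map, see [phenotype_map()].
#' @param k_reg ln(k) on asymptotic length regression, see
#'   [lk_regression()].
#' @param lw Length-weight fit, see [length_weight_fit()].
#' @param fec Fecundity model, see [fecundity_model()].
#' @param factors Optional fecundity-factor vector overriding the mode
#'   implied by `reproductive_senescence` (see [gsi_to_factors()]).
#' @param mort Optional [mortality_schedule()] overriding
#'   `actuarial_senescence`.
#' @param density Density regulation, see [density_config()].
#' @param maturation_fraction Maturation length threshold as a fraction of
#'   the individual's asymptotic length (0.67).
#' @param min_maturation_age Earliest maturation age in years (2: never
#'   before the second autumn).
#' @param max_age Hard lifespan cap in years (7).
#' @param egg_survival Probability that a fertilized egg survives to age 2
#'   (0.002); all pre-adult mortality is folded into this single number.
#' @param founders_n,founder_length_cm Burn-in founder population size and
#'   initial body length.
#' @param recruit_length_cm Length at which recruits enter the population
#'   (the empirical growth-curve origin; back-calculated vendace
#'   trajectories imply a curve origin of roughly 5 cm, i.e. the first
#'   growing season is much faster than the adult von Bertalanffy
#'   extension from zero would give).
#' @param burn_in_years Length of the unfished burn-in (1,000 years).
#' @param phases Named integer vector of scenario phase lengths in years:
#'   pristine, fishing, recovery (200, 100, 200).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(reproductive_senescence = TRUE,
                       actuarial_senescence = TRUE,
                       map = phenotype_map(),
                       k_reg = lk_regression(),
                       lw = length_weight_fit(),
                       fec = fecundity_model(),
                       factors = NULL,
                       mort = NULL,
                       density = density_config(),
                       maturation_fraction = 0.67,
                       min_maturation_age = 2,
                       max_age = 7,
                       egg_survival = 0.002,
                       founders_n = 2000,
                       founder_length_cm = 4,
                       recruit_length_cm = 5,
                       burn_in_years = 1000,
                       phases = c(pristine = 200, fishing = 100,
                                  recovery = 200)) {
  if (is.null(factors)) {
    factors <- gsi_to_factors(
      generate_gsi_table(), max_age = max_age,
      mode = if (reproductive_senescence) "senescent" else "non-senescent")
  }
  if (is.null(mort)) {
    mort <- mortality_schedule(
      if (actuarial_senescence) "senescent" else "constant")
  }
  stopifnot(inherits(map, "phenotype_map"), inherits(k_reg, "lk_regression"),
            inherits(lw, "length_weight_fit"),
            inherits(fec, "fecundity_model"),
            inherits(mort, "mortality_schedule"),
            inherits(density, "density_config"),
            maturation_fraction > 0, maturation_fraction < 1,
            min_maturation_age >= 1, max_age > min_maturation_age,
            egg_survival >= 0, egg_survival <= 1,
            length(factors) == max_age, all(factors >= 0),
            all(phases >= 0), founders_n >= 0, founder_length_cm > 0)
  structure(list(reproductive_senescence = reproductive_senescence,
                 actuarial_senescence = actuarial_senescence,
                 map = map, k_reg = k_reg, lw = lw, fec = fec,
                 factors = factors, mort = mort, density = density,
                 maturation_fraction = maturation_fraction,
                 min_maturation_age = min_maturation_age,
                 max_age = max_age, egg_survival = egg_survival,
                 founders_n = founders_n,
                 founder_length_cm = founder_length_cm,
                 recruit_length_cm = recruit_length_cm,
                 burn_in_years = burn_in_years,
                 phases = phases),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  reproductive senescence: %s\n", x$reproductive_senescence))
  cat(sprintf("  actuarial senescence:    %s\n", x$actuarial_senescence))
  cat(sprintf("  carrying capacity:       %g units, dd_slope %g\n",
              x$density$carrying_capacity, x$density$dd_slope))
  cat(sprintf("  phenotype map:           L_inf = %g + %g * allele_sum + N(0, %g) cm\n",
              x$map$linf_at_sum0, x$map$linf_per_allele, x$map$env_sd))
  cat(sprintf("  phases (years):          pristine %d, fishing %d, recovery %d\n",
              x$phases[["pristine"]], x$phases[["fishing"]],
              x$phases[["recovery"]]))
  invisible(x)
}

#' Write / read a fitted life-history parameter file
#'
#' Serializes the parameterization-stage outputs (the ln(k) regression, the
#' length-weight fit, the fecundity model and the fecundity factors) to a
#' JSON file that can later seed [sim_config()].
#'
#' @param params A named list with elements `k_reg`, `lw`, `fec`,
#'   `factors`.
#' @param path File path.
#' @return `write_life_history()` returns `path` invisibly;
#'   `read_life_history()` returns the parameter list with classes
#'   restored.
#' @export
write_life_history <- function(params, path) {
  stopifnot(all(c("k_reg", "lw", "fec", "factors") %in% names(params)))
  out <- list(
    k_reg = unclass(params$k_reg),
    lw = unclass(params$lw),
    fec = unclass(params$fec),
    factors = as.list(setNames(as.numeric(params$factors),
                               seq_along(params$factors)))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_life_history
#' @export
read_life_history <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    k_reg = lk_regression(x$k_reg$intercept, x$k_reg$slope, x$k_reg$resid_sd),
    lw = length_weight_fit(x$lw$a, x$lw$b),
    fec = fecundity_model(x$fec$intercept, x$fec$slope),
    factors = setNames(as.numeric(unlist(x$factors)),
                       names(x$factors))
  )
}
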