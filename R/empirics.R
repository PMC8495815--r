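#' Back-calculate lengths at age from scale annuli
#'
#' Monastyrsky back-calculation: the length of the fish when annulus `t` was
#' laid down is `L_t = catch_length * (S_t / S)^b_exp`, where `S_t` is the
#' annulus radius, `S` the whole-scale radius and `b_exp` the allometric
#' scale-growth exponent (0.641 for Finnish vendace stocks).
#'
#' @param catch_length Measured total length at catch (mm).
#' @param scale_radius Radius of the entire scale (any consistent unit).
#' @param annulus_radii Radii from scale focus to each annulus, ordered by
#'   age; must be strictly increasing and all smaller than `scale_radius`.
#' @param b_exp Allometric exponent, > 0.
#' @return Numeric vector of lengths (mm) at ages `1..length(annulus_radii)`.
#' @examples
#' back_calculate(146, 1, c(0.35, 0.5, 0.62))
#' @export
back_calculate <- function(catch_length, scale_radius, annulus_radii,
                           b_exp = 0.641) {
  stopifnot(length(catch_length) == 1, catch_length > 0,
            length(scale_radius) == 1, scale_radius > 0, b_exp > 0)
  if (length(annulus_radii) == 0) return(numeric(0))
  if (any(diff(annulus_radii) <= 0))
    stop("annulus radii must be strictly increasing")
  if (any(annulus_radii <= 0) || any(annulus_radii >= scale_radius))
    stop("annulus radii must be positive and smaller than the scale radius")
  catch_length * (annulus_radii / scale_radius)^b_exp
}

#' von Bertalanffy curve evaluation
#'
#' `L_t = l_inf - (l_inf - l0) * exp(-k * t)`.
#'
#' @param t Age (years), any non-negative numeric vector.
#' @param l_inf Asymptotic length.
#' @param k Intrinsic growth coefficient (per year).
#' @param l0 Length at age 0.
#' @return Length at age `t`, same unit as `l_inf`.
#' @export
vb_length <- function(t, l_inf, k, l0 = 0) {
  l_inf - (l_inf - l0) * exp(-k * t)
}

#' Construct a von Bertalanffy parameter triple
#'
#' @param l_inf Asymptotic length (cm), > 0.
#' @param k Growth coefficient (per year), > 0.
#' @param l0 Length at age 0 (cm), < `l_inf`.
#' @param sse Optional residual sum of squares from a fit.
#' @param n Optional number of points fitted.
#' @return An object of class `vb_params`.
#' @export
vb_params <- function(l_inf, k, l0 = 0, sse = NA_real_, n = NA_integer_) {
  stopifnot(l_inf > 0, k > 0, l0 < l_inf)
  structure(list(l_inf = l_inf, k = k, l0 = l0, sse = sse, n = n),
            class = "vb_params")
}

#' @export
print.vb_params <- function(x, ...) {
  cat(sprintf("vB growth: L_inf = %.4g cm, k = %.4g /yr, L0 = %.4g cm\n",
              x$l_inf, x$k, x$l0))
  invisible(x)
}

#' Fit a von Bertalanffy growth curve by nonlinear least squares
#'
#' Multi-start Levenberg-Marquardt least squares of the growth curve on
#' (age, length) points of one individual. Starting values span
#' `l_inf` in (1, 1.2, 1.5) x max(length), `k` in (0.2, 0.5, 1.0) and
#' `l0` in (0, first length / 2); the start with the smallest residual sum
#' of squares wins (ties broken by the smallest fitted `l_inf`), and the
#' search stops early once a start attains an essentially zero objective.
#'
#' @param ages Ages in years (>= 3 points).
#' @param lengths Lengths at those ages, in the unit given by `unit`.
#' @param unit `"cm"` (default) or `"mm"`; output is always in cm.
#' @param fish_id Optional identifier included in error messages.
#' @param tol Objective value treated as an exact fit (early stop).
#' @return A [vb_params()] object (lengths in cm).
#' @export
fit_vb <- function(ages, lengths, unit = c("cm", "mm"), fish_id = NULL,
                   tol = 1e-10) {
  unit <- match.arg(unit)
  stopifnot(length(ages) == length(lengths), all(lengths > 0))
  if (length(ages) < 3)
    stop("fit_vb needs at least 3 (age, length) points",
         if (!is.null(fish_id)) paste0(" [fish ", fish_id, "]") else "")
  if (unit == "mm") lengths <- lengths / 10
  dat <- data.frame(t = ages, L = lengths)
  scale_tol <- tol * max(1, sum(lengths^2))
  starts <- expand.grid(l_inf = c(1, 1.2, 1.5) * max(lengths),
                        k = c(0.2, 0.5, 1.0),
                        l0 = c(0, lengths[1] / 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        L ~ l_inf - (l_inf - l0) * exp(-k * t),
        data = dat,
        start = as.list(starts[i, ]),
        lower = c(l_inf = max(lengths), k = 1e-8, l0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    cf <- coef(fit)
    if (is.null(best) || sse < best$sse - scale_tol ||
        (abs(sse - best$sse) <= scale_tol && cf[["l_inf"]] < best$l_inf)) {
      best <- list(sse = sse, l_inf = cf[["l_inf"]], k = cf[["k"]],
                   l0 = cf[["l0"]])
    }
    if (sse < scale_tol) break
  }
  if (is.null(best))
    stop("von Bertalanffy fit failed to converge from any start",
         if (!is.null(fish_id)) paste0(" [fish ", fish_id, "]") else "")
  vb_params(best$l_inf, best$k, best$l0, sse = best$sse,
            n = length(ages))
}

#' Regress ln(k) on asymptotic length across individuals
#'
#' Ordinary least squares of `ln(k)` on `l_inf` (cm) over per-individual
#' von Bertalanffy fits; the residual SD uses the `n - 2` denominator.
#'
#' @param fits A list of [vb_params()] objects, or a data frame / list with
#'   numeric elements `l_inf` and `k`.
#' @return An [lk_regression()] with the fitted coefficients.
#' @export
fit_k_on_linf <- function(fits) {
  if (is.list(fits) && length(fits) > 0 && inherits(fits[[1]], "vb_params")) {
    l_inf <- vapply(fits, `[[`, numeric(1), "l_inf")
    k <- vapply(fits, `[[`, numeric(1), "k")
  } else {
    l_inf <- fits$l_inf
    k <- fits$k
  }
  if (any(k <= 0)) stop("all k must be positive to take ln(k)")
  n <- length(k)
  if (n < 3) stop("need at least 3 fits for the ln(k) regression")
  m <- lm(log(k) ~ l_inf)
  resid_sd <- sqrt(sum(stats::resid(m)^2) / (n - 2))
  lk_regression(intercept = unname(coef(m)[1]), slope = unname(coef(m)[2]),
                resid_sd = resid_sd)
}

#' Fit the length-weight power law on the log scale
#'
#' OLS of `ln(W)` on `ln(L)`; `a = exp(intercept)`, `b = slope`.
#'
#' @param length_mm Lengths in mm, positive.
#' @param weight_g Fresh weights in g, positive.
#' @return A [length_weight_fit()].
#' @export
fit_length_weight <- function(length_mm, weight_g) {
  stopifnot(length(length_mm) == length(weight_g))
  if (length(length_mm) < 3) stop("need at least 3 length-weight pairs")
  if (any(length_mm <= 0) || any(weight_g <= 0))
    stop("lengths and weights must be positive")
  m <- lm(log(weight_g) ~ log(length_mm))
  length_weight_fit(a = exp(unname(coef(m)[1])), b = unname(coef(m)[2]))
}

#' Eggs produced per female as a linear function of body weight
#'
#' @param weight_g Fresh weight in grams, >= 0.
#' @param model A [fecundity_model()].
#' @return Expected egg number (real, not rounded).
#' @examples
#' fecundity(18.7) # 2254.4 eggs at the mean sample weight
#' @export
fecundity <- function(weight_g, model = fecundity_model()) {
  stopifnot(all(weight_g >= 0), inherits(model, "fecundity_model"))
  model$intercept + model$slope * weight_g
}

#' Age-specific fecundity factors from median GSI
#'
#' Reproductive senescence is modelled as an age-declining multiplier on the
#' fecundity model. In `"senescent"` mode the factor for ages 2--4 is the
#' ratio of that age's median GSI to the age-1 median GSI; ages 5 and 6+
#' default to the linearly extrapolated values 0.612 and 0.498 (age 7 reuses
#' the 6+ value). Age 1 is pre-reproductive and always gets factor 0. In
#' `"non-senescent"` mode all reproductive ages get factor 1.
#'
#' An extrapolation routine (OLS of GSI on age over the observed ages,
#' converted to a ratio) is available via `extrapolate = TRUE`, but the
#' published tail values are the default since no linear scheme on the
#' table's GSI values reproduces them exactly.
#'
#' @param gsi_by_age Named numeric vector of median GSI (per mille scale)
#'   covering at least ages 1--4.
#' @param max_age Oldest age class (default 7).
#' @param mode `"senescent"` or `"non-senescent"`.
#' @param tail Factors for ages 5 and 6+ in senescent mode.
#' @param extrapolate Replace `tail` by a linear GSI extrapolation?
#' @return Named numeric vector of factors for ages `1..max_age`.
#' @examples
#' gsi_to_factors(generate_gsi_table())
#' @export
gsi_to_factors <- function(gsi_by_age, max_age = 7,
                           mode = c("senescent", "non-senescent"),
                           tail = c(0.612, 0.498), extrapolate = FALSE) {
  mode <- match.arg(mode)
  f <- setNames(numeric(max_age), seq_len(max_age))
  if (mode == "non-senescent") {
    f[-1] <- 1
    return(f)
  }
  ages <- suppressWarnings(as.integer(names(gsi_by_age)))
  if (any(is.na(ages)) || !all(1:4 %in% ages))
    stop("gsi_by_age must be named by age and cover ages 1..4")
  if (any(gsi_by_age <= 0)) stop("GSI values must be positive")
  gsi <- setNames(as.numeric(gsi_by_age), ages)
  base <- gsi[["1"]]
  for (a in 2:min(4, max_age)) f[a] <- gsi[[as.character(a)]] / base
  if (max_age >= 5) {
    if (extrapolate) {
      m <- lm(g ~ a, data = data.frame(a = ages, g = as.numeric(gsi)))
      ext <- pmax(predict(m, data.frame(a = 5:max_age)), 0) / base
      f[5:max_age] <- ext
    } else {
      f[5] <- tail[1]
      if (max_age >= 6) f[6:max_age] <- tail[2]
    }
  }
  if (any(diff(f[-1]) > 1e-12))
    warning("senescent fecundity factors are not non-increasing in age")
  f
}
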