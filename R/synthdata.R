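#' Generator truth for synthetic growth trajectories
#'
#' Bundles the "true" model behind the synthetic field sample: the
#' distribution of asymptotic length, the ln(k) on asymptotic-length
#' regression, the shared curve origin and the scale-growth exponent used
#' to synthesize annulus radii. The asymptotic-length mean/SD and the curve
#' origin are calibration constants chosen so that simulated catch lengths
#' match the original sample summaries (lengths 120--170 mm, mean about
#' 146 mm); the regression defaults are the empirical fit itself.
#'
#' @param linf_mean,linf_sd Mean and SD of true asymptotic length (cm).
#' @param k_reg [lk_regression()] used as generator truth for ln(k).
#' @param l0 Shared curve origin (length at age 0, cm) of the true growth
#'   curves; a fitting constant of back-calculated trajectories, not a
#'   hatch size.
#' @param b_exp Allometric exponent used to invert the back-calculation
#'   when synthesizing radii.
#' @param catch_frac Fraction of a growth year completed between the last
#'   annulus and capture (keeps the last annulus radius strictly inside the
#'   scale edge).
#' @return A list of class `synth_truth`.
#' @export
synth_truth <- function(linf_mean = 16, linf_sd = 0.9,
                        k_reg = lk_regression(), l0 = 6.5,
                        b_exp = 0.641, catch_frac = 0.5) {
  stopifnot(linf_mean > 0, linf_sd >= 0, inherits(k_reg, "lk_regression"),
            l0 >= 0, l0 < linf_mean, b_exp > 0,
            catch_frac > 0, catch_frac <= 1)
  structure(list(linf_mean = linf_mean, linf_sd = linf_sd, k_reg = k_reg,
                 l0 = l0, b_exp = b_exp, catch_frac = catch_frac),
            class = "synth_truth")
}

#' One synthetic scale-read fish
#'
#' Validating constructor for a single sampled fish: catch length, age and
#' the per-annulus scale radii that back-calculation consumes.
#'
#' @param fish_id Identifier.
#' @param age_at_catch Completed years at capture.
#' @param catch_length Measured length at capture (mm).
#' @param scale_radius Whole-scale radius (arbitrary consistent units).
#' @param annulus_radii Radii to each annulus, one per completed year.
#' @param fresh_weight Optional fresh weight (g).
#' @param length_window Plausibility window for the catch length (mm).
#' @return An object of class `field_sample`.
#' @export
field_sample <- function(fish_id, age_at_catch, catch_length, scale_radius,
                         annulus_radii, fresh_weight = NA_real_,
                         length_window = c(60, 200)) {
  stopifnot(age_at_catch >= 1, length(annulus_radii) == age_at_catch)
  if (any(diff(annulus_radii) <= 0))
    stop("annulus radii must be strictly increasing")
  if (any(annulus_radii >= scale_radius))
    stop("annulus radii must lie inside the scale radius")
  if (catch_length < length_window[1] || catch_length > length_window[2])
    stop(sprintf("catch length %.1f mm outside plausibility window [%g, %g]",
                 catch_length, length_window[1], length_window[2]))
  structure(list(fish_id = fish_id, age_at_catch = as.integer(age_at_catch),
                 catch_length = catch_length, scale_radius = scale_radius,
                 annulus_radii = annulus_radii, fresh_weight = fresh_weight),
            class = "field_sample")
}

#' Generate synthetic scale-read growth trajectories
#'
#' Builds a sample of fish with the structure of the original lake data
#' (default age composition 34/20/37/2 at ages 3/4/5/6, N = 93). For each
#' fish: (i) true asymptotic length is drawn from
#' `N(linf_mean, linf_sd)`; (ii) `ln(k)` from the generator regression with
#' its residual SD; (iii) true lengths at integer ages come from the von
#' Bertalanffy curve, and the catch length from the curve at
#' `age + catch_frac`; (iv) annulus radii are synthesized by inverting the
#' Monastyrsky relation, `S_i = (L_i / L_catch)^(1/b_exp)`, with the whole
#' scale radius fixed at 1. Optional measurement noise (additive, mm) is
#' applied to the annulus-level lengths before inversion.
#'
#' With zero noise the pipeline is exactly invertible: back-calculation
#' followed by a von Bertalanffy refit recovers each fish's true
#' parameters.
#'
#' @param n_by_age Named integer vector, count of fish per age at catch.
#' @param truth A [synth_truth()].
#' @param noise_sd_mm SD of additive measurement noise on annulus lengths
#'   (mm); 0 (default) gives noise-free, exactly invertible trajectories.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param max_attempts Redraws allowed per fish before failing (guards
#'   against degenerate draws).
#' @return A list of [field_sample()] objects.
#' @examples
#' fish <- generate_trajectories(seed = 1)
#' length(fish) # 93
#' @export
generate_trajectories <- function(n_by_age = c(`3` = 34, `4` = 20,
                                               `5` = 37, `6` = 2),
                                  truth = synth_truth(), noise_sd_mm = 0,
                                  seed = 1L, max_attempts = 100L) {
  stopifnot(inherits(truth, "synth_truth"), noise_sd_mm >= 0,
            all(n_by_age >= 0))
  set.seed(as.integer(seed))
  ages <- rep(as.integer(names(n_by_age)), times = n_by_age)
  out <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    a <- ages[i]
    for (attempt in seq_len(max_attempts)) {
      linf <- rnorm(1, truth$linf_mean, truth$linf_sd)
      if (linf <= truth$l0) next
      k <- exp(truth$k_reg$intercept + truth$k_reg$slope * linf +
                 rnorm(1, 0, truth$k_reg$resid_sd))
      len_mm <- 10 * vb_length(1:a, linf, k, truth$l0)
      catch_mm <- 10 * vb_length(a + truth$catch_frac, linf, k, truth$l0)
      if (noise_sd_mm > 0)
        len_mm <- len_mm + rnorm(a, 0, noise_sd_mm)
      ok <- all(diff(c(len_mm, catch_mm)) > 0) && all(len_mm > 0) &&
        catch_mm >= 60 && catch_mm <= 200
      if (!ok) next
      radii <- (len_mm / catch_mm)^(1 / truth$b_exp)
      out[[i]] <- field_sample(
        fish_id = sprintf("fish%03d", i), age_at_catch = a,
        catch_length = catch_mm, scale_radius = 1, annulus_radii = radii)
      break
    }
    if (is.null(out[[i]]))
      stop(sprintf("failed to draw a valid age-%d trajectory in %d attempts",
                   a, max_attempts))
  }
  out
}

#' Convert field samples to a long-format data frame
#'
#' One row per annulus: `fish_id, age, annulus_radius, scale_radius,
#' catch_length` (the CSV dialect the parameterization stage reads).
#'
#' @param samples List of [field_sample()] objects.
#' @return A data frame in long format.
#' @export
trajectories_to_df <- function(samples) {
  do.call(rbind, lapply(samples, function(s) {
    data.frame(fish_id = s$fish_id,
               age = seq_len(s$age_at_catch),
               annulus_radius = s$annulus_radii,
               scale_radius = s$scale_radius,
               catch_length = s$catch_length)
  }))
}

#' Generate synthetic length-weight pairs
#'
#' Lengths are drawn from the catch-length distribution of the original
#' sample (normal, mean 146 mm, SD 8.63, clipped to 120--170 mm) and weights
#' from the power law `W = a * L^b * exp(N(0, noise_sd))`.
#'
#' @param n Number of pairs (default 27, the original sample size).
#' @param a,b Power-law truth (defaults: the empirical fit).
#' @param noise_sd Relative (log-scale) SD of the weight noise.
#' @param seed Integer seed.
#' @param length_mm Optional explicit lengths overriding the random draw.
#' @return A data frame with columns `length_mm`, `weight_g`.
#' @export
generate_weight_data <- function(n = 27, a = 7e-6, b = 2.943,
                                 noise_sd = 0.05, seed = 1L,
                                 length_mm = NULL) {
  stopifnot(n > 0, a > 0, noise_sd >= 0)
  set.seed(as.integer(seed))
  if (is.null(length_mm)) {
    length_mm <- pmin(pmax(rnorm(n, 146, 8.63), 120), 170)
  } else {
    stopifnot(length(length_mm) == n)
  }
  weight_g <- a * length_mm^b * exp(rnorm(n, 0, noise_sd))
  data.frame(length_mm = length_mm, weight_g = weight_g)
}

#' Median gonadosomatic index by age
#'
#' The fixed empirical table of median GSI (per mille scale) for ages 1--4.
#' The printed age-1 entry "25" is interpreted as 25,000: the published
#' fecundity factors (0.990, 0.927, 0.754) are exactly the ratios of the
#' later entries to 25,000. The age-1 value is exposed as an argument for
#' sensitivity analyses.
#'
#' @param age1 Median GSI of age group 1.
#' @return Named numeric vector for ages 1--4.
#' @examples
#' generate_gsi_table()
#' @export
generate_gsi_table <- function(age1 = 25000) {
  c(`1` = age1, `2` = 24747, `3` = 23184, `4` = 18841)
}

#' Write the synthetic field-data files
#'
#' Writes three RFC-4180 CSV files into `dir`: `trajectories.csv` (long
#' format), `length_weight.csv` and `gsi.csv`.
#'
#' @param samples List of [field_sample()] objects.
#' @param weights Data frame from [generate_weight_data()].
#' @param gsi Named vector from [generate_gsi_table()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_field_data <- function(samples, weights, gsi, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(trajectories_to_df(samples),
            file.path(dir, "trajectories.csv"), row.names = FALSE)
  write.csv(weights, file.path(dir, "length_weight.csv"), row.names = FALSE)
  write.csv(data.frame(age = as.integer(names(gsi)),
                       median_gsi = as.numeric(gsi)),
            file.path(dir, "gsi.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read the synthetic field-data files
#'
#' @param dir Directory written by [write_field_data()].
#' @return A list with `trajectories` (long data frame), `weights` and
#'   `gsi` (named vector).
#' @export
read_field_data <- function(dir) {
  traj <- read.csv(file.path(dir, "trajectories.csv"))
  weights <- read.csv(file.path(dir, "length_weight.csv"))
  gsi_df <- read.csv(file.path(dir, "gsi.csv"))
  list(trajectories = traj, weights = weights,
       gsi = setNames(gsi_df$median_gsi, gsi_df$age))
}

#' Run the full parameterization pipeline on field data
#'
#' Back-calculates every trajectory, fits a von Bertalanffy curve per fish,
#' regresses ln(k) on asymptotic length, fits the length-weight power law
#' and derives the fecundity factors.
#'
#' @param trajectories Long-format trajectory data frame (see
#'   [trajectories_to_df()]).
#' @param weights Length-weight data frame.
#' @param gsi Named median-GSI vector.
#' @param b_exp Back-calculation exponent.
#' @param fec Fecundity model to carry through (the egg-count regression is
#'   taken from published constants, not refitted here).
#' @param mode Fecundity-factor mode.
#' @return A list with `vb_fits`, `k_reg`, `lw`, `fec`, `factors`.
#' @export
parameterize <- function(trajectories, weights, gsi, b_exp = 0.641,
                         fec = fecundity_model(),
                         mode = c("senescent", "non-senescent")) {
  mode <- match.arg(mode)
  split_fish <- split(trajectories, trajectories$fish_id)
  vb_fits <- lapply(split_fish, function(d) {
    d <- d[order(d$age), ]
    len_mm <- back_calculate(d$catch_length[1], d$scale_radius[1],
                             d$annulus_radius, b_exp = b_exp)
    fit_vb(d$age, len_mm, unit = "mm", fish_id = d$fish_id[1])
  })
  k_reg <- fit_k_on_linf(vb_fits)
  lw <- fit_length_weight(weights$length_mm, weights$weight_g)
  factors <- gsi_to_factors(gsi, mode = mode)
  list(vb_fits = vb_fits, k_reg = k_reg, lw = lw, fec = fec,
       factors = factors)
}
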