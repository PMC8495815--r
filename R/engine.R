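#' Population container
#'
#' A population is a list of parallel vectors plus an `n x 20` genotype
#' matrix; all engine operations are vectorized over individuals. Sex is
#' coded 1 = female, 2 = male.
#'
#' @param id Integer identifiers.
#' @param sex Integer vector (1 female, 2 male).
#' @param age Integer ages (years; recruits are age 0).
#' @param length Lengths (cm).
#' @param l_inf,k Individual growth-curve parameters.
#' @param mature Logical maturity flags.
#' @param age_mat,size_mat Age (years) and length (cm) at maturation,
#'   `NA` while immature.
#' @param geno Integer genotype matrix.
#' @return An object of class `fish_population`.
#' @export
new_population <- function(id, sex, age, length, l_inf, k, mature,
                           age_mat, size_mat, geno) {
  n <- length(id)
  stopifnot(length(sex) == n, length(age) == n, length(length) == n,
            length(l_inf) == n, length(k) == n, length(mature) == n,
            length(age_mat) == n, length(size_mat) == n,
            nrow(geno) == n, ncol(geno) == 20L)
  structure(list(id = as.integer(id), sex = as.integer(sex),
                 age = as.integer(age), length = as.numeric(length),
                 l_inf = as.numeric(l_inf), k = as.numeric(k),
                 mature = as.logical(mature),
                 age_mat = as.numeric(age_mat),
                 size_mat = as.numeric(size_mat), geno = geno),
            class = "fish_population")
}

#' @export
print.fish_population <- function(x, ...) {
  n <- length(x$id)
  cat(sprintf("fish_population: %d individuals", n))
  if (n > 0)
    cat(sprintf(" (%d adults age>=2, %.1f%% mature, mean length %.1f cm)",
                sum(x$age >= 2), 100 * mean(x$mature), mean(x$length)))
  cat("\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `fish_population`.
#' @return Integer count.
#' @export
population_size <- function(pop) length(pop$id)

#' Subset a population
#'
#' @param pop A `fish_population`.
#' @param keep Logical or integer index of individuals to keep.
#' @return The subset population.
#' @export
subset_population <- function(pop, keep) {
  new_population(pop$id[keep], pop$sex[keep], pop$age[keep],
                 pop$length[keep], pop$l_inf[keep], pop$k[keep],
                 pop$mature[keep], pop$age_mat[keep], pop$size_mat[keep],
                 pop$geno[keep, , drop = FALSE])
}

#' Total population biomass
#'
#' Biomass is measured in units of 1 kg fresh weight, with individual
#' weights from the length-weight fit.
#'
#' @param pop A `fish_population`.
#' @param lw A [length_weight_fit()].
#' @param min_age Count only individuals at least this old (default 0 =
#'   everyone).
#' @return Biomass in units (kg).
#' @export
biomass_units <- function(pop, lw = length_weight_fit(), min_age = 0) {
  sel <- pop$age >= min_age
  sum(predict_weight(10 * pop$length[sel], lw)) / 1000
}

#' Density-dependent growth-time factor
#'
#' `plogis(dd_intercept + dd_slope * BM / CC)` with the intercept tied to
#' `-0.85 * dd_slope`, so that the factor is exactly 0.5 when biomass is at
#' 85% of carrying capacity, close to 1 when the population is sparse, and
#' falls towards 0 as biomass approaches and exceeds capacity. The same
#' factor multiplies both the annual growth time and expected egg
#' production.
#'
#' @param biomass Current biomass (units).
#' @param cfg A [density_config()].
#' @return A factor in (0, 1).
#' @examples
#' density_factor(0.85 * 75, density_config()) # exactly 0.5
#' @export
density_factor <- function(biomass, cfg = density_config()) {
  stopifnot(biomass >= 0, inherits(cfg, "density_config"))
  stats::plogis(cfg$dd_intercept +
                  cfg$dd_slope * biomass / cfg$carrying_capacity)
}

#' Create a founder population
#'
#' `n` age-0 individuals of the given initial length with independent
#' Bernoulli(`p`) alleles; asymptotic length is expressed at creation and
#' `k` drawn from the regression.
#'
#' @param n Number of founders.
#' @param cfg A [sim_config()].
#' @param p Founder allele frequency.
#' @return A `fish_population`.
#' @export
founder_population <- function(n = 2000, cfg = sim_config(), p = 0.5) {
  geno <- random_genotypes(n, p)
  l_inf <- express_linf(geno, cfg$map)
  k <- draw_k(l_inf, cfg$k_reg)
  new_population(id = seq_len(n),
                 sex = sample(1:2, n, replace = TRUE),
                 age = rep(0L, n),
                 length = pmin(rep(cfg$founder_length_cm, n), l_inf),
                 l_inf = l_inf, k = k,
                 mature = rep(FALSE, n),
                 age_mat = rep(NA_real_, n), size_mat = rep(NA_real_, n),
                 geno = geno)
}

.empty_record <- function(year) {
  data.frame(year = year, n_fish = 0L, biomass = 0, mean_l_inf = NA_real_,
             mean_k = NA_real_, mean_size_mat = NA_real_,
             mean_age_mat = NA_real_, catch_n = 0L, catch_kg = 0,
             recruits = 0L, density = NA_real_, extinct = TRUE)
}

#' One annual population cycle
#'
#' Executes the fixed within-year event order: (1) compute biomass and the
#' density factor; (2) grow every individual with growth time equal to the
#' density factor; (3) maturation check; (4) reproduction — every mature
#' female is paired with a uniformly drawn mature male, expected eggs come
#' from [eggs_produced()] with the same density factor, and the number of
#' her offspring surviving to be tracked is Binomial(round(eggs), egg
#' survival); offspring get a Mendelian genotype, a Bernoulli(0.5) sex,
#' an expressed asymptotic length and a drawn `k`, start at length 0, and
#' enter next year's ledger at age 1 (their first autumn is the spawning
#' itself); (5) natural mortality on ages >= 2, with the maturation cost
#' added for fish that matured this year; (6) fishing, if a gear is
#' passed; (7) ages increment and fish beyond the lifespan cap are
#' removed.
#'
#' The annual record summarizes the recorded population (ages >= 2):
#' abundance, biomass, mean asymptotic length, mean `k`, mean size/age at
#' maturation, plus the year's catch and recruit counts. The density
#' factor and total biomass use every tracked individual, since juveniles
#' compete too.
#'
#' @param pop A `fish_population`.
#' @param cfg A [sim_config()].
#' @param sel Optional selectivity; `NULL` means no fishing this year.
#' @param year Year stamp written into the record.
#' @param quota_kg Optional biomass quota (kg); if given, the gear's
#'   fishing mortality is rescaled this year via [match_quota_f()].
#' @return A list: `population`, `record` (one-row data frame).
#' @export
annual_step <- function(pop, cfg = sim_config(), sel = NULL, year = NA,
                        quota_kg = NULL) {
  if (population_size(pop) == 0)
    return(list(population = pop, record = .empty_record(year)))

  ## (1) density (end-of-last-year biomass is cached on the population;
  ## lengths have not changed since, so the cache is exact)
  bm_total <- attr(pop, "bm_all")
  if (is.null(bm_total)) bm_total <- biomass_units(pop, cfg$lw)
  g <- density_factor(bm_total, cfg$density)

  ## (2) growth
  pop$length <- grow_length(pop$length, pop$l_inf, pop$k, g)

  ## (3) maturation
  newly <- check_maturation(pop$age, pop$length, pop$l_inf, pop$mature,
                            cfg$maturation_fraction, cfg$min_maturation_age)
  pop$mature <- pop$mature | newly
  pop$age_mat[newly] <- pop$age[newly]
  pop$size_mat[newly] <- pop$length[newly]

  ## (4) reproduction
  fem <- which(pop$mature & pop$sex == 1L)
  mal <- which(pop$mature & pop$sex == 2L)
  recruits <- NULL
  n_rec <- 0L
  if (length(fem) > 0 && length(mal) > 0) {
    eggs <- eggs_produced(pop$length[fem], pop$age[fem], cfg$factors,
                          cfg$lw, cfg$fec, density_factor = g)
    brood <- rbinom(length(fem), round(eggs), cfg$egg_survival)
    n_rec <- sum(brood)
    if (n_rec > 0) {
      dad_of_fem <- mal[sample.int(length(mal), length(fem),
                                   replace = TRUE)]
      geno <- .inherit_indexed(pop$geno, rep(fem, brood),
                               rep(dad_of_fem, brood),
                               runif(10L * n_rec))
      l_inf <- express_linf(geno, cfg$map)
      recruits <- list(
        sex = sample(1:2, n_rec, replace = TRUE),
        l_inf = l_inf,
        k = draw_k(l_inf, cfg$k_reg),
        geno = geno)
    }
  }

  ## (5) natural mortality on adults
  n <- population_size(pop)
  alive <- rep(TRUE, n)
  adult <- which(pop$age >= 2)
  if (length(adult) > 0) {
    rate <- natural_mortality_rate(pop$age[adult], cfg$mort, newly[adult])
    alive[adult] <- survive_natural(rate)
  }

  ## (6) fishing among natural-mortality survivors
  catch_n <- 0L
  catch_kg <- 0
  if (!is.null(sel)) {
    f <- if (!is.null(quota_kg)) {
      match_quota_f(subset_population(pop, alive), sel, quota_kg, cfg$lw)
    } else sel$f_full
    if (f > 0) {
      p <- capture_prob(pop$length, sel, f_full = f)
      caught <- alive & (runif(n) < p)
      catch_n <- sum(caught)
      catch_kg <- sum(predict_weight(10 * pop$length[caught], cfg$lw)) / 1000
      alive <- alive & !caught
    }
  }

  ## (7) ageing, lifespan cap, recruit accession: one rebuild
  keep <- which(alive & pop$age < cfg$max_age)
  next_id <- attr(pop, "next_id")
  if (is.null(next_id)) next_id <- max(pop$id, 0L) + 1L
  nas <- rep(NA_real_, n_rec)
  pop <- new_population(
    id = c(pop$id[keep], if (n_rec) next_id - 1L + seq_len(n_rec)),
    sex = c(pop$sex[keep], recruits$sex),
    age = c(pop$age[keep] + 1L, rep(1L, n_rec)),
    length = c(pop$length[keep],
               pmin(rep(cfg$recruit_length_cm, n_rec),
                    if (n_rec) recruits$l_inf else numeric(0))),
    l_inf = c(pop$l_inf[keep], recruits$l_inf),
    k = c(pop$k[keep], recruits$k),
    mature = c(pop$mature[keep], logical(n_rec)),
    age_mat = c(pop$age_mat[keep], nas),
    size_mat = c(pop$size_mat[keep], nas),
    geno = .geno_rebuild(pop$geno, keep,
                         if (n_rec) recruits$geno
                         else matrix(integer(0), 0, 20)))
  attr(pop, "next_id") <- next_id + n_rec

  w_end <- predict_weight(10 * pop$length, cfg$lw)
  attr(pop, "bm_all") <- sum(w_end) / 1000
  rec_sel <- pop$age >= 2
  n_rec_pop <- sum(rec_sel)
  mat_sel <- rec_sel & pop$mature
  record <- data.frame(
    year = year,
    n_fish = n_rec_pop,
    biomass = sum(w_end[rec_sel]) / 1000,
    mean_l_inf = if (n_rec_pop) mean(pop$l_inf[rec_sel]) else NA_real_,
    mean_k = if (n_rec_pop) mean(pop$k[rec_sel]) else NA_real_,
    mean_size_mat = if (any(mat_sel)) mean(pop$size_mat[mat_sel])
      else NA_real_,
    mean_age_mat = if (any(mat_sel)) mean(pop$age_mat[mat_sel])
      else NA_real_,
    catch_n = catch_n, catch_kg = catch_kg,
    recruits = n_rec,
    density = g,
    extinct = population_size(pop) == 0)
  list(population = pop, record = record)
}

#' Burn a founder population in to ecological stability
#'
#' Runs `years` (default from the config: 1,000) unfished annual cycles
#' from `founders_n` age-0 founders of the configured initial length with
#' Bernoulli(0.5) alleles. The stability diagnostic is the linear trend of
#' biomass over the final 100 years (|slope| < 0.05 units/yr is logged as
#' stable).
#'
#' @param cfg A [sim_config()].
#' @param years Number of burn-in years.
#' @param seed Optional integer seed.
#' @return A list of class `burn_in`: `population`, `records` (data
#'   frame, one row per year), `stable` (logical), `biomass_trend`
#'   (units/yr), `final_mean_biomass` (mean over the last 100 years).
#' @export
burn_in <- function(cfg = sim_config(), years = cfg$burn_in_years,
                    seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (cfg$founders_n == 0) stop("cannot burn in from zero founders")
  pop <- founder_population(cfg$founders_n, cfg)
  records <- vector("list", years)
  for (y in seq_len(years)) {
    step <- annual_step(pop, cfg, sel = NULL, year = y)
    pop <- step$population
    records[[y]] <- step$record
    if (population_size(pop) == 0)
      stop(sprintf("population went extinct in burn-in year %d", y))
  }
  records <- do.call(rbind, records)
  tail100 <- records[records$year > years - 100, ]
  trend <- unname(coef(lm(biomass ~ year, data = tail100))[2])
  structure(list(population = pop, records = records,
                 stable = abs(trend) < 0.05,
                 biomass_trend = trend,
                 final_mean_biomass = mean(tail100$biomass)),
            class = "burn_in")
}

#' @export
print.burn_in <- function(x, ...) {
  cat(sprintf(
    "burn-in: %d years, final 100-yr mean biomass %.1f units (trend %+.3f/yr, %s)\n",
    nrow(x$records), x$final_mean_biomass, x$biomass_trend,
    if (x$stable) "stable" else "NOT stable"))
  invisible(x)
}

.stream_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the three-phase harvest scenario over replicates
#'
#' For each replicate a starting population is sampled (with replacement)
#' from the supplied burn-in snapshots and simulated through the pristine,
#' fishing and recovery phases (defaults 200 + 100 + 200 years); the gear
#' is active only during the fishing phase. Replicates are driven by
#' independent seeds derived from the master seed, so results are
#' reproducible per (config, seed, replicate index), and extinction in one
#' replicate does not abort the others.
#'
#' @param cfg A [sim_config()].
#' @param starts A list of starting `fish_population`s (e.g. burn-in
#'   snapshots).
#' @param gear `"none"`, `"trawl"` (logistic) or `"gillnet"` (dome).
#' @param sel Optional explicit selectivity object overriding `gear`.
#' @param n_replicates Number of replicates.
#' @param seed Master seed.
#' @param quota_series Optional per-fishing-year biomass quotas (kg): a
#'   numeric vector of length equal to the fishing phase, typically a
#'   reference run's annual catch. If supplied, each fishing year's
#'   mortality is rescaled so the expected removed biomass matches.
#' @return A list of per-replicate annual-record data frames (each with a
#'   `replicate` column).
#' @export
run_scenario <- function(cfg = sim_config(), starts, gear = c("none",
                         "trawl", "gillnet"), sel = NULL,
                         n_replicates = 100, seed = 1L,
                         quota_series = NULL) {
  gear <- match.arg(gear)
  stopifnot(length(starts) >= 1)
  if (is.null(sel) && gear != "none") {
    sel <- switch(gear, trawl = selectivity_logistic(),
                  gillnet = selectivity_dome())
  }
  years <- sum(cfg$phases)
  fish_start <- cfg$phases[["pristine"]]
  fish_end <- fish_start + cfg$phases[["fishing"]]
  if (!is.null(quota_series))
    stopifnot(length(quota_series) == cfg$phases[["fishing"]])
  seeds <- .stream_seeds(seed, n_replicates + 1L)
  runs <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(seeds[r])
    pop <- starts[[sample.int(length(starts), 1)]]
    records <- vector("list", years)
    for (y in seq_len(years)) {
      fishing <- !is.null(sel) && y > fish_start && y <= fish_end
      quota <- if (fishing && !is.null(quota_series))
        quota_series[y - fish_start] else NULL
      step <- annual_step(pop, cfg,
                          sel = if (fishing) sel else NULL,
                          year = y, quota_kg = quota)
      pop <- step$population
      records[[y]] <- step$record
    }
    run <- do.call(rbind, records)
    run$replicate <- r
    runs[[r]] <- run
  }
  runs
}

#' Calibrate the density-dependence steepness
#'
#' Grid search over candidate `dd_slope` values: each candidate is burned
#' in and scored by the distance of its final-100-year mean biomass from
#' the centre of the target equilibrium band (56--61 units). The slope is
#' a free constant of the model (only the 85%-of-capacity anchor is
#' empirically fixed), so it is set by this calibration once and recorded
#' in run metadata.
#'
#' @param cfg A [sim_config()]; its `dd_slope` entry is ignored.
#' @param candidates Candidate slopes (negative).
#' @param years Burn-in length per candidate.
#' @param seed Integer seed (reused across candidates).
#' @param band Target equilibrium band (units).
#' @return A list: `dd_slope` (best candidate), `biomass` (named vector of
#'   final-100-year means per candidate).
#' @export
calibrate_dd_slope <- function(cfg = sim_config(),
                               candidates = c(-40, -30, -25, -20, -15, -10),
                               years = 600, seed = 1L,
                               band = c(56, 61)) {
  means <- vapply(candidates, function(s) {
    cfg$density <- density_config(cfg$density$carrying_capacity, s)
    burn_in(cfg, years = years, seed = seed)$final_mean_biomass
  }, numeric(1))
  names(means) <- candidates
  best <- candidates[which.min(abs(means - mean(band)))]
  list(dd_slope = best, biomass = means)
}

#' Write / read a population snapshot as CSV
#'
#' One row per individual; the genotype is serialized as a 20-character
#' 0/1 string.
#'
#' @param pop A `fish_population`.
#' @param path CSV file path.
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns the `fish_population`.
#' @export
write_population <- function(pop, path) {
  df <- data.frame(id = pop$id, sex = ifelse(pop$sex == 1L, "F", "M"),
                   age = pop$age, length_cm = pop$length,
                   l_inf_cm = pop$l_inf, k = pop$k, mature = pop$mature,
                   age_mat = pop$age_mat, size_mat = pop$size_mat,
                   genotype = apply(pop$geno, 1, paste, collapse = ""))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- read.csv(path, colClasses = c(genotype = "character"))
  geno <- t(vapply(strsplit(df$genotype, ""),
                   function(x) as.integer(x), integer(20)))
  if (nrow(df) == 0) geno <- matrix(integer(0), 0, 20)
  new_population(df$id, ifelse(df$sex == "F", 1L, 2L), df$age,
                 df$length_cm, df$l_inf_cm, df$k, df$mature,
                 df$age_mat, df$size_mat, geno)
}
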