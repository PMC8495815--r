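test_that("density factor honours the 85%-of-capacity anchor", {
  d <- density_config()
  expect_identical(density_factor(0.85 * 75, d), 0.5)
  expect_gt(density_factor(0, d), 0.99)
  expect_lt(density_factor(2 * 75, d), 0.01)
  bm <- seq(0, 150, 5)
  f <- density_factor(bm, d)
  expect_true(all(diff(f) < 0)) # strictly decreasing
  expect_true(all(f > 0 & f < 1))
})

test_that("founder populations are well formed", {
  set.seed(20)
  cfg <- sim_config()
  pop <- founder_population(300, cfg)
  expect_s3_class(pop, "fish_population")
  expect_equal(population_size(pop), 300)
  expect_true(all(pop$age == 0))
  expect_true(all(pop$length <= pop$l_inf))
  expect_true(all(pop$l_inf >= cfg$map$floor_cm))
  expect_true(all(pop$k > 0))
  expect_true(all(pop$sex %in% 1:2))
  expect_false(any(pop$mature))
})

test_that("an empty population yields an empty annual record", {
  cfg <- sim_config()
  empty <- subset_population(founder_population(5, cfg), integer(0))
  step <- annual_step(empty, cfg, year = 3)
  expect_equal(population_size(step$population), 0)
  expect_true(step$record$extinct)
  expect_equal(step$record$n_fish, 0L)
})

test_that("no mature males means no recruits", {
  set.seed(21)
  cfg <- sim_config()
  pop <- founder_population(100, cfg)
  pop$sex <- rep(1L, 100) # all female
  pop$age <- rep(3L, 100)
  pop$mature <- rep(TRUE, 100)
  pop$age_mat <- rep(2, 100)
  pop$size_mat <- pop$length
  step <- annual_step(pop, cfg, year = 1)
  expect_equal(step$record$recruits, 0L)
})

test_that("with mortality switched off, individuals are conserved", {
  set.seed(22)
  cfg <- sim_config(
    mort = mortality_schedule(rates = rep(0, 5), maturation_cost = 0),
    max_age = 50)
  pop <- founder_population(400, cfg)
  pop$age <- rep(2L, 400)
  n0 <- population_size(pop)
  step <- annual_step(pop, cfg, year = 1)
  expect_equal(population_size(step$population),
               n0 + step$record$recruits)
})

test_that("identical seeds give byte-identical runs", {
  cfg <- sim_config()
  run_once <- function() {
    set.seed(33)
    pop <- founder_population(500, cfg)
    recs <- list()
    for (y in 1:25) {
      step <- annual_step(pop, cfg, year = y)
      pop <- step$population
      recs[[y]] <- step$record
    }
    list(pop = pop, records = do.call(rbind, recs))
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$records, b$records)
  expect_identical(a$pop, b$pop)
})

test_that("burn-in reaches a bounded, demographically balanced equilibrium", {
  bi <- nonsen_burnin()
  cfg <- nonsen_config()
  # regulation sanity bound: biomass never exceeds twice carrying capacity
  expect_true(all(bi$records$biomass <=
                    2 * cfg$density$carrying_capacity))
  expect_true(bi$stable)
  # demographic balance over the last 50 years: deaths out of the adult
  # ledger are replaced by recruits reaching age 2
  r <- bi$records
  n <- nrow(r)
  yrs <- (n - 49):n
  deaths <- r$n_fish[yrs - 1] + r$recruits[yrs - 1] - r$n_fish[yrs]
  ratio <- mean(deaths) / mean(r$recruits[yrs - 1])
  expect_gte(ratio, 0.8)
  expect_lte(ratio, 1.25)
})

test_that("burn-in refuses zero founders", {
  expect_error(burn_in(sim_config(founders_n = 0)), "zero founders")
})

test_that("run_scenario fishes only in the fishing phase", {
  set.seed(24)
  cfg <- sim_config(phases = c(pristine = 6, fishing = 4, recovery = 5))
  start <- founder_population(800, cfg)
  start$age <- sample(2:5, 800, replace = TRUE)
  start$mature <- rep(TRUE, 800)
  start$age_mat <- rep(2, 800)
  start$size_mat <- start$length
  none <- run_scenario(cfg, list(start), gear = "none",
                       n_replicates = 2, seed = 5)
  expect_length(none, 2)
  expect_true(all(vapply(none, function(r) all(r$catch_n == 0), logical(1))))
  trawl <- run_scenario(cfg, list(start), gear = "trawl",
                        n_replicates = 2, seed = 5)
  for (r in trawl) {
    expect_true(all(r$catch_n[r$year <= 6 | r$year > 10] == 0))
    expect_gt(sum(r$catch_n[r$year %in% 7:10]), 0)
  }
  # determinism per (seed, replicate)
  trawl2 <- run_scenario(cfg, list(start), gear = "trawl",
                         n_replicates = 2, seed = 5)
  expect_identical(trawl, trawl2)
})

test_that("population snapshots round-trip through CSV", {
  set.seed(25)
  pop <- founder_population(40, sim_config())
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(back$id, pop$id)
  expect_equal(back$sex, pop$sex)
  expect_equal(back$length, pop$length, tolerance = 1e-12)
  expect_equal(back$l_inf, pop$l_inf, tolerance = 1e-12)
  expect_equal(unname(back$geno), unname(pop$geno))
})
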