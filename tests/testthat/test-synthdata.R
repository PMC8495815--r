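test_that("generate_trajectories reproduces the sample design", {
  fish <- generate_trajectories(seed = 1)
  expect_length(fish, 93)
  ages <- vapply(fish, `[[`, integer(1), "age_at_catch")
  expect_equal(as.integer(table(ages)), c(34L, 20L, 37L, 2L))
  expect_equal(as.integer(names(table(ages))), 3:6)
  for (f in fish[c(1, 40, 93)]) {
    expect_length(f$annulus_radii, f$age_at_catch)
    expect_true(all(diff(f$annulus_radii) > 0))
    expect_true(all(f$annulus_radii < f$scale_radius))
    expect_gte(f$catch_length, 60)
    expect_lte(f$catch_length, 200)
  }
})

test_that("an empty age map gives an empty sample", {
  expect_length(generate_trajectories(n_by_age = integer(0), seed = 1), 0)
})

test_that("identical seeds give identical samples", {
  a <- generate_trajectories(seed = 42)
  b <- generate_trajectories(seed = 42)
  expect_identical(a, b)
  c <- generate_trajectories(seed = 43)
  expect_false(identical(a, c))
})

test_that("noise-free generation round-trips through back-calculation", {
  truth <- synth_truth()
  fish <- generate_trajectories(n_by_age = c(`5` = 5), truth = truth,
                                noise_sd_mm = 0, seed = 7)
  for (f in fish) {
    lens <- back_calculate(f$catch_length, f$scale_radius, f$annulus_radii,
                           b_exp = truth$b_exp)
    fit <- fit_vb(seq_len(f$age_at_catch), lens, unit = "mm")
    # the generated trajectory is an exact vB curve, so the refit must
    # recover it to numerical precision
    pred <- 10 * vb_length(seq_len(f$age_at_catch), fit$l_inf, fit$k, fit$l0)
    expect_equal(pred, lens, tolerance = 1e-9)
  }
})

test_that("catch-length summaries emulate the original sample", {
  stats <- vapply(1:20, function(s) {
    fish <- generate_trajectories(seed = s)
    lens <- vapply(fish, `[[`, numeric(1), "catch_length")
    c(mean(lens), sd(lens))
  }, numeric(2))
  expect_gte(mean(stats[1, ]), 140)
  expect_lte(mean(stats[1, ]), 152)
  expect_gte(mean(stats[2, ]), 6)
  expect_lte(mean(stats[2, ]), 11)
})

test_that("weight data follow the power law", {
  w <- generate_weight_data(n = 27, seed = 1)
  expect_equal(nrow(w), 27)
  exact <- generate_weight_data(n = 3, noise_sd = 0, seed = 1,
                                length_mm = c(120, 146, 170))
  expect_equal(exact$weight_g, 7e-6 * c(120, 146, 170)^2.943,
               tolerance = 1e-12)
  expect_equal(exact$weight_g[2], 16.4, tolerance = 0.1)
  flat <- generate_weight_data(n = 1, a = 5, b = 0, noise_sd = 0, seed = 1)
  expect_equal(flat$weight_g, 5)
})

test_that("the GSI table is the fixed empirical profile", {
  gsi <- generate_gsi_table()
  expect_equal(unname(gsi), c(25000, 24747, 23184, 18841))
  expect_equal(names(gsi), as.character(1:4))
  expect_true(all(diff(gsi) < 0))
})

test_that("field data files round-trip through CSV", {
  fish <- generate_trajectories(n_by_age = c(`3` = 2, `4` = 1), seed = 3)
  weights <- generate_weight_data(n = 5, seed = 3)
  gsi <- generate_gsi_table()
  dir <- tempfile("fielddata")
  on.exit(unlink(dir, recursive = TRUE))
  write_field_data(fish, weights, gsi, dir)
  back <- read_field_data(dir)
  expect_equal(back$trajectories, trajectories_to_df(fish),
               tolerance = 1e-12)
  expect_equal(back$weights, weights, tolerance = 1e-12)
  expect_equal(unname(back$gsi), unname(gsi))
})

test_that("parameterize recovers generator truth from clean data", {
  fish <- generate_trajectories(seed = 11)
  weights <- generate_weight_data(n = 27, noise_sd = 0, seed = 11)
  fit <- parameterize(trajectories_to_df(fish), weights,
                      generate_gsi_table())
  expect_equal(fit$lw$a, 7e-6, tolerance = 1e-6)
  expect_equal(fit$lw$b, 2.943, tolerance = 1e-6)
  # single-sample scatter of the slope estimate is ~0.02-0.03
  expect_lt(abs(fit$k_reg$slope - -0.13), 0.05)
  expect_equal(unname(fit$factors[3:4]), c(0.927, 0.754), tolerance = 5e-4)
})
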