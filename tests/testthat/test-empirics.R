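test_that("back_calculate follows the Monastyrsky relation", {
  # single annulus at half the scale radius: 146 * 0.5^0.641
  expect_equal(back_calculate(146, 1, 0.5), 146 * 0.5^0.641,
               tolerance = 1e-12)
  # ratio 1 is impossible (annulus inside scale); near the edge the length
  # approaches the catch length
  expect_equal(back_calculate(146, 1, 1 - 1e-12), 146, tolerance = 1e-6)
  # b_exp = 1 is the linear case
  expect_equal(back_calculate(100, 2, 1, b_exp = 1), 50)
  # invariant to the scale unit
  expect_equal(back_calculate(146, 1, c(0.3, 0.5, 0.7)),
               back_calculate(146, 10, c(3, 5, 7)))
  expect_error(back_calculate(146, 1, c(0.5, 0.4)), "increasing")
  expect_error(back_calculate(146, 1, c(0.5, 1.2)), "smaller")
  expect_length(back_calculate(146, 1, numeric(0)), 0)
})

test_that("fit_vb recovers exact curves and rejects short input", {
  ages <- 1:6
  lens <- vb_length(ages, l_inf = 15.2, k = 0.41, l0 = 1.3)
  fit <- fit_vb(ages, lens)
  expect_equal(fit$l_inf, 15.2, tolerance = 1e-6)
  expect_equal(fit$k, 0.41, tolerance = 1e-6)
  expect_equal(fit$l0, 1.3, tolerance = 1e-5)
  # mm input returns cm
  fit_mm <- fit_vb(ages, 10 * lens, unit = "mm")
  expect_equal(fit_mm$l_inf, 15.2, tolerance = 1e-6)
  expect_error(fit_vb(1:2, lens[1:2]), "at least 3")
})

test_that("fit_vb tolerates measurement noise", {
  set.seed(99)
  ages <- 1:6
  lens <- vb_length(ages, 15, 0.5, 1) + rnorm(6, 0, 0.05)
  fit <- fit_vb(ages, lens)
  expect_equal(fit$l_inf, 15, tolerance = 0.15)
  expect_equal(fit$k, 0.5, tolerance = 0.15)
})

test_that("fit_k_on_linf matches the normal equations", {
  set.seed(5)
  l_inf <- runif(40, 12, 20)
  k <- exp(1.1 - 0.12 * l_inf + rnorm(40, 0, 0.2))
  reg <- fit_k_on_linf(list(l_inf = l_inf, k = k))
  # brute-force OLS
  x <- cbind(1, l_inf)
  beta <- solve(t(x) %*% x, t(x) %*% log(k))
  expect_equal(reg$intercept, beta[1], tolerance = 1e-10)
  expect_equal(reg$slope, beta[2], tolerance = 1e-10)
  res <- log(k) - x %*% beta
  expect_equal(reg$resid_sd, sqrt(sum(res^2) / (40 - 2)), tolerance = 1e-10)
  # also accepts a list of vb_params
  fits <- lapply(1:5, function(i) vb_params(l_inf[i], k[i]))
  expect_s3_class(fit_k_on_linf(fits), "lk_regression")
  expect_error(fit_k_on_linf(list(l_inf = 1:5, k = c(-1, 1, 1, 1, 1))),
               "positive")
  expect_error(fit_k_on_linf(list(l_inf = 1:2, k = c(1, 1))), "at least 3")
})

test_that("fit_length_weight inverts the power law", {
  lens <- c(120, 135, 146, 158, 170)
  w <- 7e-6 * lens^2.943
  fit <- fit_length_weight(lens, w)
  expect_equal(fit$a, 7e-6, tolerance = 1e-8)
  expect_equal(fit$b, 2.943, tolerance = 1e-8)
  # allometry: doubling the length scales weight by 2^b
  expect_equal(predict_weight(2 * 146, fit) / predict_weight(146, fit),
               2^2.943, tolerance = 1e-8)
  expect_error(fit_length_weight(lens, -w), "positive")
})

test_that("fecundity matches the printed worked example", {
  expect_equal(fecundity(18.7), 39.06 + 118.47 * 18.7, tolerance = 1e-12)
  expect_equal(fecundity(18.7), 2254.4, tolerance = 0.1)
  expect_equal(fecundity(0), 39.06)
})

test_that("gsi_to_factors reproduces the published factors", {
  f <- gsi_to_factors(generate_gsi_table())
  expect_equal(unname(f[1]), 0)
  expect_equal(unname(f[2]), 0.990, tolerance = 5e-4)
  expect_equal(unname(f[3]), 0.927, tolerance = 5e-4)
  expect_equal(unname(f[4]), 0.754, tolerance = 5e-4)
  expect_equal(unname(f[5]), 0.612)
  expect_equal(unname(f[6]), 0.498)
  expect_equal(unname(f[7]), unname(f[6])) # age 7 reuses the 6+ factor
  expect_true(all(diff(f[-1]) <= 0))
  non <- gsi_to_factors(generate_gsi_table(), mode = "non-senescent")
  expect_equal(unname(non), c(0, rep(1, 6)))
  expect_error(gsi_to_factors(c(`1` = 25000, `2` = 24747)), "ages 1..4")
  expect_error(gsi_to_factors(-generate_gsi_table()), "positive")
})
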