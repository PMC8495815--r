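test_that("random genotypes have the right shape and frequencies", {
  g <- random_genotypes(50)
  expect_equal(dim(g), c(50L, 20L))
  expect_true(all(g %in% 0:1))
  expect_equal(random_genotypes(10, p = 0),
               matrix(0L, 10, 20))
  expect_equal(random_genotypes(10, p = 1),
               matrix(1L, 10, 20))
  set.seed(1)
  sums <- allele_sum(random_genotypes(20000, p = 0.5))
  # allele sum ~ Binomial(20, 0.5): mean 10, SE of the mean 0.016
  expect_equal(mean(sums), 10, tolerance = 0.015)
})

test_that("inheritance transmits exactly one allele per parent per locus", {
  mother <- matrix(1L, 5, 20)
  father <- matrix(0L, 5, 20)
  set.seed(1)
  child <- inherit_genotypes(mother, father)
  expect_equal(child[, seq(1, 19, 2)], matrix(1L, 5, 10)) # maternal
  expect_equal(child[, seq(2, 20, 2)], matrix(0L, 5, 10)) # paternal
})

test_that("heterozygote transmission is a fair coin at every locus", {
  # both parents heterozygous (1,0) at every locus: each transmitted
  # allele is Bernoulli(0.5) independently
  n <- 20000
  mother <- matrix(rep(c(1L, 0L), n * 10), n, 20, byrow = TRUE)
  father <- mother
  set.seed(2)
  child <- inherit_genotypes(mother, father)
  freq <- colMeans(child)
  expect_true(all(abs(freq - 0.5) < 0.015)) # SE 0.0035 per column
  # and the four locus outcomes at locus 1 are uniform
  combo <- paste0(child[, 1], child[, 2])
  expect_true(all(abs(table(combo) / n - 0.25) < 0.015))
})

test_that("express_linf applies the additive map and the floor", {
  map <- phenotype_map(linf_at_sum0 = 8, linf_per_allele = 0.5, env_sd = 0,
                       floor_cm = 8)
  g0 <- matrix(0L, 3, 20)
  g20 <- matrix(1L, 3, 20)
  expect_equal(express_linf(g0, map), rep(8, 3))
  expect_equal(express_linf(g20, map), rep(18, 3))
  # floor truncates large negative environmental deviations
  map_noise <- phenotype_map(8, 0.5, env_sd = 50, floor_cm = 8)
  set.seed(3)
  expect_true(all(express_linf(matrix(0L, 500, 20), map_noise) >= 8))
})

test_that("midparent-offspring regression recovers known slopes", {
  set.seed(4)
  mid <- rnorm(5000, 13, 1)
  # offspring = midparent exactly: slope 1
  expect_equal(estimate_heritability(mid, mid), 1, tolerance = 1e-12)
  # independent offspring: slope 0
  expect_equal(estimate_heritability(mid, rnorm(5000, 13, 1)), 0,
               tolerance = 0.05)
  expect_error(estimate_heritability(mid[1:10], mid[1:10]), "at least 50")
  expect_error(estimate_heritability(rep(1, 100), rnorm(100)), "degenerate")
})

test_that("h2_experiment is reproducible and decreases with env_sd", {
  set.seed(5)
  geno <- random_genotypes(2000)
  m1 <- phenotype_map(8, 0.5, env_sd = 0.5)
  m2 <- phenotype_map(8, 0.5, env_sd = 3)
  a <- h2_experiment(geno, m1, n_pairs = 3000, seed = 9)
  b <- h2_experiment(geno, m1, n_pairs = 3000, seed = 9)
  expect_identical(a, b)
  expect_gt(a, h2_experiment(geno, m2, n_pairs = 3000, seed = 9))
})

test_that("calibrate_env_sd hits the target heritability", {
  set.seed(6)
  geno <- random_genotypes(2000)
  map <- phenotype_map(8, 0.5)
  sd_hat <- calibrate_env_sd(map, geno, target = 0.25, tol = 0.01,
                             n_pairs = 4000, seed = 11)
  m <- phenotype_map(8, 0.5, env_sd = sd_hat)
  expect_equal(h2_experiment(geno, m, n_pairs = 4000, seed = 11), 0.25,
               tolerance = 0.011)
  expect_error(calibrate_env_sd(map, matrix(1L, 100, 20)),
               "no genetic variance")
})

test_that("allele frequencies drift but stay near 0.5 without selection", {
  # pure inheritance (no selection, constant population) preserves the
  # expected allele frequency
  set.seed(7)
  geno <- random_genotypes(5000)
  for (i in 1:5) {
    idx <- sample.int(nrow(geno))
    geno <- inherit_genotypes(geno, geno[idx, , drop = FALSE])
  }
  expect_equal(mean(geno), 0.5, tolerance = 0.02)
})
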