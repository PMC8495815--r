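#' Draw founder genotypes
#'
#' Each of the 20 alleles (10 diploid loci, two binary alleles each) is an
#' independent Bernoulli draw. The default frequency 0.5 maximizes initial
#' additive variance; the burn-in then finds the stable distribution.
#'
#' @param n Number of individuals.
#' @param p Initial frequency of the 1-allele.
#' @return Integer matrix `n x 20`; columns `2l-1` and `2l` hold the two
#'   alleles of locus `l`.
#' @export
random_genotypes <- function(n, p = 0.5) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  matrix(as.integer(runif(n * 20L) < p), nrow = n, ncol = 20L)
}

#' Allele sum of each genotype
#'
#' @param geno Integer genotype matrix (`n x 20`).
#' @return Integer vector of allele sums in 0..20.
#' @export
allele_sum <- function(geno) {
  as.integer(rowSums(geno))
}


#' Mendelian inheritance of the 10-locus genotype
#'
#' Each offspring receives, at every locus, one uniformly drawn allele from
#' the mother and one from the father. Rows of `mother` and `father` are
#' paired; the result has the same number of rows.
#'
#' @param mother,father Integer genotype matrices (`n x 20`), row-paired.
#' @return Integer genotype matrix of the offspring (`n x 20`); maternal
#'   alleles land in the odd columns, paternal in the even columns.
#' @export
inherit_genotypes <- function(mother, father) {
  stopifnot(is.matrix(mother), is.matrix(father),
            ncol(mother) == 20L, ncol(father) == 20L,
            nrow(mother) == nrow(father))
  storage.mode(mother) <- "integer"
  storage.mode(father) <- "integer"
  n <- nrow(mother)
  .inherit_indexed(rbind(mother, father), seq_len(n), n + seq_len(n),
                   runif(10L * n))
}

#' Express asymptotic length from a genotype
#'
#' `L_inf = linf_at_sum0 + linf_per_allele * allele_sum + N(0, env_sd)`,
#' truncated below at the map's floor. The phenotype is expressed once at
#' birth and fixed for life.
#'
#' @param geno Integer genotype matrix (`n x 20`).
#' @param map A [phenotype_map()].
#' @return Numeric vector of asymptotic lengths (cm).
#' @export
express_linf <- function(geno, map = phenotype_map()) {
  stopifnot(inherits(map, "phenotype_map"))
  n <- nrow(geno)
  val <- map$linf_at_sum0 + map$linf_per_allele * rowSums(geno)
  if (map$env_sd > 0) val <- val + rnorm(n, 0, map$env_sd)
  pmax(val, map$floor_cm)
}

#' Estimate heritability by midparent-offspring regression
#'
#' Classical narrow-sense heritability estimate: the OLS slope of mean
#' offspring phenotype on midparent phenotype.
#'
#' @param midparent Midparent phenotypes (mean of the two parents).
#' @param offspring Offspring phenotypes (one value, or a mean, per pair).
#' @return The estimated h-squared (slope).
#' @export
estimate_heritability <- function(midparent, offspring) {
  stopifnot(length(midparent) == length(offspring))
  if (length(midparent) < 50)
    stop("need at least 50 midparent-offspring pairs")
  if (stats::var(midparent) < .Machine$double.eps)
    stop("midparent phenotypes are degenerate (zero variance)")
  unname(coef(lm(offspring ~ midparent))[2])
}

#' Simulated midparent-offspring heritability for a genotype pool
#'
#' Draws `n_pairs` parent pairs (with replacement) from the genotype pool,
#' expresses both parents and one offspring per pair with the given map,
#' and returns the midparent-offspring regression slope. This is the
#' forward experiment that [calibrate_env_sd()] inverts.
#'
#' @param genotypes Integer genotype matrix (`n x 20`) describing the
#'   population's genotype distribution.
#' @param map A [phenotype_map()].
#' @param n_pairs Number of mating pairs to simulate.
#' @param seed Optional integer seed.
#' @return Estimated h-squared.
#' @export
h2_experiment <- function(genotypes, map, n_pairs = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(genotypes)
  stopifnot(n >= 2)
  mi <- sample.int(n, n_pairs, replace = TRUE)
  fi <- sample.int(n, n_pairs, replace = TRUE)
  gm <- genotypes[mi, , drop = FALSE]
  gf <- genotypes[fi, , drop = FALSE]
  pm <- express_linf(gm, map)
  pf <- express_linf(gf, map)
  off <- express_linf(inherit_genotypes(gm, gf), map)
  estimate_heritability((pm + pf) / 2, off)
}

#' Calibrate the environmental SD to a target heritability
#'
#' Bisection on `env_sd` so that the simulated midparent-offspring
#' heritability (see [h2_experiment()]) matches the target. Common random
#' numbers (one seed reused at every candidate) make the simulated h2
#' monotone in `env_sd`, so bisection is well behaved and the result is
#' deterministic for a fixed seed.
#'
#' @param map A [phenotype_map()]; its `env_sd` entry is ignored.
#' @param genotypes Genotype matrix of the (equilibrium) population.
#' @param target Target heritability (default 0.25, centre of the
#'   realistic 0.2--0.3 band).
#' @param tol Convergence tolerance on the simulated h2.
#' @param n_pairs Pairs per evaluation.
#' @param seed Integer seed for the common random numbers.
#' @param max_iter Bisection iterations.
#' @return The calibrated `env_sd` (cm).
#' @export
calibrate_env_sd <- function(map, genotypes, target = 0.25, tol = 0.01,
                             n_pairs = 5000, seed = 1L, max_iter = 60L) {
  stopifnot(target > 0, target <= 1, tol > 0)
  if (stats::var(rowSums(genotypes)) < .Machine$double.eps)
    stop("population has no genetic variance; heritability target unreachable")
  eval_h2 <- function(sd) {
    m <- phenotype_map(map$linf_at_sum0, map$linf_per_allele, sd,
                       map$floor_cm)
    h2_experiment(genotypes, m, n_pairs = n_pairs, seed = seed)
  }
  h2_max <- eval_h2(0)
  if (h2_max < target - tol)
    stop(sprintf(
      "target h2 %.3f exceeds the additive maximum %.3f for this population",
      target, h2_max))
  if (abs(h2_max - target) <= tol) return(0)
  lo <- 0
  hi <- map$linf_per_allele * 20
  while (eval_h2(hi) > target && hi < 1e3) hi <- hi * 2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    h2 <- eval_h2(mid)
    if (abs(h2 - target) <= tol) return(mid)
    if (h2 > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
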