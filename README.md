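# vendasim

An individual-based eco-evolutionary model of a vendace-like coregonid
fish population, built to ask how **senescence** changes what fishing
does to a stock. The von Bertalanffy asymptotic length `L_inf` is an
evolving quantitative trait carried by 10 diploid biallelic loci;
individuals grow under density-dependent regulation, mature at 67% of
their own asymptotic length, reproduce with weight-based fecundity, and
die under either a constant or an age-increasing natural mortality
schedule. Two senescence switches define the study contrast:

* **Reproductive senescence** — fecundity is discounted by age-specific
  factors derived from the median gonadosomatic index (0.990, 0.927,
  0.754, 0.612, 0.498 for ages 2–6+).
* **Actuarial senescence** — instantaneous natural mortality increases
  with age (0.2 → 0.428) instead of staying at 0.257.

Populations are burned in for 1,000 unfished years and then run through
a 500-year scenario: 200 pristine years, 100 years of size-selective
harvest (logistic trawl/seine or dome-shaped gillnet selectivity,
F = 0.7), and 200 recovery years, replicated from one master seed.

The package also implements the **empirical parameterization stage**
(Monastyrsky scale back-calculation, per-fish von Bertalanffy fits, the
`ln(k)`–`L_inf` regression, the length–weight power law, GSI-derived
fecundity factors) and a **synthetic field-data generator** that
emulates the statistical structure of the original lake samples (93
scale-read growth trajectories, 27 length–weight pairs, a GSI-by-age
table), so the whole pipeline is testable without the unavailable raw
data.

## Worked example

```r
library(vendasim)

## 1. Parameterization from (synthetic) field data
fish <- generate_trajectories(seed = 1)       # 93 scale-read trajectories
weights <- generate_weight_data(seed = 1)     # 27 length-weight pairs
params <- parameterize(trajectories_to_df(fish), weights, generate_gsi_table())
cat(sprintf("ln(k) = %.3f %+.3f * L_inf (resid SD %.3f)\n",
            params$k_reg$intercept, params$k_reg$slope, params$k_reg$resid_sd))
cat(sprintf("W = %.3g * L^%.3f\n", params$lw$a, params$lw$b))
print(round(params$factors, 3))

## 2. Burn a population in to its unfished equilibrium
cfg <- sim_config(reproductive_senescence = TRUE, actuarial_senescence = TRUE)
bi <- burn_in(cfg, seed = 1)
print(bi)
print(bi$population)

## 3. Harvest scenario: 200 pristine + 100 trawl + 200 recovery years
runs <- run_scenario(cfg, list(bi$population), gear = "trawl",
                     n_replicates = 5, seed = 1)
s <- summarize_replicates(runs)
linf <- s$mean_l_inf
cat(sprintf("mean L_inf: pristine %.2f cm -> end of fishing %.2f cm -> end of recovery %.2f cm\n",
            mean(linf$mean[101:200]), linf$mean[300], linf$mean[500]))
```

Output:

```
ln(k) = 1.129 -0.121 * L_inf (resid SD 0.288)
W = 7.51e-06 * L^2.929
    1     2     3     4     5     6     7
0.000 0.990 0.927 0.754 0.612 0.498 0.498
burn-in: 1000 years, final 100-yr mean biomass 58.8 units (trend +0.001/yr, stable)
fish_population: 18421 individuals (12218 adults age>=2, 48.9% mature, mean length 8.1 cm)
mean L_inf: pristine 12.21 cm -> end of fishing 11.20 cm -> end of recovery 12.20 cm
```

The recovered regression is the empirical `ln(k) = 1.27 - 0.13 L_inf`
within sampling error of a 93-fish sample, the equilibrium biomass sits
in the 56–61 unit calibration band, and trawling drives the evolving
asymptotic length down about 1 cm over the fishing century.

A dome-shaped gillnet (`gear = "gillnet"`) targets the 12-cm peak
instead and removes less of the small, fast-maturing phenotypes; a
biomass-quota mode (`quota_series =`) keeps removed biomass identical
between paired gear scenarios. See `vignette("senescence-fishery-model")`
for the full model description and every calibrated constant.

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic data | `generate_trajectories()`, `generate_weight_data()`, `generate_gsi_table()`, `write_field_data()` |
| Parameterization | `back_calculate()`, `fit_vb()`, `fit_k_on_linf()`, `fit_length_weight()`, `fecundity()`, `gsi_to_factors()`, `parameterize()` |
| Genetics | `random_genotypes()`, `inherit_genotypes()`, `express_linf()`, `estimate_heritability()`, `calibrate_env_sd()` |
| Vital rates | `grow_length()`, `check_maturation()`, `eggs_produced()`, `natural_mortality_rate()`, `survive_natural()` |
| Fishery | `selectivity_logistic()`, `selectivity_dome()`, `retention()`, `apply_fishing()`, `match_quota_f()` |
| Engine | `sim_config()`, `founder_population()`, `annual_step()`, `burn_in()`, `run_scenario()`, `calibrate_dd_slope()` |
| Reporting | `summarize_replicates()`, `relative_change()`, `size_age_distribution()`, `plot_summary()` |
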