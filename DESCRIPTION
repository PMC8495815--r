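Package: vendasim
Title: Individual-Based Eco-Evolutionary Simulation of a Senescing
    Coregonid Fish Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An individual-based eco-evolutionary model of a vendace-like
    (Coregonus albula) fish population in which asymptotic length is an
    evolving quantitative trait encoded by ten diploid biallelic loci.
    Individuals grow along von Bertalanffy trajectories under
    density-dependent growth regulation, mature at a fixed fraction of
    their asymptotic length, reproduce with weight-based fecundity
    optionally discounted by age-specific gonadosomatic-index factors
    (reproductive senescence), and die under constant or age-increasing
    instantaneous natural mortality (actuarial senescence). Populations
    can be harvested with logistic (trawl/seine) or dome-shaped (gillnet)
    size selectivity across pristine, fishing and recovery phases. The
    package also implements the empirical parameterization stage
    (scale-based back-calculation of length at age, von Bertalanffy
    fitting, the ln(k)-versus-asymptotic-length regression, length-weight
    and fecundity fits) and a synthetic field-data generator with the
    statistical structure of the original lake samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
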