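# Shared, lazily computed fixtures. Burn-ins are the expensive shared
# resource (a 1,000-year burn-in takes ~20 s), so each configuration is
# burned in at most once per test session and reused by every file.
.vendasim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .vendasim_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .vendasim_cache)
  }
  get(key, envir = .vendasim_cache, inherits = FALSE)
}

# Default no-senescence configuration and its equilibrium burn-in.
nonsen_config <- function() {
  sim_config(reproductive_senescence = FALSE, actuarial_senescence = FALSE)
}

sen_config <- function() {
  sim_config(reproductive_senescence = TRUE, actuarial_senescence = TRUE)
}

nonsen_burnin <- function() {
  cached("nonsen_burnin", burn_in(nonsen_config(), seed = 1L))
}

sen_burnin <- function() {
  cached("sen_burnin", burn_in(sen_config(), seed = 1L))
}
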