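# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# Small noiseless two-site study with a high-N treatment; truth
# f_S known per site, ferteff(high) = 1.5.
noiseless_study <- function() memo("noiseless", {
  tru <- truth_parameters(soc_cv = 0, yield_cv = 0)
  generate_study(synthetic_designs(n_sites = 2, seed = 11), tru,
                 seed = 11)
})

# Same designs with the default 10% observation noise.
noisy_study <- function() memo("noisy", {
  generate_study(synthetic_designs(n_sites = 2, seed = 11),
                 truth_parameters(), seed = 11)
})

noisy_fit <- function() memo("noisy_fit", fit_soc(noisy_study()$study))

# A single-site, unfertilized study where only one f_S is estimated.
one_param_study <- function() memo("one_param", {
  des <- synthetic_designs(n_sites = 1, seed = 5)[1]
  des[[1]]$treatments <- des[[1]]$treatments[
    vapply(des[[1]]$treatments, function(tr) tr$n_rate == 0 &&
             tr$om_rate == 0, TRUE)]
  generate_study(des, truth_parameters(soc_cv = 0, yield_cv = 0),
                 seed = 5)
})

# Kinetics with a single nonzero rate on the slow pool (per-month k).
slow_only_kinetics <- function(k_per_month) {
  kin <- century_kinetics()
  kin$kbase[] <- 0
  kin$kbase["slow"] <- k_per_month
  kin
}
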