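# Shared fixtures. Expensive simulations are memoised so that several test
# files can reuse the reference run without re-integrating.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

zero_pulse <- function(duration = 0.8e-3, sample_rate = 800e3) {
  t <- seq(0, duration, by = 1 / sample_rate)
  force_pulse(t, numeric(length(t)))
}

reference_sim <- function() {
  memo("reference_sim", simulate_chain(chain_config(), pulse_half_sine()))
}

# blows of deliberately different amplitude and width: amplitude diversity
# probes different insertion depths and so identifies the friction law
diverse_pulses <- function() {
  list(pulse_half_sine(2000, 0.20e-3),
       pulse_half_sine(9247, 0.140e-3),
       pulse_half_sine(16000, 0.10e-3))
}

# a generating truth within +/-15% of the catalogue values, fixed seed
recovery_truth <- function() {
  withr::with_seed(42, {
    free <- parameter_space()[parameter_space()$free, ]
    fac <- stats::runif(nrow(free), 0.85, 1.15)
    truth <- as.list(stats::setNames(free$default * fac, free$parameter))
    truth$mu_kinetic <- min(truth$mu_kinetic, truth$mu_static)
    truth
  })
}

total_chain_mass <- function(chain = chain_config()) {
  sum(unlist(chain[c("impactor_mass", "loadcell_mass", "tip_mass",
                     "head_mass", "stem_mass", "tissue_mass")]))
}
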