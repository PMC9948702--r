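# Shared oracles and small fixtures.

# closed form of the 1-D logistic equation dx/dt = r x (1 - x/K)
logistic_closed_form <- function(x0, r, K, t) {
  K * x0 * exp(r * t) / (K + x0 * (exp(r * t) - 1))
}

# the measured rate vector for the barren ecology with all four strains
printed_rates <- c(ADE = 0.804, TRP = 0.869, HIS = 1.157, LYS = 0.732)

# small, fast configuration for engine-level tests
quick_config <- function(...) {
  args <- utils::modifyList(list(n_wells = 24L, n_cycles = 4L), list(...))
  do.call(cycle_config, args)
}

# ecology distribution putting all mass on one index
point_mass_dist <- function(index) {
  d <- numeric(16)
  d[index] <- 1
  d
}

# growth parameters with all strains identical (exchangeable system)
symmetric_params <- function(rate = 1) {
  growth_params(base_rates = rep(rate, 4), pool_rates = rep(rate, 4),
                overrides = NULL)
}
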