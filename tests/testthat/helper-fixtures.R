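# Shared fixtures: study-condition parameters and small builders used
# across the test files. Everything is generated in code at test time.

study_rates <- function(mechanism = "secondary") {
  default_rates(mechanism)
}

# normalized traces at the study conditions (100 uM, seeds 0/0.25/1%)
make_normalized_set <- function(noise = 0.01, seed = 1, ...) {
  lapply(gen_kinetic_traces(noise = noise, seed = seed, ...),
         normalize_trace)
}

# primary-nucleation-only data: unseeded curves at three concentrations
# (lambda = 0.1 per hour at 100 uM)
make_primary_set <- function(noise = 0.01, seed = 1) {
  rates <- rate_constants(kn = 5e-6, nc = 1, kplus = 10)
  lapply(gen_kinetic_traces(rates = rates,
                            m_total = c(50, 100, 200), seed_pct = 0,
                            times = seq(0, 40, by = 1 / 6),
                            noise = noise, seed = seed),
         normalize_trace)
}

# bulk trajectories for the oligomer tests (unseeded and 1% seeded)
make_bulk_pair <- function(times = seq(0, 40, by = 0.2)) {
  rc <- study_rates()
  list(unseeded = simulate_fibril_mass(rc, 100, 0, 0, times),
       seeded = simulate_fibril_mass(rc, 100, 1, 1 / 2000, times))
}

# symmetric logistic normalized trace with a known midpoint
logistic_trace <- function(midpoint = 5, rate = 2,
                           times = seq(0, 3 * midpoint, by = 0.01)) {
  normalized_trace(times, stats::plogis(rate * (times - midpoint)))
}
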