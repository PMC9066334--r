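# Independent per-patient microsimulation oracle: walks individual
# patients through the same per-cycle transition matrices and returns
# occupancy fractions. Used to cross-check the cohort (expected-value)
# propagation against sampling.

microsim_trace <- function(params, strategy, n_walkers, horizon, seed) {
  set.seed(seed)
  n_states <- nrow(enumerate_states())
  bands <- afcea:::mortality_band_index(
    params$start_age_years + (seq_len(horizon) - 1L) / 12)
  ubands <- sort(unique(bands))
  mats <- lapply(ubands, function(b)
    afcea:::cycle_components(params, strategy, b)$M)
  names(mats) <- as.character(ubands)
  counts <- integer(n_states)
  counts[1L] <- n_walkers
  occ <- matrix(0, horizon + 1L, n_states)
  occ[1L, ] <- counts / n_walkers
  for (t in seq_len(horizon)) {
    M <- mats[[as.character(bands[t])]]
    new_counts <- integer(n_states)
    for (s in which(counts > 0L)) {
      new_counts <- new_counts +
        as.integer(stats::rmultinom(1, counts[s], M[s, ]))
    }
    counts <- new_counts
    occ[t + 1L, ] <- counts / n_walkers
  }
  occ
}

# fixture accessor shared across test files
base_params <- function() default_parameters()
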