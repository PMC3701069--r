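# Shared fixtures, built in code.

# Kinetics with zero peak conductance: channels silenced, passive cable.
zero_kinetics <- function(species = "Na", t_star = 1e-4) {
  channel_kinetics(species, t_star = t_star, G_star = 0)
}

passive_chain <- function(n_nodes = 2, ...) {
  node_chain(n_nodes = n_nodes,
             kinetics_na = zero_kinetics("Na", 1e-4),
             kinetics_k = zero_kinetics("K", 5e-4), ...)
}

# Memoised canonical simulations so multiple test files reuse one run.
.sim_cache <- new.env(parent = emptyenv())
canonical_sim <- function(scenario = "normal", dt_us = 0.1, tmax_ms = 2) {
  key <- paste(scenario, dt_us, tmax_ms, sep = "|")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- suppressWarnings(
      run_axon_config(axon_config(scenario, dt_us = dt_us, tmax_ms = tmax_ms),
                      trace = FALSE))
  .sim_cache[[key]]
}
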