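# Shared simulation results for the slower protocol-level tests. Sweeps are
# computed once per test run on first use and reused across test files.
.sweep_cache <- new.env(parent = emptyenv())

cached_sweep <- function(condition, protocol, beta_step = 0.1) {
  key <- paste(condition, protocol, beta_step, sep = "_")
  if (is.null(.sweep_cache[[key]])) {
    .sweep_cache[[key]] <- run_sweep(condition, protocol, beta_step = beta_step)
  }
  .sweep_cache[[key]]
}

# single-population network with a direct external conductance, used for
# closed-form integrator checks and single-burster regime probes
single_pop_network <- function(id = "RG-F-L", params = default_params()) {
  net <- build_network("intact", params)
  net$populations <- net$populations[net$populations$id == id, ]
  net$connections <- net$connections[0, ]
  net$connections <- tibble::add_row(net$connections,
    source = "drive-alphaL", target = id, weight = 1,
    sign = "excitatory", crossed = FALSE, type = "drive")
  net
}

run_single_pop <- function(net, gE, duration = 25, V0 = -64, h0 = 0.9, dt = NULL) {
  simulate_gait(net, 0, 0, duration = duration, dt = dt, feedback = FALSE,
                drives = list(alphaL = gE, alphaR = 0, gammaL = 0, gammaR = 0),
                init = list(V0 = V0, h0 = h0))
}
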