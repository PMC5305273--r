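# Shared miniature builders for the test suite.  Everything is generated in
# code from fixed seeds; nothing is read from disk.

window_rate_ <- replaynet:::window_rate

# A small isolated-neuron network (no synapses) for single-cell dynamics.
single_neuron_net <- function(seed = 1) {
  build_background(network_spec(N_E = 1, N_I = 0, p_rand = 0, M = 0,
                                n_groups = 0, seed = seed))
}

# Scaled-down version of the reference network: same assembly size, gamma
# size scaling (conductances up, assembly connectivities down) so that the
# effective coupling kappa is preserved.
scaled_spec <- function(N_E = 2000, p_rc = 0.06, p_ff = 0.06, n_groups = 3,
                        wiring_mode = "feedforward", seed = 1, M = 500) {
  base <- network_spec(p_rc = p_rc, p_ff = p_ff, n_groups = n_groups,
                       wiring_mode = wiring_mode, seed = seed, M = M)
  scale_network(base, gamma = N_E / base$N_E)$spec
}

# Deterministic two-neuron chain 1 -> 2 with adjustable conductance.
two_neuron_chain <- function(g = 1, seed = 1) {
  conn <- build_background(network_spec(N_E = 2, N_I = 0, p_rand = 0,
                                        M = 0, n_groups = 0, seed = seed))
  conn$synapses <- data.frame(pre = 1L, post = 2L, class = "EE",
                              g_nS = g, delay_ms = 2)
  conn
}

# Synthetic raster: one Gaussian volley per group around given centres.
volley_raster <- function(groups, centres, jitter = 2, seed = 1) {
  with_substream(seed, "volley", {
    pieces <- lapply(seq_along(groups), function(k) {
      ids <- groups[[k]]
      data.frame(time_ms = rnorm(length(ids), centres[k], jitter),
                 neuron = ids)
    })
    df <- do.call(rbind, pieces)
    df[order(df$time_ms), ]
  })
}
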