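# Pure-function form of the homeostatic inhibitory STDP rule.  The engine
# applies the identical updates inside its event loop; these entry points
# expose the rule for analysis and testing.

#' Inhibitory STDP update at a presynaptic (inhibitory) spike
#'
#' `g' = max(g_min, g + eta * (x_post - alpha))`: depression when the
#' postsynaptic trace is below the bias `alpha = 2 rho_0 tau_STDP`,
#' potentiation above it.  This is what makes the rule homeostatic — for
#' independent Poisson firing the expected drift is
#' `eta * rho_pre * (2 rho_post tau_STDP - alpha)`, which vanishes exactly
#' when the postsynaptic neuron fires at the target rate `rho_0`.
#'
#' @param g_EI current synaptic conductance (nS).
#' @param x_post postsynaptic spike trace at the moment of the spike.
#' @param params [plasticity_params()].
#' @return Updated conductance (nS).
#' @export
#' @examples
#' stdp_on_pre(0.4, x_post = 0, plasticity_params())  # 0.4 - 0.005*0.2
stdp_on_pre <- function(g_EI, x_post, params = plasticity_params()) {
  pmax(params$g_min, g_EI + params$eta * (x_post - params$alpha))
}

#' Inhibitory STDP update at a postsynaptic (excitatory) spike
#'
#' `g' = max(g_min, g + eta * x_pre)` — always potentiating, so that
#' near-coincident pre- and postsynaptic firing strengthens inhibition.
#'
#' @inheritParams stdp_on_pre
#' @param x_pre presynaptic spike trace at the moment of the spike.
#' @export
stdp_on_post <- function(g_EI, x_pre, params = plasticity_params()) {
  pmax(params$g_min, g_EI + params$eta * x_pre)
}

#' Decay and increment spike traces
#'
#' Exponential decay over `dt` followed by a unit increment for every neuron
#' that spiked in the step: `x <- x * exp(-dt/tau_STDP); x[spikes] + 1`.
#'
#' @param x trace vector.
#' @param dt time step (ms).
#' @param spikes indices of neurons that spiked.
#' @inheritParams stdp_on_pre
#' @export
stdp_decay_traces <- function(x, dt, spikes = integer(0),
                              params = plasticity_params()) {
  x <- x * exp(-dt / params$tau_STDP)
  if (length(spikes)) x[spikes] <- x[spikes] + 1
  x
}

#' Trace of a spike train evaluated at given times
#'
#' Convenience closed form: the value of an STDP trace driven by `spike_times`
#' read out at `at` (shot-noise sum of decaying exponentials).
#'
#' @param spike_times spike times (ms).
#' @param at read-out times (ms).
#' @inheritParams stdp_on_pre
#' @return Trace values at `at`.
#' @export
trace_at <- function(spike_times, at, params = plasticity_params()) {
  vapply(at, function(t) {
    d <- t - spike_times[spike_times <= t]
    sum(exp(-d / params$tau_STDP))
  }, numeric(1))
}
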