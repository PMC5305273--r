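#' Neuron model parameters
#'
#' Parameters of the conductance-based leaky integrate-and-fire neuron.  The
#' membrane potential obeys
#' \deqn{C \, dV/dt = G^{leak}(V^{rest}-V) + G^E(V^E-V) + G^I(V^I-V) + I^{ext},}
#' synaptic conductances decay exponentially, and a threshold crossing resets
#' \eqn{V} to \eqn{V^{rest}} for a refractory period.  Defaults give a
#' membrane time constant of \eqn{C/G^{leak} = 20} ms, and the constant
#' driving current of 200 pA makes an isolated neuron fire tonically
#' (asymptotic potential \eqn{-40} mV, above threshold).
#'
#' @param C membrane capacitance (pF).
#' @param G_leak leak conductance (nS).
#' @param V_rest resting/reset potential (mV).
#' @param V_th spike threshold (mV).
#' @param V_E excitatory reversal potential (mV).
#' @param V_I inhibitory reversal potential (mV).
#' @param tau_rp absolute refractory period (ms).
#' @param tau_E excitatory synaptic time constant (ms).
#' @param tau_I inhibitory synaptic time constant (ms).
#' @param I_const constant driving current to every neuron (pA).
#' @param I_e extra population-wide current to excitatory neurons (pA).
#' @param I_i extra population-wide current to inhibitory neurons (pA).
#' @return An object of class `neuron_params`.
#' @export
#' @examples
#' np <- neuron_params()
#' np$C / np$G_leak   # membrane time constant, ms
neuron_params <- function(C = 200, G_leak = 10, V_rest = -60, V_th = -50,
                          V_E = 0, V_I = -80, tau_rp = 2, tau_E = 5,
                          tau_I = 10, I_const = 200, I_e = 0, I_i = 0) {
  p <- list(C = C, G_leak = G_leak, V_rest = V_rest, V_th = V_th,
            V_E = V_E, V_I = V_I, tau_rp = tau_rp, tau_E = tau_E,
            tau_I = tau_I, I_const = I_const, I_e = I_e, I_i = I_i)
  if (!(p$V_I < p$V_rest && p$V_rest < p$V_th && p$V_th < p$V_E)) {
    stop("neuron_params: require V_I < V_rest < V_th < V_E")
  }
  if (any(c(p$C, p$G_leak, p$tau_rp, p$tau_E, p$tau_I) <= 0)) {
    stop("neuron_params: capacitance, conductance and time constants must be positive")
  }
  class(p) <- "neuron_params"
  p
}

#' Inhibitory plasticity parameters
#'
#' Parameters of the homeostatic spike-timing-dependent rule acting on
#' inhibitory-to-excitatory synapses.  Every neuron carries a spike trace
#' \eqn{x} that is incremented at spikes and decays with `tau_STDP`.  A
#' presynaptic (inhibitory) spike changes the synapse by
#' \eqn{\eta(x_{post}-\alpha)}, a postsynaptic spike by \eqn{\eta x_{pre}},
#' with depression bias \eqn{\alpha = 2\rho_0\tau_{STDP}} fixing the target
#' postsynaptic rate \eqn{\rho_0}.
#'
#' @param tau_STDP trace time constant (ms).
#' @param eta learning rate (dimensionless).
#' @param rho_0 target excitatory firing rate (spikes/s).
#' @param g_min lower bound on the plastic conductance (nS).
#' @return An object of class `plasticity_params` with the derived `alpha`.
#' @export
#' @examples
#' plasticity_params()$alpha   # 2 * 5/s * 20 ms = 0.2
plasticity_params <- function(tau_STDP = 20, eta = 0.005, rho_0 = 5,
                              g_min = 0) {
  if (eta < 0) stop("plasticity_params: eta must be >= 0")
  if (tau_STDP <= 0) stop("plasticity_params: tau_STDP must be > 0")
  p <- list(tau_STDP = tau_STDP, eta = eta, rho_0 = rho_0, g_min = g_min,
            alpha = 2 * rho_0 * tau_STDP / 1000)
  class(p) <- "plasticity_params"
  p
}

#' Network specification
#'
#' Static description of one network experiment: population sizes, background
#' and assembly connectivities, synaptic conductances, wiring mode of the
#' embedded sequence, and the experiment seed.  Each assembly consists of `M`
#' excitatory and `M/4` inhibitory neurons.
#'
#' @param N_E,N_I numbers of excitatory and inhibitory neurons.
#' @param p_rand background connection probability.
#' @param M assembly size (excitatory members; `M` must be divisible by 4).
#' @param n_groups number of assemblies in the sequence.
#' @param p_rc recurrent within-assembly connection probability.
#' @param p_ff feedforward between-assembly connection probability.
#' @param wiring_mode `"feedforward"`, `"symmetric"`, or `"continuous"`.
#' @param g_E excitatory synaptic conductance (nS).
#' @param g_ff feedforward synaptic conductance (nS, default `g_E`).
#' @param g_I inhibitory conductance onto inhibitory targets (nS).
#' @param g_EI_init initial inhibitory-to-excitatory conductance (nS); these
#'   synapses are plastic.
#' @param delay synaptic delay (ms), identical for all synapses.
#' @param seed experiment seed; all stochastic stages derive named substreams
#'   from it (see [with_substream()]).
#' @return An object of class `network_spec`.
#' @export
#' @examples
#' spec <- network_spec(N_E = 1000, N_I = 250, M = 100, n_groups = 4)
network_spec <- function(N_E = 20000, N_I = 5000, p_rand = 0.01,
                         M = 500, n_groups = 10, p_rc = 0.06, p_ff = 0.06,
                         wiring_mode = c("feedforward", "symmetric",
                                         "continuous"),
                         g_E = 0.1, g_ff = g_E, g_I = 0.4, g_EI_init = 0.4,
                         delay = 2, seed = 1L) {
  wiring_mode <- match.arg(wiring_mode)
  spec <- list(N_E = as.integer(N_E), N_I = as.integer(N_I), p_rand = p_rand,
               M = as.integer(M), n_groups = as.integer(n_groups),
               p_rc = p_rc, p_ff = p_ff, wiring_mode = wiring_mode,
               g_E = g_E, g_ff = g_ff, g_I = g_I, g_EI_init = g_EI_init,
               delay = delay, seed = as.integer(seed))
  validate_network_spec(spec)
  class(spec) <- "network_spec"
  spec
}

validate_network_spec <- function(spec) {
  probs <- c(p_rand = spec$p_rand, p_rc = spec$p_rc, p_ff = spec$p_ff)
  if (any(probs < 0 | probs > 1)) {
    stop("network_spec: connection probabilities must lie in [0, 1] (got ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "), ")")
  }
  if (spec$N_E < 0 || spec$N_I < 0) {
    stop("network_spec: population sizes must be non-negative")
  }
  if (spec$M %% 4L != 0L) {
    stop("network_spec: M must be divisible by 4 (inhibitory subgroup M/4)")
  }
  if (spec$wiring_mode != "continuous") {
    if (spec$n_groups * spec$M > spec$N_E) {
      stop("network_spec: n_groups * M exceeds N_E; assemblies must be disjoint")
    }
    if (spec$N_I > 0 && spec$n_groups * spec$M / 4 > spec$N_I) {
      stop("network_spec: n_groups * M/4 exceeds N_I")
    }
  }
  g <- c(spec$g_E, spec$g_ff, spec$g_I, spec$g_EI_init)
  if (any(g < 0)) stop("network_spec: conductances must be >= 0")
  if (spec$delay <= 0) stop("network_spec: delay must be positive")
  invisible(spec)
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>\n")
  cat(sprintf("  N_E = %d, N_I = %d, p_rand = %g\n", x$N_E, x$N_I, x$p_rand))
  cat(sprintf("  sequence: %d groups of M = %d (%s wiring), p_rc = %g, p_ff = %g\n",
              x$n_groups, x$M, x$wiring_mode, x$p_rc, x$p_ff))
  cat(sprintf("  g_E = %g nS, g_ff = %g nS, g_I = %g nS, g_EI(init) = %g nS, delay = %g ms\n",
              x$g_E, x$g_ff, x$g_I, x$g_EI_init, x$delay))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
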