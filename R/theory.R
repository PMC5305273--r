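# Mean-field theory of assembly-sequence replay: the effective feedforward
# amplification factor and its critical line, closed-form response times,
# the diffusion approximation of the stationary rate with the resulting
# estimate of the transfer-function slope, and the size-scaling laws.

#' Effective feedforward amplification factor
#'
#' Linearising the coupled excitatory/inhibitory assembly dynamics around
#' the balanced state gives the rate transfer from one assembly to the next,
#' \deqn{\kappa = w_{ff}\,\frac{1 + k\,w_{rc}}{1 + (k-1)\,w_{rc}},}
#' with dimensionless couplings \eqn{w_{rc} = c M p_{rc} g^E} and
#' \eqn{w_{ff} = c M p_{ff} g_{ff}}.  For inhibition exactly balancing
#' excitation (`k = 1`) this reduces to
#' \eqn{\kappa = c M p_{ff} g_{ff} (1 + c M p_{rc} g^E)}.  Replay is
#' marginally stable at \eqn{\kappa = 1}: recurrence within assemblies
#' effectively scales up the feedforward connectivity.
#'
#' @param p_ff feedforward connection probability.
#' @param p_rc recurrent connection probability.
#' @param M assembly size.
#' @param g_E recurrent excitatory conductance (nS).
#' @param g_ff feedforward conductance (nS, default `g_E`).
#' @param c transfer-function slope (1/nS).
#' @param k inhibition/excitation coupling ratio (>= 1).
#' @return kappa (dimensionless).
#' @export
#' @examples
#' amplification_factor(p_ff = 0.04, p_rc = 0.08, M = 500,
#'                      g_E = 0.1, c = 0.25)   # the calibration point: 1
amplification_factor <- function(p_ff, p_rc, M = 500, g_E = 0.1,
                                 g_ff = g_E, c = 0.25, k = 1) {
  w_rc <- c * M * p_rc * g_E
  w_ff <- c * M * p_ff * g_ff
  w_ff * (1 + k * w_rc) / (1 + (k - 1) * w_rc)
}

#' Critical recurrent connectivity for marginal replay
#'
#' Inverts `kappa = 1` (with `k = 1`) for `p_rc`:
#' \deqn{p_{rc} = \frac{1}{cMg^E}\left(\frac{1}{cMp_{ff}g_{ff}} - 1\right).}
#' Values <= 0 mean the feedforward coupling alone already reaches the
#' critical line (no recurrence required).
#'
#' @inheritParams amplification_factor
#' @return Critical `p_rc` (may be negative; see above).
#' @export
critical_line <- function(p_ff, M = 500, g_E = 0.1, g_ff = g_E, c = 0.25) {
  (1 / (c * M * g_E)) * (1 / (c * M * p_ff * g_ff) - 1)
}

#' Fit the transfer-function slope from a critical point
#'
#' Solves \eqn{\kappa(c) = cMp_{ff}g_{ff}(1 + cMp_{rc}g^E) = 1} for the
#' positive root of the quadratic in `c`.  At the calibration connectivities
#' `p_rc = 0.08`, `p_ff = 0.04` (with `M = 500`, `g = 0.1` nS) this yields
#' `c = 0.25` 1/nS.
#'
#' @inheritParams amplification_factor
#' @return Slope `c` in 1/nS.
#' @export
fit_c <- function(p_rc, p_ff, M = 500, g_E = 0.1, g_ff = g_E) {
  a <- M^2 * p_ff * g_ff * p_rc * g_E
  b <- M * p_ff * g_ff
  if (b <= 0) stop("fit_c: p_ff * g_ff must be positive")
  if (a == 0) return(1 / b)
  (-b + sqrt(b^2 + 4 * a)) / (2 * a)
}

#' Synapse budget of one association on the critical line
#'
#' For a given within-assembly connectivity `p_rc`, solves `kappa = 1` for
#' the feedforward connectivity `p_ff*` and reports the per-neuron number of
#' new synapses `round(M (p_rc + p_ff*))` together with the association
#' totals `M^2 p_ff*` and `M^2 (p_rc + p_ff*)`.  The per-neuron budget is
#' minimal at `p_rc = 0` (40 synapses for the default constants), but grows
#' only mildly with recurrence (50 at `p_rc = 0.05`, 111 at `p_rc = 0.2`).
#'
#' @inheritParams amplification_factor
#' @return List: `p_ff_crit`, `per_neuron`, `ff_total`, `total`.
#' @export
synapse_budget <- function(p_rc, M = 500, g_E = 0.1, c = 0.25, g_ff = g_E) {
  p_ff <- 1 / (c * M * g_ff * (1 + c * M * p_rc * g_E))
  list(p_ff_crit = p_ff,
       per_neuron = round(M * (p_rc + p_ff)),
       ff_total = M^2 * p_ff,
       total = M^2 * (p_rc + p_ff))
}

#' Closed-form time to threshold under a conductance step
#'
#' With all conductances held fixed, the membrane relaxes exponentially
#' towards the driving potential
#' \deqn{V^* = \frac{G^{leak}V^{rest} + G^E V^E + G^I V^I + G^{inj} V^E + I^{ext}}{G^{leak}+G^E+G^I+G^{inj}}}
#' with effective time constant
#' \eqn{\tau^* = \tau_m G^{leak} / (G^{leak}+G^E+G^I+G^{inj})}, so the time
#' from `V0` to threshold is
#' \eqn{t^{AP} = \tau^* \log[(V_0 - V^*)/(V^{th} - V^*)]}.  With the typical
#' replay conductances (`G_E = 0.6`, `G_I = 5`, `G_inj = 3` nS) and
#' `V0 = -51` mV this gives about 1.4 ms — the network responds much faster
#' than the 20 ms membrane time constant.
#'
#' @param V0 initial membrane potential (mV).
#' @param G_E,G_I standing excitatory/inhibitory synaptic conductance (nS).
#' @param G_inj injected (cue) conductance, treated as excitatory (nS).
#' @param params [neuron_params()].
#' @param I_ext external current (pA, default `params$I_const`).
#' @return List: `V_star` (mV), `tau_star` (ms), `t_AP` (ms; 0 if `V0`
#'   already at threshold, `Inf` if `V*` never reaches it).
#' @export
response_time <- function(V0, G_E = 0.6, G_I = 5, G_inj = 3,
                          params = neuron_params(),
                          I_ext = params$I_const) {
  G_tot <- params$G_leak + G_E + G_I + G_inj
  V_star <- (params$G_leak * params$V_rest + G_E * params$V_E +
               G_I * params$V_I + G_inj * params$V_E + I_ext) / G_tot
  tau_m <- params$C / params$G_leak
  tau_star <- tau_m * params$G_leak / G_tot
  t_AP <- if (V0 >= params$V_th) {
    0
  } else if (V_star <= params$V_th) {
    Inf
  } else {
    tau_star * log((V0 - V_star) / (params$V_th - V_star))
  }
  list(V_star = V_star, tau_star = tau_star, t_AP = t_AP)
}

#' PSP integrals for the diffusion approximation
#'
#' Time integrals of the post-synaptic potential and of its square for a
#' single exponential-conductance synapse, linearised near threshold:
#' \deqn{J = \tau^{syn}(V^{syn}-V^{th})\,g / G^{leak}}
#' \deqn{J^{(2)} = \left[\tau^{syn} g (V^{syn}-V^{th})\right]^2 /
#'   \left[2(\tau_m+\tau^{syn})(G^{leak})^2\right].}
#' Units: mV s and mV^2 s (times are converted from ms internally), so that
#' multiplying by a presynaptic rate in spikes/s gives the mean and variance
#' contributions to the membrane potential.  Inhibitory synapses give J < 0.
#'
#' @param g_syn synaptic conductance (nS).
#' @param V_syn synaptic reversal potential (mV).
#' @param tau_syn synaptic time constant (ms).
#' @param params [neuron_params()].
#' @return List with `J` (mV s) and `J2` (mV^2 s).
#' @export
#' @examples
#' psp_integrals(0.1, 0, 5)$J   # 0.0025 mV s
psp_integrals <- function(g_syn, V_syn, tau_syn, params = neuron_params()) {
  tau_m <- params$C / params$G_leak / 1000     # s
  ts <- tau_syn / 1000                         # s
  dv <- V_syn - params$V_th
  J <- ts * dv * g_syn / params$G_leak
  J2 <- (ts * g_syn * dv)^2 / (2 * (tau_m + ts) * params$G_leak^2)
  list(J = J, J2 = J2)
}

# integrand e^{u^2} (1 + erf u), written with the scaled complementary
# error function to stay finite for strongly hyperpolarised bounds
siegert_integrand <- function(u) {
  out <- numeric(length(u))
  neg <- u <= 0
  out[neg] <- erfcx_(-u[neg])
  if (any(!neg)) {
    up <- u[!neg]
    out[!neg] <- 2 * exp(up^2) - erfcx_(up)
  }
  out
}

# scaled complementary error function erfcx(x) = e^{x^2} erfc(x), x >= 0,
# via the identity with the standard normal tail
erfcx_ <- function(x) {
  2 * exp(x^2 + stats::pnorm(x * sqrt(2), lower.tail = FALSE, log.p = TRUE))
}

#' Stationary firing rate in the diffusion approximation
#'
#' Siegert-type formula for a leaky integrate-and-fire neuron whose membrane
#' potential has mean `mu` and fluctuation scale `sigma`:
#' \deqn{\rho = \left[\tau_{rp} + \tau_m\sqrt{\pi}
#'   \int_{(V^{rest}-\mu)/\sigma}^{(V^{th}-\mu)/\sigma}
#'   e^{u^2}(1+\mathrm{erf}\,u)\,du\right]^{-1}.}
#' The rate is bounded by `1/tau_rp` (500 spikes/s for the defaults) and
#' increases monotonically in `mu`.
#'
#' @param mu mean membrane potential (mV).
#' @param sigma membrane potential fluctuation scale (mV), > 0.
#' @param params [neuron_params()].
#' @return Firing rate (spikes/s).
#' @export
stationary_rate <- function(mu, sigma, params = neuron_params()) {
  stopifnot(sigma > 0)
  tau_m <- params$C / params$G_leak / 1000   # s
  tau_rp <- params$tau_rp / 1000             # s
  a <- (params$V_rest - mu) / sigma
  b <- (params$V_th - mu) / sigma
  if (b > 25) return(0)   # integral overflows double precision; rate ~ 0
  I <- integrate(siegert_integrand, a, b, rel.tol = 1e-10,
                 stop.on.error = FALSE)$value
  1 / (tau_rp + tau_m * sqrt(pi) * I)  # spikes/s
}

# membrane potential mean and variance of one population given the
# background input structure; rates in spikes/s
population_mu_sigma <- function(rho_E, rho_I, g_EI, spec,
                                params = neuron_params(), extra = NULL) {
  JE <- psp_integrals(spec$g_E, params$V_E, params$tau_E, params)
  mu <- params$V_rest + params$I_const / params$G_leak +
    spec$N_E * spec$p_rand * JE$J * rho_E
  s2 <- spec$N_E * spec$p_rand * JE$J2 * rho_E
  JI <- psp_integrals(g_EI, params$V_I, params$tau_I, params)
  mu <- mu + spec$N_I * spec$p_rand * JI$J * rho_I
  s2 <- s2 + spec$N_I * spec$p_rand * JI$J2 * rho_I
  if (!is.null(extra)) {
    Jx <- psp_integrals(extra$g, params$V_E, params$tau_E, params)
    mu <- mu + extra$M * Jx$J * extra$rate
    s2 <- s2 + extra$M * Jx$J2 * extra$rate
  }
  list(mu = mu, sigma = sqrt(s2))
}

#' Self-consistent balanced operating point
#'
#' Solves the two-population stationary-rate system for the unknowns left
#' open by the homeostatic plasticity: the inhibitory population rate
#' `rho_I` and the learned inhibitory-to-excitatory conductance `g_EI`.
#' The inhibitory rate follows from self-consistency of the inhibitory
#' population (whose input conductances are all fixed); `g_EI` is then the
#' value at which the excitatory population sits exactly at the target rate
#' `rho_0`.
#'
#' @param spec a [network_spec()]; only the background structure is used.
#' @param params [neuron_params()].
#' @param rho_0 target excitatory rate (spikes/s).
#' @return List: `rho_I` (spikes/s), `g_EI` (nS), and the excitatory
#'   operating point `mu_E`, `sigma_E` (mV).
#' @export
solve_balance_point <- function(spec = network_spec(),
                                params = neuron_params(), rho_0 = 5) {
  # inhibitory self-consistency: inputs are E (g_E) and I (g_I), both fixed
  i_resid <- function(rho_I) {
    ms <- inh_mu_sigma(rho_0, rho_I, spec, params)
    stationary_rate(ms$mu, ms$sigma, params) - rho_I
  }
  sol_I <- uniroot(i_resid, c(1e-3, 499), tol = 1e-10)
  rho_I <- sol_I$root
  # excitatory: find the plastic conductance that holds rho_E at rho_0
  e_resid <- function(g_EI) {
    ms <- population_mu_sigma(rho_0, rho_I, g_EI, spec, params)
    stationary_rate(ms$mu, ms$sigma, params) - rho_0
  }
  lo <- 1e-4
  hi <- 20
  if (e_resid(lo) < 0 || e_resid(hi) > 0) {
    stop("solve_balance_point: no root in the physical range; residuals ",
         sprintf("f(%g) = %.3g, f(%g) = %.3g", lo, e_resid(lo), hi,
                 e_resid(hi)))
  }
  sol_g <- uniroot(e_resid, c(lo, hi), tol = 1e-10)
  g_EI <- sol_g$root
  ms <- population_mu_sigma(rho_0, rho_I, g_EI, spec, params)
  list(rho_I = rho_I, g_EI = g_EI, mu_E = ms$mu, sigma_E = ms$sigma)
}

inh_mu_sigma <- function(rho_E, rho_I, spec, params) {
  JE <- psp_integrals(spec$g_E, params$V_E, params$tau_E, params)
  JI <- psp_integrals(spec$g_I, params$V_I, params$tau_I, params)
  mu <- params$V_rest + params$I_const / params$G_leak +
    spec$N_E * spec$p_rand * JE$J * rho_E +
    spec$N_I * spec$p_rand * JI$J * rho_I
  s2 <- spec$N_E * spec$p_rand * JE$J2 * rho_E +
    spec$N_I * spec$p_rand * JI$J2 * rho_I
  list(mu = mu, sigma = sqrt(s2))
}

#' Diffusion-approximation estimate of the transfer-function slope
#'
#' Perturbs the balanced operating point with an external excitatory group
#' (`M_ext` synapses per neuron firing at `rho_ext`) and converts the rate
#' response into the slope of the linearised population transfer function:
#' \deqn{c = \frac{\rho(\rho_{ext}) - \rho_0}{M_{ext}\, g^E\, \rho_{ext}}.}
#' `method = "derivative"` instead evaluates
#' \eqn{c = (1/M_{ext} g^E)\,\partial\rho/\partial\rho_{ext}} at
#' \eqn{\rho_{ext}\to 0} by a small central difference; the finite
#' perturbation gives a slightly larger value because the transfer function
#' is convex at the operating point.
#'
#' @param balance result of [solve_balance_point()] (computed if `NULL`).
#' @param spec,params,rho_0 as in [solve_balance_point()].
#' @param M_ext number of external synapses per neuron.
#' @param rho_ext external group rate (spikes/s).
#' @param method `"finite"` (default) or `"derivative"`.
#' @return Slope `c` in 1/nS.
#' @export
estimate_slope_c <- function(balance = NULL, spec = network_spec(),
                             params = neuron_params(), rho_0 = 5,
                             M_ext = 500, rho_ext = 5,
                             method = c("finite", "derivative")) {
  method <- match.arg(method)
  if (is.null(balance)) balance <- solve_balance_point(spec, params, rho_0)
  rate_at <- function(rx) {
    ms <- population_mu_sigma(rho_0, balance$rho_I, balance$g_EI, spec,
                              params,
                              extra = list(M = M_ext, g = spec$g_E,
                                           rate = rx))
    stationary_rate(ms$mu, ms$sigma, params)
  }
  if (method == "finite") {
    (rate_at(rho_ext) - rho_0) / (M_ext * spec$g_E * rho_ext)
  } else {
    h <- 0.01
    ((rate_at(h) - rate_at(0)) / h) / (M_ext * spec$g_E)
  }
}

#' Scale a network to a different size
#'
#' Rescales a specification to `N_E' = gamma N_E` while preserving both the
#' input fluctuations and the assembly coupling: conductances scale as
#' `g / sqrt(gamma)`, assembly connectivities as `p * sqrt(gamma)`, and the
#' background probability stays fixed, so `kappa` is invariant.  Also
#' reports the memory fraction `u` — the proportion of a sequence neuron's
#' excitatory inputs that are assembly (memory) synapses:
#' \deqn{u = \frac{(p_{rc}+p_{ff})\sqrt\gamma M}
#'   {(p_{rc}+p_{ff})\sqrt\gamma M + p_{rand}\gamma N^E}.}
#'
#' @param spec a [network_spec()].
#' @param gamma size scaling factor (> 0).
#' @return List: `spec` (the scaled specification), `u` (memory fraction),
#'   `gamma`.
#' @export
#' @examples
#' scale_network(network_spec(), gamma = 9)$u   # ~0.09
scale_network <- function(spec, gamma) {
  stopifnot(gamma > 0)
  s <- sqrt(gamma)
  scaled <- spec
  scaled$N_E <- as.integer(round(spec$N_E * gamma))
  scaled$N_I <- as.integer(round(spec$N_I * gamma))
  scaled$g_E <- spec$g_E / s
  scaled$g_ff <- spec$g_ff / s
  scaled$g_I <- spec$g_I / s
  scaled$g_EI_init <- spec$g_EI_init / s
  scaled$p_rc <- min(1, spec$p_rc * s)
  scaled$p_ff <- min(1, spec$p_ff * s)
  validate_network_spec(scaled)
  list(spec = scaled, u = memory_fraction(scaled), gamma = gamma)
}

#' Memory fraction of a sequence neuron's excitatory inputs
#'
#' @param spec a [network_spec()].
#' @return `(p_rc + p_ff) M / ((p_rc + p_ff) M + p_rand N_E)`.
#' @export
memory_fraction <- function(spec) {
  mem <- (spec$p_rc + spec$p_ff) * spec$M
  mem / (mem + spec$p_rand * spec$N_E)
}
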