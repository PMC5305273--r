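# replaynet

Simulation and mean-field analysis of **memory replay in balanced
recurrent spiking networks**.

## The problem

During hippocampal sharp-wave ripples and neocortical up-states, neurons
fire in sequences that mirror prior experience.  The synaptic footprint
left by a single experience is tiny, so how can it steer the activity of a
large network during recall?  `replaynet` implements a network model that
answers this with *recurrent amplification*: sequences of Hebbian
assemblies — groups of `M` excitatory and `M/4` inhibitory neurons wired
internally with probability `p_rc` — are chained by sparse feedforward
excitatory connections (`p_ff`) inside a 25,000-neuron conductance-based
leaky integrate-and-fire network that homeostatic inhibitory plasticity
holds in a balanced, asynchronous-irregular state.

The core quantity is the **effective feedforward connectivity**

```
kappa = c * M * p_ff * g_ff * (1 + c * M * p_rc * g_E)
```

the rate gain between consecutive assemblies (`c` is the slope of the
population transfer function, in 1/nS).  `kappa = 1` separates sequences
that cannot propagate from those that replay: recurrence within assemblies
(`p_rc`) multiplies up the feedforward coupling, so a handful of new
synapses per neuron suffices for replay.  The package provides

* network construction (random background + feedforward / symmetric /
  continuous assembly sequences, duplicate synapses merged by weight
  summation) — `build_background()`, `embed_sequence()`;
* a fast clock-driven simulator (Rcpp) with exact conductance decay,
  2 ms delays and the trace-based homeostatic inhibitory STDP rule —
  `simulate_network()`;
* protocol drivers: annealed balancing, cued-replay trials, spontaneous
  phases, excitability modulation, and a linear-track paradigm with
  forward and reverse replay — `balance_phase()`, `cued_replay_trial()`,
  `spontaneous_phase()`, `linear_track_protocol()`;
* the replay measurement battery (2 ms Gaussian population rates, 30 and
  180 spikes/s activation and burst thresholds, 2–20 ms chain delays,
  dummy-group veto, CV, 5 ms-bin synchrony, pulse-packet portraits) —
  `score_trial()`, `count_spontaneous_replays()`, `pulse_packet_state()`;
* the mean-field theory: `amplification_factor()`, `critical_line()`,
  `fit_c()`, `synapse_budget()`, `response_time()`, `stationary_rate()`,
  `solve_balance_point()`, `estimate_slope_c()`, `scale_network()`.

Units everywhere: ms, mV, nS, pA, spikes/s.

## Worked example

```r
library(replaynet)

# the marginal-stability calibration: kappa = 1 at p_rc=0.08, p_ff=0.04
amplification_factor(p_ff = 0.04, p_rc = 0.08, M = 500, g_E = 0.1, c = 0.25)
#> [1] 1

# cost of one new association at p_rc = 0.05, on the kappa = 1 line
b <- synapse_budget(p_rc = 0.05)
c(p_ff_crit = round(b$p_ff_crit, 4), per_neuron = b$per_neuron)
#> p_ff_crit = 0.0492, per_neuron = 50

# diffusion approximation of the balanced operating point
bp <- solve_balance_point()
round(c(rho_I = bp$rho_I, g_EI = bp$g_EI), 3)
#> rho_I = 19.998 spikes/s, g_EI = 0.501 nS
round(estimate_slope_c(bp), 3)      # transfer-function slope, 1/nS
#> [1] 0.129

# closed-form response to a 3 nS cue from V0 = -51 mV
round(response_time(-51)$t_AP, 2)   # ms
#> [1] 1.44

# scaling to a 180,000-neuron network: memory fraction of inputs
round(scale_network(network_spec(), gamma = 9)$u, 3)
#> [1] 0.091
```

Interpretation: at the calibration point a unit `kappa` confirms the
fitted slope `c = 0.25 /nS`; an association at moderate recurrence costs
50 new synapses per neuron; the self-consistent balanced state has
inhibitory neurons at ~20 spikes/s and a learned inhibitory conductance of
~0.5 nS; a cued near-threshold neuron fires within ~1.4 ms (much faster
than the 20 ms membrane time constant); and scaling up the network makes
the memory trace relatively sparser (9 % of a neuron's excitatory inputs).

A full simulated experiment (build, balance, cue, score) at the reference
scale — about ten minutes of compute for 20 s of balancing:

```r
spec <- network_spec(p_rc = 0.06, p_ff = 0.06, seed = 1)  # N_E = 20,000
conn <- embed_sequence(build_background(spec))
bal  <- balance_phase(conn, duration = 20000)
tail(bal$log$rate_E, 1)         # excitatory rate after balancing, spikes/s
#> [1] 4.879275
out  <- cued_replay_trial(bal$conn, bal$state)
score_trial(out$raster, bal$conn, t_start = attr(out$raster, "t_cue"))
#> <replay_score> quality = 1, chain = 10, reason = none
```

The cue ignites all ten assemblies in order within ~100 ms on an otherwise
asynchronous 5 spikes/s background — a replay.  Size-scaled versions
(`scale_network(spec, gamma)` with `gamma < 1`) run proportionally faster
and keep `kappa` invariant, but damp pulse-packet propagation (see the
methods vignette), so desk-scale runs are used for contrasts, not for the
quantitative replay boundary.

A thin command-line front end with `balance`, `replay`, `spontaneous`,
`track`, `scan` and `theory` subcommands lives in `inst/cli/replaynet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/replaynet.R", package="replaynet"))')" \
    theory --seed 1 --out out/
```

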