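---
title: "Assembly-sequence replay in balanced networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-sequence replay in balanced networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replaynet)
```

## The scientific question

How can the few synapses plausibly changed by a single experience control
large-scale network activity during memory retrieval?  `replaynet`
implements a network model in which sequences of Hebbian cell assemblies —
groups of recurrently connected excitatory and inhibitory neurons — are
linked by sparse feedforward synapses and embedded in a large, sparsely
connected random network held in a balanced, asynchronous-irregular (AI)
state.  Recurrent connections *within* an assembly transiently amplify the
input arriving from the previous assembly ("balanced amplification"), so
that surprisingly few between-assembly synapses suffice for a stimulation
of the first assembly to ignite a fast, ordered wave of activations — a
replay, as observed in hippocampal sharp-wave ripples.

## The neuron and network model

Neurons are conductance-based leaky integrate-and-fire units,

$$C\,\frac{dV_i}{dt} = G^{leak}(V^{rest}-V_i) + G^E_i(V^E-V_i) +
G^I_i(V^I-V_i) + I^{ext},$$

with $C = 200$ pF, $G^{leak} = 10$ nS (membrane time constant 20 ms),
$V^{rest} = -60$ mV, $V^{th} = -50$ mV, $V^E = 0$ mV, $V^I = -80$ mV, and a
2 ms refractory period during which $V$ is clamped at $V^{rest}$.  Synaptic
conductances jump by the synaptic weight at each presynaptic spike (after a
uniform 2 ms delay) and decay exponentially with $\tau^E = 5$ ms and
$\tau^I = 10$ ms.  A constant current $I^{const} = 200$ pA makes isolated
neurons tonically active; network inhibition turns this into irregular,
fluctuation-driven firing.  A single 0.1 nS excitatory event produces a
$\approx 0.1$ mV EPSP at rest.

The reference network has $N^E = 20{,}000$ excitatory and $N^I = 5{,}000$
inhibitory neurons, randomly connected with probability
$p_{rand} = 0.01$.  An assembly is formed by picking $M = 500$ excitatory
and $M/4$ inhibitory neurons and wiring every ordered pair with probability
$p_{rc}$; ten disjoint assemblies are chained by excitatory feedforward
connections with probability $p_{ff}$ (conductance $g_{ff}$, by default
equal to the recurrent $g^E = 0.1$ nS).  New synapses add on top of the
background ones: a doubly-connected pair simply carries the summed weight.
Three wiring modes are supported: `feedforward` (the reference chain),
`symmetric` (backward projections added, enabling reverse replay), and
`continuous` (no discrete assemblies: every neuron connects to its $M$
nearest neighbours on a line, and to the following $M$ cells beyond them —
relative windows $[-M/2, M/2]$ and $(M/2, 3M/2]$, truncated at the edges).

## Homeostatic inhibitory plasticity

All inhibitory-to-excitatory synapses follow a trace-based STDP rule.
Every neuron carries a trace $x$ incremented at its spikes and decaying
with $\tau_{STDP} = 20$ ms.  At a presynaptic (inhibitory) spike the
synapse changes by $\eta(x_{post}-\alpha)$; at a postsynaptic spike by
$\eta x_{pre}$; weights are clipped at 0 nS (negative inhibitory
conductances are unphysical; the paper-level description leaves the bound
open).  The depression bias $\alpha = 2\rho_0\tau_{STDP}$ makes the
expected drift for independent Poisson firing
$2\eta\tau_{STDP}\rho_{pre}(\rho_{post}-\rho_0)$, so each excitatory
neuron is individually steered to the target rate $\rho_0 = 5$ spikes/s.
Inhibitory neurons settle near 20 spikes/s at the reference scale.

### The annealing schedule

Balancing runs for 50 s (20 s in the scaled benchmarks below) while $\eta$
decreases from $0.005$ to $10^{-5}$ over ten equal epochs.  Only the
endpoints of the schedule are fixed by the model description; the shape is
a package choice.  We use a **linear** ramp: the relevant resource is the
integrated learning $\int\eta\,dt$, which must cover the distance from the
initial $g^{EI}_0 = 0.4/\sqrt{\gamma}$ nS to the homeostatic fixed point.
A geometric ramp between the same endpoints concentrates essentially all
learning in the first epoch ($\sum\eta$ about 25-fold smaller) and, in
size-scaled networks whose fixed point lies further from the
initialisation, quenches the weights mid-journey while their drift is
still positive.  With the linear ramp the scaled benchmark in the test
suite balances to within 10 % of the target rate, and the learned
conductance can be checked against the diffusion-theory balance point
(`solve_balance_point()` gives $g^{EI} = 0.50$ nS at the reference
scale).

## Simulation engine

The network is integrated clock-driven with $dt = 0.1$ ms (which must
divide the 2 ms delay):

* conductances decay by their exact per-step factors
  $e^{-dt/\tau}$;
* the membrane potential advances by the locally linearised closed form
  (exponential Euler) with conductances held at their start-of-step
  values — stable for the stiff conductance inputs of a cue;
* threshold crossings are registered at the end of the step (no
  interpolation), reset $V$, start the refractory clock, and enqueue
  deliveries one delay later in a circular event buffer;
* plasticity updates are applied at spike events; traces decay for all
  neurons before the spikes of a step are processed, so trace reads are
  uniform end-of-step values.

The engine contains no randomness: all stochasticity (wiring, initial
potentials drawn uniformly between $V^{rest}$ and $V^{th}$ to avoid
start-up synchrony, cue membership and jitter) is drawn in R from named
substreams of the experiment seed, so every stage is independently
reproducible and a saved state can be reloaded and continued bit-exactly.
Halving $dt$ moves single-neuron spike times by at most one coarse step,
and a three-neuron circuit matches an adaptive-step ODE oracle to better
than 0.05 ms.

## Protocols and replay metrics

A full experiment has three phases: (1) balancing as above; (2) cued
replay — plasticity off, all (or a fraction of) the first assembly's
excitatory neurons receive a 3 nS conductance kick, enough to fire a
near-threshold neuron within about 1.4 ms; (3) spontaneous activity — no
assembly-specific input, optionally with small population-wide currents
$I^e$/$I^i$ that move the network between retrieval-like and
consolidation-like regimes.  A linear-track driver chains these phases for
symmetric sequences (contextual cue currents at the track ends, global
suppression plus periodic location volleys during locomotion).

Replay quality follows the model's measurement rules: population rates are
smoothed with a 2 ms Gaussian kernel; a group is activated at the maximum
of a super-threshold (30 spikes/s) excursion; activations above 180
spikes/s count as bursts; two activation peaks of one group within 30 ms
flag a double peak; consecutive groups must activate within 2–20 ms of
each other; and a "dummy group" of $M$ background neurons detects
whole-network events.  A trial scores quality 1 only for a clean full
chain; the chain length is kept as a diagnostic.  Spontaneous replays are
last-assembly activations preceded by at least three predecessors in
order.  Spike-train irregularity (CV of inter-spike intervals), pairwise
synchrony (correlation of 5 ms binned trains) and pulse-packet portraits
(participation $\alpha$, first-spike dispersion $\sigma$; first spikes
because single spikes dominate during replay) complete the battery.

## Mean-field theory

Linearising the coupled E/I assembly dynamics around the balanced state
gives the *effective feedforward connectivity*

$$\kappa = c\,M p_{ff} g_{ff}\,(1 + c\,M p_{rc} g^E),$$

the rate gain from one assembly to the next ($k = 1$ case; the general
$k\ge1$ form is implemented too).  $\kappa = 1$ is the marginal-stability
line for replay; solving it for the slope constant at the calibration
connectivities $(p_{rc}, p_{ff}) = (0.08, 0.04)$ gives $c = 0.25$ nS$^{-1}$.
The per-neuron synapse budget of an association on this line is
$M(p_{rc}+p_{ff}^*)$ — 40 synapses at $p_{rc}=0$, 50 at 0.05, 111 at 0.2 —
so recurrence makes the *feedforward* requirement almost arbitrarily small
at a modest total cost.

The slope is also computed from first principles via the diffusion
approximation: PSP integrals $J$ and $J^{(2)}$ (we use the dimensionally
consistent $J^{(2)} = [\tau^{syn} g (V^{syn}-V^{th})]^2 /
[2(\tau_m+\tau^{syn})(G^{leak})^2]$, and $\sigma^2 = \sum_k J^{(2)}_k
\rho_k$) feed a Siegert-type stationary rate formula; a two-equation
self-consistency pins the unknown inhibitory rate and plastic conductance;
an external-group perturbation ($M_{ext} = 500$ synapses at 5 spikes/s,
matching the assembly geometry — the description leaves the perturbation
size open) then yields $c \approx 0.13$ nS$^{-1}$, with a tangent-slope
variant giving $\approx 0.11$ nS$^{-1}$.  The quadrature uses scaled
complementary error functions to avoid overflow of $e^{u^2}$.

Finally, the size-scaling laws: growing the network to
$\tilde N = \gamma N$ while keeping assemblies of fixed size $M$ preserves
both input fluctuations and assembly coupling if conductances scale as
$g/\sqrt\gamma$ and assembly connectivities as $p\sqrt\gamma$ ($p_{rand}$
fixed).  $\kappa$ is exactly invariant, and the memory fraction
$u = (p_{rc}+p_{ff})\sqrt\gamma M / [(p_{rc}+p_{ff})\sqrt\gamma M +
p_{rand}\gamma N^E]$ falls from 0.23 at the reference size to 0.09 at
$\tilde N^E = 180{,}000$.  (The extracted source text prints $g/\gamma$,
but only the square-root rule reproduces the printed $u$ values and keeps
$\sigma$ constant, so that is what the package implements.)

## What the generators emulate — and what they do not

All inputs are generated internally: the network builder *is* the data
generator, and its defaults are the reference conditions above.  The
scaled-down configurations used in tests keep $M = 500$ and apply the
$\gamma$-scaling, so the theory quantities ($\kappa$, $u$) are preserved
exactly.  The scaling is, however, only approximate for conductance-based
neurons: quantal sizes grow as $1/\sqrt\gamma$, an assembly occupies a
$1/\gamma$-fold larger fraction of the network, and shared-input
correlations strengthen.  At $\gamma = 1/4$ the balanced state survives
(the acceptance benchmark measures ~5.5 spikes/s at synchrony
$<10^{-3}$), but pulse-packet propagation is measurably damped relative
to the reference scale: supercritical desk-scale chains reach most but
not all assemblies.  Tests passing at desk scale therefore validate the
mechanics and the contrasts (supercritical vs subcritical coupling), not
the quantitative replay boundary of the reference network, which requires
reference-scale runs (minutes to hours of compute).

## Numerical choices and degenerate inputs

* Exponential-Euler with $dt = 0.1$ ms; spike times quantised to step
  ends; delays as a ring buffer of $\mathrm{delay}/dt$ slots.
* Duplicate synapses merged by conductance summation at build time;
  self-connections never created.
* Empty rasters, zero-probability wiring, zero-duration runs and
  zero-conductance kicks are exact no-ops.
* Peak detection: one activation per contiguous super-threshold excursion
  (its maximum); ties broken by the earlier sample.
* The Siegert integrand switches to $\mathrm{erfcx}$ on the
  hyperpolarised side; operating points more than $25\sigma$ below
  threshold report rate 0.
* Problem sizes in the test suite: single neurons to $N^E = 2{,}500$ for
  unit tests, $N^E = 5{,}000$ ($\gamma = 1/4$, 8 assemblies) for the
  balancing and replay benchmarks — chosen so the full suite exercises
  every protocol at desk scale.

## Known limitations

* The replay boundary at strongly scaled-down sizes sits above the
  $\kappa = 1$ prediction (see above); quantitative heat-map positions
  require the reference scale.
* One uniform inhibitory population; no interneuron diversity, no
  short-term plasticity, no theta-phase modelling.
* No overlapping assemblies; sequences are at most `n_groups` long.
* The diffusion slope $c$ describes stationary transfer; the transfer of
  fast transients is steeper (the fitted 0.25 vs the computed 0.13
  nS$^{-1}$), which the model treats as a fitted constant rather than a
  derived one.
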