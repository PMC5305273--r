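# R-side interface to the clock-driven engine: network state objects,
# conductance kicks, and the main run loop.

#' Create the initial dynamical state of a network
#'
#' Membrane potentials start uniformly distributed between `V_rest` and
#' `V_th` (drawn from the `"init"` substream of the experiment seed) to
#' avoid spurious synchrony at t = 0; conductances, refractory clocks and
#' plasticity traces start at zero, and no spikes are in flight.
#'
#' @param conn a `connectivity_set`.
#' @param params [neuron_params()].
#' @param seed optional seed override (defaults to `conn$spec$seed`).
#' @return An object of class `network_state`.
#' @export
initial_state <- function(conn, params = neuron_params(),
                          seed = conn$spec$seed) {
  n <- conn$spec$N_E + conn$spec$N_I
  V <- with_substream(seed, "init",
                      runif(n, params$V_rest, params$V_th))
  structure(list(V = V, G_E = numeric(n), G_I = numeric(n),
                 ref_ms = numeric(n), x = numeric(n),
                 inflight = data.frame(step_offset = integer(0),
                                       neuron = integer(0)),
                 t_ms = 0),
            class = "network_state")
}

#' Instantaneous excitatory conductance kick
#'
#' Increments `G_E` of the given neurons by `g_max`, the stimulation used to
#' trigger assembly activations (default cue strength 3 nS, enough to make a
#' near-threshold neuron fire within a couple of milliseconds).
#'
#' @param state a `network_state`.
#' @param ids neuron ids to stimulate.
#' @param g_max conductance increment (nS).
#' @return The modified state.
#' @export
apply_conductance_kick <- function(state, ids, g_max) {
  stopifnot(inherits(state, "network_state"))
  if (g_max < 0) stop("apply_conductance_kick: g_max must be >= 0")
  if (length(ids) && (min(ids) < 1 || max(ids) > length(state$V))) {
    stop("apply_conductance_kick: neuron id out of range")
  }
  state$G_E[ids] <- state$G_E[ids] + g_max
  state
}

# Flatten a connectivity set into the CSR arrays the engine consumes.
# Returns the permutation used so updated plastic weights can be written
# back into the synapse table.
engine_arrays <- function(conn) {
  s <- conn$synapses
  n <- conn$spec$N_E + conn$spec$N_I
  ord <- order(s$pre, s$post)
  pre0 <- s$pre[ord] - 1L
  row_ptr <- c(0L, cumsum(tabulate(s$pre[ord], nbins = n)))
  list(row_ptr = as.integer(row_ptr),
       col = as.integer(s$post[ord] - 1L),
       w = s$g_nS[ord],
       inh = s$pre[ord] > conn$spec$N_E,
       plastic = s$class[ord] == "IE_plastic",
       ord = ord,
       delay = if (nrow(s)) s$delay_ms[[1L]] else conn$spec$delay)
}

#' Run the network for a stretch of time
#'
#' Advances the conductance-based LIF network with fixed step `dt` (which
#' must divide the synaptic delay), optional inhibitory plasticity, scheduled
#' conductance kicks, and optional per-neuron extra currents.  The run is
#' fully deterministic given the input state.
#'
#' @param conn a `connectivity_set`.
#' @param state a `network_state` (created with [initial_state()] if `NULL`).
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param params [neuron_params()]; population-wide extra currents go in its
#'   `I_e` / `I_i` fields.
#' @param eta inhibitory STDP learning rate; 0 switches plasticity off.
#' @param plasticity [plasticity_params()] (trace time constant, bias, floor).
#' @param kicks `NULL` or a data frame with columns `time_ms`, `neuron`,
#'   `g_nS`: scheduled excitatory conductance increments.
#' @param I_extra `NULL` or a length-N vector of additional per-neuron
#'   currents (pA), e.g. assembly-specific drive.
#' @param record ids whose membrane potential should be recorded each step.
#' @param record_conductances also record `G_E`/`G_I` for those ids.
#' @return A list of class `sim_result`: `raster` (data frame `time_ms`,
#'   `neuron`), the advanced `state`, `conn` (with updated plastic weights),
#'   and `traces` (`NULL` or a list of matrices with a `time_ms` vector).
#' @export
#' @examples
#' spec <- network_spec(N_E = 40, N_I = 8, M = 8, n_groups = 2,
#'                      p_rand = 0.05, seed = 7)
#' conn <- build_background(spec)
#' out <- simulate_network(conn, duration = 100)
#' head(out$raster)
simulate_network <- function(conn, state = NULL, duration, dt = 0.1,
                             params = neuron_params(), eta = 0,
                             plasticity = plasticity_params(),
                             kicks = NULL, I_extra = NULL,
                             record = NULL, record_conductances = FALSE) {
  stopifnot(inherits(conn, "connectivity_set"))
  if (duration < 0) stop("duration must be >= 0")
  if (is.null(state)) state <- initial_state(conn, params)
  n <- conn$spec$N_E + conn$spec$N_I
  arr <- engine_arrays(conn)
  if (abs(arr$delay / dt - round(arr$delay / dt)) > 1e-9) {
    stop("dt must divide the synaptic delay exactly")
  }
  if (duration == 0) {
    return(structure(list(raster = empty_raster(), state = state,
                          conn = conn, traces = NULL),
                     class = "sim_result"))
  }
  steps <- round(duration / dt)

  if (is.null(kicks)) {
    kicks <- data.frame(time_ms = numeric(0), neuron = integer(0),
                        g_nS = numeric(0))
  }
  if (nrow(kicks)) {
    if (any(kicks$g_nS < 0)) stop("kick conductance must be >= 0")
    if (any(kicks$neuron < 1 | kicks$neuron > n)) {
      stop("kick neuron id out of range")
    }
    ks <- floor((kicks$time_ms - state$t_ms) / dt + 1e-9)
    keep <- ks >= 0 & ks < steps
    kicks <- kicks[keep, , drop = FALSE]
    ks <- ks[keep]
    o <- order(ks)
    kicks <- kicks[o, , drop = FALSE]
    ks <- as.integer(ks[o])
  } else {
    ks <- integer(0)
  }

  if (is.null(I_extra)) I_extra <- numeric(n)
  if (length(I_extra) != n) stop("I_extra must have one entry per neuron")

  rec_ids <- if (is.null(record)) integer(0) else as.integer(record)
  if (length(rec_ids) && (min(rec_ids) < 1 || max(rec_ids) > n)) {
    stop("recorder asked for unknown neuron id")
  }

  res <- cpp_simulate(n, conn$spec$N_E,
                      arr$row_ptr, arr$col, arr$w, arr$inh, arr$plastic,
                      state$V, state$G_E, state$G_I, state$ref_ms, state$x,
                      as.integer(state$inflight$step_offset),
                      as.integer(state$inflight$neuron - 1L),
                      state$t_ms, duration, dt, arr$delay,
                      unclass(params), I_extra,
                      eta, plasticity$alpha, plasticity$tau_STDP,
                      plasticity$g_min,
                      ks, as.integer(kicks$neuron - 1L), kicks$g_nS,
                      rec_ids - 1L, isTRUE(record_conductances))

  new_state <- structure(list(V = res$V, G_E = res$gE, G_I = res$gI,
                              ref_ms = res$ref, x = res$trace,
                              inflight = data.frame(
                                step_offset = res$inflight_step,
                                neuron = res$inflight_id + 1L),
                              t_ms = state$t_ms + duration),
                         class = "network_state")

  if (eta > 0) {
    g_new <- conn$synapses$g_nS
    g_new[arr$ord] <- res$w
    conn$synapses$g_nS <- g_new
  }

  traces <- NULL
  if (length(rec_ids)) {
    tvec <- state$t_ms + seq_len(steps) * dt
    traces <- list(time_ms = tvec, ids = rec_ids, V = res$recV)
    if (isTRUE(record_conductances)) {
      traces$G_E <- res$recGE
      traces$G_I <- res$recGI
    }
  }

  structure(list(raster = data.frame(time_ms = res$spike_t,
                                     neuron = res$spike_i + 1L),
                 state = new_state, conn = conn, traces = traces),
            class = "sim_result")
}

empty_raster <- function() {
  data.frame(time_ms = numeric(0), neuron = integer(0))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d spikes, state at t = %g ms\n",
              nrow(x$raster), x$state$t_ms))
  invisible(x)
}

# population firing rate (spikes/s per neuron) of an id set over a window
window_rate <- function(raster, ids, t0, t1) {
  if (t1 <= t0 || length(ids) == 0L) return(0)
  k <- sum(raster$neuron %in% ids & raster$time_ms > t0 &
             raster$time_ms <= t1)
  k / length(ids) / ((t1 - t0) / 1000)
}
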