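# Experiment drivers: the balancing phase with annealed inhibitory
# plasticity, cued-replay trials, the spontaneous phase, and the
# linear-track paradigm for symmetric sequences.

#' Learning-rate annealing schedule
#'
#' Per-epoch learning rates decaying from `eta_start` to `eta_end`.  The
#' linear ramp is the default: it matches both endpoints while keeping the
#' integrated learning (`sum(eta) * epoch length`) large enough for the
#' plastic weights to travel all the way to their homeostatic fixed point
#' within the balancing phase — important in size-scaled networks, where
#' the initial inhibitory conductance starts further from its target.  A
#' geometric ramp (much smaller integrated learning, smoother quench) is
#' available via `type`.
#'
#' @param eta_start,eta_end schedule endpoints.
#' @param n_epochs number of equal-duration epochs.
#' @param type `"linear"` (default) or `"geometric"`.
#' @return Vector of `n_epochs` per-epoch learning rates.
#' @export
eta_schedule <- function(eta_start = 0.005, eta_end = 1e-5, n_epochs = 10,
                         type = c("linear", "geometric")) {
  type <- match.arg(type)
  if (eta_start == 0) return(rep(0, n_epochs))
  if (n_epochs == 1L) return(eta_start)
  if (type == "linear") {
    seq(eta_start, eta_end, length.out = n_epochs)
  } else {
    eta_start *
      (eta_end / eta_start)^((seq_len(n_epochs) - 1) / (n_epochs - 1))
  }
}

#' Balance the network with homeostatic inhibitory plasticity
#'
#' Runs the network for `duration` ms with the inhibitory STDP rule enabled
#' and the learning rate annealed geometrically from `eta_start` to
#' `eta_end` over `n_epochs` equal epochs.  After convergence the
#' excitatory population fires asynchronously and irregularly near the
#' target rate while inhibitory neurons settle several-fold higher.  If the
#' excitatory rate stays above `rate_ceiling` for more than 1 s within an
#' epoch, the run is reported as a balance failure (diagnostics in the
#' returned log) instead of raising an error.
#'
#' @param conn a `connectivity_set`.
#' @param state optional `network_state` to continue from.
#' @param duration total balancing time (ms); a short re-balancing after an
#'   embedding change (~5000 ms) is obtained by just lowering this.
#' @param eta_start,eta_end,n_epochs,schedule annealing schedule
#'   (see [eta_schedule()]).
#' @param dt integration step (ms).
#' @param params [neuron_params()].
#' @param plasticity [plasticity_params()].
#' @param rate_ceiling divergence threshold (spikes/s).
#' @return List of class `balance_result`: `conn` (learned weights),
#'   `state`, `balanced` flag, and a per-epoch `log` (eta, excitatory and
#'   inhibitory rates, mean plastic conductance).
#' @export
balance_phase <- function(conn, state = NULL, duration = 50000,
                          eta_start = 0.005, eta_end = 1e-5, n_epochs = 10,
                          schedule = c("linear", "geometric"),
                          dt = 0.1, params = neuron_params(),
                          plasticity = plasticity_params(),
                          rate_ceiling = 100) {
  stopifnot(inherits(conn, "connectivity_set"))
  if (is.null(state)) state <- initial_state(conn, params)
  etas <- eta_schedule(eta_start, eta_end, n_epochs, match.arg(schedule))
  ep_dur <- duration / n_epochs
  N_E <- conn$spec$N_E
  e_ids <- seq_len(N_E)
  i_ids <- if (conn$spec$N_I > 0) N_E + seq_len(conn$spec$N_I) else integer(0)
  log <- data.frame(epoch = integer(0), eta = numeric(0),
                    rate_E = numeric(0), rate_I = numeric(0),
                    mean_g_EI = numeric(0))
  balanced <- TRUE
  for (ep in seq_len(n_epochs)) {
    out <- simulate_network(conn, state, duration = ep_dur, dt = dt,
                            params = params, eta = etas[ep],
                            plasticity = plasticity)
    conn <- out$conn
    state <- out$state
    t1 <- state$t_ms
    rate_E <- window_rate(out$raster, e_ids, t1 - ep_dur, t1)
    rate_I <- if (length(i_ids)) {
      window_rate(out$raster, i_ids, t1 - ep_dur, t1)
    } else {
      NA_real_
    }
    plastic <- conn$synapses$class == "IE_plastic"
    log <- rbind(log, data.frame(epoch = ep, eta = etas[ep],
                                 rate_E = rate_E, rate_I = rate_I,
                                 mean_g_EI = mean(conn$synapses$g_nS[plastic])))
    # divergence guard: a full second above the ceiling
    if (ep_dur >= 1000) {
      wins <- seq(t1 - ep_dur, t1 - 1000, by = 1000)
      over <- vapply(wins, function(w0) {
        window_rate(out$raster, e_ids, w0, w0 + 1000) > rate_ceiling
      }, logical(1))
      if (any(over)) {
        balanced <- FALSE
        break
      }
    }
  }
  structure(list(conn = conn, state = state, balanced = balanced,
                 log = log),
            class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  cat(sprintf("<balance_result> %s after %d epochs\n",
              if (x$balanced) "balanced" else "FAILED (rate ceiling exceeded)",
              nrow(x$log)))
  print(x$log, row.names = FALSE)
  invisible(x)
}

#' One cued-replay trial
#'
#' Stimulates a fraction of the first assembly's excitatory neurons with a
#' conductance kick (`g_max`, default 3 nS — enough to fire each cued
#' neuron) at times drawn from a normal distribution around `t_cue` with SD
#' `cue_jitter`, then records the network for `window` ms.  Plasticity is
#' off.  Cue membership and jitter are drawn from a trial-specific
#' substream, so trials are individually reproducible.
#'
#' @param conn a balanced `connectivity_set` with an embedded sequence.
#' @param state the balanced `network_state` to start from (the trial does
#'   not modify it).
#' @param cue_fraction fraction of group-1 excitatory neurons cued, in
#'   (0, 1]; `ceiling(cue_fraction * M)` members are drawn.
#' @param cue_jitter SD of per-neuron cue times (ms).
#' @param g_max cue conductance (nS).
#' @param t_cue cue time after trial start (ms).
#' @param window recording window after the cue (ms).
#' @param trial trial index; seeds the cue substream together with
#'   `conn$spec$seed`.
#' @param dt,params as in [simulate_network()].
#' @return A `sim_result`; the raster has attributes `t_cue` and `cue_ids`.
#' @export
cued_replay_trial <- function(conn, state, cue_fraction = 1, cue_jitter = 0,
                              g_max = 3, t_cue = 50, window = 200,
                              trial = 1, dt = 0.1,
                              params = neuron_params()) {
  if (!length(conn$groups)) stop("cued_replay_trial: no embedded sequence")
  if (cue_fraction <= 0 || cue_fraction > 1) {
    stop("cued_replay_trial: cue_fraction must be in (0, 1]")
  }
  g1 <- conn$groups[[1L]]$E
  n_cue <- ceiling(cue_fraction * length(g1))
  cue <- with_substream(conn$spec$seed, paste0("cue-trial-", trial), {
    ids <- if (n_cue == length(g1)) g1 else sort(sample(g1, n_cue))
    times <- state$t_ms + t_cue + if (cue_jitter > 0) {
      rnorm(n_cue, 0, cue_jitter)
    } else {
      numeric(n_cue)
    }
    list(ids = ids, times = times)
  })
  kicks <- data.frame(time_ms = cue$times, neuron = cue$ids, g_nS = g_max)
  out <- simulate_network(conn, state, duration = t_cue + window, dt = dt,
                          params = params, eta = 0, kicks = kicks)
  attr(out$raster, "t_cue") <- state$t_ms + t_cue
  attr(out$raster, "cue_ids") <- cue$ids
  out
}

#' Spontaneous-activity phase
#'
#' Runs the network with plasticity off and no assembly-specific input —
#' only the constant driving current plus optional small population-wide
#' currents `I_e` (excitatory) and `I_i` (inhibitory) that shift the
#' network between the asynchronous-irregular and spontaneous-replay
#' regimes.
#'
#' @param conn a balanced `connectivity_set`.
#' @param state starting `network_state`.
#' @param duration length of the phase (ms).
#' @param I_e,I_i population-wide currents (pA).
#' @param dt,params as in [simulate_network()].
#' @return A `sim_result`.
#' @export
spontaneous_phase <- function(conn, state, duration, I_e = 0, I_i = 0,
                              dt = 0.1, params = neuron_params()) {
  params$I_e <- I_e
  params$I_i <- I_i
  simulate_network(conn, state, duration = duration, dt = dt,
                   params = params, eta = 0)
}

#' Linear-track protocol for symmetric sequences
#'
#' Emulates a virtual run on a linear track with a symmetric assembly
#' sequence: a rest period with a contextual cue current (+`I_cue` pA) into
#' the first assembly (spontaneous forward replays), a locomotion period
#' with global suppression (`I_run` pA to all excitatory neurons) and brief
#' conductance volleys every `theta_interval` ms to the assembly coding the
#' current location, and a final rest with the cue on the last assembly
#' (spontaneous reverse replays).
#'
#' @param conn a balanced symmetric-mode `connectivity_set`.
#' @param state starting state.
#' @param rest_duration duration of each rest segment (ms).
#' @param run_duration duration of the locomotion segment (ms).
#' @param I_cue contextual cue current during rest (pA).
#' @param I_run global excitatory current during locomotion (pA, negative).
#' @param g_theta conductance of the location volleys (nS).
#' @param theta_interval interval between location volleys (ms).
#' @param dt,params as in [simulate_network()].
#' @return List of class `track_result`: combined `raster`, `segments`
#'   (label, start, end), final `state`.
#' @export
linear_track_protocol <- function(conn, state, rest_duration = 500,
                                  run_duration = 1000, I_cue = 2,
                                  I_run = -10, g_theta = 3,
                                  theta_interval = 100, dt = 0.1,
                                  params = neuron_params()) {
  if (conn$spec$wiring_mode != "symmetric") {
    stop("linear_track_protocol expects a symmetric-mode network")
  }
  n <- conn$spec$N_E + conn$spec$N_I
  n_groups <- length(conn$groups)
  rasters <- list()
  segments <- data.frame(label = character(0), t0 = numeric(0),
                         t1 = numeric(0))
  seg <- function(label, t0, t1) {
    segments <<- rbind(segments, data.frame(label = label, t0 = t0, t1 = t1))
  }

  # rest at the start: cue current into the first assembly
  I_extra <- numeric(n)
  I_extra[conn$groups[[1L]]$E] <- I_cue
  out <- simulate_network(conn, state, duration = rest_duration, dt = dt,
                          params = params, I_extra = I_extra)
  rasters[[1L]] <- out$raster
  seg("rest_start", state$t_ms, out$state$t_ms)
  state <- out$state

  # locomotion: global suppression + periodic volleys to the location group
  t0 <- state$t_ms
  kick_times <- seq(t0, t0 + run_duration - 1e-9, by = theta_interval)
  loc_group <- pmin(n_groups,
                    floor((kick_times - t0) / run_duration * n_groups) + 1L)
  kicks <- do.call(rbind, lapply(seq_along(kick_times), function(k) {
    ids <- conn$groups[[loc_group[k]]]$E
    data.frame(time_ms = kick_times[k], neuron = ids, g_nS = g_theta)
  }))
  params_run <- params
  params_run$I_e <- params$I_e + I_run
  out <- simulate_network(conn, state, duration = run_duration, dt = dt,
                          params = params_run, kicks = kicks)
  rasters[[2L]] <- out$raster
  seg("locomotion", t0, out$state$t_ms)
  state <- out$state

  # rest at the end: cue current into the last assembly
  I_extra <- numeric(n)
  I_extra[conn$groups[[n_groups]]$E] <- I_cue
  out <- simulate_network(conn, state, duration = rest_duration, dt = dt,
                          params = params, I_extra = I_extra)
  rasters[[3L]] <- out$raster
  seg("rest_end", state$t_ms, out$state$t_ms)

  structure(list(raster = do.call(rbind, rasters), segments = segments,
                 state = out$state),
            class = "track_result")
}
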