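# Replay measurement battery: smoothed population rates, group-activation
# detection, replay scoring, spontaneous-replay counting, spike-train
# statistics and pulse-packet state portraits.  All functions are pure
# functions of the raster they receive.

#' Gaussian-smoothed population firing rate
#'
#' Sum of Gaussian kernels (width `sigma`) over all spikes of the id set,
#' divided by the number of neurons; units spikes/s per neuron.  A single
#' fully synchronous volley of the whole set peaks at
#' `1000 / (sigma * sqrt(2*pi))` spikes/s (about 199.5 for sigma = 2 ms).
#'
#' @param raster data frame with `time_ms`, `neuron`.
#' @param ids neuron ids defining the population.
#' @param sigma kernel width (ms).
#' @param t_range `c(t0, t1)` evaluation window (ms); defaults to the raster
#'   range padded by 4 sigma.
#' @param dt evaluation grid step (ms).
#' @return Data frame of class `rate_trace` with `time_ms` and `rate`.
#' @export
population_rate <- function(raster, ids, sigma = 2, t_range = NULL,
                            dt = 0.1) {
  if (is.null(t_range)) {
    if (nrow(raster) == 0L) {
      t_range <- c(0, 1)
    } else {
      t_range <- range(raster$time_ms) + c(-4, 4) * sigma
    }
  }
  grid <- seq(t_range[1], t_range[2], by = dt)
  ts <- raster$time_ms[raster$neuron %in% ids]
  ts <- ts[ts >= t_range[1] - 6 * sigma & ts <= t_range[2] + 6 * sigma]
  out <- data.frame(time_ms = grid, rate = 0)
  if (length(ts) == 0L || length(ids) == 0L) {
    class(out) <- c("rate_trace", "data.frame")
    return(out)
  }
  # bin spikes onto the grid, then convolve with the (6 sigma) kernel
  pad <- ceiling(6 * sigma / dt)
  nbins <- length(grid) + 2L * pad
  bin <- round((ts - t_range[1]) / dt) + 1L + pad
  bin <- bin[bin >= 1L & bin <= nbins]
  counts <- tabulate(bin, nbins = nbins)
  kx <- seq(-pad, pad) * dt
  kern <- dnorm(kx, sd = sigma)
  sm <- convolve(counts, rev(kern), type = "open")
  core <- sm[(2L * pad + 1L):(2L * pad + length(grid))]
  out$rate <- core * 1000 / length(ids)
  class(out) <- c("rate_trace", "data.frame")
  out
}

#' Detect assembly activations in a smoothed rate trace
#'
#' A group is activated at the time its rate, while above `theta_act`,
#' attains a local maximum: each contiguous super-threshold excursion yields
#' one activation at its maximum.  An activation is a burst if its peak
#' reaches `theta_burst`; two successive activation peaks of the same group
#' within `double_peak_window` ms flag both as double peaks.
#'
#' @param trace a `rate_trace`, or a list of them (one per group).
#' @param theta_act activation threshold (spikes/s).
#' @param theta_burst bursting threshold (spikes/s).
#' @param double_peak_window window for the double-peak rule (ms).
#' @return Data frame with `group`, `t_peak`, `peak_rate`, `is_burst`,
#'   `double_peak` (class `group_activations`).
#' @export
detect_activations <- function(trace, theta_act = 30, theta_burst = 180,
                               double_peak_window = 30) {
  traces <- if (inherits(trace, "rate_trace")) list(trace) else trace
  out <- lapply(seq_along(traces), function(g) {
    tr <- traces[[g]]
    above <- tr$rate >= theta_act
    if (!any(above)) {
      return(data.frame(group = integer(0), t_peak = numeric(0),
                        peak_rate = numeric(0), is_burst = logical(0),
                        double_peak = logical(0)))
    }
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    t_peak <- peak <- numeric(length(runs))
    for (k in seq_along(runs)) {
      i0 <- starts[runs[k]]
      i1 <- ends[runs[k]]
      seg <- tr$rate[i0:i1]
      j <- i0 + which.max(seg) - 1L
      t_peak[k] <- tr$time_ms[j]
      peak[k] <- tr$rate[j]
    }
    dp <- logical(length(runs))
    if (length(runs) > 1L) {
      close_pairs <- which(diff(t_peak) <= double_peak_window)
      dp[close_pairs] <- TRUE
      dp[close_pairs + 1L] <- TRUE
    }
    data.frame(group = g, t_peak = t_peak, peak_rate = peak,
               is_burst = peak >= theta_burst, double_peak = dp)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("group_activations", "data.frame")
  res
}

#' Score one replay attempt
#'
#' Walks the activation chain from group 1: each group must activate the
#' next within `delay_window` ms.  Any burst or double peak on the chain, or
#' an activation of the dummy group, voids the replay (quality 0); a clean
#' full chain scores quality 1.  The chain length (number of groups reached)
#' is reported alongside for diagnostic shading.
#'
#' @param activations a `group_activations` data frame for groups
#'   `1..n_groups` (activations of other groups are ignored).
#' @param n_groups length of the embedded sequence.
#' @param dummy_active was the dummy group activated during the trial?
#' @param delay_window admissible group-to-group peak delay `c(min, max)` ms.
#' @param t_start only activations at or after this time are considered.
#' @return List of class `replay_score`: `quality` (0/1), `chain_length`,
#'   `failure_reason` (one of `none`, `burst`, `double_peak`, `dummy_active`,
#'   `delay_violation`, `died_out`).
#' @export
score_replay <- function(activations, n_groups, dummy_active = FALSE,
                         delay_window = c(2, 20), t_start = -Inf) {
  act <- activations[activations$t_peak >= t_start, , drop = FALSE]
  chain <- list()
  reason <- "none"
  a1 <- act[act$group == 1L, , drop = FALSE]
  if (nrow(a1) == 0L) {
    return(new_replay_score(0, 0L, "died_out"))
  }
  cur <- a1[which.min(a1$t_peak), , drop = FALSE]
  chain[[1L]] <- cur
  for (g in seq_len(n_groups)[-1L]) {
    nxt <- act[act$group == g & act$t_peak > cur$t_peak, , drop = FALSE]
    if (nrow(nxt) == 0L) {
      reason <- "died_out"
      break
    }
    nxt <- nxt[which.min(nxt$t_peak), , drop = FALSE]
    d <- nxt$t_peak - cur$t_peak
    if (d < delay_window[1] || d > delay_window[2]) {
      reason <- "delay_violation"
      break
    }
    cur <- nxt
    chain[[g]] <- cur
  }
  chain <- do.call(rbind, chain)
  if (reason == "none") {
    if (any(chain$is_burst)) reason <- "burst"
    else if (any(chain$double_peak)) reason <- "double_peak"
    else if (isTRUE(dummy_active)) reason <- "dummy_active"
  }
  quality <- as.numeric(reason == "none" && nrow(chain) == n_groups)
  new_replay_score(quality, nrow(chain), reason)
}

new_replay_score <- function(quality, chain_length, reason) {
  structure(list(quality = quality, chain_length = as.integer(chain_length),
                 failure_reason = reason),
            class = "replay_score")
}

#' @export
print.replay_score <- function(x, ...) {
  cat(sprintf("<replay_score> quality = %g, chain = %d, reason = %s\n",
              x$quality, x$chain_length, x$failure_reason))
  invisible(x)
}

#' Count spontaneous replay events
#'
#' A spontaneous replay is an activation of the last assembly that was
#' preceded, in sequence order and within the admissible delay window at
#' every step, by activations of at least `min_chain` earlier assemblies.
#' Events involving bursting or double-peaked activations are disregarded.
#'
#' @param raster spike raster of the spontaneous phase.
#' @param conn the `connectivity_set` (for group membership; excitatory
#'   members are used).
#' @param t_range analysis window `c(t0, t1)` ms; the event rate is per
#'   second of this window.
#' @param min_chain minimum number of predecessor assemblies (default 3).
#' @param delay_window admissible peak-to-peak delay (ms).
#' @param sigma,theta_act,theta_burst,double_peak_window as in
#'   [population_rate()] / [detect_activations()].
#' @return List: `rate` (events/s), `n_events`, `events` (times of the
#'   last-group peaks), `activations`.
#' @export
count_spontaneous_replays <- function(raster, conn, t_range,
                                      min_chain = 3, delay_window = c(2, 20),
                                      sigma = 2, theta_act = 30,
                                      theta_burst = 180,
                                      double_peak_window = 30) {
  groups <- conn$groups
  n <- length(groups)
  traces <- lapply(groups, function(g) {
    population_rate(raster, g$E, sigma = sigma, t_range = t_range)
  })
  act <- detect_activations(traces, theta_act, theta_burst,
                            double_peak_window)
  last <- act[act$group == n, , drop = FALSE]
  events <- numeric(0)
  for (k in seq_len(nrow(last))) {
    ev <- last[k, ]
    if (ev$is_burst || ev$double_peak) next
    t_cur <- ev$t_peak
    depth <- 0L
    ok <- TRUE
    for (g in rev(seq_len(n - 1L))) {
      cand <- act[act$group == g &
                    t_cur - act$t_peak >= delay_window[1] &
                    t_cur - act$t_peak <= delay_window[2], , drop = FALSE]
      if (nrow(cand) == 0L) break
      cand <- cand[which.max(cand$t_peak), , drop = FALSE]
      if (cand$is_burst || cand$double_peak) {
        ok <- FALSE
        break
      }
      depth <- depth + 1L
      t_cur <- cand$t_peak
    }
    if (ok && depth >= min_chain) events <- c(events, ev$t_peak)
  }
  T_s <- (t_range[2] - t_range[1]) / 1000
  list(rate = length(events) / T_s, n_events = length(events),
       events = events, activations = act)
}

#' Coefficient of variation of inter-spike intervals
#'
#' @param spike_times spike times of one neuron (ms).
#' @return `sd(ISI)/mean(ISI)`, or `NA` for fewer than 3 spikes.
#' @export
cv_isi <- function(spike_times) {
  if (length(spike_times) < 3L) return(NA_real_)
  isi <- diff(sort(spike_times))
  sd(isi) / mean(isi)
}

#' Mean CV of ISIs over a set of neurons
#'
#' Neurons contributing fewer than `min_spikes` spikes are skipped: the
#' sample standard deviation over a handful of intervals is biased low
#' (roughly by a factor `1 - 3/(4 n_ISI)` for Poisson-like trains), so
#' short trains systematically understate the irregularity.  The default
#' requires ten spikes (nine intervals), keeping that bias below ~10%.
#'
#' @param raster spike raster.
#' @param ids neuron ids.
#' @param min_spikes minimum spikes per neuron to enter the average.
#' @export
mean_cv_isi <- function(raster, ids, min_spikes = 10L) {
  cvs <- vapply(ids, function(i) {
    ts <- raster$time_ms[raster$neuron == i]
    if (length(ts) < min_spikes) return(NA_real_)
    cv_isi(ts)
  }, numeric(1))
  mean(cvs, na.rm = TRUE)
}

#' Mean pairwise spike-train synchrony
#'
#' Spike trains are binned (default 5 ms) and the mean Pearson correlation
#' coefficient over all neuron pairs is returned.  Pairs in which either
#' train has zero variance are skipped.
#'
#' @param raster spike raster.
#' @param ids neuron ids.
#' @param bin bin width (ms).
#' @param t_range analysis window (ms).
#' @param max_neurons cap on the number of neurons used (subsampled
#'   deterministically by taking the first ids) to bound the pair count.
#' @return Mean pairwise correlation coefficient.
#' @export
pairwise_synchrony <- function(raster, ids, bin = 5, t_range = NULL,
                               max_neurons = 200L) {
  if (is.null(t_range)) t_range <- range(raster$time_ms)
  if (length(ids) > max_neurons) ids <- ids[seq_len(max_neurons)]
  breaks <- seq(t_range[1], t_range[2] + bin, by = bin)
  nb <- length(breaks) - 1L
  counts <- matrix(0L, nrow = nb, ncol = length(ids))
  sub <- raster[raster$neuron %in% ids & raster$time_ms >= t_range[1] &
                  raster$time_ms <= t_range[2], , drop = FALSE]
  for (k in seq_along(ids)) {
    ts <- sub$time_ms[sub$neuron == ids[k]]
    if (length(ts)) {
      b <- pmin(nb, findInterval(ts, breaks, rightmost.closed = TRUE))
      counts[, k] <- tabulate(b, nbins = nb)
    }
  }
  keep <- apply(counts, 2, sd) > 0
  if (sum(keep) < 2L) return(NA_real_)
  cm <- cor(counts[, keep, drop = FALSE])
  mean(cm[upper.tri(cm)])
}

#' Pulse-packet state of a group
#'
#' Characterises one volley by the fraction `alpha` of group members firing
#' at least once inside the window and the standard deviation `sigma` of
#' their first-spike times.
#'
#' @param raster spike raster.
#' @param ids excitatory members of the group.
#' @param window `c(t0, t1)` ms.
#' @return List with `alpha` and `sigma` (ms; 0 when one neuron fires).
#' @export
pulse_packet_state <- function(raster, ids, window) {
  sub <- raster[raster$neuron %in% ids & raster$time_ms >= window[1] &
                  raster$time_ms <= window[2], , drop = FALSE]
  if (nrow(sub) == 0L) return(list(alpha = 0, sigma = NA_real_))
  first <- vapply(split(sub$time_ms, sub$neuron), min, numeric(1))
  sigma <- if (length(first) > 1L) sd(first) else 0
  list(alpha = length(first) / length(ids), sigma = sigma)
}

#' Rate traces for all embedded groups
#'
#' @param raster spike raster.
#' @param conn `connectivity_set` with embedded groups.
#' @param which `"E"` (default) to use the excitatory members, `"I"` for
#'   inhibitory, `"both"` for all.
#' @param include_dummy also append the dummy group's trace.
#' @inheritParams population_rate
#' @return List of `rate_trace` objects (dummy trace last when requested).
#' @export
group_rate_traces <- function(raster, conn, which = "E", sigma = 2,
                              t_range = NULL, dt = 0.1,
                              include_dummy = FALSE) {
  sets <- lapply(conn$groups, function(g) {
    switch(which, E = g$E, I = g$I, both = c(g$E, g$I))
  })
  if (include_dummy) sets <- c(sets, list(conn$dummy))
  lapply(sets, population_rate, raster = raster, sigma = sigma,
         t_range = t_range, dt = dt)
}

#' Score a cued trial end-to-end
#'
#' Convenience wrapper: computes group and dummy rate traces, detects
#' activations, and scores the replay.
#'
#' @param raster spike raster of a trial.
#' @param conn `connectivity_set` with embedded groups.
#' @param t_start scoring starts here (typically the cue time).
#' @param ... passed to [detect_activations()] / [score_replay()].
#' @inheritParams population_rate
#' @return A `replay_score`.
#' @export
score_trial <- function(raster, conn, t_start = -Inf, sigma = 2,
                        t_range = NULL, ...) {
  traces <- group_rate_traces(raster, conn, sigma = sigma, t_range = t_range)
  act <- detect_activations(traces)
  dummy_tr <- population_rate(raster, conn$dummy, sigma = sigma,
                              t_range = t_range)
  dummy_act <- detect_activations(dummy_tr)
  dummy_on <- nrow(dummy_act[dummy_act$t_peak >= t_start, ]) > 0L
  score_replay(act, n_groups = length(conn$groups),
               dummy_active = dummy_on, t_start = t_start, ...)
}
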