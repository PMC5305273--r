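# Replay metrics: rate kernels, activation detection, replay scoring,
# spontaneous-event counting, CV, synchrony, pulse-packet portraits.

test_that("population rate has the closed-form synchronous peak and conserves spike mass", {
  ids <- 1:100
  raster <- data.frame(time_ms = rep(50, 100), neuron = ids)
  tr <- population_rate(raster, ids, sigma = 2, t_range = c(0, 100))
  expect_equal(max(tr$rate), 1000 / (2 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(tr$time_ms[which.max(tr$rate)], 50)
  # kernel integrates to spike count / |ids|
  mass <- sum(tr$rate) * 0.1 / 1000
  expect_equal(mass, nrow(raster) / length(ids), tolerance = 1e-6)
  # empty raster: identically zero
  tr0 <- population_rate(empty <- data.frame(time_ms = numeric(0),
                                             neuron = integer(0)),
                         ids, t_range = c(0, 100))
  expect_true(all(tr0$rate == 0))
})

test_that("a homogeneous Poisson population is estimated at its rate", {
  ids <- 1:200
  raster <- with_substream(5, "poisson-pop", {
    data.frame(time_ms = runif(200 * 5, 0, 1000),  # 5 spikes/s per neuron
               neuron = rep(ids, 5))
  })
  tr <- population_rate(raster, ids, t_range = c(100, 900))
  expect_equal(mean(tr$rate), 5, tolerance = 0.15)
})

test_that("activation detection finds peaks, bursts and double peaks", {
  grid <- seq(0, 300, by = 0.1)
  bump <- function(t0, amp) amp * exp(-(grid - t0)^2 / (2 * 3^2))
  mk <- function(rate) {
    structure(data.frame(time_ms = grid, rate = rate),
              class = c("rate_trace", "data.frame"))
  }
  # constant sub-threshold trace: nothing detected
  expect_identical(nrow(detect_activations(mk(rep(10, length(grid))))), 0L)
  # clean bump at 100 spikes/s
  act <- detect_activations(mk(bump(150, 100)))
  expect_identical(nrow(act), 1L)
  expect_equal(act$t_peak, 150, tolerance = 0.11)
  expect_false(act$is_burst)
  # bursting bump
  act2 <- detect_activations(mk(bump(150, 200)))
  expect_true(act2$is_burst)
  # two super-threshold peaks 20 ms apart: double peak flagged
  act3 <- detect_activations(mk(bump(150, 100) + bump(170, 100)))
  expect_true(any(act3$double_peak))
  # same two peaks 60 ms apart: no flag
  act4 <- detect_activations(mk(bump(100, 100) + bump(160, 100)))
  expect_identical(nrow(act4), 2L)
  expect_false(any(act4$double_peak))
})

test_that("replay scoring walks the chain and reports the failure taxonomy", {
  mk_act <- function(times, burst = FALSE, dp = FALSE) {
    data.frame(group = seq_along(times), t_peak = times,
               peak_rate = ifelse(burst, 200, 100),
               is_burst = rep(burst, length(times)),
               double_peak = rep(dp, length(times)))
  }
  clean <- mk_act(seq(50, by = 5, length.out = 10))
  s <- score_replay(clean, n_groups = 10)
  expect_equal(s$quality, 1)
  expect_identical(s$chain_length, 10L)
  expect_identical(s$failure_reason, "none")
  # dummy activation voids an otherwise clean replay
  s2 <- score_replay(clean, n_groups = 10, dummy_active = TRUE)
  expect_equal(s2$quality, 0)
  expect_identical(s2$failure_reason, "dummy_active")
  # a 25 ms gap violates the 2-20 ms delay window
  gap <- mk_act(c(50, 55, 80, 85, 90, 95, 100, 105, 110, 115))
  s3 <- score_replay(gap, n_groups = 10)
  expect_identical(s3$failure_reason, "delay_violation")
  expect_identical(s3$chain_length, 2L)
  # bursting chain
  s4 <- score_replay(mk_act(seq(50, by = 5, length.out = 10), burst = TRUE),
                     n_groups = 10)
  expect_equal(s4$quality, 0)
  expect_identical(s4$failure_reason, "burst")
  # propagation dies after 4 groups
  s5 <- score_replay(mk_act(seq(50, by = 5, length.out = 4)), n_groups = 10)
  expect_identical(s5$failure_reason, "died_out")
  expect_identical(s5$chain_length, 4L)
})

test_that("scoring is invariant to neuron relabelling within groups", {
  fx <- make_fixture("clean-replay-raster", seed = 3)
  s1 <- score_trial(fx$raster, fx$conn)
  # permute ids within each group consistently in raster and membership
  perm <- fx
  with_substream(8, "perm", {
    for (k in seq_along(perm$conn$groups)) {
      old <- perm$conn$groups[[k]]$E
      new <- sample(old)
      m <- match(perm$raster$neuron, old)
      sel <- !is.na(m)
      perm$raster$neuron[sel] <- new[m[sel]]
      perm$conn$groups[[k]]$E <- new
    }
  })
  s2 <- score_trial(perm$raster, perm$conn)
  expect_identical(s1, s2)
})

test_that("synthetic fixtures score as constructed", {
  clean <- make_fixture("clean-replay-raster")
  s <- score_trial(clean$raster, clean$conn)
  expect_equal(s$quality, 1)
  burst <- make_fixture("burst-raster")
  sb <- score_trial(burst$raster, burst$conn)
  expect_equal(sb$quality, 0)
  expect_identical(sb$failure_reason, "burst")
})

test_that("spontaneous replay counting finds constructed events at the right rate", {
  n_groups <- 10
  M <- 20
  groups <- lapply(seq_len(n_groups), function(k) ((k - 1) * M + 1):(k * M))
  conn <- list(groups = lapply(groups, function(g) list(E = g)),
               dummy = (n_groups * M + 1):(n_groups * M + M))
  # two clean full replays within 10 s
  r1 <- volley_raster(groups, seq(2000, by = 6, length.out = n_groups),
                      jitter = 1.5, seed = 1)
  r2 <- volley_raster(groups, seq(7000, by = 6, length.out = n_groups),
                      jitter = 1.5, seed = 2)
  raster <- rbind(r1, r2)
  cnt <- count_spontaneous_replays(raster, conn, t_range = c(0, 10000))
  expect_identical(cnt$n_events, 2L)
  expect_equal(cnt$rate, 0.2)
  # no last-group activation: zero events
  cnt0 <- count_spontaneous_replays(r1[r1$neuron <= (n_groups - 1) * M, ],
                                    conn, t_range = c(0, 10000))
  expect_identical(cnt0$n_events, 0L)
  # a partial chain reaching only 2 predecessors does not count
  part <- volley_raster(groups[7:10],
                        seq(4000, by = 6, length.out = 4), jitter = 1.5,
                        seed = 3)
  cntp <- count_spontaneous_replays(part, conn, t_range = c(0, 10000),
                                    min_chain = 3)
  expect_identical(cntp$n_events, 1L)  # 3 predecessors: exactly at the bar
  cntp4 <- count_spontaneous_replays(part, conn, t_range = c(0, 10000),
                                     min_chain = 4)
  expect_identical(cntp4$n_events, 0L)
})

test_that("CV of inter-spike intervals separates regular, Poisson and bursty firing", {
  expect_equal(cv_isi(seq(0, 1000, by = 10)), 0)
  pois <- with_substream(9, "cv-poisson", cumsum(rexp(2000, 1 / 10)))
  expect_equal(cv_isi(pois), 1, tolerance = 0.05)
  # bursty train (triplets at 2 ms inside 300 ms cycles): two ISI scales
  # give CV = sqrt(2*(2-100)^2 + (296-100)^2)/sqrt(3)/100 > 1
  base <- seq(0, 30000, by = 300)
  bursts <- sort(c(base, base + 2, base + 4))
  expect_gt(cv_isi(bursts), 1)
  expect_true(is.na(cv_isi(c(1, 2))))
})

test_that("pairwise synchrony is 1 for co-active, ~0 for independent neurons", {
  ids <- 1:40
  co <- data.frame(time_ms = rep(seq(100, 900, by = 100), each = 40),
                   neuron = rep(ids, 9))
  expect_equal(pairwise_synchrony(co, ids, t_range = c(0, 1000)), 1)
  ind <- with_substream(3, "sync-null", {
    data.frame(time_ms = runif(40 * 50, 0, 10000),
               neuron = rep(ids, 50))
  })
  expect_lt(abs(pairwise_synchrony(ind, ids, t_range = c(0, 10000))), 0.05)
})

test_that("pulse-packet state reports participation and first-spike dispersion", {
  ids <- 1:50
  sync <- data.frame(time_ms = rep(100, 50), neuron = ids)
  ps <- pulse_packet_state(sync, ids, window = c(90, 110))
  expect_equal(ps$alpha, 1)
  expect_equal(ps$sigma, 0)
  # 20% participation with known jitter
  sub <- with_substream(4, "packet", {
    data.frame(time_ms = rnorm(10, 100, 3), neuron = 1:10)
  })
  ps2 <- pulse_packet_state(sub, ids, window = c(80, 120))
  expect_equal(ps2$alpha, 0.2)
  expect_equal(ps2$sigma, sd(sub$time_ms))
  # empty window
  ps0 <- pulse_packet_state(sync, ids, window = c(200, 300))
  expect_equal(ps0$alpha, 0)
})

test_that("metrics are pure: identical inputs give identical outputs", {
  fx <- make_fixture("clean-replay-raster")
  a <- score_trial(fx$raster, fx$conn)
  b <- score_trial(fx$raster, fx$conn)
  expect_identical(a, b)
  t1 <- population_rate(fx$raster, fx$conn$groups[[1]]$E,
                        t_range = c(0, 200))
  t2 <- population_rate(fx$raster, fx$conn$groups[[1]]$E,
                        t_range = c(0, 200))
  expect_identical(t1, t2)
})
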