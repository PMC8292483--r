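test_that("antidromic identification applies the latency, reliability and waveform criteria", {
  ok <- simulate_speed_tuned_spikes(antidromic_latency = 0.003, seed = 51)
  res <- identify_antidromic(ok$train, ok$pulses)
  expect_true(res$identified)
  expect_lt(res$median_latency, 0.005)
  expect_gte(res$response_reliability, 0.5)
  expect_gte(res$waveform_similarity, 0.9)

  slow <- simulate_speed_tuned_spikes(antidromic_latency = 0.006, seed = 52)
  expect_false(identify_antidromic(slow$train, slow$pulses)$identified)

  mism <- simulate_speed_tuned_spikes(
    antidromic_latency = 0.003,
    evoked_template = spike_waveform_template("wide"), seed = 53)
  res3 <- identify_antidromic(mism$train, mism$pulses)
  expect_false(res3$identified)
  expect_lt(res3$waveform_similarity, 0.9)

  # unreliable: no pulse-locked spikes at all
  quiet <- simulate_speed_tuned_spikes(pulse_reliability = 0,
                                       baseline_rate = 0.5, slope = 0,
                                       seed = 54)
  res4 <- identify_antidromic(quiet$train, quiet$pulses)
  expect_false(res4$identified)
  expect_lt(res4$response_reliability, 0.5)
})

test_that("waveform similarity equals a direct correlation of mean waveforms", {
  sim <- simulate_speed_tuned_spikes(antidromic_latency = 0.003, seed = 55)
  res <- identify_antidromic(sim$train, sim$pulses)
  st <- sim$train$spike_times
  ev_idx <- unlist(lapply(sim$pulses$pulse_times, function(p)
    which(st > p & st - p <= 0.01)[1]))
  ev_idx <- ev_idx[!is.na(ev_idx)]
  m_ev <- colMeans(sim$train$waveforms[ev_idx, , drop = FALSE])
  m_lo <- colMeans(sim$train$waveforms[-ev_idx, , drop = FALSE])
  expect_equal(res$waveform_similarity, cor(m_ev, m_lo), tolerance = 1e-12)
})

test_that("a planted step response gives positive post-event Z scores", {
  set.seed(56)
  events <- seq(20, 180, by = 10)
  # 5 Hz baseline, 25 Hz for 1 s after each event (regular jittered spikes)
  base <- sort(runif(200 * 5, 0, 200))
  extra <- unlist(lapply(events, function(ev) ev + sort(runif(20, 0, 1))))
  al <- align_to_events(sort(c(base, extra)), events)
  post <- al$zscore[al$time > 0.1 & al$time < 0.9]
  expect_gt(mean(post), 2)
  expect_lt(abs(mean(al$zscore[al$time < -1])), 2)
})

test_that("an exactly periodic train is flagged for zero baseline SD", {
  events <- seq(20, 80, by = 10)
  train <- seq(0.05, 100, by = 0.1)  # 10 Hz metronome aligned to bins
  al <- align_to_events(train, events, bin = 0.1)
  expect_true(al$baseline_degenerate)
  expect_true(all(is.na(al$zscore)))
})

test_that("Z-scored averages are calibrated under a homogeneous Poisson null", {
  set.seed(57)
  inside <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    st <- sort(runif(2000, 0, 100))      # 20 Hz homogeneous
    events <- seq(10, 90, by = 8)
    al <- align_to_events(st, events)
    mz <- mean(al$zscore)
    if (abs(mz) < 3 / sqrt(length(al$time))) inside <- inside + 1
  }
  expect_gte(inside / n_rep, 0.85)
})

test_that("Z-scoring is invariant to affine changes of the signal", {
  set.seed(58)
  st <- sort(runif(3000, 0, 100))
  events <- seq(10, 90, by = 10)
  al <- align_to_events(st, events)
  # affine transform of the mean response leaves the Z-score unchanged
  al2 <- make_aligned(al$time, 3 * al$mean + 7,
                      baseline_window = al$baseline_window)
  expect_equal(al2$zscore, al$zscore, tolerance = 1e-9)
})

test_that("the 15%-of-peak rule is analytic on ramps and steps", {
  tt <- seq(-1.99, 1.99, by = 0.02)
  ramp <- ifelse(tt < -0.2, 0, ifelse(tt < 0, (tt + 0.2) / 0.2, 1))
  est <- detect_onset_offset(make_aligned(tt, ramp, baseline_sd = 0))
  expect_equal(est$onset_time, -0.17, tolerance = 1e-9)
  step <- ifelse(tt >= -0.1, 1, 0)
  est2 <- detect_onset_offset(make_aligned(tt, step, baseline_sd = 0))
  expect_lt(abs(est2$onset_time + 0.1), 0.0201)
  # time-translation equivariance of the ramp estimate
  ramp_sh <- ifelse(tt < 0.1, 0, ifelse(tt < 0.3, (tt - 0.1) / 0.2, 1))
  est3 <- detect_onset_offset(make_aligned(tt, ramp_sh, baseline_sd = 0))
  expect_equal(est3$onset_time, est$onset_time + 0.3, tolerance = 1e-9)
  # offset: symmetric decay back into the baseline band
  pulse <- ifelse(tt < 0, 0, ifelse(tt < 0.2, tt / 0.2,
                                    pmax(0, 1 - (tt - 0.2) / 0.4)))
  est4 <- detect_onset_offset(make_aligned(tt, pulse, baseline_sd = 0))
  expect_equal(est4$offset_time, 0.2 + 0.85 * 0.4, tolerance = 0.021)
  # a flat response is undefined
  flat <- detect_onset_offset(make_aligned(tt, rep(1, length(tt)),
                                           baseline_sd = 0))
  expect_true(is.na(flat$onset_time))
})

test_that("population onset lead recovers the planted 100 ms within 30 ms", {
  leads <- vapply(1:6, function(u) {
    sim <- simulate_speed_tuned_spikes(seed = 60 + u)
    al <- align_to_events(sim$train, sim$bouts$onset_time)
    detect_onset_offset(al, smooth_sd = 0.05)$onset_time
  }, numeric(1))
  expect_lt(abs(mean(leads) + 0.1), 0.03)
})

test_that("locomotion bouts come from hysteresis thresholding", {
  tt <- seq(0, 60, by = 0.02)
  expect_equal(nrow(locomotion_bouts(data.frame(time = tt, speed = 0))), 0L)
  sq <- ifelse(tt >= 10 & tt < 20 | tt >= 35 & tt < 50, 20, 0)
  b <- locomotion_bouts(data.frame(time = tt, speed = sq))
  expect_equal(nrow(b), 2L)
  expect_equal(b$onset_time, c(10, 35), tolerance = 0.021)
  expect_equal(b$offset_time, c(20, 50), tolerance = 0.021)
  # dip between the thresholds does not close the bout
  dip <- ifelse(tt >= 10 & tt < 20, 20, 0)
  dip[tt >= 14 & tt < 15] <- 2   # below on (3) but above off (1)
  b2 <- locomotion_bouts(data.frame(time = tt, speed = dip))
  expect_equal(nrow(b2), 1L)
  # planted bouts are recovered with high overlap
  sim <- simulate_treadmill_speed(seed = 62)
  b3 <- locomotion_bouts(sim$speed)
  expect_equal(nrow(b3), nrow(sim$bouts))
  jac <- vapply(seq_len(nrow(b3)), function(i) {
    inter <- min(b3$offset_time[i], sim$bouts$offset_time[i]) -
      max(b3$onset_time[i], sim$bouts$onset_time[i])
    uni <- max(b3$offset_time[i], sim$bouts$offset_time[i]) -
      min(b3$onset_time[i], sim$bouts$onset_time[i])
    inter / uni
  }, numeric(1))
  expect_gte(min(jac), 0.9)
})

test_that("speed tuning is exactly monotone for deterministic monotone rates", {
  # staircase speed: one plateau per 3 cm/s bin, regular spikes whose rate
  # equals the plateau speed (even rates so windows hold whole periods)
  fr <- 50
  plateaus <- seq(4.5, 28.5, by = 3)
  rates_up <- seq(4, 20, by = 2)   # one even rate per plateau
  dur <- 10
  tt <- seq(0, length(plateaus) * dur - 1 / fr, by = 1 / fr)
  sp <- rep(plateaus, each = dur * fr)
  spikes_for <- function(rates) {
    unlist(lapply(seq_along(plateaus), function(i) {
      t0 <- (i - 1) * dur
      seq(t0 + 1e-4, t0 + dur - 1e-4, by = 1 / rates[i])
    }))
  }
  kin <- kinematic_series(tt, speed = sp)
  bouts <- data.frame(onset_time = 0, offset_time = length(plateaus) * dur)
  up <- speed_tuning(spikes_for(rates_up), kin, bouts = bouts)
  expect_equal(attr(up, "spearman_rho"), 1.0)
  down <- speed_tuning(spikes_for(rev(rates_up)), kin, bouts = bouts)
  expect_equal(attr(down, "spearman_rho"), -1.0)
  expect_true(all(up$normalized_rate >= 0 & up$normalized_rate <= 1))
  expect_equal(min(up$normalized_rate), 0)
  expect_equal(max(up$normalized_rate), 1)
})

test_that("Spearman rho equals the brute-force rank oracle, ties included", {
  set.seed(63)
  for (k in 1:25) {
    n <- sample(4:50, 1)
    x <- sample(round(runif(n, 0, 10), 1))   # duplicates likely
    y <- round(runif(n, 0, 10), 1)
    sr <- spearman_rank(x, y)
    expect_equal(sr$rho, oracle_spearman(x, y), tolerance = 1e-12)
  }
  # perfect monotone maps
  expect_equal(spearman_rank(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rank(1:10, -(1:10)^3)$rho, -1)
})

test_that("flat-rate units rarely show spurious speed tuning", {
  inside <- vapply(1:8, function(s) {
    sim <- simulate_speed_tuned_spikes(slope = 0, seed = 64 + s)
    tc <- speed_tuning(sim$train, sim$speed, bouts = sim$bouts)
    attr(tc, "spearman_p") > 0.05
  }, logical(1))
  expect_gte(sum(inside), 6)
})
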