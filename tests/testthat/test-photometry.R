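flat_trace <- function(f = 100, dur = 60, fs = 100) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  fluorescence_trace(tt, rep(f, length(tt)))
}

test_that("dF/F is zero for constant fluorescence and exact on plateaus", {
  d <- compute_dff(flat_trace())
  expect_equal(d$dff, rep(0, nrow(d)), tolerance = 1e-9)
  tr <- flat_trace(dur = 120)
  raw <- tr$raw
  raw[tr$time >= 60 & tr$time < 65] <- 100 * 1.05
  tr2 <- fluorescence_trace(tr$time, raw)
  d2 <- compute_dff(tr2, lowpass_hz = NA)
  on_plateau <- d2$time >= 61 & d2$time < 64
  expect_equal(d2$dff[on_plateau], rep(0.05, sum(on_plateau)),
               tolerance = 1e-6)
  off_plateau <- d2$time < 55
  expect_lt(max(abs(d2$dff[off_plateau])), 1e-6)
})

test_that("dF/F is invariant to a positive gain on the raw trace", {
  sim <- simulate_photometry(seed = 71)
  d1 <- compute_dff(sim$trace)
  tr2 <- fluorescence_trace(sim$trace$time, sim$trace$raw * 7.3)
  d2 <- compute_dff(tr2)
  expect_equal(d2$dff, d1$dff, tolerance = 1e-9)
})

test_that("a non-positive baseline is an error", {
  tt <- seq(0, 10, by = 0.01)
  tr <- fluorescence_trace(tt, rep(-5, length(tt)))
  expect_error(compute_dff(tr), "F0")
})

test_that("planted transient amplitudes are recovered", {
  sim <- simulate_photometry(noise_sd = 0, seed = 72)
  d <- compute_dff(sim$trace)
  eta <- event_triggered_average(d, sim$locomotion_onsets)
  amp <- max(eta$mean) - mean(eta$mean[eta$time < -1])
  expect_lt(abs(amp - 0.08) / 0.08, 0.05)
})

test_that("the event-triggered average reproduces the kernel shape", {
  sim <- simulate_photometry(duration = 200, noise_sd = 0,
                             locomotion_onsets = seq(20, 180, by = 10),
                             transient_lead = 0.12,  # grid-aligned
                             bleach_tau = Inf, seed = 73)
  d <- compute_dff(sim$trace, lowpass_hz = NA)
  eta <- event_triggered_average(d, sim$locomotion_onsets - 0.12)
  post <- eta$time >= 0 & eta$time <= 1.5
  kernel <- 0.08 * exp(-eta$time[post] / 0.5)
  expect_equal(eta$mean[post], kernel, tolerance = 0.02)
  # zero signal averages to zero
  d0 <- compute_dff(flat_trace(dur = 100))
  eta0 <- event_triggered_average(d0, seq(10, 90, by = 10))
  expect_lt(max(abs(eta0$mean)), 1e-9)
})

test_that("event jitter attenuates the average by the convolution factor", {
  set.seed(74)
  onsets <- seq(20, 380, by = 10)
  jit <- rnorm(length(onsets), 0, 0.05)
  sim <- simulate_photometry(duration = 400, noise_sd = 0,
                             locomotion_onsets = onsets + jit,
                             transient_lead = 0, bleach_tau = Inf, seed = 74)
  d <- compute_dff(sim$trace, lowpass_hz = NA)
  eta <- event_triggered_average(d, onsets)
  got <- max(eta$mean)
  # oracle: exponential kernel convolved with the jitter density
  tg <- seq(-0.4, 1, by = 0.001)
  kern <- function(t) ifelse(t >= 0, exp(-t / 0.5), 0)
  dens <- dnorm(tg, 0, 0.05)
  conv <- vapply(tg, function(t0)
    sum(kern(t0 - tg) * dens) * 0.001, numeric(1))
  expect_lt(abs(got - 0.08 * max(conv)) / (0.08 * max(conv)), 0.05)
  expect_lt(got, 0.08)  # attenuation happened
})

test_that("noiseless onset lead matches the planted lead to one sample", {
  sim <- simulate_photometry(noise_sd = 0, transient_lead = 0.12, seed = 75)
  eta <- event_triggered_average(compute_dff(sim$trace, lowpass_hz = NA),
                                 sim$locomotion_onsets)
  est <- onset_lead(eta)
  expect_lt(abs(est$onset_time + 0.12), 0.011)
  # transient at the event time: onset near zero
  sim2 <- simulate_photometry(noise_sd = 0, transient_lead = 0, seed = 76)
  eta2 <- event_triggered_average(compute_dff(sim2$trace, lowpass_hz = NA),
                                  sim2$locomotion_onsets)
  expect_lt(abs(onset_lead(eta2)$onset_time), 0.011)
})

test_that("session onset leads recover the planted value within 30 ms", {
  leads <- vapply(1:6, function(u) {
    sim <- simulate_photometry(seed = 200 + u)
    eta <- event_triggered_average(compute_dff(sim$trace),
                                   sim$locomotion_onsets)
    onset_lead(eta)$onset_time
  }, numeric(1))
  expect_lt(abs(mean(leads) + 0.125), 0.03)
})

test_that("the input-output curve tracks a monotone planted map", {
  sched <- data.frame(time = seq(5, 315, by = 2.5),
                      power = rep(c(2, 5, 10, 15, 20), each = 25))
  sim <- simulate_photometry(duration = 320, locomotion_onsets = numeric(0),
                             pulse_schedule = sched, seed = 77)
  er <- evoked_responses(compute_dff(sim$trace), sched)
  io <- input_output_curve(er)
  expect_true(all(diff(io$mean_amplitude) > 0))
  # noiseless amplitudes match the planted map closely
  sim0 <- simulate_photometry(duration = 320, locomotion_onsets = numeric(0),
                              pulse_schedule = sched, noise_sd = 0,
                              bleach_tau = Inf, seed = 78)
  er0 <- evoked_responses(compute_dff(sim0$trace, lowpass_hz = NA), sched)
  planted <- 0.3 * er0$power / (er0$power + 10)
  expect_equal(er0$amplitude, planted, tolerance = 0.02)
  expect_error(input_output_curve(er0[er0$power == 2, , drop = FALSE]),
               "two distinct")
})

test_that("suppression ratio is 1 for identical groups and tracks the factor", {
  sched <- data.frame(time = seq(5, 65, by = 2.5), power = 10)
  ctl <- simulate_photometry(duration = 70, locomotion_onsets = numeric(0),
                             pulse_schedule = sched, seed = 79)
  er_ctl <- evoked_responses(compute_dff(ctl$trace), sched)
  expect_equal(suppression_ratio(er_ctl, er_ctl), 1.0)
  sup0 <- simulate_photometry(duration = 70, locomotion_onsets = numeric(0),
                              pulse_schedule = sched, suppression_factor = 0,
                              noise_sd = 0, bleach_tau = Inf, seed = 80)
  er0 <- evoked_responses(compute_dff(sup0$trace, lowpass_hz = NA), sched)
  expect_equal(er0$amplitude, 0, tolerance = 1e-9)
})
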