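test_that("all generators are bit-identical under a fixed seed", {
  expect_identical(simulate_hunting_trial(n_episodes = 4, seed = 7),
                   simulate_hunting_trial(n_episodes = 4, seed = 7))
  expect_identical(simulate_speed_tuned_spikes(seed = 7),
                   simulate_speed_tuned_spikes(seed = 7))
  expect_identical(simulate_photometry(seed = 7),
                   simulate_photometry(seed = 7))
  expect_identical(simulate_gait(seed = 7), simulate_gait(seed = 7))
  expect_identical(simulate_looming_trial(seed = 7),
                   simulate_looming_trial(seed = 7))
  expect_identical(simulate_puncta_image(seed = 7),
                   simulate_puncta_image(seed = 7))
  # different seeds differ (noise is the only stochastic gait component)
  expect_false(identical(simulate_gait(paw_noise_sd = 0.1, seed = 7)$paws,
                         simulate_gait(paw_noise_sd = 0.1, seed = 8)$paws))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99); a <- runif(3)
  set.seed(99); invisible(simulate_hunting_trial(n_episodes = 3, seed = 1))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("ground truth round-trips through JSON exactly", {
  sim <- simulate_hunting_trial(n_episodes = 6, seed = 31)
  path <- tempfile(fileext = ".json")
  write_ground_truth(sim$ground_truth, path)
  back <- read_ground_truth(path)
  expect_equal(unclass(back), unclass(sim$ground_truth))
  g <- simulate_gait(seed = 3)
  write_ground_truth(g$ground_truth, path)
  expect_equal(unclass(read_ground_truth(path)), unclass(g$ground_truth))
})

test_that("a trial with no planted episodes yields none downstream", {
  sim <- simulate_hunting_trial(n_episodes = 0, position_noise_sd = 0,
                                seed = 32)
  ep <- detect_approach_episodes(kinematics(sim$trajectory))
  expect_equal(nrow(ep), 0L)
  expect_equal(length(sim$attacks$attack_times), 0L)
})

test_that("planted hunting trajectories satisfy the criteria exactly where planned", {
  sim <- simulate_hunting_trial(n_episodes = 8, position_noise_sd = 0,
                                seed = 33)
  kin <- kinematics(sim$trajectory)
  orc <- oracle_detect_episodes(kin)   # independent criteria scan
  gt <- sim$ground_truth$episode_intervals
  expect_equal(nrow(orc), nrow(gt))
  expect_equal(orc$start_time, gt$start, tolerance = 1e-9)
  expect_equal(orc$end_time, gt$end, tolerance = 1e-9)
})

test_that("hunting generator validates its parameters", {
  expect_error(simulate_hunting_trial(n_episodes = 3,
                                      peak_speeds = c(10, 20), seed = 1),
               "one entry per")
  expect_error(simulate_hunting_trial(n_episodes = 2,
                                      peak_speeds = c(10, -5), seed = 1),
               "> 0")
  expect_error(simulate_hunting_trial(n_episodes = -1, seed = 1))
})

test_that("speed-tuned spikes have higher rates in faster windows", {
  sim <- simulate_speed_tuned_spikes(slope = 1.2, seed = 34)
  tc <- speed_tuning(sim$train, sim$speed, bouts = sim$bouts)
  lo <- tc$mean_rate[tc$speed_bin_center <= 9]
  hi <- tc$mean_rate[tc$speed_bin_center >= 21]
  expect_gt(mean(hi), mean(lo))
})

test_that("pulse-locked spikes stay within 5 ms of the pulses", {
  sim <- simulate_speed_tuned_spikes(antidromic_latency = 0.003,
                                     latency_jitter_sd = 0.0002, seed = 35)
  lat <- unlist(lapply(sim$pulses$pulse_times, function(p) {
    d <- sim$train$spike_times - p
    d[d > 0 & d <= 0.01][1]
  }))
  expect_true(all(lat < 0.005, na.rm = TRUE))
})

test_that("negative instantaneous rates are clipped and logged", {
  sim <- simulate_speed_tuned_spikes(baseline_rate = 2, slope = -1,
                                     seed = 36)
  expect_gt(sim$ground_truth$n_clipped, 0)
})

test_that("a noiseless photometry transient starts exactly at the planted lead", {
  sim <- simulate_photometry(duration = 60, locomotion_onsets = 30,
                             noise_sd = 0, seed = 37)
  raw <- sim$trace$raw
  i_rise <- which(diff(raw) > 1e-9)[1] + 1L
  expect_equal(sim$trace$time[i_rise], 30 - 0.125, tolerance = 1 / 100)
})

test_that("zero suppression abolishes evoked transients", {
  sched <- data.frame(time = c(10, 14, 18), power = 10)
  sim <- simulate_photometry(duration = 30, locomotion_onsets = numeric(0),
                             pulse_schedule = sched, suppression_factor = 0,
                             noise_sd = 0, seed = 38)
  expect_equal(var(sim$trace$raw), 0)
  expect_error(simulate_photometry(suppression_factor = 1.5, seed = 1),
               "suppression")
  expect_error(simulate_photometry(amplitude_map = function(p) p + 1,
                                   seed = 1),
               "0 mW")
})

test_that("gait generator plants stride = speed / frequency and validates duty", {
  g <- simulate_gait(body_speed = 20, step_frequency = 4, seed = 39)
  expect_equal(g$ground_truth$stride_length, 5)
  expect_error(simulate_gait(duty_cycle = 1.2, seed = 1), "duty_cycle")
  expect_error(simulate_gait(duty_cycle = 0, seed = 1), "duty_cycle")
})

test_that("a null looming escape stays at baseline", {
  lt <- simulate_looming_trial(baseline_speed = 8, escape_speed = 8,
                               seed = 40)
  sp <- compute_speed(lt$trajectory)
  em <- escape_metrics(looming_session(sp, lt$ground_truth$stimulus_onsets))
  expect_lt(abs(em$peak_speed_during - 8) / 8, 0.25)
  expect_equal(em$peak_speed_during, lt$ground_truth$peak_speed_during,
               tolerance = 1e-6)
})

test_that("puncta generator honours counts, masks and feasibility", {
  p0 <- simulate_puncta_image(n_puncta = 0, noise_sd = 0, seed = 41)
  expect_equal(var(as.vector(p0$image)), 0)
  p <- simulate_puncta_image(n_puncta = 40, seed = 42)
  expect_equal(p$ground_truth$n_puncta, 40)
  expect_equal(p$ground_truth$density,
               40 / (sum(p$mask) * 0.1^2))
  expect_error(simulate_puncta_image(n_puncta = 500, width = 40, height = 40,
                                     seed = 43),
               "mask too small")
})
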