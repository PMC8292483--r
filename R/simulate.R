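#' Ground-truth serialization
#'
#' Generator ground truth (every planted quantity plus the echoed
#' parameters) is stored as type-preserving JSON so that a round trip
#' through disk reproduces the object exactly.
#'
#' @param gt A `"ground_truth"` list.
#' @param path File path (JSON).
#' @return `write_ground_truth` invisibly returns `path`;
#'   `read_ground_truth` returns the `"ground_truth"` object.
#' @export
write_ground_truth <- function(gt, path) {
  writeLines(jsonlite::serializeJSON(unclass(gt)), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  structure(jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n")),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

ground_truth <- function(...) structure(list(...), class = "ground_truth")

#' Simulate a predatory-hunting trial
#'
#' Builds a predator-prey trajectory with a planted number of approach
#' episodes. During each episode the predator runs straight at the prey
#' with a smooth speed profile peaking at the planted episode speed, head
#' oriented at the prey (azimuth 0), until the predator-prey distance
#' drops to contact range; a contact phase with Poisson jaw attacks
#' follows, then the prey relocates while the predator retreats with its
#' head turned away from the prey (azimuth 180, so neither approach
#' criterion holds between episodes). Gaussian position noise emulates
#' tracking jitter.
#'
#' @param n_episodes Number of planted approach episodes (each hunting
#'   trial contains 10-20 in wild-type mice; default 15).
#' @param peak_speeds Planted per-episode peak approach speeds (cm/s);
#'   default uniform in 25-45.
#' @param frame_rate Frames per second (default 50).
#' @param arena Arena extent (cm), default 25 x 25.
#' @param start_distance Range (cm) of the predator-prey distance at
#'   episode start.
#' @param contact_duration Range (s) of the post-capture contact phase.
#' @param retreat_speed Predator speed between episodes (cm/s).
#' @param attack_rate Poisson jaw-attack rate (per s) while the
#'   (noise-free) PPD is below `attack_ppd`.
#' @param attack_ppd PPD threshold below which attacks are emitted (cm).
#' @param contact_distance PPD reached at the end of an approach (cm).
#' @param position_noise_sd Tracking noise SD per coordinate (cm).
#' @param seed Integer seed; identical seed and parameters give
#'   bit-identical output.
#' @return List with `trajectory` (a [trajectory()]), `attacks`
#'   (an [attack_log()]), and `ground_truth` (planted episode intervals,
#'   planted and realized peak speeds, attack times, capture time, echoed
#'   parameters).
#' @export
simulate_hunting_trial <- function(n_episodes = 15, peak_speeds = NULL,
                                   frame_rate = 50, arena = c(25, 25),
                                   start_distance = c(12, 16),
                                   contact_duration = c(0.6, 1.5),
                                   retreat_speed = 18, attack_rate = 2,
                                   attack_ppd = 3, contact_distance = 1.2,
                                   position_noise_sd = 0.1, seed = NULL) {
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  stopifnot_scalar(attack_rate, "attack_rate", nonneg = TRUE)
  if (n_episodes < 0) stop("n_episodes must be >= 0")
  with_seed(sub_seed(seed, 1L), {
    if (is.null(peak_speeds)) peak_speeds <- stats::runif(n_episodes, 25, 45)
    if (length(peak_speeds) != n_episodes)
      stop("peak_speeds must have one entry per planned episode")
    if (n_episodes > 0 && any(peak_speeds <= 0))
      stop("peak speeds must be > 0")
    fr <- frame_rate
    margin <- 5
    rand_point <- function()
      c(stats::runif(1, margin, arena[1] - margin),
        stats::runif(1, margin, arena[2] - margin))

    px <- py <- hx <- hy <- qx <- qy <- numeric(0)  # pred, head, prey
    phase <- character(0)
    ep_start <- ep_end <- ep_peak_realized <- numeric(0)

    head_len <- 1.5
    append_frames <- function(pred, head_u, prey) {
      # pred, prey: n x 2; head_u: n x 2 unit vectors
      px <<- c(px, pred[, 1]); py <<- c(py, pred[, 2])
      hx <<- c(hx, pred[, 1] + head_len * head_u[, 1])
      hy <<- c(hy, pred[, 2] + head_len * head_u[, 2])
      qx <<- c(qx, prey[, 1]); qy <<- c(qy, prey[, 2])
    }

    if (n_episodes == 0L) {
      n <- round(10 * fr)
      prey <- c(margin, margin)
      pred <- c(arena[1] - margin, arena[2] - margin)
      u <- (pred - prey) / sqrt(sum((pred - prey)^2))  # head away from prey
      append_frames(matrix(pred, n, 2, byrow = TRUE),
                    matrix(u, n, 2, byrow = TRUE),
                    matrix(prey, n, 2, byrow = TRUE))
      attacks_t <- numeric(0)
    } else {
      prey <- rand_point()
      # choose per-episode approach geometry
      d0 <- stats::runif(n_episodes, start_distance[1], start_distance[2])
      starts <- matrix(NA_real_, n_episodes, 2)
      dir_to_prey <- matrix(NA_real_, n_episodes, 2)
      prey_pos <- matrix(NA_real_, n_episodes, 2)
      cur_prey <- prey
      for (k in seq_len(n_episodes)) {
        prey_pos[k, ] <- cur_prey
        repeat {
          ang <- stats::runif(1, 0, 2 * pi)
          s <- cur_prey + d0[k] * c(cos(ang), sin(ang))
          if (all(s > 1) && s[1] < arena[1] - 1 && s[2] < arena[2] - 1) break
        }
        starts[k, ] <- s
        dir_to_prey[k, ] <- (cur_prey - s) / d0[k]
        cur_prey <- rand_point()
      }

      # initial exploration: sit at first start, head away from prey
      n0 <- round(1.5 * fr)
      append_frames(matrix(starts[1, ], n0, 2, byrow = TRUE),
                    matrix(-dir_to_prey[1, ], n0, 2, byrow = TRUE),
                    matrix(prey_pos[1, ], n0, 2, byrow = TRUE))

      for (k in seq_len(n_episodes)) {
        u <- dir_to_prey[k, ]
        run <- d0[k] - contact_distance
        tk <- pi * run / (2 * peak_speeds[k])  # sine profile duration
        m <- max(ceiling(tk * fr), round(0.3 * fr))
        # cumulative distance along the sine speed profile
        s_along <- run * (1 - cos(pi * seq_len(m) / m)) / 2
        pred <- cbind(starts[k, 1] + u[1] * s_along,
                      starts[k, 2] + u[2] * s_along)
        ep_start <- c(ep_start, length(px) + 1L)  # first moving frame
        append_frames(pred, matrix(u, m, 2, byrow = TRUE),
                      matrix(prey_pos[k, ], m, 2, byrow = TRUE))
        ep_end <- c(ep_end, length(px))  # provisional; refined below
        step <- diff(c(0, s_along)) * fr
        ep_peak_realized <- c(ep_peak_realized, max(step))

        # contact phase: small wiggle at contact range, head at prey
        nc <- round(stats::runif(1, contact_duration[1],
                                 contact_duration[2]) * fr)
        wig <- 0.15 * cbind(sin(seq_len(nc) / 3), cos(seq_len(nc) / 4))
        cpos <- matrix(pred[m, ], nc, 2, byrow = TRUE) + wig
        append_frames(cpos, matrix(u, nc, 2, byrow = TRUE),
                      matrix(prey_pos[k, ], nc, 2, byrow = TRUE))

        if (k < n_episodes) {
          # retreat to next start while the prey relocates; head away
          from <- cpos[nc, ]
          to <- starts[k + 1L, ]
          nrtr <- max(2L, ceiling(sqrt(sum((to - from)^2)) /
                                    retreat_speed * fr))
          frac <- seq_len(nrtr) / nrtr
          pred <- cbind(from[1] + (to[1] - from[1]) * frac,
                        from[2] + (to[2] - from[2]) * frac)
          prey_path <- cbind(
            prey_pos[k, 1] + (prey_pos[k + 1L, 1] - prey_pos[k, 1]) * frac,
            prey_pos[k, 2] + (prey_pos[k + 1L, 2] - prey_pos[k, 2]) * frac)
          away <- pred - prey_path
          away <- away / pmax(sqrt(rowSums(away^2)), 1e-9)
          append_frames(pred, away, prey_path)
        }
      }
      # trailing second at the prey, head away (ingestion)
      nt <- round(1 * fr)
      last_pred <- c(px[length(px)], py[length(py)])
      last_prey <- c(qx[length(qx)], qy[length(qy)])
      u_away <- last_pred - last_prey
      u_away <- u_away / max(sqrt(sum(u_away^2)), 1e-9)
      append_frames(matrix(last_pred, nt, 2, byrow = TRUE),
                    matrix(u_away, nt, 2, byrow = TRUE),
                    matrix(last_prey, nt, 2, byrow = TRUE))
    }

    n <- length(px)
    time <- (seq_len(n) - 1L) / fr
    ppd_clean <- sqrt((qx - px)^2 + (qy - py)^2)

    # refine planted episode ends: first frame below the capture distance
    if (n_episodes > 0L) {
      for (k in seq_along(ep_start)) {
        seg <- ep_start[k]:ep_end[k]
        ep_end[k] <- seg[which(ppd_clean[seg] < attack_ppd)[1]]
      }
    }

    # attacks: Poisson while the noise-free PPD is below the threshold
    atk_seed <- sub_seed(if (is.null(seed)) NULL else seed, 2L)
    attacks_t <- with_seed(atk_seed, {
      close_frames <- which(ppd_clean < attack_ppd)
      hit <- close_frames[stats::runif(length(close_frames)) <
                            attack_rate / fr]
      time[hit]
    })

    noise_seed <- sub_seed(if (is.null(seed)) NULL else seed, 3L)
    if (position_noise_sd > 0) {
      with_seed(noise_seed, {
        px <- px + stats::rnorm(n, 0, position_noise_sd)
        py <- py + stats::rnorm(n, 0, position_noise_sd)
        hx <- hx + stats::rnorm(n, 0, position_noise_sd)
        hy <- hy + stats::rnorm(n, 0, position_noise_sd)
        qx <- qx + stats::rnorm(n, 0, position_noise_sd)
        qy <- qy + stats::rnorm(n, 0, position_noise_sd)
      })
    }

    traj <- trajectory(time, px, py, hx, hy, qx, qy, arena = arena)
    gt <- ground_truth(
      episode_intervals = if (n_episodes > 0L)
        data.frame(start = time[ep_start], end = time[ep_end]) else
          data.frame(start = numeric(0), end = numeric(0)),
      episode_peak_speeds = peak_speeds,
      episode_peak_speeds_realized = ep_peak_realized,
      attack_times = attacks_t,
      capture_time = if (length(attacks_t)) max(attacks_t) else NA_real_,
      params = list(n_episodes = n_episodes, frame_rate = frame_rate,
                    arena = arena, attack_rate = attack_rate,
                    attack_ppd = attack_ppd,
                    contact_distance = contact_distance,
                    position_noise_sd = position_noise_sd, seed = seed))
    list(trajectory = traj,
         attacks = attack_log(attacks_t, prey_intro_time = 0),
         ground_truth = gt)
  })
}

#' Simulate a treadmill locomotion speed profile
#'
#' Alternating rest and locomotion bouts; bout speeds meander inside the
#' analyzed 3-30 cm/s range and bout initiation is rapid (default 100 ms
#' rise), mirroring spontaneous treadmill walking.
#'
#' @param duration Total duration (s).
#' @param frame_rate Sampling rate of the speed series (Hz).
#' @param bout_duration,rest_duration Ranges (s).
#' @param speed_range Range of bout target speeds (cm/s).
#' @param rise_time Bout initiation/termination ramp (s).
#' @param seed Integer seed.
#' @return List with `speed` (a [kinematic_series()] with speed only) and
#'   `bouts` (data frame of planted `onset_time`, `offset_time`).
#' @export
simulate_treadmill_speed <- function(duration = 300, frame_rate = 50,
                                     bout_duration = c(4, 8),
                                     rest_duration = c(3, 6),
                                     speed_range = c(8, 28),
                                     rise_time = 0.1, seed = NULL) {
  with_seed(seed, {
    fr <- frame_rate
    n <- round(duration * fr)
    sp <- numeric(n)
    onsets <- offsets <- numeric(0)
    t <- stats::runif(1, rest_duration[1], rest_duration[2])
    while (t < duration - bout_duration[1] - 1) {
      bd <- stats::runif(1, bout_duration[1], bout_duration[2])
      target <- stats::runif(1, speed_range[1], speed_range[2])
      i0 <- round(t * fr) + 1L
      i1 <- min(n, round((t + bd) * fr))
      idx <- i0:i1
      tt <- (idx - i0) / fr
      # rapid rise, slow meander around the target, rapid fall
      envelope <- pmin(1, tt / rise_time, (bd - tt) / rise_time)
      meander <- 1 + 0.25 * sin(2 * pi * tt / stats::runif(1, 3, 6) +
                                  stats::runif(1, 0, 2 * pi))
      sp[idx] <- pmax(0, target * envelope * meander)
      onsets <- c(onsets, t)
      offsets <- c(offsets, t + bd)
      t <- t + bd + stats::runif(1, rest_duration[1], rest_duration[2])
    }
    time <- (seq_len(n) - 1L) / fr
    list(speed = kinematic_series(time, speed = sp, frame_rate = fr),
         bouts = data.frame(onset_time = onsets, offset_time = offsets))
  })
}

#' Built-in spike waveform templates
#'
#' Two fixed biphasic extracellular waveform shapes (32 samples at 10 kHz)
#' with low mutual correlation, used to plant matching or mismatched
#' pulse-evoked waveforms.
#'
#' @param type `"narrow"` or `"wide"`.
#' @return Numeric vector of length 32.
#' @export
spike_waveform_template <- function(type = c("narrow", "wide")) {
  type <- match.arg(type)
  s <- seq_len(32)
  if (type == "narrow")
    -exp(-((s - 10) / 1.8)^2) + 0.45 * exp(-((s - 16) / 4)^2)
  else
    -0.7 * exp(-((s - 20) / 5)^2) + 0.6 * exp(-((s - 8) / 3)^2)
}

#' Simulate a speed-tuned unit with antidromic tagging
#'
#' Spikes are drawn from an inhomogeneous Poisson process with rate
#' `baseline_rate + slope * speed(t + onset_lead)` (thinning; negative
#' instantaneous rates are clipped at 0 and the clip count recorded).
#' After the locomotion recording, a block of light pulses is delivered
#' and each pulse evokes an antidromic spike at the planted latency plus
#' jitter. Every spike carries a waveform: the locomotion template for
#' spontaneous spikes, `evoked_template` for pulse-evoked ones.
#'
#' @param speed A [kinematic_series()] (or data frame with `time`,
#'   `speed`); default: a fresh [simulate_treadmill_speed()] profile.
#' @param baseline_rate Baseline firing rate (Hz).
#' @param slope Rate gain (Hz per cm/s).
#' @param onset_lead Lead of the rate over the speed signal (s; the rate
#'   at `t` follows the speed at `t + onset_lead`).
#' @param n_pulses Number of light pulses in the tagging block.
#' @param antidromic_latency Planted first-spike latency (s).
#' @param latency_jitter_sd Latency jitter SD (s).
#' @param pulse_reliability Probability that a pulse evokes a spike.
#' @param waveform_template Locomotion waveform (default narrow template).
#' @param evoked_template Pulse-evoked waveform (default: same template,
#'   i.e. a genuine projection unit; pass the wide template to plant a
#'   mismatched unit).
#' @param waveform_noise_sd Per-sample waveform noise SD.
#' @param seed Integer seed.
#' @return List with `train` ([spike_train()]), `pulses`
#'   ([light_pulse_log()]), `speed`, `bouts` (planted bout table or
#'   `NULL`), and `ground_truth`.
#' @export
simulate_speed_tuned_spikes <- function(speed = NULL, baseline_rate = 5,
                                        slope = 1, onset_lead = 0.1,
                                        n_pulses = 50,
                                        antidromic_latency = 0.003,
                                        latency_jitter_sd = 0.0002,
                                        pulse_reliability = 1,
                                        waveform_template =
                                          spike_waveform_template("narrow"),
                                        evoked_template = NULL,
                                        waveform_noise_sd = 0.05,
                                        seed = NULL) {
  stopifnot_scalar(baseline_rate, "baseline_rate", nonneg = TRUE)
  stopifnot_scalar(onset_lead, "onset_lead", nonneg = TRUE)
  if (is.null(evoked_template)) evoked_template <- waveform_template
  bouts <- NULL
  if (is.null(speed)) {
    tm <- simulate_treadmill_speed(seed = sub_seed(seed, 11L))
    speed <- tm$speed
    bouts <- tm$bouts
  }
  with_seed(sub_seed(seed, 12L), {
    t_end <- speed$time[nrow(speed)]
    rate_at <- function(t) {
      s <- stats::approx(speed$time, speed$speed, xout = t + onset_lead,
                         rule = 2, yleft = 0, yright = 0)$y
      baseline_rate + slope * s
    }
    # thinning over the locomotion recording plus a quiet tagging block
    pulse_block <- n_pulses + 2
    total <- t_end + 2 + pulse_block
    lam_max <- max(baseline_rate + slope * max(speed$speed, na.rm = TRUE),
                   baseline_rate, 1e-6)
    n_cand <- stats::rpois(1, lam_max * total)
    cand <- sort(stats::runif(n_cand, 0, total))
    lam <- ifelse(cand <= t_end, rate_at(cand), baseline_rate)
    n_clipped <- sum(lam < 0)
    lam <- pmax(lam, 0)
    keep <- stats::runif(n_cand) < lam / lam_max
    st <- cand[keep]

    pulse_times <- t_end + 2 + seq_len(n_pulses)  # 1 Hz tagging
    evoked <- pulse_times[stats::runif(n_pulses) < pulse_reliability] +
      antidromic_latency
    evoked <- evoked + stats::rnorm(length(evoked), 0, latency_jitter_sd)
    all_t <- c(st, evoked)
    is_evoked <- c(rep(FALSE, length(st)), rep(TRUE, length(evoked)))
    o <- order(all_t)
    all_t <- all_t[o]; is_evoked <- is_evoked[o]

    nspk <- length(all_t)
    wf <- matrix(NA_real_, nspk, length(waveform_template))
    if (nspk) {
      base_wf <- outer(rep(1, nspk), waveform_template)
      base_wf[is_evoked, ] <- outer(rep(1, sum(is_evoked)), evoked_template)
      wf <- base_wf + matrix(stats::rnorm(nspk * ncol(wf), 0,
                                          waveform_noise_sd),
                             nspk, ncol(wf))
    }
    gt <- ground_truth(
      baseline_rate = baseline_rate, slope = slope, onset_lead = onset_lead,
      antidromic_latency = antidromic_latency,
      latency_jitter_sd = latency_jitter_sd,
      pulse_reliability = pulse_reliability,
      matching_waveform = identical(waveform_template, evoked_template),
      n_clipped = n_clipped,
      bout_onsets = if (is.null(bouts)) NULL else bouts$onset_time,
      params = list(n_pulses = n_pulses,
                    waveform_noise_sd = waveform_noise_sd, seed = seed))
    list(train = spike_train(all_t, wf),
         pulses = light_pulse_log(pulse_times),
         speed = speed, bouts = bouts, ground_truth = gt)
  })
}

#' Simulate a fiber-photometry recording
#'
#' The dF/F signal is a train of transients (impulses convolved with an
#' exponential decay kernel): one transient `transient_lead` seconds
#' before each locomotion onset, plus, in evoked mode, one transient at
#' each stimulation pulse with amplitude `amplitude_map(power) *
#' suppression_factor`. The raw trace is `F0 * (1 + dff)` with a slow
#' bleaching baseline and Gaussian noise.
#'
#' @param duration Recording duration (s).
#' @param sample_rate Sampling rate (Hz), default 100.
#' @param locomotion_onsets Locomotion onset times (s); default ~every
#'   5.5 s from 10 s on.
#' @param transient_lead Planted lead of the transient before each
#'   locomotion onset (s).
#' @param amplitude Transient peak dF/F at locomotion onsets.
#' @param kernel_decay Exponential decay time constant (s).
#' @param noise_sd Noise SD in dF/F units.
#' @param pulse_schedule Optional data frame `time`, `power` (mW) for
#'   evoked mode.
#' @param amplitude_map Function power (mW) -> peak dF/F; must map 0 to 0.
#'   Default `0.3 * p / (p + 10)` (monotone, mildly saturating).
#' @param suppression_factor Multiplies all evoked amplitudes (antagonist
#'   emulation); must lie in [0, 1].
#' @param f0 Baseline fluorescence (arbitrary units).
#' @param bleach_tau Baseline bleaching time constant (s); `Inf` disables.
#' @param seed Integer seed.
#' @return List with `trace` ([fluorescence_trace()]),
#'   `locomotion_onsets`, `pulse_schedule`, and `ground_truth`.
#' @export
simulate_photometry <- function(duration = 120, sample_rate = 100,
                                locomotion_onsets = NULL,
                                transient_lead = 0.125, amplitude = 0.08,
                                kernel_decay = 0.5, noise_sd = 0.01,
                                pulse_schedule = NULL,
                                amplitude_map = function(p) 0.3 * p / (p + 10),
                                suppression_factor = 1,
                                f0 = 100, bleach_tau = Inf, seed = NULL) {
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (suppression_factor < 0 || suppression_factor > 1)
    stop("suppression_factor must lie in [0, 1]")
  if (abs(amplitude_map(0)) > 1e-12)
    stop("amplitude_map must map 0 mW to amplitude 0")
  with_seed(sub_seed(seed, 21L), {
    fs <- sample_rate
    n <- round(duration * fs)
    time <- (seq_len(n) - 1L) / fs
    if (is.null(locomotion_onsets))
      locomotion_onsets <- seq(10, duration - 5, by = 5.5) +
        stats::runif(length(seq(10, duration - 5, by = 5.5)), -0.5, 0.5)
    if (any(locomotion_onsets < 0 | locomotion_onsets > duration))
      stop("locomotion onsets must lie within the trace span")
    sig <- numeric(n)
    add_transient <- function(t0, amp) {
      i0 <- round(t0 * fs) + 1L
      if (i0 > n || i0 < 1L) return()
      idx <- i0:n
      sig[idx] <<- sig[idx] + amp * exp(-(idx - i0) / (kernel_decay * fs))
    }
    for (ev in locomotion_onsets)
      add_transient(ev - transient_lead, amplitude)
    planted_evoked <- NULL
    if (!is.null(pulse_schedule)) {
      amps <- vapply(pulse_schedule$power, amplitude_map, numeric(1)) *
        suppression_factor
      for (i in seq_len(nrow(pulse_schedule)))
        add_transient(pulse_schedule$time[i], amps[i])
      planted_evoked <- data.frame(power = pulse_schedule$power,
                                   amplitude = amps)
    }
    base <- if (is.finite(bleach_tau)) f0 * exp(-time / bleach_tau) else
      rep(f0, n)
    raw <- base * (1 + sig) + f0 * stats::rnorm(n, 0, noise_sd)
    gt <- ground_truth(
      transient_lead = transient_lead, amplitude = amplitude,
      kernel_decay = kernel_decay,
      locomotion_onsets = locomotion_onsets,
      planted_evoked = planted_evoked,
      suppression_factor = suppression_factor,
      params = list(duration = duration, sample_rate = sample_rate,
                    noise_sd = noise_sd, f0 = f0,
                    bleach_tau = bleach_tau, seed = seed))
    list(trace = fluorescence_trace(time, raw),
         locomotion_onsets = locomotion_onsets,
         pulse_schedule = pulse_schedule, ground_truth = gt)
  })
}

#' Simulate runway paw traces
#'
#' The body advances at constant speed; each paw alternates stance (fixed
#' on the ground) and swing (advancing one stride). The planted stride
#' length is `body_speed / step_frequency`. Default parameters are
#' commensurate with the 50 Hz frame grid so that noiseless recovery is
#' exact.
#'
#' @param body_speed Body speed along the runway (cm/s).
#' @param step_frequency Steps per second per paw (Hz).
#' @param duty_cycle Stance fraction of the cycle, in (0, 1).
#' @param duration Walk duration (s).
#' @param frame_rate Frames per second.
#' @param paw_noise_sd Tracking noise SD per coordinate (cm).
#' @param phases Per-paw phase offsets (fractions of a cycle); default a
#'   trot (diagonal pairs in phase).
#' @param seed Integer seed.
#' @return List with `paws` ([paw_traces()]) and `ground_truth`
#'   (`step_frequency`, `stride_length`, planted stance-onset times).
#' @export
simulate_gait <- function(body_speed = 20, step_frequency = 5,
                          duty_cycle = 0.6, duration = 10,
                          frame_rate = 50, paw_noise_sd = 0,
                          phases = c(lf = 0, rf = 0.5, lh = 0.5, rh = 0),
                          seed = NULL) {
  stopifnot_scalar(body_speed, "body_speed", positive = TRUE)
  stopifnot_scalar(step_frequency, "step_frequency", positive = TRUE)
  if (duty_cycle <= 0 || duty_cycle >= 1)
    stop("duty_cycle must lie strictly between 0 and 1")
  with_seed(sub_seed(seed, 31L), {
    fr <- frame_rate
    n <- round(duration * fr)
    time <- (seq_len(n) - 1L) / fr
    stride <- body_speed / step_frequency
    x_off <- c(lf = 3, rf = 3, lh = 0, rh = 0)
    y_off <- c(lf = 1.5, rf = -1.5, lh = 1.2, rh = -1.2)
    mk_paw <- function(p) {
      tau <- step_frequency * time + phases[[p]]
      i <- floor(tau)
      u <- tau - i
      x <- ifelse(u < duty_cycle, stride * i,
                  stride * (i + (u - duty_cycle) / (1 - duty_cycle)))
      cbind(x + x_off[[p]], rep(y_off[[p]], n))
    }
    paw_list <- lapply(PAW_LABELS, mk_paw)
    names(paw_list) <- PAW_LABELS
    body <- cbind(body_speed * time, rep(0, n))
    if (paw_noise_sd > 0) {
      paw_list <- lapply(paw_list, function(m)
        m + matrix(stats::rnorm(2 * n, 0, paw_noise_sd), n, 2))
      body <- body + matrix(stats::rnorm(2 * n, 0, paw_noise_sd), n, 2)
    }
    onsets <- lapply(PAW_LABELS, function(p) {
      i <- seq.int(ceiling(phases[[p]]), floor(step_frequency * duration +
                                                 phases[[p]]))
      on <- (i - phases[[p]]) / step_frequency
      on[on > 0 & on < duration]
    })
    names(onsets) <- PAW_LABELS
    gt <- ground_truth(step_frequency = step_frequency,
                       stride_length = stride,
                       stance_onsets = onsets,
                       params = list(body_speed = body_speed,
                                     duty_cycle = duty_cycle,
                                     duration = duration,
                                     frame_rate = frame_rate,
                                     paw_noise_sd = paw_noise_sd,
                                     seed = seed))
    list(paws = paw_traces(time, paw_list$lf, paw_list$rf, paw_list$lh,
                           paw_list$rh, body),
         ground_truth = gt)
  })
}

#' Simulate a looming-escape trial
#'
#' Locomotion speed is planted directly: baseline wandering before the
#' stimuli, a rapid burst to the escape speed during the three stimulus
#' cycles, then a decay into freezing (speed 0). Positions are integrated
#' from the speed profile along a slowly turning heading with reflection
#' at the arena walls, so path-length binned speed recovers the profile.
#'
#' @param baseline_speed Mean pre-stimulus speed (cm/s).
#' @param escape_speed Planted escape speed (cm/s).
#' @param stim_start Time of the first stimulus onset (s).
#' @param cycle_interval Interval between the three cycle onsets (s).
#' @param freeze_duration Freezing period after the escape (s).
#' @param frame_rate Frames per second.
#' @param arena Arena extent (cm), default 35 x 35.
#' @param position_noise_sd Tracking noise SD (cm); default 0 (speed
#'   variation is planted in the profile itself).
#' @param seed Integer seed.
#' @return List with `trajectory`, `stimulus_log` (onsets and stimulus
#'   metadata), `speed_profile` (planted per-frame speed), and
#'   `ground_truth` including the planted escape metrics computed on the
#'   200 ms-binned noise-free profile.
#' @export
simulate_looming_trial <- function(baseline_speed = 8, escape_speed = 40,
                                   stim_start = 12, cycle_interval = 1,
                                   freeze_duration = 10, frame_rate = 50,
                                   arena = c(35, 35),
                                   position_noise_sd = 0, seed = NULL) {
  with_seed(sub_seed(seed, 41L), {
    fr <- frame_rate
    onsets <- stim_start + cycle_interval * (0:2)
    t_decay0 <- onsets[3] + 0.8
    t_decay1 <- onsets[3] + 2          # end of during-window
    duration <- t_decay1 + freeze_duration
    n <- round(duration * fr)
    time <- (seq_len(n) - 1L) / fr
    ph <- stats::runif(2, 0, 2 * pi)
    sp <- numeric(n)
    before <- time < onsets[1]
    sp[before] <- pmax(0, baseline_speed *
                         (1 + 0.15 * sin(2 * pi * time[before] / 5 + ph[1]) +
                            0.10 * sin(2 * pi * time[before] / 1.7 + ph[2])))
    rise <- time >= onsets[1] & time < onsets[1] + 0.25
    sp[rise] <- baseline_speed + (escape_speed - baseline_speed) *
      (time[rise] - onsets[1]) / 0.25
    plateau <- time >= onsets[1] + 0.25 & time < t_decay0
    sp[plateau] <- escape_speed
    decay <- time >= t_decay0 & time < t_decay1
    sp[decay] <- escape_speed * (t_decay1 - time[decay]) / (t_decay1 - t_decay0)
    # time >= t_decay1: freezing, speed 0

    # integrate positions along a slowly turning heading; near the walls
    # the heading is steered back toward the centre so every within-bin
    # increment keeps its planted length (no reflection shortening)
    turn <- stats::rnorm(n, 0, 0.6 / sqrt(fr))
    theta <- numeric(n)
    theta[1] <- stats::runif(1, 0, 2 * pi)
    pos <- matrix(NA_real_, n, 2)
    pos[1, ] <- arena / 2
    for (i in 2:n) {
      th <- theta[i - 1] + turn[i]
      margin_d <- min(pos[i - 1, 1], arena[1] - pos[i - 1, 1],
                      pos[i - 1, 2], arena[2] - pos[i - 1, 2])
      if (margin_d < 5) {  # steer toward the centre
        to_c <- atan2(arena[2] / 2 - pos[i - 1, 2],
                      arena[1] / 2 - pos[i - 1, 1])
        d_ang <- atan2(sin(to_c - th), cos(to_c - th))
        th <- th + sign(d_ang) * min(abs(d_ang), 0.25)
      }
      theta[i] <- th
      pos[i, ] <- pos[i - 1, ] + sp[i - 1] / fr * c(cos(th), sin(th))
    }
    hd <- cbind(cos(theta), sin(theta))
    if (position_noise_sd > 0) {
      pos <- pos + matrix(stats::rnorm(2 * n, 0, position_noise_sd), n, 2)
    }
    traj <- trajectory(time, pos[, 1], pos[, 2],
                       pos[, 1] + hd[, 1], pos[, 2] + hd[, 2],
                       arena = arena)

    # planted escape metrics on the 200 ms-binned noise-free profile,
    # using the step speeds that path-length binning actually averages
    fpb <- round(0.2 * fr)
    nb <- n %/% fpb
    binned <- vapply(seq_len(nb), function(b) {
      i <- ((b - 1L) * fpb + 1L):(b * fpb - 1L)
      mean(sp[i])
    }, numeric(1))
    bt <- vapply(seq_len(nb), function(b)
      mean(time[((b - 1L) * fpb + 1L):(b * fpb)]), numeric(1))
    during <- bt >= onsets[1] & bt < onsets[3] + 2
    after <- bt >= onsets[3] + 2 & bt < onsets[3] + 12
    pre <- bt >= onsets[1] - 10 & bt < onsets[1]
    gt <- ground_truth(
      baseline_speed = baseline_speed, escape_speed = escape_speed,
      stimulus_onsets = onsets,
      peak_speed_during = max(binned[during]),
      avg_speed_after = mean(binned[after]),
      avg_speed_before = mean(binned[pre]),
      params = list(frame_rate = frame_rate, arena = arena,
                    position_noise_sd = position_noise_sd,
                    freeze_duration = freeze_duration, seed = seed))
    list(trajectory = traj,
         stimulus_log = data.frame(onset = onsets, expansion_ms = 250,
                                   angle_from_deg = 2, angle_to_deg = 20),
         speed_profile = data.frame(time = time, speed = sp),
         ground_truth = gt)
  })
}

#' Simulate a punctate fluorescence micrograph
#'
#' Places `n_puncta` non-overlapping bright disks fully inside the region
#' mask on a dim background, plus Gaussian noise. Fails with a parameter
#' error when the mask cannot hold the requested number of
#' non-overlapping puncta.
#'
#' @param n_puncta Number of puncta.
#' @param width,height Image size (pixels).
#' @param mask Logical region mask (defaults to the whole image).
#' @param punctum_radius Disk radius (pixels).
#' @param peak_intensity Disk intensity.
#' @param background Background intensity.
#' @param noise_sd Gaussian noise SD.
#' @param pixel_size Pixel edge (micrometres), default 0.1 (63x confocal).
#' @param seed Integer seed.
#' @return List with `image` (numeric matrix in [0, 1]), `mask`, and
#'   `ground_truth` (`n_puncta`, centres, mask area, planted density).
#' @export
simulate_puncta_image <- function(n_puncta = 50, width = 128, height = 128,
                                  mask = NULL, punctum_radius = 3,
                                  peak_intensity = 0.8, background = 0.1,
                                  noise_sd = 0.05, pixel_size = 0.1,
                                  seed = NULL) {
  if (n_puncta < 0) stop("n_puncta must be >= 0")
  if (is.null(mask)) mask <- matrix(TRUE, height, width)
  mask <- as.matrix(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  with_seed(sub_seed(seed, 51L), {
    r <- punctum_radius
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(centers) < n_puncta) {
      tries <- tries + 1L
      if (tries > 5000L * max(1, n_puncta))
        stop("mask too small for the requested non-overlapping puncta")
      cand <- c(stats::runif(1, r + 1, nr - r), stats::runif(1, r + 1, nc - r))
      rr <- round(cand[1]); cc <- round(cand[2])
      # disk fully inside the mask
      dr <- (-r):r
      ok <- TRUE
      for (d in dr) {
        wspan <- floor(sqrt(r^2 - d^2))
        if (!all(mask[rr + d, (cc - wspan):(cc + wspan)])) { ok <- FALSE; break }
      }
      if (!ok) next
      if (nrow(centers) &&
          any((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 <
                (2 * r + 2)^2)) next
      centers <- rbind(centers, cand)
    }
    img <- matrix(background, nr, nc)
    for (i in seq_len(nrow(centers))) {
      rr <- round(centers[i, 1]); cc <- round(centers[i, 2])
      for (d in (-r):r) {
        wspan <- floor(sqrt(r^2 - d^2))
        img[rr + d, (cc - wspan):(cc + wspan)] <- peak_intensity
      }
    }
    clean <- img
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      img[img < 0] <- 0
      img[img > 1] <- 1
    }
    area_um2 <- sum(mask) * pixel_size^2
    gt <- ground_truth(n_puncta = n_puncta, centers = centers,
                       region_area_um2 = area_um2,
                       density = n_puncta / area_um2,
                       params = list(punctum_radius = punctum_radius,
                                     peak_intensity = peak_intensity,
                                     background = background,
                                     noise_sd = noise_sd,
                                     pixel_size = pixel_size, seed = seed))
    list(image = img, clean_image = clean, mask = mask, ground_truth = gt)
  })
}
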