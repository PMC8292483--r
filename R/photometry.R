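#' Fluorescence trace container
#'
#' @param time Sample times (s), uniform (100 Hz in the standard fiber
#'   photometry setup).
#' @param raw Raw fluorescence (arbitrary units), finite.
#' @param channel `"sensor"` or `"control"` (e.g. EGFP).
#' @return Object of class `"fluorescence_trace"` (data frame with
#'   attributes `sample_rate`, `channel`).
#' @export
fluorescence_trace <- function(time, raw, channel = c("sensor", "control")) {
  channel <- match.arg(channel)
  if (length(time) != length(raw)) stop("time and raw must match")
  if (any(!is.finite(raw))) stop("raw fluorescence must be finite")
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop("sampling must be uniform and increasing")
  structure(data.frame(time = time, raw = raw),
            sample_rate = 1 / mean(dt), channel = channel,
            class = c("fluorescence_trace", "data.frame"))
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %s channel, %d samples at %.0f Hz\n",
              attr(x, "channel"), nrow(x), attr(x, "sample_rate")))
  invisible(x)
}

#' Compute dF/F from a raw fluorescence trace
#'
#' `dF/F = (F - F0) / F0` with `F0` a running low-percentile baseline
#' (default: 10th percentile over a 30 s sliding window, evaluated on a
#' coarse grid and interpolated), which tracks slow bleaching while
#' ignoring transients. The raw trace is first low-pass filtered
#' (zero-phase Butterworth, `lowpass_hz` cut-off) when the sampling rate
#' allows. dF/F is invariant to any positive gain applied to the raw trace.
#'
#' @param trace A [fluorescence_trace()].
#' @param method `"running_percentile"` or `"fixed"` (a single percentile
#'   over the whole trace; appropriate for short, stable recordings).
#' @param percentile Baseline percentile in [0, 1], default 0.1.
#' @param window Baseline window length (s), default 30.
#' @param lowpass_hz Low-pass cut-off (Hz); `NA` disables filtering.
#' @return Object of class `"dff_trace"`: data frame with `time`, `dff`,
#'   attributes `sample_rate`, `baseline_method`.
#' @export
compute_dff <- function(trace, method = c("running_percentile", "fixed"),
                        percentile = 0.1, window = 30, lowpass_hz = 40) {
  method <- match.arg(method)
  fs <- attr(trace, "sample_rate")
  f <- trace$raw
  if (is.finite(lowpass_hz) && lowpass_hz < fs / 2) {
    bf <- signal::butter(2, 2 * lowpass_hz / fs, type = "low")
    # reflect-pad before zero-phase filtering to suppress edge transients
    np <- min(length(f) - 1L, 200L)
    padded <- c(2 * f[1] - f[(np + 1L):2L], f,
                2 * f[length(f)] - f[(length(f) - 1L):(length(f) - np)])
    f <- signal::filtfilt(bf, padded)[(np + 1L):(np + length(f))]
  }
  tt <- trace$time
  if (method == "fixed" || tt[length(tt)] - tt[1] <= window) {
    f0 <- rep(stats::quantile(f, percentile, names = FALSE), length(f))
  } else {
    grid <- seq(tt[1], tt[length(tt)], by = window / 60)
    q <- vapply(grid, function(g)
      stats::quantile(f[tt >= g - window / 2 & tt <= g + window / 2],
                      percentile, names = FALSE), numeric(1))
    f0 <- stats::approx(grid, q, xout = tt, rule = 2)$y
  }
  if (any(f0 <= 0))
    stop("baseline F0 <= 0; raw trace is not background-corrected")
  structure(data.frame(time = tt, dff = (f - f0) / f0),
            sample_rate = fs, baseline_method = method,
            channel = attr(trace, "channel"),
            class = c("dff_trace", "data.frame"))
}

#' Event-triggered average of a dF/F trace
#'
#' Extracts the peri-event segment of the trace around each event and
#' averages across events; shares the `"aligned_response"` container with
#' spike-train alignment (rate semantics replaced by dF/F).
#'
#' @param dff A `"dff_trace"`.
#' @param events Event times (s); events whose window is not fully inside
#'   the trace are dropped.
#' @param window Peri-event window `c(before, after)` (s).
#' @param baseline_window Baseline window relative to the event (s).
#' @return An `"aligned_response"` with `type = "dff"`.
#' @export
event_triggered_average <- function(dff, events, window = c(-2, 2),
                                    baseline_window = c(-2, -1)) {
  fs <- attr(dff, "sample_rate")
  dt <- 1 / fs
  tt <- dff$time
  events <- events[events + window[1] >= tt[1] &
                     events + window[2] <= tt[length(tt)]]
  if (length(events) == 0L) stop("no event window fully inside the trace")
  offs <- seq(round(window[1] * fs), round(window[2] * fs))
  per_trial <- t(vapply(events, function(ev) {
    i0 <- which.min(abs(tt - ev))
    dff$dff[i0 + offs]
  }, numeric(length(offs))))
  finish_aligned(offs * dt, per_trial, dt, baseline_window, type = "dff")
}

#' Onset lead of an average photometry response
#'
#' The time at which the event-triggered average starts to rise, by the
#' same 15%-of-peak rule used for spike PSTHs ([detect_onset_offset()]).
#' Negative values mean the fluorescence leads the behavioral event.
#'
#' @param avg An `"aligned_response"` (typically from
#'   [event_triggered_average()]).
#' @param ... Passed to [detect_onset_offset()].
#' @return An `"onset_estimate"`.
#' @export
onset_lead <- function(avg, ...) {
  detect_onset_offset(avg, ...)
}

#' Evoked-transient amplitude
#'
#' Averages the trace across stimulation pulses, then takes the peak dF/F
#' in the post-stimulus window minus the mean over the pre-stimulus window.
#'
#' @param dff A `"dff_trace"`.
#' @param pulse_times Stimulation pulse times (s).
#' @param power Laser power (mW) recorded alongside the amplitude.
#' @param pre,post Pre-/post-stimulus window lengths (s), default 1 each.
#' @return Object of class `"evoked_response"`: list with
#'   `stimulus_power`, `amplitude`, `n_pulses`.
#' @export
evoked_amplitude <- function(dff, pulse_times, power = NA_real_,
                             pre = 1, post = 1) {
  fs <- attr(dff, "sample_rate")
  tt <- dff$time
  pulse_times <- pulse_times[pulse_times - pre >= tt[1] &
                               pulse_times + post <= tt[length(tt)]]
  if (length(pulse_times) == 0L) stop("no pulse window inside the trace")
  offs <- seq(-round(pre * fs), round(post * fs))
  avg <- colMeans(t(vapply(pulse_times, function(p) {
    i0 <- which.min(abs(tt - p))
    dff$dff[i0 + offs]
  }, numeric(length(offs)))))
  pre_mean <- mean(avg[offs < 0])
  amp <- max(avg[offs >= 0]) - pre_mean
  structure(list(stimulus_power = power, amplitude = amp,
                 n_pulses = length(pulse_times)),
            class = "evoked_response")
}

#' Evoked amplitudes for a multi-power pulse log
#'
#' @param dff A `"dff_trace"`.
#' @param pulse_log Data frame with columns `time` and `power` (mW).
#' @inheritParams evoked_amplitude
#' @return Data frame with one row per power: `power`, `amplitude`,
#'   `n_pulses`.
#' @export
evoked_responses <- function(dff, pulse_log, pre = 1, post = 1) {
  powers <- sort(unique(pulse_log$power))
  do.call(rbind, lapply(powers, function(p) {
    ev <- evoked_amplitude(dff, pulse_log$time[pulse_log$power == p],
                           power = p, pre = pre, post = post)
    data.frame(power = p, amplitude = ev$amplitude,
               n_pulses = ev$n_pulses)
  }))
}

#' Input-output curve of evoked responses
#'
#' Mean amplitude (and SEM over sessions) per laser power, with an optional
#' control channel reported alongside.
#'
#' @param responses Data frame with `power` and `amplitude` (possibly
#'   several sessions per power), as from [evoked_responses()].
#' @param control Optional data frame of the same form for the control
#'   channel (e.g. EGFP).
#' @return A `data.frame` of class `"io_curve"`: `power`,
#'   `mean_amplitude`, `sem`, `n`, and `control_mean` when supplied.
#' @export
input_output_curve <- function(responses, control = NULL) {
  if (length(unique(responses$power)) < 2L)
    stop("need at least two distinct laser powers")
  agg <- function(df) {
    powers <- sort(unique(df$power))
    data.frame(power = powers,
               mean_amplitude = vapply(powers, function(p)
                 mean(df$amplitude[df$power == p]), numeric(1)),
               sem = vapply(powers, function(p) {
                 v <- df$amplitude[df$power == p]
                 if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
               }, numeric(1)),
               n = vapply(powers, function(p)
                 sum(df$power == p), numeric(1)))
  }
  out <- agg(responses)
  if (!is.null(control)) {
    ctl <- agg(control)
    out$control_mean <- ctl$mean_amplitude[match(out$power, ctl$power)]
  }
  structure(out, class = c("io_curve", "data.frame"))
}

#' Suppression ratio of evoked responses
#'
#' Ratio of mean evoked amplitude under a treatment (e.g. a D2 antagonist)
#' to the mean amplitude under the control condition; 1 means no
#' suppression, 0 complete abolition.
#'
#' @param treated,control Data frames with an `amplitude` column (or
#'   `"evoked_response"` objects).
#' @return Numeric scalar ratio.
#' @export
suppression_ratio <- function(treated, control) {
  amp <- function(x) if (inherits(x, "evoked_response")) x$amplitude else
    x$amplitude
  mean(amp(treated)) / mean(amp(control))
}
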