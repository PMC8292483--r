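#' Spike train with per-spike waveforms
#'
#' @param spike_times Sorted spike times (s).
#' @param waveforms Optional numeric matrix, one row per spike, of waveform
#'   amplitude samples (uniform length; 10 kHz sampling in the standard
#'   recording setup).
#' @param unit_id Optional unit label.
#' @return Object of class `"spike_train"`.
#' @export
spike_train <- function(spike_times, waveforms = NULL, unit_id = NA) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) {
    o <- order(spike_times)
    spike_times <- spike_times[o]
    if (!is.null(waveforms)) waveforms <- waveforms[o, , drop = FALSE]
  }
  if (!is.null(waveforms)) {
    waveforms <- as.matrix(waveforms)
    if (nrow(waveforms) != length(spike_times))
      stop("one waveform row per spike required")
  }
  structure(list(spike_times = spike_times, waveforms = waveforms,
                 unit_id = unit_id), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes%s\n", x$unit_id,
              length(x$spike_times),
              if (is.null(x$waveforms)) "" else
                sprintf(", %d-sample waveforms", ncol(x$waveforms))))
  invisible(x)
}

#' Light pulse log
#'
#' @param pulse_times Sorted pulse onset times (s).
#' @param pulse_width Pulse width (s), default 1 ms.
#' @param wavelength Wavelength tag (nm), default 473.
#' @return Object of class `"light_pulse_log"`.
#' @export
light_pulse_log <- function(pulse_times, pulse_width = 0.001,
                            wavelength = 473) {
  stopifnot_scalar(pulse_width, "pulse_width", positive = TRUE)
  pulse_times <- sort(as.numeric(pulse_times))
  structure(list(pulse_times = pulse_times, pulse_width = pulse_width,
                 wavelength = wavelength), class = "light_pulse_log")
}

#' Antidromic identification of projection units
#'
#' A unit counts as antidromically identified when (a) the median first-
#' spike latency to terminal photostimulation is below `latency_max`
#' (5 ms), (b) spikes follow the pulses reliably, and (c) the mean
#' pulse-evoked waveform is quantitatively comparable (Pearson correlation)
#' to the mean waveform of spikes fired during locomotion.
#'
#' @param train A [spike_train()] with waveforms, containing both
#'   spontaneous/locomotion spikes and any pulse-evoked spikes.
#' @param pulses A [light_pulse_log()] with at least 20 pulses.
#' @param locomotion_train A [spike_train()] of at least 20 spikes fired
#'   during locomotion, providing the waveform template. Defaults to all
#'   spikes of `train` outside the pulse search windows.
#' @param search_window First-spike search window after each pulse (s).
#' @param latency_max Identification latency criterion (s), default 5 ms.
#' @param reliability_min Minimum fraction of pulses followed by a spike.
#' @param similarity_min Minimum waveform correlation.
#' @return List of class `"antidromic_result"` with `median_latency`,
#'   `response_reliability`, `waveform_similarity`, `identified`, and the
#'   per-pulse `latencies`.
#' @export
identify_antidromic <- function(train, pulses, locomotion_train = NULL,
                                search_window = 0.010, latency_max = 0.005,
                                reliability_min = 0.5,
                                similarity_min = 0.9) {
  pt <- pulses$pulse_times
  if (length(pt) < 20L) stop("need at least 20 light pulses")
  st <- train$spike_times
  if (is.null(train$waveforms)) stop("spike train has no waveforms")

  lat <- rep(NA_real_, length(pt))
  evoked_idx <- integer(0)
  for (i in seq_along(pt)) {
    j <- findInterval(pt[i], st) + 1L
    if (j <= length(st) && st[j] - pt[i] <= search_window) {
      lat[i] <- st[j] - pt[i]
      evoked_idx <- c(evoked_idx, j)
    }
  }
  reliability <- mean(!is.na(lat))

  if (is.null(locomotion_train)) {
    in_win <- rep(FALSE, length(st))
    in_win[evoked_idx] <- TRUE
    locomotion_train <- spike_train(st[!in_win],
                                    train$waveforms[!in_win, , drop = FALSE],
                                    unit_id = train$unit_id)
  }
  if (length(locomotion_train$spike_times) < 20L)
    stop("need at least 20 locomotion spikes for the waveform template")

  if (length(evoked_idx) == 0L) {
    res <- list(median_latency = NA_real_, response_reliability = 0,
                waveform_similarity = NA_real_, identified = FALSE,
                latencies = lat)
    return(structure(res, class = "antidromic_result"))
  }
  mean_evoked <- colMeans(train$waveforms[evoked_idx, , drop = FALSE])
  mean_loco <- colMeans(locomotion_train$waveforms)
  similarity <- stats::cor(mean_evoked, mean_loco)
  med <- stats::median(lat, na.rm = TRUE)
  identified <- is.finite(med) && med < latency_max &&
    reliability >= reliability_min &&
    is.finite(similarity) && similarity >= similarity_min
  structure(list(median_latency = med, response_reliability = reliability,
                 waveform_similarity = similarity, identified = identified,
                 latencies = lat),
            class = "antidromic_result")
}

#' @export
print.antidromic_result <- function(x, ...) {
  cat(sprintf(paste0("<antidromic_result> %s (median latency %.2f ms, ",
                     "reliability %.2f, waveform r = %.3f)\n"),
              if (x$identified) "IDENTIFIED" else "not identified",
              1000 * x$median_latency, x$response_reliability,
              x$waveform_similarity))
  invisible(x)
}

#' Peri-event alignment of a spike train
#'
#' Bins spikes around each event, converts counts to rates, averages across
#' events, and Z-scores the average against its own baseline window
#' statistics (mean and SD of the trial-averaged rate over the baseline
#' bins). A zero baseline SD (e.g. an exactly periodic train) leaves the
#' Z-scored trace undefined and flags the response.
#'
#' @param train A [spike_train()] or numeric vector of spike times.
#' @param events Event times (s); events whose window is not fully inside
#'   the recording span are dropped.
#' @param window Peri-event window `c(before, after)` in s.
#' @param bin Bin width (s), default 20 ms.
#' @param baseline_window Window, relative to the event, that defines the
#'   baseline statistics.
#' @return Object of class `"aligned_response"`: `time` (bin centres
#'   relative to the event), `per_trial` (events x bins rate matrix, Hz),
#'   `mean` (Hz), `zscore`, `baseline_mean`, `baseline_sd`, `dt`,
#'   `n_events`, and `baseline_degenerate` flag.
#' @export
align_to_events <- function(train, events, window = c(-2, 2), bin = 0.02,
                            baseline_window = c(-2, -1)) {
  st <- if (inherits(train, "spike_train")) train$spike_times else
    as.numeric(train)
  stopifnot_scalar(bin, "bin", positive = TRUE)
  span <- range(st)
  events <- events[events + window[1] >= span[1] - bin &
                     events + window[2] <= span[2] + bin]
  if (length(events) < 1L) stop("no event window fully inside the recording")
  edges <- seq(window[1], window[2], by = bin)
  nb <- length(edges) - 1L
  per_trial <- t(vapply(events, function(ev) {
    h <- graphics::hist(st[st >= ev + window[1] & st < ev + window[2]] - ev,
                        breaks = edges, plot = FALSE)
    h$counts / bin
  }, numeric(nb)))
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  finish_aligned(centers, per_trial, bin, baseline_window, type = "rate")
}

finish_aligned <- function(centers, per_trial, dt, baseline_window, type) {
  m <- colMeans(per_trial)
  bl <- centers >= baseline_window[1] & centers <= baseline_window[2]
  if (!any(bl)) stop("baseline window outside the peri-event window")
  bm <- mean(m[bl]); bs <- stats::sd(m[bl])
  degen <- !is.finite(bs) || bs == 0
  z <- if (degen) rep(NA_real_, length(m)) else (m - bm) / bs
  structure(list(time = centers, per_trial = per_trial, mean = m,
                 zscore = z, baseline_mean = bm, baseline_sd = bs,
                 baseline_window = baseline_window, dt = dt,
                 n_events = nrow(per_trial),
                 baseline_degenerate = degen, type = type),
            class = "aligned_response")
}

#' @export
print.aligned_response <- function(x, ...) {
  cat(sprintf("<aligned_response> %d events, [%g, %g] s at %g ms bins (%s)%s\n",
              x$n_events, x$time[1] - x$dt / 2,
              x$time[length(x$time)] + x$dt / 2, 1000 * x$dt, x$type,
              if (x$baseline_degenerate) " [baseline SD = 0]" else ""))
  invisible(x)
}

#' @export
plot.aligned_response <- function(x, what = c("zscore", "mean"), ...) {
  what <- match.arg(what)
  y <- x[[what]]
  graphics::plot(x$time, y, type = "l", xlab = "time from event (s)",
                 ylab = if (what == "zscore") "Z-scored rate" else
                   if (x$type == "rate") "rate (Hz)" else "dF/F", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Response onset and offset by the 15%-of-peak rule
#'
#' The onset is the time at which the (optionally smoothed) trial-averaged
#' response first reaches 15% of its peak amplitude relative to the
#' baseline and stays there for `hold` consecutive bins; the crossing time
#' is linearly interpolated between bins, which makes the estimator exact
#' on piecewise-linear inputs. The offset is the first post-peak time at
#' which the response falls back below the same band and stays there.
#' Negative onset times mean the signal leads the event.
#'
#' @param resp An `"aligned_response"`.
#' @param threshold_fraction Fraction of peak amplitude, default 0.15.
#' @param smooth_sd SD of Gaussian smoothing applied to the mean response
#'   before thresholding (s); 0 disables. For spike PSTHs 0.05 is typical.
#' @param hold Number of consecutive supra-threshold bins required.
#' @param peak_window Window, relative to the event, searched for the peak.
#' @param min_peak_sd If the baseline SD is positive, the peak must exceed
#'   the baseline by this many baseline SDs, otherwise the estimate is
#'   undefined (guards against pure-noise "responses").
#' @return List of class `"onset_estimate"`: `onset_time`, `offset_time`,
#'   `threshold_fraction`, `peak_time`, `peak_value` (all `NA` when the
#'   response never rises meaningfully above baseline).
#' @export
detect_onset_offset <- function(resp, threshold_fraction = 0.15,
                                smooth_sd = 0, hold = 3L,
                                peak_window = c(-0.5, 1),
                                min_peak_sd = 2) {
  s <- resp$mean
  if (smooth_sd > 0) s <- gaussian_smooth(s, smooth_sd, resp$dt)
  bl <- resp$time >= resp$baseline_window[1] &
    resp$time <= resp$baseline_window[2]
  bm <- mean(s[bl])
  pw <- resp$time >= peak_window[1] & resp$time <= peak_window[2]
  if (!any(pw)) stop("peak window outside the peri-event window")
  pk_rel <- which.max(s[pw])
  pk <- which(pw)[pk_rel]
  peak_amp <- s[pk] - bm
  undefined <- list(onset_time = NA_real_, offset_time = NA_real_,
                    threshold_fraction = threshold_fraction,
                    peak_time = NA_real_, peak_value = NA_real_)
  if (!is.finite(peak_amp) || peak_amp <= 0)
    return(structure(undefined, class = "onset_estimate"))
  if (is.finite(resp$baseline_sd) && resp$baseline_sd > 0 &&
      peak_amp < min_peak_sd * resp$baseline_sd)
    return(structure(undefined, class = "onset_estimate"))
  thr <- bm + threshold_fraction * peak_amp

  # onset: the crossing attached to the peak -- the latest pre-peak run of
  # `hold` consecutive sub-threshold bins ends just before the onset
  below <- s < thr
  onset <- resp$time[1]
  e <- NA_integer_
  if (pk > hold) {
    for (j in (pk - 1L):hold) {
      if (all(below[(j - hold + 1L):j])) { e <- j; break }
    }
  }
  if (is.finite(e)) {
    onset <- if (s[e + 1L] == s[e]) resp$time[e + 1L]
    else resp$time[e] + (thr - s[e]) / (s[e + 1L] - s[e]) * resp$dt
  }
  offset <- NA_real_
  if (pk < length(s)) {
    below <- s < thr
    for (i in (pk + 1L):length(s)) {
      run <- i:min(length(s), i + hold - 1L)
      if (below[i] && all(below[run])) {
        offset <- if (s[i] == s[i - 1L]) resp$time[i]
        else resp$time[i - 1L] +
          (thr - s[i - 1L]) / (s[i] - s[i - 1L]) * resp$dt
        break
      }
    }
  }
  structure(list(onset_time = onset, offset_time = offset,
                 threshold_fraction = threshold_fraction,
                 peak_time = resp$time[pk], peak_value = peak_amp),
            class = "onset_estimate")
}

#' @export
print.onset_estimate <- function(x, ...) {
  cat(sprintf("<onset_estimate> onset %.1f ms, offset %.1f ms (%.0f%% of peak)\n",
              1000 * x$onset_time, 1000 * x$offset_time,
              100 * x$threshold_fraction))
  invisible(x)
}

#' Locomotion bouts by hysteresis thresholding
#'
#' A bout starts when the binned speed rises to `on_threshold` and ends
#' when it falls below `off_threshold` (hysteresis avoids flicker at the
#' boundary); bouts shorter than `min_duration` are discarded.
#'
#' @param speed A [kinematic_series()] or data frame with `time`, `speed`.
#' @param on_threshold Speed that opens a bout (cm/s).
#' @param off_threshold Speed that closes a bout (cm/s); must be below
#'   `on_threshold`.
#' @param min_duration Minimum bout duration (s).
#' @return A `data.frame` with `onset_time`, `offset_time` per bout.
#' @export
locomotion_bouts <- function(speed, on_threshold = 3, off_threshold = 1,
                             min_duration = 1) {
  if (off_threshold >= on_threshold)
    stop("off_threshold must be below on_threshold")
  tt <- speed$time
  sp <- speed$speed
  ok <- !is.na(sp)
  onsets <- numeric(0); offsets <- numeric(0)
  active <- FALSE; t0 <- NA_real_
  for (i in seq_along(sp)) {
    if (!ok[i]) next
    if (!active && sp[i] >= on_threshold) {
      active <- TRUE; t0 <- tt[i]
    } else if (active && sp[i] < off_threshold) {
      active <- FALSE
      onsets <- c(onsets, t0); offsets <- c(offsets, tt[i])
    }
  }
  if (active) {
    onsets <- c(onsets, t0); offsets <- c(offsets, tt[length(tt)])
  }
  keep <- (offsets - onsets) >= min_duration
  data.frame(onset_time = onsets[keep], offset_time = offsets[keep])
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Thin wrapper over [stats::cor.test()]: for `n <= exact_max` untied
#' observations the p-value comes from the exact permutation distribution
#' of the rank statistic; otherwise the asymptotic approximation is used.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest n for which the exact null is used.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rank <- function(x, y, exact_max = 10L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, p_value = NA_real_, n = n))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= exact_max))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Locomotion speed tuning of a unit
#'
#' Partitions locomotion bouts into consecutive `window`-long (500 ms)
#' windows; each window contributes its mean speed and the unit's firing
#' rate. Rates are averaged within speed bins, min-max normalized to [0, 1]
#' across occupied bins, and the association between speed and rate is
#' measured by the Spearman rank correlation over the bins whose centres
#' fall in `analysis_range` (3-30 cm/s).
#'
#' @param train A [spike_train()] or numeric spike times.
#' @param speed A [kinematic_series()] or data frame with `time`, `speed`.
#' @param bouts Optional bout table from [locomotion_bouts()]; computed
#'   from `speed` with default thresholds when missing.
#' @param window Analysis window length (s), default 0.5.
#' @param bin_width Speed bin width (cm/s), default 3.
#' @param analysis_range Speed range for the correlation (cm/s).
#' @param min_windows Minimum number of windows a speed bin needs before it
#'   enters the correlation (default 10, i.e. 5 s of locomotion). Sparse
#'   edge bins have unstable mean rates whose unequal variances break the
#'   exchangeability that the rank-permutation null relies on; they stay in
#'   the curve but are excluded from the test.
#' @return A `data.frame` of class `"speed_tuning_curve"` with one row per
#'   occupied speed bin (`speed_bin_center`, `mean_rate`,
#'   `normalized_rate`, `n_windows`), and attributes `spearman_rho`,
#'   `spearman_p`, `n_windows_total`, plus the per-window samples in
#'   attribute `windows`.
#' @export
speed_tuning <- function(train, speed, bouts = NULL, window = 0.5,
                         bin_width = 3, analysis_range = c(3, 30),
                         min_windows = 10) {
  st <- if (inherits(train, "spike_train")) train$spike_times else
    as.numeric(train)
  if (is.null(bouts)) bouts <- locomotion_bouts(speed)
  if (nrow(bouts) == 0L) stop("no locomotion bouts to analyze")
  tt <- speed$time
  sp <- speed$speed
  cs <- cumsum(ifelse(is.na(sp), 0, sp))
  cna <- cumsum(is.na(sp))
  ws <- numeric(0); wr <- numeric(0)
  for (b in seq_len(nrow(bouts))) {
    t0 <- bouts$onset_time[b]
    nwin <- floor((bouts$offset_time[b] - t0) / window)
    if (nwin < 1L) next
    bounds <- t0 + (0:nwin) * window
    bi <- findInterval(bounds - 1e-9, tt)  # samples strictly before bound
    sc <- findInterval(bounds - 1e-9, st)
    for (w in seq_len(nwin)) {
      lo <- bi[w] + 1L; hi <- bi[w + 1L]
      if (hi < lo) next
      if (cna[hi] - (if (lo > 1L) cna[lo - 1L] else 0L) > 0L) next
      ws <- c(ws, (cs[hi] - (if (lo > 1L) cs[lo - 1L] else 0)) / (hi - lo + 1L))
      wr <- c(wr, (sc[w + 1L] - sc[w]) / window)
    }
  }
  if (length(ws) == 0L) stop("no complete analysis windows inside bouts")
  bin_id <- floor(ws / bin_width)
  centers <- sort(unique(bin_id)) * bin_width + bin_width / 2
  mean_rate <- vapply(sort(unique(bin_id)),
                      function(b) mean(wr[bin_id == b]), numeric(1))
  n_win <- vapply(sort(unique(bin_id)),
                  function(b) sum(bin_id == b), numeric(1))
  rng <- range(mean_rate)
  normalized <- if (diff(rng) == 0) rep(0, length(mean_rate)) else
    (mean_rate - rng[1]) / diff(rng)
  in_range <- centers >= analysis_range[1] & centers <= analysis_range[2] &
    n_win >= min_windows
  if (sum(in_range) >= 3L) {
    sr <- spearman_rank(centers[in_range], normalized[in_range])
  } else {
    sr <- list(rho = NA_real_, p_value = NA_real_, n = sum(in_range))
  }
  structure(data.frame(speed_bin_center = centers, mean_rate = mean_rate,
                       normalized_rate = normalized, n_windows = n_win),
            spearman_rho = sr$rho, spearman_p = sr$p_value,
            n_windows_total = length(ws),
            windows = data.frame(speed = ws, rate = wr),
            analysis_range = analysis_range,
            class = c("speed_tuning_curve", "data.frame"))
}

#' @export
print.speed_tuning_curve <- function(x, ...) {
  cat(sprintf("<speed_tuning_curve> %d bins, %d windows; Spearman rho = %.4f (p = %.3g)\n",
              nrow(x), attr(x, "n_windows_total"),
              attr(x, "spearman_rho"), attr(x, "spearman_p")))
  invisible(x)
}

#' @export
plot.speed_tuning_curve <- function(x, ...) {
  graphics::plot(x$speed_bin_center, x$normalized_rate, type = "b",
                 pch = 16, xlab = "locomotion speed (cm/s)",
                 ylab = "normalized firing rate", ylim = c(0, 1), ...)
  invisible(x)
}

#' Average tuning curves across units
#'
#' Population curve: mean and SEM of the per-unit normalized rates in each
#' speed bin (bins are shared because normalization happens per unit before
#' averaging).
#'
#' @param curves List of `"speed_tuning_curve"` objects.
#' @return A `data.frame` with `speed_bin_center`, `mean_normalized_rate`,
#'   `sem`, `n_units`.
#' @export
average_tuning_curves <- function(curves) {
  centers <- sort(unique(unlist(lapply(curves, `[[`, "speed_bin_center"))))
  rows <- lapply(centers, function(cc) {
    v <- unlist(lapply(curves, function(cv) {
      i <- match(cc, cv$speed_bin_center)
      if (is.na(i)) NULL else cv$normalized_rate[i]
    }))
    data.frame(speed_bin_center = cc, mean_normalized_rate = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), n_units = length(v))
  })
  do.call(rbind, rows)
}
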