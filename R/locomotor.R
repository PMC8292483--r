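#' Paw position traces in the linear runway
#'
#' @param time Frame times (s), uniform (50 Hz standard).
#' @param lf,rf,lh,rh Two-column matrices (or data frames) of (x, y) paw
#'   positions in cm, ground frame, for the left-fore, right-fore,
#'   left-hind and right-hind paws.
#' @param body Two-column matrix of body-centroid positions (cm).
#' @return Object of class `"paw_traces"` (data frame with columns
#'   `time, lf_x, lf_y, rf_x, rf_y, lh_x, lh_y, rh_x, rh_y, body_x,
#'   body_y` and attribute `frame_rate`).
#' @export
paw_traces <- function(time, lf, rf, lh, rh, body) {
  as2 <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2L || nrow(m) != length(time))
      stop("each paw/body trace must be an n x 2 matrix matching time")
    m
  }
  lf <- as2(lf); rf <- as2(rf); lh <- as2(lh); rh <- as2(rh); body <- as2(body)
  df <- data.frame(time = time,
                   lf_x = lf[, 1], lf_y = lf[, 2],
                   rf_x = rf[, 1], rf_y = rf[, 2],
                   lh_x = lh[, 1], lh_y = lh[, 2],
                   rh_x = rh[, 1], rh_y = rh[, 2],
                   body_x = body[, 1], body_y = body[, 2])
  structure(df, frame_rate = 1 / mean(diff(time)),
            class = c("paw_traces", "data.frame"))
}

PAW_LABELS <- c("lf", "rf", "lh", "rh")

#' Detect stance onsets per paw
#'
#' During stance a paw is planted (moving backward relative to the body);
#' during swing it moves forward. Stance onsets are therefore the
#' transitions of the body-frame paw velocity from forward (above
#' `+velocity_eps`) to backward (below `-velocity_eps`); the hysteresis
#' pair rejects jitter, a moving average smooths the velocity, and a
#' minimum inter-step interval suppresses double counts. A stationary
#' mouse yields zero steps.
#'
#' @param paws A [paw_traces()].
#' @param min_interval Minimum time between consecutive stance onsets (s).
#' @param smooth_frames Moving-average window (frames) for the velocity.
#' @param velocity_eps Hysteresis threshold (cm/s).
#' @return Named list (lf, rf, lh, rh) of stance-onset time vectors, class
#'   `"step_events"`.
#' @export
detect_steps <- function(paws, min_interval = 0.1, smooth_frames = 5L,
                         velocity_eps = 2) {
  dt <- 1 / attr(paws, "frame_rate")
  out <- lapply(PAW_LABELS, function(p) {
    relx <- paws[[paste0(p, "_x")]] - paws$body_x
    v <- moving_average(c(NA, diff(relx)) / dt, smooth_frames)
    onsets <- numeric(0)
    armed <- FALSE
    last <- -Inf
    for (i in seq_along(v)) {
      if (is.na(v[i])) next
      if (v[i] > velocity_eps) armed <- TRUE
      else if (armed && v[i] < -velocity_eps) {
        if (paws$time[i] - last >= min_interval) {
          onsets <- c(onsets, paws$time[i])
          last <- paws$time[i]
        }
        armed <- FALSE
      }
    }
    onsets
  })
  names(out) <- PAW_LABELS
  structure(out, class = "step_events")
}

#' @export
print.step_events <- function(x, ...) {
  cat("<step_events>",
      paste(sprintf("%s: %d", toupper(PAW_LABELS),
                    vapply(x[PAW_LABELS], length, integer(1))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Gait summary: step frequency and stride length
#'
#' Step frequency per paw is `(n_steps - 1) / (time between first and last
#' stance onset)`; stride length is the mean ground-frame displacement of
#' the paw between consecutive stance onsets. Fewer than two steps leave
#' the stride undefined (`NA`) and the frequency 0.
#'
#' @param steps A `"step_events"` list from [detect_steps()].
#' @param paws The [paw_traces()] the steps came from.
#' @return A `data.frame` of class `"gait_summary"`: one row per paw
#'   (`paw`, `n_steps`, `step_frequency`, `stride_length`), with
#'   fore/hind aggregate means in attribute `aggregates`.
#' @export
gait_summary <- function(steps, paws) {
  rows <- lapply(PAW_LABELS, function(p) {
    on <- steps[[p]]
    n <- length(on)
    if (n < 2L)
      return(data.frame(paw = toupper(p), n_steps = n,
                        step_frequency = if (n == 0L) 0 else NA_real_,
                        stride_length = NA_real_))
    idx <- vapply(on, function(tt) which.min(abs(paws$time - tt)), integer(1))
    px <- paws[[paste0(p, "_x")]][idx]
    py <- paws[[paste0(p, "_y")]][idx]
    data.frame(paw = toupper(p), n_steps = n,
               step_frequency = (n - 1) / (on[n] - on[1]),
               stride_length = mean(sqrt(diff(px)^2 + diff(py)^2)))
  })
  out <- do.call(rbind, rows)
  agg <- c(fore_step_frequency = mean(out$step_frequency[1:2]),
           fore_stride_length = mean(out$stride_length[1:2]),
           hind_step_frequency = mean(out$step_frequency[3:4]),
           hind_stride_length = mean(out$stride_length[3:4]))
  structure(out, aggregates = agg,
            class = c("gait_summary", "data.frame"))
}

#' Looming-stimulus session
#'
#' A binned locomotion speed series together with the onsets of the three
#' looming-stimulus cycles (expanding overhead dark disk, 2 to 20 degrees
#' of visual angle in 250 ms per cycle in the standard protocol).
#'
#' @param speed Data frame with `time` and `speed` (200 ms bins), e.g.
#'   from [compute_speed()].
#' @param stimulus_onsets Sorted stimulus onset times (s).
#' @param expansion_ms,angle_deg,luminance_cdm2 Stimulus metadata tags.
#' @return Object of class `"looming_session"`.
#' @export
looming_session <- function(speed, stimulus_onsets,
                            expansion_ms = 250, angle_deg = c(2, 20),
                            luminance_cdm2 = c(background = 3.6,
                                               disk = 0.1)) {
  stimulus_onsets <- sort(stimulus_onsets)
  if (stimulus_onsets[1] <= speed$time[1])
    stop("need a pre-stimulus baseline before the first onset")
  structure(list(speed = data.frame(time = speed$time, speed = speed$speed),
                 stimulus_onsets = stimulus_onsets,
                 expansion_ms = expansion_ms, angle_deg = angle_deg,
                 luminance_cdm2 = luminance_cdm2),
            class = "looming_session")
}

#' Escape metrics around looming stimuli
#'
#' Peak locomotion speed during the stimuli, average speed after, and
#' average (spontaneous) speed before. Default windows: before = the
#' `before_s` seconds preceding the first onset; during = first onset to
#' last onset + `during_pad_s`; after = the `after_s` seconds following
#' the during-window.
#'
#' @param session A [looming_session()].
#' @param before_s,during_pad_s,after_s Window extents (s).
#' @return List of class `"escape_metrics"` with `peak_speed_during`,
#'   `avg_speed_after`, `avg_speed_before` and the window bounds.
#' @export
escape_metrics <- function(session, before_s = 10, during_pad_s = 2,
                           after_s = 10) {
  on <- session$stimulus_onsets
  tt <- session$speed$time
  sp <- session$speed$speed
  before <- c(max(tt[1], on[1] - before_s), on[1])
  during <- c(on[1], on[length(on)] + during_pad_s)
  after <- c(during[2], min(tt[length(tt)], during[2] + after_s))
  if (after[2] <= after[1] || before[2] <= before[1])
    stop("windows fall outside the session")
  win <- function(w) sp[tt >= w[1] & tt < w[2]]
  structure(list(peak_speed_during = max(win(during), na.rm = TRUE),
                 avg_speed_after = mean(win(after), na.rm = TRUE),
                 avg_speed_before = mean(win(before), na.rm = TRUE),
                 windows = list(before = before, during = during,
                                after = after)),
            class = "escape_metrics")
}

#' @export
print.escape_metrics <- function(x, ...) {
  cat(sprintf(paste0("<escape_metrics> peak during %.1f cm/s, ",
                     "avg after %.2f, avg before %.2f\n"),
              x$peak_speed_during, x$avg_speed_after, x$avg_speed_before))
  invisible(x)
}
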