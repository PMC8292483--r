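#' Attack log
#'
#' Times of predatory jaw attacks scored frame-by-frame from the horizontal
#' cameras, together with the prey introduction time that anchors all
#' latency-type metrics.
#'
#' @param attack_times Sorted attack times (s), all at or after
#'   `prey_intro_time`. May be empty.
#' @param prey_intro_time Time of prey introduction (s), default 0.
#' @return An object of class `"attack_log"`.
#' @export
attack_log <- function(attack_times, prey_intro_time = 0) {
  attack_times <- as.numeric(attack_times)
  if (is.unsorted(attack_times)) attack_times <- sort(attack_times)
  if (length(attack_times) && attack_times[1] < prey_intro_time)
    stop("attack times must not precede prey introduction")
  structure(list(attack_times = attack_times,
                 prey_intro_time = prey_intro_time),
            class = "attack_log")
}

#' @export
print.attack_log <- function(x, ...) {
  cat(sprintf("<attack_log> %d jaw attack(s), prey introduced at %.2f s\n",
              length(x$attack_times), x$prey_intro_time))
  invisible(x)
}

#' Speed of approach
#'
#' The mean of the per-episode peak locomotion speeds across all approach
#' episodes of a trial. With no episodes the metric is undefined and `NA`
#' is returned (never 0, which is a valid speed).
#'
#' @param episodes An `"approach_episodes"` data frame.
#' @return Mean peak speed (cm/s), or `NA_real_` if there are no episodes.
#' @export
approach_speed <- function(episodes) {
  if (nrow(episodes) == 0L) return(NA_real_)
  mean(episodes$peak_speed)
}

#' Frequency of approach
#'
#' Number of approach episodes divided by the time to prey capture.
#'
#' @param episodes An `"approach_episodes"` data frame.
#' @param time_to_capture Trial duration from prey introduction to the last
#'   jaw attack (s); must be positive.
#' @return Episodes per second.
#' @export
approach_frequency <- function(episodes, time_to_capture) {
  stopifnot_scalar(time_to_capture, "time_to_capture", positive = TRUE)
  nrow(episodes) / time_to_capture
}

#' Attack metrics of a hunting trial
#'
#' Time to prey capture (prey introduction to last jaw attack), latency to
#' attack (prey introduction to first jaw attack), and attack frequency
#' (number of attacks / time to capture). With no attacks all three are
#' undefined and returned as `NA`.
#'
#' @param attacks An [attack_log()].
#' @return Named list with `time_to_capture`, `latency_to_attack`,
#'   `attack_frequency`.
#' @export
attack_metrics <- function(attacks) {
  at <- attacks$attack_times
  if (length(at) == 0L)
    return(list(time_to_capture = NA_real_, latency_to_attack = NA_real_,
                attack_frequency = NA_real_))
  ttc <- at[length(at)] - attacks$prey_intro_time
  list(time_to_capture = ttc,
       latency_to_attack = at[1] - attacks$prey_intro_time,
       attack_frequency = length(at) / ttc)
}

#' Net effect of a paired manipulation
#'
#' The within-subject net effect of an ON/OFF manipulation (e.g. laser ON
#' minus laser OFF) on any scalar metric: `net = on - off`, exactly.
#'
#' @param on,off Metric values under the two conditions.
#' @return List of class `"net_effect"` with `on`, `off`, `net`.
#' @export
net_effect <- function(on, off) {
  structure(list(on = on, off = off, net = on - off), class = "net_effect")
}

#' @export
print.net_effect <- function(x, ...) {
  cat(sprintf("<net_effect> on = %.4g, off = %.4g, net = %.4g\n",
              x$on, x$off, x$net))
  invisible(x)
}

#' Full per-trial hunting quantification
#'
#' Convenience wrapper: detects approach episodes from the kinematic series
#' and combines them with the attack log into the five standard hunting
#' metrics.
#'
#' @param kin A [kinematic_series()].
#' @param attacks An [attack_log()].
#' @param ... Passed to [detect_approach_episodes()].
#' @return List of class `"hunting_trial_result"` with `time_to_capture`,
#'   `latency_to_attack`, `attack_frequency`, `approach_speed`,
#'   `approach_frequency`, and the `episodes` table.
#' @export
hunting_trial <- function(kin, attacks, ...) {
  ep <- detect_approach_episodes(kin, ...)
  am <- attack_metrics(attacks)
  af <- if (is.na(am$time_to_capture)) NA_real_ else
    approach_frequency(ep, am$time_to_capture)
  structure(c(am, list(approach_speed = approach_speed(ep),
                       approach_frequency = af,
                       episodes = ep)),
            class = "hunting_trial_result")
}

#' @export
print.hunting_trial_result <- function(x, ...) {
  cat("<hunting_trial_result>\n")
  cat(sprintf("  time to capture:    %.2f s\n", x$time_to_capture))
  cat(sprintf("  latency to attack:  %.2f s\n", x$latency_to_attack))
  cat(sprintf("  attack frequency:   %.4f /s\n", x$attack_frequency))
  cat(sprintf("  approach speed:     %.2f cm/s\n", x$approach_speed))
  cat(sprintf("  approach frequency: %.4f /s\n", x$approach_frequency))
  cat(sprintf("  episodes:           %d\n", nrow(x$episodes)))
  invisible(x)
}

#' Average per-mouse metrics over trials
#'
#' Per-metric arithmetic mean over a list of trial results (the standard
#' three-trials-per-mouse design). Undefined (`NA`) metrics are excluded
#' from their mean and the number of defined trials is reported per metric.
#'
#' @param trial_results List of `"hunting_trial_result"` objects.
#' @return List of class `"hunting_trial_result"` with averaged metrics and
#'   an `n_defined` attribute giving per-metric counts.
#' @export
average_per_mouse <- function(trial_results) {
  stopifnot(length(trial_results) >= 1L)
  metrics <- c("time_to_capture", "latency_to_attack", "attack_frequency",
               "approach_speed", "approach_frequency")
  vals <- lapply(metrics, function(m)
    vapply(trial_results, function(tr) tr[[m]], numeric(1)))
  names(vals) <- metrics
  out <- lapply(vals, function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  out$episodes <- do.call(rbind, lapply(trial_results, `[[`, "episodes"))
  structure(out,
            n_defined = vapply(vals, function(v) sum(!is.na(v)), integer(1)),
            n_trials = length(trial_results),
            class = "hunting_trial_result")
}

#' Per-frame ethogram labels for plotting
#'
#' Exports the frame-level behavioral annotation used for ethogram panels:
#' locomotion speed, an approach/other label, and jaw-attack marks.
#'
#' @param kin A [kinematic_series()].
#' @param episodes An `"approach_episodes"` table for the same series.
#' @param attacks Optional [attack_log()].
#' @return A `data.frame` of class `"ethogram"` with columns `time`,
#'   `speed`, `approach` (logical), `attack` (logical).
#' @export
ethogram <- function(kin, episodes, attacks = NULL) {
  appr <- rep(FALSE, nrow(kin))
  for (i in seq_len(nrow(episodes)))
    appr[kin$time >= episodes$start_time[i] &
           kin$time <= episodes$end_time[i]] <- TRUE
  atk <- rep(FALSE, nrow(kin))
  if (!is.null(attacks) && length(attacks$attack_times)) {
    idx <- vapply(attacks$attack_times,
                  function(a) which.min(abs(kin$time - a)), integer(1))
    atk[idx] <- TRUE
  }
  structure(data.frame(time = kin$time, speed = kin$speed,
                       approach = appr, attack = atk),
            class = c("ethogram", "data.frame"))
}

#' @export
plot.ethogram <- function(x, ...) {
  graphics::plot(x$time, x$speed, type = "n", xlab = "time (s)",
                 ylab = "speed (cm/s)", ...)
  r <- rle(x$approach)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values))
    graphics::rect(x$time[starts[k]], graphics::par("usr")[3],
                   x$time[ends[k]], graphics::par("usr")[4],
                   col = grDevices::adjustcolor("orange", 0.3), border = NA)
  graphics::lines(x$time, x$speed)
  if (any(x$attack))
    graphics::abline(v = x$time[x$attack], col = "goldenrod3")
  invisible(x)
}
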