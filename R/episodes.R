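#' Detect approach episodes in a kinematic series
#'
#' An approach episode is a maximal interval satisfying the two empirical
#' criteria for appetitive approach: (a) the predator-prey distance (PPD)
#' decreases essentially monotonically until it falls below `ppd_capture`
#' (3 cm), and (b) the azimuth angle of the prey relative to the predator's
#' head stays within `+/- azimuth_limit` (90 deg) throughout.
#'
#' "Essentially monotonically" is made precise with a running-minimum slack:
#' within an episode the PPD may never exceed any earlier within-episode
#' value by more than `rise_tolerance` cm, which absorbs tracking jitter
#' without admitting sustained climbs. An episode ends at the first frame
#' with PPD below `ppd_capture` (contact is the attack log's business) and
#' starts at the furthest preceding frame from which both criteria hold,
#' which lands on the latest local PPD maximum before the descent. Episodes
#' separated by less than `min_gap` seconds are merged when the azimuth
#' criterion also holds across the gap; episodes shorter than
#' `min_duration` (one speed bin) are discarded. Frames with missing
#' azimuth or PPD violate both criteria.
#'
#' @param kin A [kinematic_series()] with `azimuth` and `ppd`.
#' @param ppd_capture Capture distance threshold (cm), default 3.
#' @param azimuth_limit Azimuth half-range (deg), default 90.
#' @param rise_tolerance Permitted PPD back-tracking within an episode (cm).
#' @param min_gap Minimum separation between episodes (s); shorter
#'   azimuth-compatible interruptions merge.
#' @param min_duration Minimum episode duration (s).
#' @return A `data.frame` of class `"approach_episodes"` with one row per
#'   episode: `start_time`, `end_time`, `peak_speed` (max binned speed
#'   inside the episode, cm/s), `min_ppd` (cm).
#' @examples
#' t <- seq(0, 2, by = 0.02)
#' kin <- kinematic_series(t, speed = 10, azimuth = 0,
#'                         ppd = pmax(20 - 10 * t, 1))
#' detect_approach_episodes(kin)
#' @export
detect_approach_episodes <- function(kin, ppd_capture = 3,
                                     azimuth_limit = 90,
                                     rise_tolerance = 0.5,
                                     min_gap = 0.5, min_duration = 0.2) {
  ppd <- kin$ppd
  az <- kin$azimuth
  n <- length(ppd)
  if (all(is.na(ppd)) || all(is.na(az))) {
    warning("azimuth or PPD entirely missing; no episodes detectable")
    return(empty_episodes())
  }
  az_ok <- !is.na(az) & abs(az) <= azimuth_limit
  ppd_ok <- !is.na(ppd)

  # crossing frames: first frame of a descent below the capture distance
  cross <- which(seq_len(n) > 1L & ppd_ok &
                   c(FALSE, ppd_ok[-n]) &
                   ppd < ppd_capture &
                   c(Inf, ppd[-n]) >= ppd_capture)

  runs <- matrix(integer(0), ncol = 2L)
  for (e in cross) {
    if (!az_ok[e]) next
    s <- e
    run_max <- ppd[e]
    # extend backwards while the candidate frame keeps both criteria:
    # every later value must stay within rise_tolerance of it
    while (s > 1L && az_ok[s - 1L] && ppd_ok[s - 1L] &&
           run_max <= ppd[s - 1L] + rise_tolerance) {
      s <- s - 1L
      run_max <- max(run_max, ppd[s])
    }
    runs <- rbind(runs, c(s, e))
  }
  finalize_episodes(runs, kin, min_gap, min_duration, az_ok)
}

empty_episodes <- function() {
  structure(data.frame(start_time = numeric(0), end_time = numeric(0),
                       peak_speed = numeric(0), min_ppd = numeric(0)),
            class = c("approach_episodes", "data.frame"))
}

# Shared post-processing: azimuth-compatible merging of near episodes, then
# the minimum-duration gate, then per-episode summaries.
finalize_episodes <- function(runs, kin, min_gap, min_duration, az_ok) {
  if (nrow(runs) == 0L) return(empty_episodes())
  runs <- runs[order(runs[, 1L]), , drop = FALSE]
  time <- kin$time
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (k in 2L:nrow(runs)) {
      last <- nrow(merged)
      gap_t <- time[runs[k, 1L]] - time[merged[last, 2L]]
      gap_idx <- seq.int(merged[last, 2L] + 1L, length.out =
                           max(0L, runs[k, 1L] - merged[last, 2L] - 1L))
      if (gap_t < min_gap && all(az_ok[gap_idx]))
        merged[last, 2L] <- runs[k, 2L]
      else
        merged <- rbind(merged, runs[k, , drop = FALSE])
    }
  }
  keep <- (time[merged[, 2L]] - time[merged[, 1L]]) >= min_duration
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty_episodes())
  out <- data.frame(
    start_time = time[merged[, 1L]],
    end_time = time[merged[, 2L]],
    peak_speed = vapply(seq_len(nrow(merged)), function(i) {
      sp <- kin$speed[merged[i, 1L]:merged[i, 2L]]
      if (all(is.na(sp))) NA_real_ else max(sp, na.rm = TRUE)
    }, numeric(1)),
    min_ppd = vapply(seq_len(nrow(merged)), function(i)
      min(kin$ppd[merged[i, 1L]:merged[i, 2L]], na.rm = TRUE), numeric(1)))
  structure(out, class = c("approach_episodes", "data.frame"))
}

#' @export
print.approach_episodes <- function(x, ...) {
  cat(sprintf("<approach_episodes> %d episode(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
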