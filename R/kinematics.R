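# Linear interpolation of short tracking dropouts; gaps longer than
# `gap_limit` frames stay NA so downstream bins are flagged missing
# rather than silently filled.
interp_gaps <- function(x, gap_limit = 3L) {
  if (!anyNA(x)) return(x)
  n <- length(x)
  idx <- which(!is.na(x))
  if (length(idx) < 2L) return(x)
  filled <- stats::approx(idx, x[idx], xout = seq_len(n), rule = 1)$y
  # identify NA runs longer than gap_limit and restore them to NA
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths > gap_limit))
    filled[starts[k]:ends[k]] <- NA_real_
  filled
}

#' Instantaneous locomotion speed in fixed time bins
#'
#' Speed is computed per time bin from the predator centroid. The default
#' follows the convention of summing the within-bin path length and dividing
#' by the bin duration (200 ms bins at 50 frames/s); endpoint displacement
#' per bin is available as an alternative. Tracking dropouts up to
#' `gap_limit` frames are linearly interpolated; bins containing longer
#' gaps are returned as `NA`, never as zero.
#'
#' @param traj A [trajectory()].
#' @param bin Bin duration in seconds (default 0.2).
#' @param gap_limit Maximum dropout length, in frames, to interpolate.
#' @param method `"path"` (within-bin path length / bin duration) or
#'   `"displacement"` (endpoint displacement / bin duration).
#' @return A `data.frame` with columns `time` (bin centres, s) and
#'   `speed` (cm/s).
#' @export
compute_speed <- function(traj, bin = 0.2, gap_limit = 3L,
                          method = c("path", "displacement")) {
  method <- match.arg(method)
  stopifnot_scalar(bin, "bin", positive = TRUE)
  fr <- attr(traj, "frame_rate")
  fpb <- round(bin * fr)
  if (fpb < 2L) stop("need at least 2 frames per bin")
  x <- interp_gaps(traj$pred_x, gap_limit)
  y <- interp_gaps(traj$pred_y, gap_limit)
  n <- nrow(traj)
  nb <- n %/% fpb
  if (nb < 1L) stop("trajectory shorter than one bin")
  speed <- numeric(nb)
  tc <- numeric(nb)
  for (b in seq_len(nb)) {
    i <- ((b - 1L) * fpb + 1L):(b * fpb)
    tc[b] <- mean(traj$time[i])
    xi <- x[i]; yi <- y[i]
    if (anyNA(xi) || anyNA(yi)) {
      speed[b] <- NA_real_
    } else if (method == "path") {
      speed[b] <- sum(sqrt(diff(xi)^2 + diff(yi)^2)) / (bin * (fpb - 1L) / fpb)
    } else {
      speed[b] <- sqrt((xi[fpb] - xi[1])^2 + (yi[fpb] - yi[1])^2) /
        (bin * (fpb - 1L) / fpb)
    }
  }
  data.frame(time = tc, speed = speed)
}

#' Azimuth angle of the prey relative to the predator's head direction
#'
#' Signed angle, in degrees, between the head-direction vector (centroid to
#' head point) and the centroid-to-prey vector. 0 deg means the prey is dead
#' ahead; positive angles put the prey to the animal's left; exactly
#' anti-collinear geometry is reported as +180 by tie-break. Frames where
#' the head point coincides with the centroid, or where prey or head
#' tracking is missing, return `NA`.
#'
#' @param traj A [trajectory()] with prey coordinates.
#' @return Numeric vector of per-frame azimuth angles in (-180, 180].
#' @export
compute_azimuth <- function(traj) {
  if (!"prey_x" %in% names(traj))
    stop("trajectory has no prey coordinates")
  hx <- traj$head_x - traj$pred_x
  hy <- traj$head_y - traj$pred_y
  px <- traj$prey_x - traj$pred_x
  py <- traj$prey_y - traj$pred_y
  dot <- hx * px + hy * py
  crs <- hx * py - hy * px
  az <- atan2(crs, dot) * 180 / pi
  az[az <= -180] <- 180  # deterministic tie-break at anti-collinear
  bad <- (hx == 0 & hy == 0) | (px == 0 & py == 0)
  az[which(bad)] <- NA_real_
  az
}

#' Predator-prey distance (PPD)
#'
#' Euclidean distance, per frame, between the predator centroid and the prey
#' centroid. Frames with missing prey tracking return `NA`.
#'
#' @param traj A [trajectory()] with prey coordinates.
#' @return Numeric vector of per-frame distances (cm).
#' @export
compute_ppd <- function(traj) {
  if (!"prey_x" %in% names(traj))
    stop("trajectory has no prey coordinates")
  sqrt((traj$prey_x - traj$pred_x)^2 + (traj$prey_y - traj$pred_y)^2)
}

#' Assemble the derived kinematic series of a trajectory
#'
#' Bundles binned speed, azimuth angle and PPD onto the trajectory's frame
#' time base. Speed is computed in `speed_bin` bins and held constant across
#' the frames of each bin; frames beyond the last complete bin carry the
#' last bin's value.
#'
#' @inheritParams compute_speed
#' @param speed_bin Speed bin duration in seconds.
#' @return A `data.frame` of class `"kinematic_series"` with columns
#'   `time`, `speed`, `azimuth`, `ppd` and attributes `frame_rate`,
#'   `speed_bin`.
#' @export
kinematics <- function(traj, speed_bin = 0.2, gap_limit = 3L,
                       method = c("path", "displacement")) {
  sp <- compute_speed(traj, bin = speed_bin, gap_limit = gap_limit,
                      method = match.arg(method))
  fr <- attr(traj, "frame_rate")
  fpb <- round(speed_bin * fr)
  n <- nrow(traj)
  bin_of <- pmin((seq_len(n) - 1L) %/% fpb + 1L, nrow(sp))
  kinematic_series(time = traj$time,
                   speed = sp$speed[bin_of],
                   azimuth = compute_azimuth(traj),
                   ppd = compute_ppd(traj),
                   frame_rate = fr, speed_bin = speed_bin)
}

#' Construct a kinematic series directly
#'
#' Used by the generators and by tests to build series without going through
#' positions. All vectors share the frame time base.
#'
#' @param time Frame times (s), uniform.
#' @param speed Binned locomotion speed expanded to frames (cm/s); may be NA.
#' @param azimuth Azimuth angle per frame, degrees in (-180, 180]; may be NA.
#' @param ppd Predator-prey distance per frame (cm); may be NA.
#' @param frame_rate Frames per second; inferred from `time` if missing.
#' @param speed_bin Speed bin duration (s) recorded as an attribute.
#' @return A `"kinematic_series"` data frame.
#' @export
kinematic_series <- function(time, speed = NA_real_, azimuth = NA_real_,
                             ppd = NA_real_, frame_rate = NULL,
                             speed_bin = 0.2) {
  n <- length(time)
  if (is.null(frame_rate)) frame_rate <- 1 / mean(diff(time))
  df <- data.frame(time = time,
                   speed = rep_len(speed, n),
                   azimuth = rep_len(azimuth, n),
                   ppd = rep_len(ppd, n))
  if (any(df$speed < 0, na.rm = TRUE)) stop("speed must be >= 0")
  if (any(abs(df$azimuth) > 180, na.rm = TRUE))
    stop("azimuth must lie in [-180, 180]")
  if (any(df$ppd < 0, na.rm = TRUE)) stop("ppd must be >= 0")
  structure(df, frame_rate = frame_rate, speed_bin = speed_bin,
            class = c("kinematic_series", "data.frame"))
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %d frames at %.1f Hz; speed bin %.0f ms\n",
              nrow(x), attr(x, "frame_rate"), 1000 * attr(x, "speed_bin")))
  invisible(x)
}
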