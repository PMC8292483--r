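#' Construct a predator-prey trajectory
#'
#' A trajectory holds synchronized, uniformly sampled positions of the
#' predator centroid, a predator head point (used for head direction), and
#' optionally the prey centroid, all in centimetres in the arena frame.
#' Tracking dropouts are encoded as `NA` coordinates.
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing
#'   and uniformly spaced (video frame times; 50 frames/s in the standard
#'   overhead-camera setup).
#' @param pred_x,pred_y Predator centroid coordinates (cm).
#' @param head_x,head_y Predator head-point coordinates (cm).
#' @param prey_x,prey_y Optional prey centroid coordinates (cm).
#' @param arena Arena extent `c(width, height)` in cm, used only for
#'   validation and plotting.
#' @return A `data.frame` of class `"trajectory"` with attributes
#'   `frame_rate` (Hz) and `arena`.
#' @examples
#' t <- seq(0, 1, by = 0.02)
#' tr <- trajectory(t, pred_x = 10 * t, pred_y = rep(5, length(t)),
#'                  head_x = 10 * t + 1, head_y = rep(5, length(t)),
#'                  prey_x = rep(20, length(t)), prey_y = rep(5, length(t)))
#' @export
trajectory <- function(time, pred_x, pred_y, head_x, head_y,
                       prey_x = NULL, prey_y = NULL, arena = c(25, 25)) {
  n <- length(time)
  if (n < 2L) stop("a trajectory needs at least two frames")
  dt <- diff(time)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("timestamps must be uniformly spaced")
  lens <- c(length(pred_x), length(pred_y), length(head_x), length(head_y))
  if (is.null(prey_x) != is.null(prey_y))
    stop("supply both or neither of prey_x/prey_y")
  if (!is.null(prey_x)) lens <- c(lens, length(prey_x), length(prey_y))
  if (any(lens != n)) stop("all coordinate vectors must match length(time)")
  df <- data.frame(time = time, pred_x = pred_x, pred_y = pred_y,
                   head_x = head_x, head_y = head_y)
  if (!is.null(prey_x)) {
    df$prey_x <- prey_x
    df$prey_y <- prey_y
  }
  structure(df,
            frame_rate = 1 / mean(dt),
            arena = arena,
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames at %.1f Hz (%.1f s), prey %s\n",
              nrow(x), attr(x, "frame_rate"),
              x$time[nrow(x)] - x$time[1],
              if ("prey_x" %in% names(x)) "tracked" else "absent"))
  invisible(x)
}

#' Read or write tracking tables
#'
#' Tracking tables are plain CSV with columns `time, pred_x, pred_y, head_x,
#' head_y` and optionally `prey_x, prey_y`.
#'
#' @param path File path.
#' @param arena Arena extent passed to [trajectory()].
#' @return `read_tracking_csv` returns a `"trajectory"`;
#'   `write_tracking_csv` invisibly returns `path`.
#' @export
read_tracking_csv <- function(path, arena = c(25, 25)) {
  df <- utils::read.csv(path)
  need <- c("time", "pred_x", "pred_y", "head_x", "head_y")
  if (!all(need %in% names(df)))
    stop("tracking CSV must contain columns: ", paste(need, collapse = ", "))
  has_prey <- all(c("prey_x", "prey_y") %in% names(df))
  trajectory(df$time, df$pred_x, df$pred_y, df$head_x, df$head_y,
             prey_x = if (has_prey) df$prey_x, prey_y = if (has_prey) df$prey_y,
             arena = arena)
}

#' @rdname read_tracking_csv
#' @param traj A `"trajectory"`.
#' @export
write_tracking_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
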