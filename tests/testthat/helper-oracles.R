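# Independent oracles used across the suite. Each re-implements the checked
# quantity with a different algorithm than the package code path.

# --- approach-episode oracle: exhaustive per-crossing criteria scan --------
# For each downward crossing of the capture distance, scan candidate start
# frames downward, re-checking the full interval criteria from scratch each
# time (running-minimum slack via cummin). Merging and the duration gate are
# re-implemented in plain code.
oracle_detect_episodes <- function(kin, ppd_capture = 3, azimuth_limit = 90,
                                   rise_tolerance = 0.5, min_gap = 0.5,
                                   min_duration = 0.2) {
  ppd <- kin$ppd; az <- kin$azimuth; tt <- kin$time
  n <- length(ppd)
  ok <- !is.na(az) & abs(az) <= azimuth_limit & !is.na(ppd)
  valid <- function(s, e) {
    if (!all(ok[s:e])) return(FALSE)
    pm <- ppd[s:e]
    if (length(pm) > 1L &&
        any(pm[-1] > cummin(pm)[-length(pm)] + rise_tolerance)) return(FALSE)
    TRUE
  }
  runs <- NULL
  for (e in 2:n) {
    if (is.na(ppd[e]) || is.na(ppd[e - 1])) next
    if (!(ppd[e] < ppd_capture && ppd[e - 1] >= ppd_capture)) next
    if (!ok[e]) next
    s_best <- e
    s <- e - 1L
    while (s >= 1L && valid(s, e)) {
      s_best <- s
      s <- s - 1L
    }
    runs <- rbind(runs, c(s_best, e))
  }
  if (is.null(runs)) runs <- matrix(integer(0), ncol = 2)
  # merge azimuth-compatible near episodes, then duration gate
  if (nrow(runs) > 1L) {
    runs <- runs[order(runs[, 1]), , drop = FALSE]
    merged <- runs[1, , drop = FALSE]
    for (k in 2:nrow(runs)) {
      last <- nrow(merged)
      gap_ok <- TRUE
      if (runs[k, 1] - merged[last, 2] > 1L) {
        gap <- (merged[last, 2] + 1L):(runs[k, 1] - 1L)
        gap_ok <- all(!is.na(az[gap]) & abs(az[gap]) <= azimuth_limit)
      }
      if (tt[runs[k, 1]] - tt[merged[last, 2]] < min_gap && gap_ok)
        merged[last, 2] <- runs[k, 2]
      else merged <- rbind(merged, runs[k, , drop = FALSE])
    }
    runs <- merged
  }
  keep <- nrow(runs) > 0 & (tt[runs[, 2]] - tt[runs[, 1]]) >= min_duration
  runs <- runs[keep, , drop = FALSE]
  out <- data.frame(start_time = numeric(0), end_time = numeric(0),
                    peak_speed = numeric(0), min_ppd = numeric(0))
  for (k in seq_len(nrow(runs))) {
    seg <- runs[k, 1]:runs[k, 2]
    sp <- kin$speed[seg]
    out <- rbind(out, data.frame(
      start_time = tt[runs[k, 1]], end_time = tt[runs[k, 2]],
      peak_speed = if (all(is.na(sp))) NA_real_ else max(sp, na.rm = TRUE),
      min_ppd = min(ppd[seg], na.rm = TRUE)))
  }
  out
}

# Structured random kinematic series exercising crossings, azimuth flips,
# jitter, and missing frames.
random_kin_series <- function(n = NULL) {
  if (is.null(n)) n <- sample(100:400, 1)
  tt <- (seq_len(n) - 1) / 50
  ppd <- numeric(n)
  ppd[1] <- runif(1, 2, 15)
  state <- sample(c(-1, 1), 1)
  for (i in 2:n) {
    if (runif(1) < 0.03) state <- -state
    ppd[i] <- ppd[i - 1] + state * runif(1, 0.05, 0.3) + rnorm(1, 0, 0.08)
    if (ppd[i] < 0.2) { ppd[i] <- 0.2; state <- 1 }
    if (ppd[i] > 20) { ppd[i] <- 20; state <- -1 }
  }
  # piecewise-constant azimuth blocks with jitter
  nblock <- max(2, rpois(1, n / 40))
  bl <- sort(sample(2:(n - 1), nblock - 1))
  vals <- runif(nblock, -180, 180)
  idx <- cut(seq_len(n), breaks = c(0, bl, n), labels = FALSE)
  az <- vals[idx] + rnorm(n, 0, 4)
  az <- ((az + 180) %% 360) - 180
  az[az == -180] <- 180
  if (runif(1) < 0.5) ppd[sample(n, max(1, round(0.02 * n)))] <- NA
  if (runif(1) < 0.5) az[sample(n, max(1, round(0.02 * n)))] <- NA
  kinematic_series(tt, speed = runif(n, 0, 40), azimuth = az, ppd = ppd)
}

# Interval-level F1 with Jaccard >= 0.5 matching.
interval_f1 <- function(detected, truth, min_jaccard = 0.5) {
  if (nrow(truth) == 0 && nrow(detected) == 0) return(1)
  jac <- function(a1, a2, b1, b2) {
    inter <- max(0, min(a2, b2) - max(a1, b1))
    uni <- max(a2, b2) - min(a1, b1)
    if (uni <= 0) 0 else inter / uni
  }
  used <- rep(FALSE, nrow(detected))
  tp <- 0
  for (i in seq_len(nrow(truth))) {
    best <- 0; bj <- NA
    for (j in seq_len(nrow(detected))) {
      if (used[j]) next
      v <- jac(truth$start[i], truth$end[i],
               detected$start_time[j], detected$end_time[j])
      if (v > best) { best <- v; bj <- j }
    }
    if (!is.na(bj) && best >= min_jaccard) { tp <- tp + 1; used[bj] <- TRUE }
  }
  fp <- nrow(detected) - tp
  fn <- nrow(truth) - tp
  2 * tp / (2 * tp + fp + fn)
}

# --- Spearman oracle: manual average ranks + Pearson on ranks --------------
oracle_spearman <- function(x, y) {
  rk <- function(v) vapply(v, function(vi)
    sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# --- connected components oracle: vectorized min-label propagation ---------
oracle_count_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  lab[fg] <- seq_len(sum(fg))
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    nb <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      s <- shift(lab, dr, dc)
      take <- fg & s > 0L & (nb == 0L | s < nb)
      nb[take] <- s[take]
    }
    new <- ifelse(fg & nb > 0L & nb < lab, nb, lab)
    if (identical(new, lab)) break
    lab <- new
  }
  length(setdiff(unique(as.vector(lab)), 0L))
}

# --- gait oracle: sign-change stance count on a noiseless trace ------------
oracle_stance_onsets <- function(relx, time) {
  v <- diff(relx)
  idx <- which(v[-1] <= 0 & v[-length(v)] > 0) + 1L
  time[idx]
}

# Build an aligned_response from an analytic mean signal.
make_aligned <- function(time, mean_signal, baseline_window = c(-2, -1),
                         baseline_sd = NULL) {
  dt <- mean(diff(time))
  bl <- time >= baseline_window[1] & time <= baseline_window[2]
  bm <- mean(mean_signal[bl])
  bs <- if (is.null(baseline_sd)) sd(mean_signal[bl]) else baseline_sd
  structure(list(time = time, per_trial = rbind(mean_signal),
                 mean = mean_signal,
                 zscore = if (isTRUE(bs > 0)) (mean_signal - bm) / bs else
                   rep(NA_real_, length(mean_signal)),
                 baseline_mean = bm, baseline_sd = bs,
                 baseline_window = baseline_window, dt = dt, n_events = 1,
                 baseline_degenerate = !isTRUE(bs > 0), type = "rate"),
            class = "aligned_response")
}
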