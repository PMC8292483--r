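make_linear_traj <- function(v = 10, dur = 4, fr = 50, prey = c(40, 5)) {
  t <- seq(0, dur, by = 1 / fr)
  trajectory(t, pred_x = v * t, pred_y = rep(5, length(t)),
             head_x = v * t + 1, head_y = rep(5, length(t)),
             prey_x = rep(prey[1], length(t)), prey_y = rep(prey[2], length(t)),
             arena = c(60, 10))
}

test_that("binned speed is exact for stationary and uniform motion", {
  tr0 <- make_linear_traj(v = 0)
  expect_true(all(compute_speed(tr0)$speed == 0))
  tr <- make_linear_traj(v = 10)
  sp <- compute_speed(tr)
  expect_equal(sp$speed, rep(10, nrow(sp)), tolerance = 1e-12)
  # displacement method agrees on straight-line motion
  sp2 <- compute_speed(tr, method = "displacement")
  expect_equal(sp2$speed, sp$speed, tolerance = 1e-12)
})

test_that("binned speed approaches the arc-length rate for circular motion", {
  r <- 5; w <- 2; fr <- 200
  t <- seq(0, 5, by = 1 / fr)
  tr <- trajectory(t, pred_x = 10 + r * cos(w * t), pred_y = 10 + r * sin(w * t),
                   head_x = 10 + (r + 1) * cos(w * t),
                   head_y = 10 + (r + 1) * sin(w * t), arena = c(20, 20))
  sp <- compute_speed(tr, bin = 0.1)
  # chord-sum oracle per bin
  fpb <- round(0.1 * fr)
  oracle <- vapply(seq_len(nrow(sp)), function(b) {
    i <- ((b - 1) * fpb + 1):(b * fpb)
    sum(sqrt(diff(tr$pred_x[i])^2 + diff(tr$pred_y[i])^2)) / ((fpb - 1) / fr)
  }, numeric(1))
  expect_equal(sp$speed, oracle, tolerance = 1e-12)
  expect_equal(sp$speed, rep(r * w, nrow(sp)), tolerance = 1e-3)
})

test_that("gaps are interpolated up to the limit and flagged beyond it", {
  tr <- make_linear_traj(v = 10)
  tr$pred_x[20:22] <- NA  # 3-frame gap: interpolated
  sp <- compute_speed(tr)
  expect_false(anyNA(sp$speed))
  expect_equal(sp$speed, rep(10, nrow(sp)), tolerance = 1e-12)
  tr$pred_x[60:70] <- NA  # 11-frame gap: flagged missing, not zero
  sp2 <- compute_speed(tr)
  expect_true(anyNA(sp2$speed))
  expect_false(any(sp2$speed == 0, na.rm = TRUE))
})

test_that("azimuth matches the atan2 oracle and its sign convention", {
  t <- c(0, 0.02)
  mk <- function(prey) trajectory(t, c(0, 0), c(0, 0), c(1, 1), c(0, 0),
                                  rep(prey[1], 2), rep(prey[2], 2),
                                  arena = c(10, 10))
  expect_equal(compute_azimuth(mk(c(5, 0)))[1], 0)            # dead ahead
  expect_equal(compute_azimuth(mk(c(-5, 0)))[1], 180)         # behind: +180
  expect_equal(compute_azimuth(mk(c(0, 1)))[1], 90)           # left: positive
  expect_equal(compute_azimuth(mk(c(0, -1)))[1], -90)
  # random geometry against the cross/dot oracle
  set.seed(42)
  for (k in 1:20) {
    p <- runif(2, -3, 3); h <- runif(2, -1, 1); q <- runif(2, -3, 3)
    tr <- trajectory(t, rep(p[1], 2), rep(p[2], 2),
                     rep(p[1] + h[1], 2), rep(p[2] + h[2], 2),
                     rep(q[1], 2), rep(q[2], 2), arena = c(10, 10))
    hd <- h; pv <- q - p
    want <- atan2(hd[1] * pv[2] - hd[2] * pv[1],
                  hd[1] * pv[1] + hd[2] * pv[2]) * 180 / pi
    expect_equal(compute_azimuth(tr)[1], want, tolerance = 1e-12)
  }
  # head coincident with centroid: flagged missing
  tr_bad <- trajectory(t, c(0, 0), c(0, 0), c(0, 0), c(0, 0),
                       c(1, 1), c(1, 1), arena = c(10, 10))
  expect_true(all(is.na(compute_azimuth(tr_bad))))
})

test_that("PPD is the per-frame Euclidean distance", {
  t <- c(0, 0.02)
  tr <- trajectory(t, c(0, 0), c(0, 0), c(1, 1), c(0, 0),
                   c(3, 3), c(4, 4), arena = c(10, 10))
  expect_equal(compute_ppd(tr), c(5, 5))
  set.seed(1)
  n <- 51
  tt <- seq(0, 1, length.out = n)
  px <- runif(n, 0, 10); py <- runif(n, 0, 10)
  qx <- runif(n, 0, 10); qy <- runif(n, 0, 10)
  tr2 <- trajectory(tt, px, py, px + 1, py, qx, qy, arena = c(10, 10))
  expect_equal(compute_ppd(tr2), sqrt((qx - px)^2 + (qy - py)^2))
})

test_that("kinematics are invariant under rigid motions of the frame", {
  set.seed(7)
  sim <- simulate_hunting_trial(n_episodes = 3, seed = 11)
  tr <- sim$trajectory
  th <- 0.7; dx <- 12; dy <- -4
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + dx,
                             y = sin(th) * x + cos(th) * y + dy)
  p <- rot(tr$pred_x, tr$pred_y); h <- rot(tr$head_x, tr$head_y)
  q <- rot(tr$prey_x, tr$prey_y)
  tr2 <- trajectory(tr$time, p$x, p$y, h$x, h$y, q$x, q$y, arena = c(60, 60))
  expect_equal(compute_speed(tr2)$speed, compute_speed(tr)$speed,
               tolerance = 1e-9)
  expect_equal(compute_ppd(tr2), compute_ppd(tr), tolerance = 1e-9)
  expect_equal(compute_azimuth(tr2), compute_azimuth(tr), tolerance = 1e-6)
})

test_that("doubling the frame rate leaves binned speed unchanged on straight paths", {
  v <- 14
  mk <- function(fr) {
    t <- seq(0, 2, by = 1 / fr)
    trajectory(t, v * t, rep(0, length(t)), v * t + 1, rep(0, length(t)),
               arena = c(40, 10))
  }
  s1 <- compute_speed(mk(50))$speed
  s2 <- compute_speed(mk(100))$speed
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("tracking CSV round-trips through read/write", {
  sim <- simulate_hunting_trial(n_episodes = 2, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_tracking_csv(sim$trajectory, path)
  tr2 <- read_tracking_csv(path, arena = attr(sim$trajectory, "arena"))
  expect_equal(as.data.frame(tr2), as.data.frame(sim$trajectory),
               tolerance = 1e-9)
})
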