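#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cor cor.test quantile rnorm runif rpois rexp median sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All generators route their randomness through
# this so identical (seed, params) give bit-identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-stream sub-seed fan-out from one global seed.
sub_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + as.numeric(stream) * 1009) %% 2147483629
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Moving average with symmetric window (odd k); ends use shrinking windows.
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  h <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cn[hi + 1L] - cn[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Discrete Gaussian smoothing of a regularly sampled signal; sd in the same
# units as dt. Kernel renormalized at the edges so constants are preserved.
gaussian_smooth <- function(x, sd, dt) {
  if (sd <= 0) return(x)
  half <- max(1L, ceiling(3 * sd / dt))
  kt <- seq(-half, half) * dt
  k <- exp(-0.5 * (kt / sd)^2)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    kk <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
    out[i] <- sum(x[lo:hi] * kk) / sum(kk)
  }
  out
}
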