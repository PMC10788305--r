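# Shared numerical helpers: zero-phase filtering, analytic signal,
# circular statistics, and the hierarchical seed scheme used by the
# synthetic generator.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth high-pass at `lo` Hz followed by an
#' order-`order` low-pass at `hi` Hz, each run forward-backward
#' (\code{signal::filtfilt}) so the net filter is zero-phase. The cascade is
#' used instead of a direct band-pass because band edges near 0.5 Hz at
#' sleep-EEG sampling rates make a direct order-4 band-pass numerically
#' fragile, while the cascade is stable and preserves event timing, which
#' the coupling analysis depends on.
#'
#' @param x numeric vector, signal in uV.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz; `lo = 0` skips the high-pass, `hi = Inf`
#'   (or `hi >= fs/2`) skips the low-pass.
#' @param order filter order of each cascade stage (default 4).
#' @return filtered numeric vector, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, lo, hi, order = 4) {
  stopifnot(fs > 0, length(x) > 3 * order)
  y <- as.numeric(x)
  if (lo > 0) {
    bf <- signal::butter(order, lo / (fs / 2), type = "high")
    y <- signal::filtfilt(bf, y)
  }
  if (is.finite(hi) && hi < fs / 2) {
    bf <- signal::butter(order, hi / (fs / 2), type = "low")
    y <- signal::filtfilt(bf, y)
  }
  y
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x numeric vector (should be band-limited; callers filter first).
#' @return complex vector `x + i * H(x)`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Instantaneous phase in degrees, convention: 0 deg at the positive peak of
# a cosine-like oscillation, increasing with time, wrapped to [0, 360).
instantaneous_phase_deg <- function(x) {
  ph <- Arg(analytic_signal(x)) * 180 / pi
  ph %% 360
}

# Centered moving average with window of n samples (n made odd).
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  if (n == 1L) return(x)
  k <- (n - 1L) %/% 2L
  xp <- c(rep(x[1], k), x, rep(x[length(x)], k))
  as.numeric(stats::filter(xp, rep(1 / n, n), sides = 2))[(k + 1):(k + length(x))]
}

# ---- circular statistics (degrees) ----

#' Circular mean of angles in degrees, in [0, 360)
#' @param deg numeric vector of angles in degrees.
#' @export
circ_mean_deg <- function(deg) {
  r <- mean(exp(1i * deg * pi / 180))
  (Arg(r) * 180 / pi) %% 360
}

#' Mean resultant length of angles in degrees (in [0, 1])
#' @param deg numeric vector of angles in degrees.
#' @export
circ_r <- function(deg) Mod(mean(exp(1i * deg * pi / 180)))

# Smallest absolute angular difference in degrees, in [0, 180].
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Draw from a von Mises distribution (degrees)
#'
#' Best-Fisher rejection sampler. `kappa = 0` yields the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration parameter (>= 0).
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  (out * 180 / pi) %% 360
}

# ---- hierarchical seed substreams ----
# All generator randomness flows from one integer seed; substreams for
# (subject, channel, event, ...) are derived with a fixed integer mix so
# regenerating one subject is stable regardless of the rest of the cohort.
substream_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 2246822519 + 374761393) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Sample skewness (biased, moment estimator) -- used by the polarity statistic.
skewness <- function(x) {
  x <- x - mean(x)
  s2 <- mean(x^2)
  if (s2 <= 0) return(0)
  mean(x^3) / s2^1.5
}
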