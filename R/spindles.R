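# Sleep spindle detection: slow (11 Hz) and fast (15 Hz) classes detected
# on the smoothed magnitude of a 7-cycle complex Morlet wavelet transform
# of retained N2 signal, with a dual relative-amplitude threshold, a
# band-ratio quality check, and morphology metrics (density, amplitude,
# duration, frequency, chirp).

SPINDLE_FC <- c(slow = 11, fast = 15)

#' Smoothed Morlet wavelet envelope
#'
#' Magnitude of the complex Morlet wavelet transform at center frequency
#' `fc` with `n_cycles` cycles, smoothed by a centered moving average of
#' `smooth_s` seconds. The wavelet is scaled so a unit-amplitude sinusoid
#' at `fc` yields an envelope of about 1, making the envelope
#' interpretable in uV.
#'
#' @param x numeric signal (concatenated retained N2 epochs).
#' @param fs Hz (>= 100).
#' @param fc center frequency, Hz.
#' @param n_cycles wavelet cycles (7).
#' @param smooth_s smoothing window (0.1 s).
#' @export
cwt_envelope <- function(x, fs, fc, n_cycles = 7, smooth_s = 0.1) {
  stopifnot(fs >= 100, fc > 0)
  sigma <- n_cycles / (2 * pi * fc)
  half <- ceiling(4 * sigma * fs)
  if (2 * half + 1 >= length(x))
    stop("signal too short for a ", n_cycles, "-cycle wavelet at ", fc,
         " Hz")
  t <- (seq(-half, half)) / fs
  g <- exp(-t^2 / (2 * sigma^2))
  w <- g * exp(1i * 2 * pi * fc * t)
  w <- w * (2 / sum(g))                        # unit-sine -> envelope ~ 1
  n <- length(x)
  nf <- stats::nextn(n + length(w) - 1L, 2)
  conv <- stats::fft(stats::fft(c(x, rep(0, nf - n))) *
                       stats::fft(c(w, rep(0, nf - length(w)))),
                     inverse = TRUE) / nf
  env <- Mod(conv[(half + 1):(half + n)])
  moving_average(env, round(smooth_s * fs))
}

#' Dual-threshold spindle candidate detection
#'
#' A candidate is a maximal run of envelope above `lo_mult` (2) times the
#' envelope mean lasting at least `lo_dur` (0.5 s) that contains a sub-run
#' above `hi_mult` (4.5) times the mean lasting at least `hi_dur` (0.3 s).
#' Candidates longer than 3 s are rejected; consecutive candidates closer
#' than 0.5 s are merged unless the merged interval would exceed 3 s.
#' Thresholds are relative, so detection is invariant to signal gain.
#'
#' @param envelope from [cwt_envelope()]; its mean over all supplied
#'   samples is the threshold baseline.
#' @param fs Hz.
#' @return data.frame: start_s, stop_s (half-open), peak_s, amplitude
#'   (envelope max, uV), duration.
#' @export
detect_spindles <- function(envelope, fs, lo_mult = 2, hi_mult = 4.5,
                            lo_dur = 0.5, hi_dur = 0.3, max_dur = 3,
                            merge_gap = 0.5) {
  m <- mean(envelope)
  if (!is.finite(m) || m <= 0) stop("degenerate envelope (zero mean)")
  above_lo <- envelope > lo_mult * m
  above_hi <- envelope > hi_mult * m

  r <- rle(above_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= round(lo_dur * fs))
  ivs <- list()
  for (k in cand) {
    i0 <- starts[k]; i1 <- ends[k]
    rh <- rle(above_hi[i0:i1])
    if (any(rh$values & rh$lengths >= round(hi_dur * fs))) {
      ivs[[length(ivs) + 1L]] <- c(i0, i1)
    }
  }
  if (!length(ivs)) {
    return(data.frame(start_s = numeric(0), stop_s = numeric(0),
                      peak_s = numeric(0), amplitude = numeric(0),
                      duration = numeric(0)))
  }
  iv <- do.call(rbind, ivs)
  # reject > 3 s, then merge near neighbours unless merged > 3 s
  keep <- (iv[, 2] - iv[, 1] + 1) / fs <= max_dur
  iv <- iv[keep, , drop = FALSE]
  if (nrow(iv) > 1) {
    merged <- list(iv[1, ])
    for (k in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      gap <- (iv[k, 1] - last[2] - 1) / fs
      span <- (iv[k, 2] - last[1] + 1) / fs
      if (gap < merge_gap && span <= max_dur) {
        merged[[length(merged)]] <- c(last[1], iv[k, 2])
      } else {
        merged[[length(merged) + 1L]] <- iv[k, ]
      }
    }
    iv <- do.call(rbind, merged)
  }
  if (!nrow(iv)) {
    return(data.frame(start_s = numeric(0), stop_s = numeric(0),
                      peak_s = numeric(0), amplitude = numeric(0),
                      duration = numeric(0)))
  }
  peak_i <- vapply(seq_len(nrow(iv)), function(k) {
    seg <- iv[k, 1]:iv[k, 2]
    seg[which.max(envelope[seg])]
  }, numeric(1))
  data.frame(start_s = (iv[, 1] - 1) / fs,
             stop_s = iv[, 2] / fs,
             peak_s = (peak_i - 1) / fs,
             amplitude = envelope[peak_i],
             duration = (iv[, 2] - iv[, 1] + 1) / fs)
}

#' Band-ratio quality check of spindle candidates
#'
#' For each event, the relative increase of event-window activity over the
#' stage mean is compared between the non-spindle bands -- delta (1-4),
#' theta (4-8), beta (15-30 Hz) -- and the spindle band (`fc` +/- 2 Hz).
#' Band activity is the variance of the zero-phase band-pass filtered
#' signal (filtering the whole timeline once avoids the spectral leakage
#' a short-window periodogram would suffer at sub-second event lengths);
#' each ratio is event-window band variance over whole-stage band
#' variance. The event fails when the largest non-spindle ratio strictly
#' exceeds the spindle-band ratio (equal ratios pass).
#'
#' @param events candidates from [detect_spindles()] (times on the same
#'   timeline as `x`).
#' @param x the signal the candidates were detected on.
#' @param fs Hz.
#' @param fc spindle center frequency.
#' @return `events` with columns `qc_pass` (logical) and `qc_reason`.
#' @export
spindle_qc <- function(events, x, fs, fc) {
  if (!nrow(events)) {
    events$qc_pass <- logical(0); events$qc_reason <- character(0)
    return(events)
  }
  bands <- list(delta = c(1, 4), theta = c(4, 8), beta = c(15, 30),
                spindle = c(fc - 2, fc + 2))
  filt <- lapply(bands, function(b)
    bandpass_filter(x, fs, b[1], min(b[2], fs / 2 - 1)))
  stage_var <- vapply(filt, function(f) mean(f^2), numeric(1))
  events$qc_pass <- TRUE
  events$qc_reason <- ""
  for (k in seq_len(nrow(events))) {
    i0 <- max(1L, round(events$start_s[k] * fs) + 1L)
    i1 <- min(length(x), round(events$stop_s[k] * fs))
    ratio <- vapply(names(bands), function(b) {
      mean(filt[[b]][i0:i1]^2) / (stage_var[[b]] + .Machine$double.eps)
    }, numeric(1))
    if (max(ratio[c("delta", "theta", "beta")]) > ratio["spindle"]) {
      events$qc_pass[k] <- FALSE
      events$qc_reason[k] <- "nonspindle_band_increase"
    }
  }
  events
}

# Instantaneous-frequency slope of one event, from a quadratic fit to the
# unwrapped Hilbert phase. The signal is high-pass filtered (zero-phase)
# well below the spindle band -- a narrow band-pass around fc genuinely
# compresses the frequency excursion of a short enveloped chirp and would
# bias the chirp toward zero -- and the unwrapped analytic phase is fit
# with a + b*t + c*t^2 over samples whose envelope exceeds `gate` of the
# event peak, weighted by squared envelope so low-SNR flanks contribute
# little. IF(t) = (b + 2 c t) / 2 pi, so the fitted frequency at the
# event center is b / 2 pi and the frequency slope is c / pi (Hz/s).
# Exact on a clean Hann-windowed linear chirp. Returns
# list(slope Hz/s, f0 Hz).
.event_if_slope <- function(x, envelope, fs, i0, i1, fc, pad_s = 0.5,
                            gate = 0.3) {
  pad <- round(pad_s * fs)
  j0 <- max(1L, i0 - pad); j1 <- min(length(x), i1 + pad)
  seg <- bandpass_filter(x[j0:j1], fs, max(4, fc - 7), Inf, order = 4)
  ph <- Arg(analytic_signal(seg))
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi
  phu <- cumsum(c(ph[1], dph))               # unwrapped phase
  core <- (i0 - j0 + 1L):(i1 - j0 + 1L)
  e <- envelope[i0:i1]
  keep <- e > gate * max(e)
  if (sum(keep) < 8) return(list(slope = NA_real_, f0 = NA_real_))
  tt <- (seq_along(core) - (length(core) + 1) / 2) / fs
  fit <- stats::lm.wfit(cbind(1, tt[keep], tt[keep]^2),
                        phu[core][keep], e[keep]^2)
  list(slope = fit$coefficients[3] / pi,
       f0 = fit$coefficients[2] / (2 * pi))
}

#' Spindle morphology and summary metrics
#'
#' Per event, the unwrapped Hilbert phase of the high-pass filtered signal
#' (event padded 0.5 s) is fit with a quadratic in time, with
#' envelope-squared weights over samples above 30% of the event's envelope
#' peak. Frequency is the fitted instantaneous frequency at the event
#' center; chirp -- the difference between mean frequency of the event's
#' last and first halves -- is the fitted frequency slope times half the
#' event duration (negative = deceleration). Density = events per
#' retained stage minute.
#'
#' @param events qc-passed events from [spindle_qc()].
#' @param x signal on the events' timeline.
#' @param fs Hz.
#' @param fc spindle center frequency.
#' @param retained_minutes denominator for density.
#' @param envelope the envelope the events were detected on (required for
#'   the SNR gating; when NULL the raw interval samples are used
#'   ungated).
#' @return list(events = per-event metrics, summary = list(density,
#'   n_events, and means of amplitude, duration, frequency, chirp)).
#' @export
spindle_metrics <- function(events, x, fs, fc, retained_minutes,
                            envelope = NULL) {
  ev <- events[events$qc_pass, , drop = FALSE]
  n <- nrow(ev)
  ev$frequency <- rep(NA_real_, n)
  ev$chirp <- rep(NA_real_, n)
  if (is.null(envelope)) envelope <- rep(1, length(x))
  for (k in seq_len(n)) {
    i0 <- round(ev$start_s[k] * fs) + 1L
    i1 <- round(ev$stop_s[k] * fs)
    sl <- .event_if_slope(x, envelope, fs, i0, i1, fc)
    if (is.finite(sl$slope)) {
      ev$frequency[k] <- sl$f0
      ev$chirp[k] <- sl$slope * (i1 - i0 + 1) / fs / 2
    }
  }
  summary <- list(
    density = n / retained_minutes,
    n_events = n,
    amplitude = if (n) mean(ev$amplitude) else NA_real_,
    duration = if (n) mean(ev$duration) else NA_real_,
    frequency = if (n) mean(ev$frequency, na.rm = TRUE) else NA_real_,
    chirp = if (n) mean(ev$chirp, na.rm = TRUE) else NA_real_)
  list(events = ev, summary = summary)
}

#' Detect spindles of one class on one channel of a cleaned record
#'
#' Runs envelope extraction, dual-threshold detection, QC and metrics on
#' the concatenated retained N2 epochs of `ch`, and maps event times back
#' to the record timeline.
#'
#' @param ep an `epoched_psg` after [reject_artifacts()].
#' @param ch channel name.
#' @param class "slow" (11 Hz) or "fast" (15 Hz).
#' @param stage stage analysed (N2).
#' @return list(events, summary) as [spindle_metrics()], with events
#'   carrying both concatenated-timeline and record-timeline (`*_rec`)
#'   times.
#' @export
detect_spindle_events <- function(ep, ch, class = c("fast", "slow"),
                                  stage = "N2") {
  class <- match.arg(class)
  fc <- SPINDLE_FC[[class]]
  ss <- stage_signal(ep, stage, ch)
  if (ss$minutes < 1) {
    return(list(events = NULL,
                summary = list(density = NA_real_, n_events = 0L),
                retained_minutes = ss$minutes))
  }
  env <- cwt_envelope(ss$x, ss$fs, fc)
  cand <- detect_spindles(env, ss$fs)
  cand <- spindle_qc(cand, ss$x, ss$fs, fc)
  res <- spindle_metrics(cand, ss$x, ss$fs, fc, ss$minutes, envelope = env)
  ev <- res$events
  if (nrow(ev)) {
    ep_n <- 30 * ss$fs
    to_rec <- function(s) {
      idx <- pmin(pmax(floor(s * ss$fs), 0), length(ss$x) - 1L)
      k <- idx %/% ep_n + 1L                 # which retained epoch
      (ss$epochs[k] - 1L) * 30 + (idx %% ep_n) / ss$fs
    }
    ev$start_rec <- to_rec(ev$start_s)
    ev$peak_rec <- to_rec(ev$peak_s)
    ev$stop_rec <- to_rec(ev$stop_s - 1 / ss$fs) + 1 / ss$fs
    ev$class <- class
    ev$channel <- ch
  }
  list(events = ev, summary = res$summary, retained_minutes = ss$minutes)
}
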