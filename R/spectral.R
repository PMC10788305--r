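# Welch spectral estimation and classical band summaries.
#
# Normalization contract: one-sided power spectral density in uV^2/Hz with
# taper power compensated (scale 2 / (fs * sum(w^2)); DC and Nyquist bins
# not doubled), so that rectangular band integration of the PSD of a
# sinusoid recovers its variance (Parseval).

#' Classical sleep-EEG band scheme
#'
#' slow 0.5-1, delta 1-4, theta 4-8, alpha 8-12, sigma 12-15, beta 15-30,
#' total 0.5-35 Hz. Band membership is half-open [lo, hi) with the
#' boundary assigned to the higher band (12 Hz belongs to sigma).
#' @export
band_scheme <- function() {
  data.frame(band = c("slow", "delta", "theta", "alpha", "sigma", "beta",
                      "total"),
             lo = c(0.5, 1, 4, 8, 12, 15, 0.5),
             hi = c(1, 4, 8, 12, 15, 30, 35),
             stringsAsFactors = FALSE)
}

.tukey_window <- function(n, r = 0.5) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < r / 2
  hi <- t >= 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / r - 2 / r + 1)))
  w
}

# PSD of one segment with taper w; one-sided, uV^2/Hz.
.segment_psd <- function(x, fs, w) {
  n <- length(x)
  X <- stats::fft(x * w)
  p <- Mod(X)^2 / (fs * sum(w^2))
  half <- floor(n / 2) + 1
  p <- p[seq_len(half)]
  if (n %% 2 == 0) {
    p[2:(half - 1)] <- 2 * p[2:(half - 1)]
  } else {
    p[2:half] <- 2 * p[2:half]
  }
  p
}

#' Welch power spectral density of staged 30-s epochs
#'
#' Each 30-s epoch is cut into 4-s segments overlapping by 50% (2 s),
#' tapered with a Tukey (50%) window; segment periodograms are averaged
#' within each epoch and then across epochs. The 4-s segment gives a
#' 0.25 Hz frequency grid.
#'
#' @param x numeric vector: concatenated retained 30-s epochs (length a
#'   multiple of `30 * fs`), or a matrix with one epoch per column.
#' @param fs sampling rate (Hz).
#' @param seg_s segment length in seconds (4).
#' @param overlap fractional overlap between segments (0.5).
#' @return list(freq, psd): frequency grid (Hz, 0.25 Hz steps) and PSD in
#'   uV^2/Hz.
#' @export
welch_psd <- function(x, fs, seg_s = 4, overlap = 0.5) {
  ep_n <- as.integer(30 * fs)
  if (is.matrix(x)) {
    stopifnot(nrow(x) == ep_n)
    epochs <- x
  } else {
    if (length(x) < seg_s * fs)
      stop("signal shorter than one Welch segment (", seg_s, " s)")
    n_ep <- floor(length(x) / ep_n)
    if (n_ep < 1) stop("need at least one full 30-s epoch")
    epochs <- matrix(x[seq_len(n_ep * ep_n)], nrow = ep_n)
  }
  nseg <- as.integer(seg_s * fs)
  step <- as.integer(nseg * (1 - overlap))
  w <- .tukey_window(nseg, 0.5)
  starts <- seq(1L, ep_n - nseg + 1L, by = step)
  half <- floor(nseg / 2) + 1

  acc <- numeric(half)
  for (e in seq_len(ncol(epochs))) {
    pe <- numeric(half)
    for (s0 in starts) {
      pe <- pe + .segment_psd(epochs[s0:(s0 + nseg - 1L), e], fs, w)
    }
    acc <- acc + pe / length(starts)
  }
  list(freq = seq(0, fs / 2, by = fs / nseg),
       psd = acc / ncol(epochs))
}

#' Band power summaries from a PSD
#'
#' Rectangular integration over half-open bands [lo, hi); `relative` is
#' the band's share of total (0.5-35 Hz) power; `log_absolute` is the
#' natural log of absolute power (uV^2), NA-masked when power is
#' non-positive.
#'
#' @param psd list(freq, psd) from [welch_psd()].
#' @param scheme from [band_scheme()].
#' @return data.frame: band, absolute, log_absolute, relative.
#' @export
band_powers <- function(psd, scheme = band_scheme()) {
  df <- psd$freq[2] - psd$freq[1]
  absolute <- vapply(seq_len(nrow(scheme)), function(i) {
    sel <- psd$freq >= scheme$lo[i] & psd$freq < scheme$hi[i]
    sum(psd$psd[sel]) * df
  }, numeric(1))
  total <- absolute[scheme$band == "total"]
  relative <- if (total > 0) absolute / total else rep(NA_real_,
                                                       length(absolute))
  data.frame(band = scheme$band,
             absolute = absolute,
             log_absolute = ifelse(absolute > 0, log(absolute), NA_real_),
             relative = relative,
             stringsAsFactors = FALSE)
}

# Mean band power of an arbitrary (short) window via the periodogram;
# used by spindle QC where windows are shorter than a Welch segment.
band_power_fft <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  p <- Mod(X)^2 / (fs * n)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- floor(n / 2) + 1
  p <- p[seq_len(half)]
  p[-1] <- 2 * p[-1]
  freqs <- freqs[seq_len(half)]
  sel <- freqs >= lo & freqs < hi
  if (!any(sel)) return(0)
  sum(p[sel]) * fs / n
}

#' Per-stage, per-channel power summary of a cleaned record
#'
#' @param ep an `epoched_psg` after [reject_artifacts()].
#' @param stages,channels which stage/channel combinations to summarize.
#' @return long data.frame: stage, channel, band, absolute, log_absolute,
#'   relative (rows missing when a stage/channel has no retained epochs).
#' @export
power_summary <- function(ep, stages = c("N2", "N3", "R"),
                          channels = ep$recording$channels) {
  out <- list()
  for (stg in stages) {
    for (ch in channels) {
      ss <- stage_signal(ep, stg, ch)
      if (ss$minutes == 0) next
      bp <- band_powers(welch_psd(ss$x, ss$fs))
      bp$stage <- stg; bp$channel <- ch
      out[[length(out) + 1L]] <- bp
    }
  }
  if (!length(out)) {
    return(data.frame(band = character(0), absolute = numeric(0),
                      log_absolute = numeric(0), relative = numeric(0),
                      stage = character(0), channel = character(0)))
  }
  do.call(rbind, out)[, c("stage", "channel", "band", "absolute",
                          "log_absolute", "relative")]
}
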