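# Preprocessing: contralateral-mastoid referencing, resampling to 200 Hz,
# zero-phase 0.5-35 Hz band-pass, and line-noise removal by spectrum
# interpolation. Followed by epoching onto the 30-s staging grid.

#' Remove mains line noise by spectrum interpolation
#'
#' Replaces the amplitude spectrum inside `mains +/- halfwidth` Hz (and the
#' first harmonic, when below Nyquist) with a log-linear interpolation of
#' the mean flank amplitudes, preserving phase, then inverse-transforms.
#'
#' @param x numeric signal.
#' @param fs Hz.
#' @param mains mains frequency (default 60).
#' @param halfwidth half-width of the replaced band in Hz (default 1).
#' @param harmonics how many harmonics to clean (default 2 = mains and
#'   2*mains).
#' @export
remove_line_noise <- function(x, fs, mains = 60, halfwidth = 1,
                              harmonics = 2) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  amp <- Mod(X)
  for (h in seq_len(harmonics)) {
    f0 <- mains * h
    if (f0 + halfwidth >= fs / 2) next
    for (side in list(freqs, fs - freqs)) {   # positive and mirrored bins
      band <- which(side >= f0 - halfwidth & side <= f0 + halfwidth)
      lo <- which(side >= f0 - 2 * halfwidth & side < f0 - halfwidth)
      hi <- which(side > f0 + halfwidth & side <= f0 + 2 * halfwidth)
      if (!length(band) || !length(lo) || !length(hi)) next
      la <- log(mean(amp[lo]) + .Machine$double.eps)
      ha <- log(mean(amp[hi]) + .Machine$double.eps)
      w <- (side[band] - (f0 - halfwidth)) / (2 * halfwidth)
      amp[band] <- exp(la * (1 - w) + ha * w)
    }
  }
  ph <- Arg(X)
  Re(stats::fft(complex(modulus = amp, argument = ph), inverse = TRUE) / n)
}

# Resample one channel to target_fs using a polyphase filter.
.resample_channel <- function(x, fs, target_fs) {
  if (fs == target_fs) return(x)
  # smallest integer ratio p/q = target/fs
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(target_fs, fs)
  p <- target_fs / d; q <- fs / d
  y <- signal::resample(x, p, q)
  n_out <- round(length(x) * target_fs / fs)
  length(y) <- n_out
  y[is.na(y)] <- 0
  y
}

#' Preprocess a PSG recording
#'
#' Pipeline: contralateral-mastoid re-reference (F3/C3/O1 minus M2,
#' F4/C4/O2 minus M1) when mastoid channels are present; down-sample to
#' 200 Hz when the input rate exceeds it (lower rates are kept); spectrum-
#' interpolation line-noise removal; zero-phase 0.5-35 Hz band-pass.
#'
#' @param rec a [psg_recording()].
#' @param cfg list: `target_fs` (200), `band` (c(0.5, 35)), `mains` (60),
#'   `mains_halfwidth` (1), `reference` ("auto" applies the mastoid
#'   re-reference when M1/M2 exist, "require" errors when absent, "none"
#'   skips), `line_noise` (TRUE).
#' @return preprocessed [psg_recording()] restricted to the six EEG
#'   channels.
#' @export
preprocess <- function(rec, cfg = list()) {
  stopifnot(inherits(rec, "psg_recording"))
  cfg <- utils::modifyList(list(target_fs = 200, band = c(0.5, 35),
                                mains = 60, mains_halfwidth = 1,
                                reference = "auto", line_noise = TRUE), cfg)
  if (rec$fs < 100) stop("sampling rate below 100 Hz is not supported")
  dat <- rec$data
  chs <- rec$channels

  has_mast <- all(c("M1", "M2") %in% chs)
  if (identical(cfg$reference, "require") && !has_mast)
    stop("mastoid channels M1/M2 required for re-referencing but absent")
  if (cfg$reference %in% c("auto", "require") && has_mast) {
    contra <- c(F3 = "M2", C3 = "M2", O1 = "M2",
                F4 = "M1", C4 = "M1", O2 = "M1")
    for (ch in intersect(names(contra), chs)) {
      dat[, ch] <- dat[, ch] - dat[, contra[[ch]]]
    }
  }
  keep <- intersect(EEG_CHANNELS, chs)
  if (!length(keep)) stop("no EEG channels among: ",
                          paste(chs, collapse = ", "))
  dat <- dat[, keep, drop = FALSE]

  fs <- rec$fs
  if (fs > cfg$target_fs) {
    dat <- apply(dat, 2, .resample_channel, fs = fs,
                 target_fs = cfg$target_fs)
    fs <- cfg$target_fs
  }
  if (isTRUE(cfg$line_noise)) {
    dat <- apply(dat, 2, remove_line_noise, fs = fs, mains = cfg$mains,
                 halfwidth = cfg$mains_halfwidth)
  }
  dat <- apply(dat, 2, bandpass_filter, fs = fs,
               lo = cfg$band[1], hi = cfg$band[2])
  psg_recording(dat, fs, keep, reference = "contralateral mastoid",
                start_time = rec$start_time)
}

#' Epoch a recording onto the 30-s staging grid
#'
#' @param rec a (preprocessed) [psg_recording()].
#' @param hyp the matching [hypnogram()].
#' @return an object of class `epoched_psg`: the recording, hypnogram, and
#'   an initially all-kept QC table (filled by [reject_artifacts()]).
#' @export
epoch_psg <- function(rec, hyp) {
  ep_n <- as.integer(30 * rec$fs)
  n_ep <- min(length(hyp), floor(nrow(rec$data) / ep_n))
  qc <- expand.grid(epoch = seq_len(n_ep), channel = rec$channels,
                    stringsAsFactors = FALSE)
  qc$stage <- as.character(hyp)[qc$epoch]
  qc$kept <- TRUE
  qc$reasons <- ""
  structure(list(recording = rec, hypnogram = hyp, n_epochs = n_ep,
                 qc = qc, hjorth = NULL),
            class = "epoched_psg")
}

#' @export
print.epoched_psg <- function(x, ...) {
  cat(sprintf("<epoched_psg> %d epochs x %d channels @ %g Hz; %.1f%% kept\n",
              x$n_epochs, length(x$recording$channels), x$recording$fs,
              100 * mean(x$qc$kept)))
  invisible(x)
}

# Extract the samples of epoch `i` (1-based) on channel `ch`.
epoch_samples <- function(ep, i, ch) {
  fs <- ep$recording$fs
  ep_n <- as.integer(30 * fs)
  ep$recording$data[((i - 1L) * ep_n + 1L):(i * ep_n), ch]
}

# Concatenated samples of retained epochs of one stage on one channel;
# also returns retained minutes. Used by the detectors.
stage_signal <- function(ep, stage, ch) {
  q <- ep$qc[ep$qc$channel == ch & ep$qc$stage == stage & ep$qc$kept, ]
  eps <- sort(q$epoch)
  fs <- ep$recording$fs
  ep_n <- as.integer(30 * fs)
  if (!length(eps)) {
    return(list(x = numeric(0), epochs = integer(0), minutes = 0, fs = fs))
  }
  idx <- as.vector(vapply(eps, function(i) ((i - 1L) * ep_n + 1L):(i * ep_n),
                          integer(ep_n)))
  list(x = ep$recording$data[idx, ch], epochs = eps,
       minutes = length(eps) * 0.5, fs = fs)
}
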