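# Synthetic PSG generator: ground-truthed multichannel sleep EEG built
# from a 1/f^alpha aperiodic background, mild stage-dependent oscillations,
# and implanted spindle / slow-oscillation events whose every parameter is
# logged. All randomness flows from one integer seed through hierarchical
# substreams (subject -> channel -> event class), so regenerating part of a
# cohort is stable.

EEG_CHANNELS <- c("F3", "F4", "C3", "C4", "O1", "O2")

#' Construct a PSG recording container
#'
#' @param data numeric matrix, samples x channels, in uV.
#' @param fs sampling rate (Hz).
#' @param channels channel names (column order).
#' @param reference per-channel reference label.
#' @param start_time record start (seconds, clock-agnostic).
#' @export
psg_recording <- function(data, fs, channels = colnames(data),
                          reference = "contralateral mastoid",
                          start_time = 0) {
  data <- as.matrix(data)
  stopifnot(fs > 0, ncol(data) == length(channels))
  colnames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels,
                 reference = rep_len(reference, length(channels)),
                 start_time = start_time),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %d channels x %.1f min @ %g Hz\n",
              ncol(x$data), nrow(x$data) / x$fs / 60, x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Subject profile for the synthetic cohort
#'
#' `trajectory_offset` shifts the age at which all feature-generating
#' curves are evaluated, modelling a developmental delay (negative) or
#' advance (positive) as used for the delayed clinical subgroup.
#'
#' @param subject_id identifier token.
#' @param age years.
#' @param sex "F" or "M".
#' @param race category label.
#' @param group "non-NDD" or a named subgroup.
#' @param ahi apnea-hypopnea index (events/h).
#' @param medication logical.
#' @param trajectory_offset years.
#' @export
subject_profile <- function(subject_id, age, sex = "F", race = "white",
                            group = "non-NDD", ahi = 0, medication = FALSE,
                            trajectory_offset = 0) {
  stopifnot(is.finite(age), age > 0, is.finite(trajectory_offset))
  list(subject_id = as.character(subject_id), age = age, sex = sex,
       race = race, group = group, ahi = ahi, medication = medication,
       trajectory_offset = trajectory_offset)
}

#' Specification of one implanted event class
#'
#' @param class one of "slow_spindle", "fast_spindle", "so".
#' @param density events per minute of eligible stage time.
#' @param amplitude uV. For spindles, the peak of the Hann envelope; for
#'   SOs, the negative-peak magnitude (positive half-wave amplitude is
#'   `pos_fraction` of it).
#' @param duration seconds (spindles: full event; SOs: negative half-wave).
#' @param frequency Hz (spindle carrier; ignored for SOs).
#' @param ramp Hz, total linear intra-event instantaneous-frequency change
#'   (end minus start), symmetric about `frequency`. The measured chirp
#'   (last-half minus first-half mean frequency) of such an event is
#'   `ramp / 2`.
#' @param coupling_phase degrees, preferred SO phase of spindle peaks
#'   (0 = SO positive peak).
#' @param coupling_kappa von Mises concentration; 0 = no coupling (peaks
#'   placed uniformly in the stage).
#' @param pos_duration s, SO positive half-wave duration.
#' @param pos_fraction SO positive amplitude as fraction of negative.
#' @param amplitude_cv lognormal coefficient of variation of per-event
#'   amplitudes around `amplitude` (0 = identical events).
#' @param stages stages eligible for implantation (default N2).
#' @param channels channels receiving this event class.
#' @export
event_spec <- function(class = c("fast_spindle", "slow_spindle", "so"),
                       density = 2, amplitude = 25,
                       duration = if (class == "so") 0.8 else 1.0,
                       frequency = switch(class, slow_spindle = 11,
                                          fast_spindle = 15, so = NA_real_),
                       ramp = 0, coupling_phase = 0, coupling_kappa = 0,
                       pos_duration = 0.5, pos_fraction = 0.6,
                       amplitude_cv = 0, stages = "N2",
                       channels = switch(class,
                                         slow_spindle = c("F3", "F4"),
                                         fast_spindle = c("C3", "C4"),
                                         so = c("F3", "F4", "C3", "C4"))) {
  class <- match.arg(class)
  stopifnot(density >= 0, amplitude >= 0, duration > 0,
            coupling_kappa >= 0, pos_duration > 0, amplitude_cv >= 0)
  if (class != "so" && (duration < 0.3 || duration > 3))
    stop("spindle duration outside detectable range 0.3-3 s")
  if (class == "so" && (duration < 0.3 || duration > 1.5))
    stop("SO negative half-wave duration outside 0.3-1.5 s")
  if (class == "so" && pos_duration > 1)
    stop("SO positive half-wave duration above 1 s")
  list(class = class, density = density, amplitude = amplitude,
       duration = duration, frequency = frequency, ramp = ramp,
       coupling_phase = coupling_phase, coupling_kappa = coupling_kappa,
       pos_duration = pos_duration, pos_fraction = pos_fraction,
       amplitude_cv = amplitude_cv, stages = stages, channels = channels)
}

#' Analytic spindle waveform
#'
#' Hann-windowed sinusoid with a linear instantaneous-frequency ramp
#' symmetric about the carrier frequency; peak (envelope maximum) at the
#' event center.
#'
#' @param fs Hz; @param duration s; @param frequency Hz carrier;
#' @param ramp total Hz change start to end; @param amplitude uV envelope
#'   peak.
#' @return numeric vector of `round(duration * fs)` samples.
#' @export
spindle_waveform <- function(fs, duration, frequency, ramp = 0,
                             amplitude = 1) {
  n <- max(4L, round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  d <- (n - 1) / fs
  # phase = 2*pi * integral of f(t) = f0 + ramp*(t/d - 1/2)
  phase <- 2 * pi * (frequency * t + ramp * (t^2 / (2 * d) - t / 2))
  env <- 0.5 * (1 - cos(2 * pi * t / d))       # Hann, max 1 at center
  amplitude * env * sin(phase)
}

#' Analytic slow-oscillation waveform
#'
#' Biphasic raised cosine: a negative half-wave of `dur_neg` seconds
#' followed by a positive half-wave of `dur_pos` seconds, starting and
#' ending at zero.
#'
#' @param fs Hz; @param dur_neg,dur_pos s; @param neg_amp uV magnitude of
#'   the negative peak; @param pos_amp uV positive peak.
#' @export
so_waveform <- function(fs, dur_neg, dur_pos, neg_amp, pos_amp) {
  n1 <- max(2L, round(dur_neg * fs))
  n2 <- max(2L, round(dur_pos * fs))
  t1 <- (seq_len(n1) - 1) / (n1 - 1)
  t2 <- (seq_len(n2) - 1) / (n2 - 1)
  c(-neg_amp * 0.5 * (1 - cos(2 * pi * t1)),
    pos_amp * 0.5 * (1 - cos(2 * pi * t2)))
}

#' 1/f^alpha aperiodic noise via spectral shaping
#'
#' @param n samples; @param fs Hz; @param alpha spectral exponent;
#' @param rms target root-mean-square amplitude (uV).
#' @return numeric vector (uses the current RNG stream).
#' @export
aperiodic_noise <- function(n, fs, alpha = 1.5, rms = 15) {
  if (n < 4) return(stats::rnorm(n, 0, rms))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]       # mirror to physical frequency
  g <- ifelse(f <= 0, 0, f^(-alpha / 2))
  x <- Re(stats::fft(X * g, inverse = TRUE) / n)
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x / s * rms
}

#' Default stage-dependent background-noise parameters
#'
#' Spectral exponents (`alpha`), total RMS amplitudes (uV) and the RMS of
#' the ongoing 11-16 Hz sigma-activity floor per stage. The exponents are
#' sleep-EEG conventions, not fitted claims; the sigma floor reflects the
#' continuous sigma-band activity present in NREM outside discrete
#' spindles -- a pure power-law background would be unrealistically quiet
#' in that band.
#' @export
default_noise_params <- function() {
  list(alpha = c(W = 1.0, N1 = 1.2, N2 = 1.5, N3 = 2.0, R = 1.2),
       rms = c(W = 10, N1 = 12, N2 = 15, N3 = 25, R = 12),
       sigma_rms = c(W = 0.5, N1 = 1, N2 = 2, N3 = 1.5, R = 0.5),
       stage_osc = TRUE)
}

# mild stage-dependent oscillatory content (uV amplitudes kept small so
# detectors are driven by implanted events, not by the colouring)
.stage_oscillation <- function(stage, n, fs, t0) {
  t <- t0 + (seq_len(n) - 1) / fs
  switch(stage,
         W = 6 * sin(2 * pi * 9.5 * t),
         N3 = 8 * sin(2 * pi * 0.9 * t),
         R = 4 * sin(2 * pi * 5.5 * t),
         numeric(n) * 0)
}

# Map an SO phase (deg, 0 = positive peak, increasing in time) to a time
# offset within an SO event that starts at its down-going zero crossing.
# Over the event the phase runs 90 -> 270 (negative half-wave, duration
# dn) -> 450 (positive half-wave, duration dp).
.so_phase_to_time <- function(phase_deg, dur_neg, dur_pos) {
  ph <- ((phase_deg - 90) %% 360) + 90          # in [90, 450)
  ifelse(ph < 270,
         dur_neg * (ph - 90) / 180,
         dur_neg + dur_pos * (ph - 270) / 180)
}

#' Synthesize one ground-truthed PSG record
#'
#' Builds a 6-channel uV signal as stagewise 1/f^alpha background plus mild
#' stage oscillations plus implanted events. Spindles are Hann-windowed
#' sinusoids with a linear frequency ramp; SOs are biphasic raised-cosine
#' waves. When an event spec has `coupling_kappa > 0`, spindle peaks are
#' placed at SO phases drawn from von Mises(`coupling_phase`, kappa) inside
#' implanted SO events of the same channel. Every implanted event is logged
#' once in the ground truth.
#'
#' @param profile from [subject_profile()] (metadata only; curves are
#'   applied by [simulate_cohort()]).
#' @param hyp a [hypnogram()].
#' @param specs list of [event_spec()]s.
#' @param noise list(alpha = per-stage exponents, rms = per-stage uV,
#'   stage_osc = logical); see `default_noise_params()`. `rms = 0`
#'   disables the background.
#' @param fs sampling rate, one of 128, 200, 256, 512.
#' @param seed integer seed.
#' @return list(recording = [psg_recording()], truth = list(events =
#'   data.frame(class, channel, start_s, stop_s, peak_s, phase_at_peak),
#'   artifact_log = empty data.frame, params = specs)).
#' @export
synthesize_record <- function(profile, hyp, specs = list(),
                              noise = default_noise_params(),
                              fs = 128, seed = 1) {
  stopifnot(fs %in% c(128, 200, 256, 512))
  np <- utils::modifyList(default_noise_params(), noise)
  st <- as.character(hyp)
  ep_n <- as.integer(30 * fs)
  n <- ep_n * length(st)
  dat <- matrix(0, n, length(EEG_CHANNELS),
                dimnames = list(NULL, EEG_CHANNELS))

  runs <- rle(st)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L

  for (ci in seq_along(EEG_CHANNELS)) {
    with_seed(substream_seed(seed, 7L, ci), {
      for (k in seq_along(runs$values)) {
        stg <- runs$values[k]
        i0 <- (run_start[k] - 1L) * ep_n + 1L
        i1 <- run_end[k] * ep_n
        len <- i1 - i0 + 1L
        seg <- if (np$rms[[stg]] > 0) {
          aperiodic_noise(len, fs, np$alpha[[stg]], np$rms[[stg]])
        } else numeric(len)
        srms <- (np$sigma_rms %||% 0)[[stg]] %||% 0
        if (np$rms[[stg]] > 0 && srms > 0 && len > 30) {
          sb <- bandpass_filter(stats::rnorm(len), fs, 11, 16)
          seg <- seg + sb / stats::sd(sb) * srms
        }
        if (isTRUE(np$stage_osc) && np$rms[[stg]] > 0) {
          seg <- seg + .stage_oscillation(stg, len, fs, (i0 - 1) / fs)
        }
        dat[i0:i1, ci] <- seg
      }
    })
  }

  events <- list()
  # SOs first so coupled spindles can target them
  ord <- order(vapply(specs, function(s) s$class != "so", logical(1)))
  for (si in ord) {
    sp <- specs[[si]]
    for (ch in sp$channels) {
      ci <- match(ch, EEG_CHANNELS)
      if (is.na(ci)) stop("unknown channel in event spec: ", ch)
      elig_runs <- which(runs$values %in% sp$stages)
      stage_min <- sum(runs$lengths[elig_runs]) * 0.5
      n_ev <- round(sp$density * stage_min)
      if (n_ev == 0) next
      if (!length(elig_runs))
        stop("no epochs of stage ", paste(sp$stages, collapse = "/"),
             " available for ", sp$class, " implantation")
      with_seed(substream_seed(seed, 13L, si, ci), {
        total_dur <- if (sp$class == "so") {
          sp$duration + sp$pos_duration
        } else sp$duration
        run_sec <- cbind(start = (run_start[elig_runs] - 1L) * 30,
                         stop = run_end[elig_runs] * 30)
        placed <- matrix(numeric(0), ncol = 2)   # start, stop (s)
        amps <- if (sp$amplitude_cv > 0) {
          sdlog <- sqrt(log(1 + sp$amplitude_cv^2))
          sp$amplitude * stats::rlnorm(n_ev, -sdlog^2 / 2, sdlog)
        } else rep(sp$amplitude, n_ev)

        so_pool <- NULL
        if (sp$class != "so" && sp$coupling_kappa > 0) {
          so_pool <- do.call(rbind, Filter(function(e)
            e$class == "so" & e$channel == ch,
            events))
          if (is.null(so_pool) || !nrow(so_pool))
            stop("coupled ", sp$class, " requested on ", ch,
                 " but no SOs implanted there")
        }

        for (e in seq_len(n_ev)) {
          ok <- FALSE
          for (try in 1:200) {
            if (!is.null(so_pool)) {
              j <- sample.int(nrow(so_pool), 1)
              ph <- rvonmises_deg(1, sp$coupling_phase, sp$coupling_kappa)
              tp <- so_pool$start_s[j] +
                .so_phase_to_time(ph, so_pool$dur_neg[j], so_pool$dur_pos[j])
              t0 <- tp - total_dur / 2
            } else {
              rn <- elig_runs[sample.int(length(elig_runs), 1,
                                         prob = runs$lengths[elig_runs])]
              ri <- match(rn, elig_runs)
              t0 <- stats::runif(1, run_sec[ri, 1],
                                 run_sec[ri, 2] - total_dur)
              ph <- NA_real_
              tp <- t0 + total_dur / 2
            }
            t1 <- t0 + total_dur
            inside <- any(t0 >= run_sec[, 1] & t1 <= run_sec[, 2])
            clash <- nrow(placed) > 0 &&
              any(t0 < placed[, 2] & t1 > placed[, 1])
            if (inside && !clash) { ok <- TRUE; break }
          }
          if (!ok)
            stop("could not place ", sp$class, " events at density ",
                 sp$density, "/min in stage ",
                 paste(sp$stages, collapse = "/"),
                 " (stage time too short or too crowded)")
          placed <- rbind(placed, c(t0, t1))
          i0 <- round(t0 * fs) + 1L
          wav <- if (sp$class == "so") {
            so_waveform(fs, sp$duration, sp$pos_duration,
                        amps[e], amps[e] * sp$pos_fraction)
          } else {
            spindle_waveform(fs, sp$duration, sp$frequency, sp$ramp, amps[e])
          }
          idx <- i0:(i0 + length(wav) - 1L)
          idx <- idx[idx >= 1 & idx <= n]
          dat[idx, ci] <- dat[idx, ci] + wav[seq_along(idx)]
          peak_s <- if (sp$class == "so") {
            t0 + sp$duration / 2                # negative peak
          } else if (!is.null(so_pool)) tp else t0 + total_dur / 2
          events[[length(events) + 1L]] <- data.frame(
            class = sp$class, channel = ch, start_s = t0, stop_s = t1,
            peak_s = peak_s, phase_at_peak = ph,
            amplitude = amps[e],
            dur_neg = if (sp$class == "so") sp$duration else NA_real_,
            dur_pos = if (sp$class == "so") sp$pos_duration else NA_real_,
            stringsAsFactors = FALSE)
        }
      })
    }
  }

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(class = character(0), channel = character(0),
               start_s = numeric(0), stop_s = numeric(0),
               peak_s = numeric(0), phase_at_peak = numeric(0),
               amplitude = numeric(0), dur_neg = numeric(0),
               dur_pos = numeric(0))
  if (nrow(ev)) ev <- ev[order(ev$channel, ev$start_s), ]
  rownames(ev) <- NULL

  list(recording = psg_recording(dat, fs, EEG_CHANNELS),
       truth = list(events = ev,
                    artifact_log = data.frame(channel = character(0),
                                              epoch = integer(0),
                                              kind = character(0)),
                    specs = specs, profile = profile))
}

#' Inject artifacts into a recording
#'
#' @param rec a [psg_recording()].
#' @param artifact_spec data.frame with columns `channel`, `epoch`
#'   (1-based; `NA` allowed for `polarity_flip`, which negates the whole
#'   channel) and `kind` in {clip, flatline, high_amplitude, line60,
#'   polarity_flip}.
#' @param seed integer seed (placement of spikes within the epoch).
#' @return list(recording, artifact_log).
#' @export
inject_artifacts <- function(rec, artifact_spec, seed = 1) {
  stopifnot(inherits(rec, "psg_recording"))
  kinds <- c("clip", "flatline", "high_amplitude", "line60", "polarity_flip")
  if (is.null(artifact_spec) || nrow(artifact_spec) == 0) {
    return(list(recording = rec,
                artifact_log = data.frame(channel = character(0),
                                          epoch = integer(0),
                                          kind = character(0))))
  }
  if (!all(artifact_spec$kind %in% kinds))
    stop("unknown artifact kind(s): ",
         paste(setdiff(artifact_spec$kind, kinds), collapse = ", "))
  fs <- rec$fs
  ep_n <- as.integer(30 * fs)
  dat <- rec$data
  with_seed(substream_seed(seed, 31L), {
    for (r in seq_len(nrow(artifact_spec))) {
      ch <- artifact_spec$channel[r]
      ci <- match(ch, rec$channels)
      if (is.na(ci)) stop("unknown channel: ", ch)
      kind <- artifact_spec$kind[r]
      if (kind == "polarity_flip") {
        dat[, ci] <- -dat[, ci]
        next
      }
      ep <- artifact_spec$epoch[r]
      idx <- ((ep - 1L) * ep_n + 1L):(ep * ep_n)
      x <- dat[idx, ci]
      dat[idx, ci] <- switch(kind,
        clip = {
          lim <- 0.3 * max(abs(x))
          pmin(pmax(x, -lim), lim)
        },
        flatline = {
          k <- as.integer(0.2 * ep_n)
          i0 <- sample.int(ep_n - k, 1)
          x[i0:(i0 + k - 1L)] <- x[i0]
          x
        },
        high_amplitude = {
          i0 <- sample.int(ep_n - as.integer(fs), 1)
          t <- seq_len(as.integer(fs)) / fs
          x[i0:(i0 + length(t) - 1L)] <-
            x[i0:(i0 + length(t) - 1L)] + 250 * sin(2 * pi * 2 * t)
          x
        },
        line60 = {
          t <- (idx - 1) / fs
          x + 20 * sin(2 * pi * 60 * t)
        })
    }
  })
  list(recording = psg_recording(dat, fs, rec$channels, rec$reference,
                                 rec$start_time),
       artifact_log = artifact_spec[, c("channel", "epoch", "kind")])
}
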