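# SO-spindle coupling: gross overlap (spindle peak inside an SO event),
# SO phase at the spindle peak (filter-Hilbert, 0 deg = SO positive peak),
# inter-trial phase clustering (ITPC), and permutation z-scores under
# count-preserving null shuffles.

#' Instantaneous SO phase series
#'
#' Filter-Hilbert phase of the 0.5-4 Hz signal in degrees. Convention:
#' 0 deg at the SO positive peak, 180 deg at the negative peak, increasing
#' with time, wrapped to [0, 360).
#'
#' @param x numeric signal, uV.
#' @param fs Hz.
#' @param filter apply the internal 0.5-4 Hz zero-phase filter (TRUE).
#' @export
so_phase <- function(x, fs, filter = TRUE) {
  xf <- if (filter) bandpass_filter(x, fs, 0.5, 4) else x
  instantaneous_phase_deg(xf)
}

.phase_at <- function(phase, fs, times_s) {
  idx <- pmin(pmax(round(times_s * fs) + 1L, 1L), length(phase))
  phase[idx]
}

#' Observed SO-spindle coupling on one channel timeline
#'
#' A spindle overlaps an SO iff its peak time falls in
#' [down_zc, end_zc). ITPC is the magnitude of the mean unit phasor of SO
#' phases at overlapping spindle peaks.
#'
#' @param spindle_peaks_s spindle peak times (s, stage timeline).
#' @param so_events data.frame from [detect_so()].
#' @param phase phase series from [so_phase()] on the same timeline.
#' @param fs Hz.
#' @return list: n_spindles, n_overlap, overlap_prop, mean_angle (deg in
#'   [0, 360), NA when no overlap), itpc, phases (deg, overlapping peaks).
#' @export
couple <- function(spindle_peaks_s, so_events, phase, fs) {
  n_sp <- length(spindle_peaks_s)
  if (n_sp == 0) {
    return(list(n_spindles = 0L, n_overlap = 0L, overlap_prop = NA_real_,
                mean_angle = NA_real_, itpc = NA_real_,
                phases = numeric(0), reason = "no spindles"))
  }
  inside <- .peaks_in_intervals(spindle_peaks_s, so_events)
  n_ov <- sum(inside)
  ph <- if (n_ov) .phase_at(phase, fs, spindle_peaks_s[inside]) else
    numeric(0)
  list(n_spindles = n_sp, n_overlap = n_ov,
       overlap_prop = n_ov / n_sp,
       mean_angle = if (n_ov) circ_mean_deg(ph) else NA_real_,
       itpc = if (n_ov) circ_r(ph) else NA_real_,
       phases = ph, reason = "")
}

# Membership of times in disjoint ordered [start, stop) intervals.
.peaks_in_intervals <- function(t, so_events) {
  if (!nrow(so_events)) return(rep(FALSE, length(t)))
  o <- order(so_events$down_zc)
  breaks <- as.vector(rbind(so_events$down_zc[o], so_events$end_zc[o]))
  findInterval(t, breaks) %% 2 == 1
}

#' Permutation z-scores for coupling metrics
#'
#' Overlap null: each permutation circularly shifts all spindle peaks by a
#' uniform random offset over the stage timeline, preserving the numbers
#' of spindles and SOs. ITPC null: each permutation reassigns every
#' overlapping spindle a uniform random time inside a randomly chosen SO
#' interval, preserving counts and the gross overlap. z = (observed -
#' null mean) / null SD.
#'
#' @param obs observed result from [couple()].
#' @param spindle_peaks_s,so_events,phase,fs as in [couple()].
#' @param timeline_s total stage timeline length (s).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed for the permutation stream (independent of
#'   detection).
#' @return list(overlap_z, itpc_z, n_perm); a z is NA with a reason when
#'   its null SD is degenerate.
#' @export
permutation_null <- function(obs, spindle_peaks_s, so_events, phase, fs,
                             timeline_s, n_perm = 10000, seed = 1) {
  out <- list(overlap_z = NA_real_, itpc_z = NA_real_, n_perm = n_perm,
              reason = "")
  if (obs$n_spindles == 0 || !nrow(so_events)) {
    out$reason <- "no events"
    return(out)
  }
  with_seed(substream_seed(seed, 97L), {
    # overlap null: circular shift of the spindle peak series
    offs <- stats::runif(n_perm, 0, timeline_s)
    shifted <- outer(spindle_peaks_s, offs, `+`) %% timeline_s
    o <- order(so_events$down_zc)
    breaks <- as.vector(rbind(so_events$down_zc[o], so_events$end_zc[o]))
    ins <- matrix(findInterval(shifted, breaks) %% 2 == 1,
                  nrow = length(spindle_peaks_s))
    null_ov <- colSums(ins)
    s_ov <- stats::sd(null_ov)
    if (is.finite(s_ov) && s_ov > 0) {
      out$overlap_z <- (obs$n_overlap - mean(null_ov)) / s_ov
    } else out$reason <- paste(out$reason, "degenerate overlap null")

    # itpc null: uniform times within randomly chosen SO intervals
    if (obs$n_overlap >= 1) {
      n_ov <- obs$n_overlap
      # interval chosen with probability proportional to its length, i.e.
      # uniformly over the union of SO time, matching the null hypothesis
      # of spindle peaks independent of SO timing
      len <- so_events$end_zc - so_events$down_zc
      j <- matrix(sample.int(nrow(so_events), n_ov * n_perm,
                             replace = TRUE, prob = len), nrow = n_ov)
      u <- matrix(stats::runif(n_ov * n_perm), nrow = n_ov)
      tt <- so_events$down_zc[j] +
        u * (so_events$end_zc[j] - so_events$down_zc[j])
      ph <- matrix(.phase_at(phase, fs, tt), nrow = n_ov)
      null_itpc <- Mod(colMeans(exp(1i * ph * pi / 180)))
      s_it <- stats::sd(null_itpc)
      if (is.finite(s_it) && s_it > 0) {
        out$itpc_z <- (obs$itpc - mean(null_itpc)) / s_it
      } else out$reason <- paste(out$reason, "degenerate itpc null")
    }
  })
  out
}

#' Full coupling analysis for one channel and spindle class
#'
#' Detects spindles and SOs on the concatenated retained N2 timeline of a
#' cleaned record, computes the observed coupling and its permutation
#' z-scores.
#'
#' @param ep an `epoched_psg` after [reject_artifacts()].
#' @param ch channel.
#' @param class spindle class ("fast" or "slow").
#' @param so_mode SO threshold mode.
#' @param n_perm permutations.
#' @param seed permutation seed.
#' @return one-row data.frame (class, channel, n_spindles, n_overlap,
#'   overlap_prop, overlap_z, mean_angle, itpc, itpc_z, n_perm).
#' @export
coupling_analysis <- function(ep, ch, class = "fast", so_mode = "relative",
                              n_perm = 10000, seed = 1, stage = "N2") {
  ss <- stage_signal(ep, stage, ch)
  sp <- detect_spindle_events(ep, ch, class, stage)
  so <- detect_so_events(ep, ch, so_mode, stage)
  peaks <- if (!is.null(sp$events) && nrow(sp$events)) sp$events$peak_s
           else numeric(0)
  phase <- so_phase(ss$x, ss$fs)
  obs <- couple(peaks, so$events, phase, ss$fs)
  z <- permutation_null(obs, peaks, so$events, phase, ss$fs,
                        timeline_s = length(ss$x) / ss$fs,
                        n_perm = n_perm, seed = seed)
  data.frame(class = class, channel = ch,
             n_spindles = obs$n_spindles, n_overlap = obs$n_overlap,
             overlap_prop = obs$overlap_prop, overlap_z = z$overlap_z,
             mean_angle = obs$mean_angle, itpc = obs$itpc,
             itpc_z = z$itpc_z, n_perm = n_perm,
             stringsAsFactors = FALSE)
}
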