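# Slow-oscillation detection: zero-crossing candidates on the 0.5-4 Hz
# filtered signal, temporal criteria on the two half-waves, and either a
# relative (2x the per-channel candidate mean; the default) or an absolute
# (-40 uV negative peak, 75 uV peak-to-peak) amplitude threshold.

#' Detect slow oscillations
#'
#' Candidates are anchored at a positive-to-negative zero crossing
#' (`down_zc`): the negative half-wave up to the next up-crossing must
#' last 0.3-1.5 s, and the following positive half-wave (to the next
#' down-crossing, `end_zc`) at most 1 s. In relative mode the negative
#' peak magnitude and peak-to-peak amplitude must strictly exceed twice
#' their respective means over all temporal-criteria-passing candidates
#' (two-pass detection, so thresholds do not depend on the selection); in
#' absolute mode the negative peak must be below -40 uV and peak-to-peak
#' above 75 uV (strict comparisons).
#'
#' @param x numeric signal (concatenated retained N2 epochs), uV.
#' @param fs Hz.
#' @param mode "relative" or "absolute".
#' @param rel_mult relative-mode multiplier (2).
#' @param abs_neg,abs_p2p absolute-mode thresholds (uV).
#' @param filter apply the internal 0.5-4 Hz zero-phase filter (TRUE).
#' @return data.frame, one row per SO: down_zc, up_zc, end_zc,
#'   neg_peak_time, pos_peak_time (s); neg_peak (uV, < 0), pos_peak, p2p;
#'   duration (end_zc - down_zc); slope (p2p / (pos_peak_time -
#'   neg_peak_time), uV/s).
#' @export
detect_so <- function(x, fs, mode = c("relative", "absolute"),
                      rel_mult = 2, abs_neg = -40, abs_p2p = 75,
                      filter = TRUE) {
  mode <- match.arg(mode)
  if (length(x) < 10 * fs) stop("need at least 10 s of usable signal")
  xf <- if (filter) bandpass_filter(x, fs, 0.5, 4) else x
  s <- sign(xf)
  s[s == 0] <- 1
  flips <- which(diff(s) != 0)
  down <- flips[s[flips] > 0]     # positive -> negative
  up <- flips[s[flips] < 0]       # negative -> positive
  if (length(down) < 2 || !length(up)) return(.empty_so())

  # pair each down-crossing with the next up- and down-crossings
  u_i <- up[findInterval(down, up) + 1L]
  d2_i <- down[findInterval(u_i, down) + 1L]
  ok <- !is.na(u_i) & !is.na(d2_i)
  d0 <- down[ok]; u_i <- u_i[ok]; d2_i <- d2_i[ok]
  dur_neg <- (u_i - d0) / fs
  dur_pos <- (d2_i - u_i) / fs
  ok <- dur_neg >= 0.3 & dur_neg <= 1.5 & dur_pos <= 1
  if (!any(ok)) return(.empty_so())
  d0 <- d0[ok]; u_i <- u_i[ok]; d2_i <- d2_i[ok]
  neg_i <- vapply(seq_along(d0), function(k)
    d0[k] + which.min(xf[(d0[k] + 1):u_i[k]]), numeric(1))
  pos_i <- vapply(seq_along(d0), function(k)
    u_i[k] + which.max(xf[(u_i[k] + 1):d2_i[k]]), numeric(1))
  cd <- data.frame(
    down_zc = d0 / fs, up_zc = u_i / fs, end_zc = d2_i / fs,
    neg_peak_time = (neg_i - 1) / fs, pos_peak_time = (pos_i - 1) / fs,
    neg_peak = xf[neg_i], pos_peak = xf[pos_i])
  cd$p2p <- cd$pos_peak - cd$neg_peak
  cd$duration <- cd$end_zc - cd$down_zc
  cd$slope <- cd$p2p / (cd$pos_peak_time - cd$neg_peak_time)

  keep <- if (mode == "relative") {
    thr_neg <- rel_mult * mean(abs(cd$neg_peak))
    thr_p2p <- rel_mult * mean(cd$p2p)
    abs(cd$neg_peak) > thr_neg & cd$p2p > thr_p2p
  } else {
    cd$neg_peak < abs_neg & cd$p2p > abs_p2p
  }
  out <- cd[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_so <- function() {
  data.frame(down_zc = numeric(0), up_zc = numeric(0), end_zc = numeric(0),
             neg_peak_time = numeric(0), pos_peak_time = numeric(0),
             neg_peak = numeric(0), pos_peak = numeric(0),
             p2p = numeric(0), duration = numeric(0), slope = numeric(0))
}

#' Summarize detected slow oscillations
#'
#' @param events from [detect_so()].
#' @param retained_minutes denominator for density.
#' @return list(density, n_events, and means of neg_peak, p2p, duration,
#'   slope).
#' @export
so_metrics <- function(events, retained_minutes) {
  n <- nrow(events)
  list(density = n / retained_minutes, n_events = n,
       neg_peak = if (n) mean(events$neg_peak) else NA_real_,
       p2p = if (n) mean(events$p2p) else NA_real_,
       duration = if (n) mean(events$duration) else NA_real_,
       slope = if (n) mean(events$slope) else NA_real_)
}

#' Detect SOs on one channel of a cleaned record
#'
#' @param ep an `epoched_psg` after [reject_artifacts()].
#' @param ch channel.
#' @param mode threshold mode, see [detect_so()].
#' @param stage stage analysed (N2).
#' @return list(events, summary, retained_minutes); events are on the
#'   concatenated retained-stage timeline.
#' @export
detect_so_events <- function(ep, ch, mode = "relative", stage = "N2") {
  ss <- stage_signal(ep, stage, ch)
  if (ss$minutes < 1) {
    return(list(events = .empty_so(),
                summary = list(density = NA_real_, n_events = 0L),
                retained_minutes = ss$minutes))
  }
  ev <- detect_so(ss$x, ss$fs, mode)
  list(events = ev, summary = so_metrics(ev, ss$minutes),
       retained_minutes = ss$minutes)
}
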