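# Record-level handling: signal-polarity resolution on central channels
# and record exclusion rules (short sleep, too few retained epochs,
# persistent line noise, spectral-power outliers, ambiguous polarity).

#' Polarity statistic T_DIFF for one channel
#'
#' Published polarity checks of this kind rely on an external tool's
#' statistic; here T_DIFF is defined as the standardized mean -- mean divided by SD, a
#' Cohen's-d-like effect size rather than a t statistic, so its null
#' distribution tightens with the number of epochs -- of the per-epoch
#' skewness of the 0.5-4 Hz filtered signal across retained N2 epochs.
#' Physiologic slow oscillations produce dominant negative deflections,
#' hence negative skewness and T_DIFF < -1 ("normal"); a polarity-flipped
#' record gives T_DIFF > 1; symmetric noise concentrates inside [-1, 1]
#' ("ambiguous"). The statistic is odd: T_DIFF(-x) = -T_DIFF(x).
#'
#' @param ep an `epoched_psg` (after [reject_artifacts()]).
#' @param ch channel name.
#' @param stage stage used (N2).
#' @return the t statistic, or NA when fewer than `min_epochs` retained
#'   epochs are available.
#' @export
t_diff <- function(ep, ch, stage = "N2", min_epochs = 10) {
  q <- ep$qc[ep$qc$channel == ch & ep$qc$stage == stage & ep$qc$kept, ]
  eps <- q$epoch
  if (length(eps) < min_epochs) return(NA_real_)
  fs <- ep$recording$fs
  sk <- vapply(eps, function(i) {
    x <- bandpass_filter(epoch_samples(ep, i, ch), fs, 0.5, 4)
    skewness(x)
  }, numeric(1))
  mean(sk) / stats::sd(sk)
}

#' Resolve signal polarity from central channels
#'
#' Computes T_DIFF at each tested channel during N2. T_DIFF > 1 means the
#' channel set should be flipped; T_DIFF < -1 means normal polarity; the
#' closed interval [-1, 1] (or insufficient N2) marks the record
#' polarity-ambiguous.
#'
#' @param ep an `epoched_psg` after rejection.
#' @param channels channels to test (default C3, C4).
#' @return list(t_diff = named numeric, channel_decision = named character
#'   in {normal, flipped, ambiguous}, record = overall decision: "flipped"
#'   if any tested channel flips, "ambiguous" if any is ambiguous and none
#'   flips, else "normal").
#' @export
resolve_polarity <- function(ep, channels = c("C3", "C4")) {
  td <- vapply(channels, function(ch) t_diff(ep, ch), numeric(1))
  dec <- ifelse(is.na(td), "ambiguous",
                ifelse(td > 1, "flipped",
                       ifelse(td < -1, "normal", "ambiguous")))
  names(dec) <- channels
  record <- if (any(dec == "flipped")) "flipped"
            else if (any(dec == "ambiguous")) "ambiguous"
            else "normal"
  list(t_diff = td, channel_decision = dec, record = record)
}

#' SPK line-noise measure from a power spectrum
#'
#' Ratio of mean power in the mains band (mains +/- 0.5 Hz) to the median
#' power in the 45-55 Hz flank; z-scored across a cohort by the caller.
#' This is a declared substitute for an external tool's statistic of the
#' same role.
#'
#' @param freqs,psd PSD grid (Hz) and values; must cover the mains band.
#' @param mains mains frequency.
#' @export
spk_measure <- function(freqs, psd, mains = 60) {
  band <- freqs >= mains - 0.5 & freqs <= mains + 0.5
  flank <- freqs >= 45 & freqs <= 55
  if (!any(band) || !any(flank)) return(NA_real_)
  mean(psd[band]) / (stats::median(psd[flank]) + .Machine$double.eps)
}

#' Record-level exclusion report
#'
#' Applies: TST < 180 min; fewer than 10 retained epochs in any analysed
#' stage; SPK z-score > 5 on any channel (cohort mode); spectral power at
#' 1 Hz beyond +/- 4 SD or at 25 Hz above 4 SD on any channel (cohort
#' mode); ambiguous polarity. Cohort-referenced rules are skipped when the
#' corresponding z-scores are not supplied (single-record mode).
#'
#' @param tst_min total sleep time in minutes.
#' @param stage_epoch_counts named retained-epoch counts (N2, N3, R).
#' @param polarity record decision from [resolve_polarity()] (or NULL).
#' @param spk_z,p1hz_z,p25hz_z per-channel z-scores against the cohort
#'   (or NULL in single-record mode).
#' @return list(record_kept, reasons) with reasons drawn from
#'   {tst_lt_180, stage_epochs_lt_10, spk_gt_5sd, power_outlier_1hz,
#'   power_outlier_25hz, polarity_ambiguous}.
#' @export
apply_record_exclusions <- function(tst_min, stage_epoch_counts,
                                    polarity = NULL, spk_z = NULL,
                                    p1hz_z = NULL, p25hz_z = NULL) {
  reasons <- character(0)
  if (tst_min < 180) reasons <- c(reasons, "tst_lt_180")
  if (any(stage_epoch_counts < 10)) reasons <- c(reasons,
                                                 "stage_epochs_lt_10")
  if (!is.null(spk_z) && any(spk_z > 5, na.rm = TRUE))
    reasons <- c(reasons, "spk_gt_5sd")
  if (!is.null(p1hz_z) && any(abs(p1hz_z) > 4, na.rm = TRUE))
    reasons <- c(reasons, "power_outlier_1hz")
  if (!is.null(p25hz_z) && any(p25hz_z > 4, na.rm = TRUE))
    reasons <- c(reasons, "power_outlier_25hz")
  if (!is.null(polarity) && identical(polarity, "ambiguous"))
    reasons <- c(reasons, "polarity_ambiguous")
  list(record_kept = length(reasons) == 0, reasons = reasons)
}
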