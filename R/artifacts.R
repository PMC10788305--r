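# Epoch-level artifact rejection: absolute-amplitude, flat/clipped-signal
# and Hjorth-parameter outlier rules, applied per stage and channel, with
# the Hjorth passes run twice on survivors; channels losing more than half
# of their epochs in a stage are dropped for that stage.

#' Hjorth parameters of a signal segment
#'
#' Activity = variance (uV^2); mobility = sqrt(var(diff(x)) / var(x));
#' complexity = mobility(diff(x)) / mobility(x).
#'
#' @param x numeric vector (>= 3 finite samples).
#' @return list(activity, mobility, complexity, degenerate). A
#'   zero-variance input returns zeros with `degenerate = TRUE`.
#' @export
hjorth <- function(x) {
  stopifnot(length(x) >= 3, all(is.finite(x)))
  v0 <- stats::var(x)
  if (v0 <= 0) {
    return(list(activity = 0, mobility = 0, complexity = 0,
                degenerate = TRUE))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- stats::var(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  cmp <- if (v1 > 0) sqrt(v2 / v1) / mob else 0
  list(activity = v0, mobility = mob, complexity = cmp, degenerate = FALSE)
}

#' Default artifact-rejection thresholds
#'
#' @param max_amp_uv absolute-amplitude limit (uV).
#' @param flat_eps_uv per-sample first-difference magnitude below which a
#'   sample counts as flat (uV).
#' @param flat_clip_prop fraction of an epoch that may be flat or clipped.
#' @param hjorth_sd_all SD limit against the all-channel pooled mean.
#' @param hjorth_sd_chan SD limit against the same-channel mean.
#' @param hjorth_passes number of outlier-removal passes.
#' @param chan_drop_prop channel dropped when this fraction of its epochs
#'   is flagged.
#' @export
artifact_thresholds <- function(max_amp_uv = 200, flat_eps_uv = 0.05,
                                flat_clip_prop = 0.10, hjorth_sd_all = 3,
                                hjorth_sd_chan = 4, hjorth_passes = 2,
                                chan_drop_prop = 0.5) {
  as.list(environment())
}

.add_reason <- function(reasons, idx, code) {
  reasons[idx] <- ifelse(reasons[idx] == "", code,
                         paste(reasons[idx], code, sep = ","))
  reasons
}

#' Flag artifactual epochs
#'
#' Per stage and channel, epochs are flagged when (a) any |sample| exceeds
#' 200 uV; (b) the signal is flat (first difference below `flat_eps_uv`)
#' or clipped (at the channel's recorded extrema) for more than 10% of the
#' epoch; (c) any Hjorth parameter lies more than 3 SD from the pooled
#' all-channel mean for that stage; (d) more than 4 SD from the
#' same-channel epoch mean; (e) more than 4 SD from the pooled
#' all-channel, all-epoch mean. The Hjorth rules run twice, recomputing
#' the reference statistics on survivors. A channel is dropped for a stage
#' when more than half of its epochs are flagged.
#'
#' @param ep an `epoched_psg` from [epoch_psg()].
#' @param thresholds from [artifact_thresholds()].
#' @param stages stages subjected to rejection.
#' @return the `epoched_psg` with `qc$kept` / `qc$reasons` filled and a
#'   `hjorth` data.frame attached.
#' @export
reject_artifacts <- function(ep, thresholds = artifact_thresholds(),
                             stages = c("N2", "N3", "R")) {
  th <- thresholds
  qc <- ep$qc
  fs <- ep$recording$fs
  chs <- ep$recording$channels
  ch_extrema <- apply(ep$recording$data, 2, range)

  hj <- data.frame(epoch = qc$epoch, channel = qc$channel, stage = qc$stage,
                   activity = NA_real_, mobility = NA_real_,
                   complexity = NA_real_)

  for (stg in stages) {
    rows_stage <- which(qc$stage == stg)
    if (length(unique(qc$epoch[rows_stage])) < 2) {
      if (length(rows_stage))
        warning("fewer than 2 epochs in stage ", stg,
                "; rejection skipped for this stage")
      next
    }
    for (r in rows_stage) {
      x <- epoch_samples(ep, qc$epoch[r], qc$channel[r])
      ci <- match(qc$channel[r], chs)
      if (max(abs(x)) > th$max_amp_uv)
        qc$reasons <- .add_reason(qc$reasons, r, "amp_gt_200")
      flat <- mean(abs(diff(x)) < th$flat_eps_uv)
      clip <- mean(x <= ch_extrema[1, ci] + 1e-9 |
                     x >= ch_extrema[2, ci] - 1e-9)
      if (flat > th$flat_clip_prop)
        qc$reasons <- .add_reason(qc$reasons, r, "flat")
      if (clip > th$flat_clip_prop)
        qc$reasons <- .add_reason(qc$reasons, r, "clipped")
      h <- hjorth(x)
      hj$activity[r] <- h$activity
      hj$mobility[r] <- h$mobility
      hj$complexity[r] <- h$complexity
      if (h$degenerate)
        qc$reasons <- .add_reason(qc$reasons, r, "degenerate")
    }
    qc$kept[rows_stage] <- qc$reasons[rows_stage] == ""

    # Hjorth outlier passes on survivors, statistics recomputed each pass
    for (pass in seq_len(th$hjorth_passes)) {
      surv <- rows_stage[qc$kept[rows_stage]]
      if (length(surv) < 3) break
      newly <- logical(length(qc$kept))
      for (par in c("activity", "mobility", "complexity")) {
        v <- hj[[par]][surv]
        m_all <- mean(v); s_all <- stats::sd(v)
        if (is.finite(s_all) && s_all > 0) {
          z <- abs(v - m_all) / s_all
          bad3 <- surv[z > th$hjorth_sd_all]
          bad4 <- surv[z > th$hjorth_sd_chan]
          if (length(bad3))
            qc$reasons <- .add_reason(qc$reasons, bad3,
                                      paste0("hjorth3sd_", par, "_p", pass))
          if (length(bad4))
            qc$reasons <- .add_reason(qc$reasons, bad4,
                                      paste0("hjorth4sd_all_", par, "_p", pass))
          newly[bad3] <- TRUE
        }
        for (ch in chs) {
          sc <- surv[qc$channel[surv] == ch]
          if (length(sc) < 3) next
          vc <- hj[[par]][sc]
          m <- mean(vc); s <- stats::sd(vc)
          if (!is.finite(s) || s == 0) next
          bad <- sc[abs(vc - m) / s > th$hjorth_sd_chan]
          if (length(bad)) {
            qc$reasons <- .add_reason(qc$reasons, bad,
                                      paste0("hjorth4sd_chan_", par, "_p", pass))
            newly[bad] <- TRUE
          }
        }
      }
      qc$kept[rows_stage] <- qc$reasons[rows_stage] == ""
      if (!any(newly)) break
    }

    # channel drop: >50% of this stage's epochs flagged on a channel
    for (ch in chs) {
      rc <- rows_stage[qc$channel[rows_stage] == ch]
      if (length(rc) && mean(!qc$kept[rc]) > th$chan_drop_prop) {
        left <- rc[qc$kept[rc]]
        if (length(left))
          qc$reasons <- .add_reason(qc$reasons, left, "channel_dropped")
        qc$kept[rc] <- FALSE
      }
    }
  }
  ep$qc <- qc
  ep$hjorth <- hj
  ep
}
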