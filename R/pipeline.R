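# End-to-end single-record pipeline: preprocess -> epoch -> artifact
# rejection -> macro / spectral / spindle / SO / coupling features, with a
# deterministic flat feature vector and fixed-format writers so identical
# inputs reproduce identical output files.

#' Run the full analysis pipeline on one record
#'
#' @param rec a raw [psg_recording()].
#' @param hyp the matching [hypnogram()].
#' @param cfg list: `preprocess` (passed to [preprocess()]), `channels`
#'   (analysed channels), `spindle_channels` (named list slow/fast),
#'   `so_mode`, `so_channels`, `coupling` (list(class, channel)), `n_perm`,
#'   `seed` (permutation seed).
#' @return list(features = named numeric vector, macro, power, spindles,
#'   sos, coupling, epoched).
#' @export
run_record_pipeline <- function(rec, hyp, cfg = list()) {
  cfg <- utils::modifyList(list(
    preprocess = list(),
    spindle_channels = list(slow = "F3", fast = "C3"),
    so_mode = "relative", so_channels = "C3",
    coupling = list(class = "fast", channel = "C3"),
    n_perm = 1000, seed = 1,
    power_stages = "N2"), cfg)

  pre <- preprocess(rec, cfg$preprocess)
  ep <- epoch_psg(pre, hyp)
  ep <- reject_artifacts(ep)

  macro <- compute_macro(hyp)
  feats <- c(tst = macro$tst, sme = macro$sme, waso = macro$waso,
             sfi = macro$sfi, rem_latency = macro$rem_latency,
             n_cycles = macro$n_cycles, ti_nr_r = macro$ti_nr_r)
  names(macro$stage_minutes) <- paste0("min_", names(macro$stage_minutes))
  feats <- c(feats, macro$stage_minutes)

  pow <- power_summary(ep, stages = cfg$power_stages)
  if (nrow(pow)) {
    pv <- stats::setNames(
      pow$log_absolute,
      paste("logpow", pow$stage, pow$channel, pow$band, sep = "_"))
    rv <- stats::setNames(
      pow$relative,
      paste("relpow", pow$stage, pow$channel, pow$band, sep = "_"))
    feats <- c(feats, pv, rv)
  }

  spindles <- list()
  for (cls in names(cfg$spindle_channels)) {
    for (ch in cfg$spindle_channels[[cls]]) {
      res <- detect_spindle_events(ep, ch, cls)
      spindles[[paste(cls, ch, sep = "_")]] <- res
      s <- res$summary
      feats <- c(feats, stats::setNames(
        c(s$density, s$amplitude %||% NA_real_, s$duration %||% NA_real_,
          s$frequency %||% NA_real_, s$chirp %||% NA_real_),
        paste0("sp_", cls, "_", ch, "_",
               c("density", "amplitude", "duration", "frequency", "chirp"))))
    }
  }

  sos <- list()
  for (ch in cfg$so_channels) {
    res <- detect_so_events(ep, ch, cfg$so_mode)
    sos[[ch]] <- res
    s <- res$summary
    feats <- c(feats, stats::setNames(
      c(s$density, s$neg_peak %||% NA_real_, s$p2p %||% NA_real_,
        s$duration %||% NA_real_, s$slope %||% NA_real_),
      paste0("so_", ch, "_",
             c("density", "neg_peak", "p2p", "duration", "slope"))))
  }

  coup <- coupling_analysis(ep, cfg$coupling$channel, cfg$coupling$class,
                            cfg$so_mode, n_perm = cfg$n_perm,
                            seed = cfg$seed)
  feats <- c(feats, stats::setNames(
    c(coup$overlap_prop, coup$overlap_z, coup$mean_angle, coup$itpc,
      coup$itpc_z),
    paste0("coup_", cfg$coupling$class, "_", cfg$coupling$channel, "_",
           c("overlap", "overlap_z", "angle", "itpc", "itpc_z"))))

  list(features = feats, macro = macro, power = pow, spindles = spindles,
       sos = sos, coupling = coup, epoched = ep)
}

#' Write a feature vector with fixed formatting
#'
#' Values are serialized with \code{format(..., digits = 15)} so that
#' byte-identical inputs yield byte-identical files.
#'
#' @param features named numeric vector.
#' @param path output TSV.
#' @export
write_features_tsv <- function(features, path) {
  df <- data.frame(feature = names(features),
                   value = vapply(features, function(v)
                     format(v, digits = 15, scientific = FALSE),
                     character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
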