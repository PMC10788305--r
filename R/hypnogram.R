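# Hypnogram container, stage-file I/O, and the synthetic hypnogram
# generator. A hypnogram is the per-30-s-epoch sequence of scored sleep
# stages (W, N1, N2, N3, R) that anchors all stage-aware computation.

STAGES <- c("W", "N1", "N2", "N3", "R")
SLEEP_STAGES <- c("N1", "N2", "N3", "R")

# Alias table for stage labels found in the wild; keys are upper-cased.
.stage_aliases <- c(
  "W" = "W", "WAKE" = "W", "STAGE W" = "W", "0" = "W",
  "N1" = "N1", "S1" = "N1", "NREM1" = "N1", "STAGE 1" = "N1", "1" = "N1",
  "N2" = "N2", "S2" = "N2", "NREM2" = "N2", "STAGE 2" = "N2", "2" = "N2",
  "N3" = "N3", "S3" = "N3", "S4" = "N3", "NREM3" = "N3", "NREM4" = "N3",
  "SWS" = "N3", "STAGE 3" = "N3", "STAGE 4" = "N3", "3" = "N3", "4" = "N3",
  "R" = "R", "REM" = "R", "STAGE R" = "R", "5" = "R"
)

#' Construct a hypnogram
#'
#' @param stages character vector of per-epoch stage labels; labels are
#'   normalized through a documented alias table (e.g. "REM" -> "R",
#'   "S2" -> "N2").
#' @param epoch_s epoch duration in seconds (fixed at 30 in this package).
#' @return an object of class `hypnogram`: a character vector of stages in
#'   {W, N1, N2, N3, R} with attribute `epoch_s`.
#' @export
hypnogram <- function(stages, epoch_s = 30) {
  stopifnot(epoch_s == 30, length(stages) >= 1)
  key <- toupper(trimws(as.character(stages)))
  mapped <- .stage_aliases[key]
  if (anyNA(mapped)) {
    bad <- unique(key[is.na(mapped)])
    stop("unrecognized stage label(s): ", paste(bad, collapse = ", "))
  }
  structure(unname(mapped), epoch_s = epoch_s, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x, levels = STAGES))
  cat(sprintf("<hypnogram> %d epochs (%.1f min)\n",
              length(x), length(x) * attr(x, "epoch_s") / 60))
  print(tab)
  invisible(x)
}

n_epochs <- function(hyp) length(hyp)

#' Read a stage annotation file
#'
#' Tab-separated file with columns `epoch_index` (0-based), `onset_s` and
#' `stage`; stage labels go through the alias table of [hypnogram()].
#'
#' @param path path to the TSV file.
#' @return a `hypnogram`.
#' @export
read_stages <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("epoch_index", "stage") %in% names(df)))
  df <- df[order(df$epoch_index), ]
  if (!identical(as.integer(df$epoch_index), seq_len(nrow(df)) - 1L)) {
    stop("epoch_index must be a contiguous 0-based sequence")
  }
  hypnogram(df$stage)
}

#' Write a stage annotation file
#' @param hyp a `hypnogram`.
#' @param path output TSV path.
#' @export
write_stages <- function(hyp, path) {
  df <- data.frame(
    epoch_index = seq_along(hyp) - 1L,
    onset_s = (seq_along(hyp) - 1L) * attr(hyp, "epoch_s"),
    stage = as.character(hyp)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default hypnogram generator parameters
#'
#' Defaults describe a typical pediatric night: four ~90-min NREM/REM
#' cycles, ~20% REM, 10 min of wake before sleep onset, and ~2 brief
#' awakenings per hour.
#'
#' @param n_cycles number of NREM->R cycles.
#' @param cycle_minutes mean cycle length (min).
#' @param stage_dwell named mean bout lengths (min) for N1, N2, N3.
#' @param rem_fraction proportion of each cycle spent in R.
#' @param wake_onset_minutes wake before sleep onset (min).
#' @param waso_rate brief-awakening rate (events per hour of sleep).
#' @export
hypnogram_params <- function(n_cycles = 4, cycle_minutes = 90,
                             stage_dwell = c(N1 = 2, N2 = 12, N3 = 10),
                             rem_fraction = 0.2,
                             wake_onset_minutes = 10, waso_rate = 2) {
  p <- list(n_cycles = n_cycles, cycle_minutes = cycle_minutes,
            stage_dwell = stage_dwell, rem_fraction = rem_fraction,
            wake_onset_minutes = wake_onset_minutes, waso_rate = waso_rate)
  if (p$n_cycles < 1 || p$cycle_minutes <= 0 || any(p$stage_dwell <= 0) ||
      p$wake_onset_minutes < 0 || p$waso_rate < 0)
    stop("hypnogram parameters: durations must be positive")
  if (p$rem_fraction < 0 || p$rem_fraction > 1)
    stop("rem_fraction must be in [0, 1]")
  p
}

#' Simulate a stage sequence
#'
#' Builds `n_cycles` alternating NREM->R blocks. Each NREM block opens with
#' an N1 bout and then alternates N2/N3 bouts with geometrically distributed
#' lengths around the configured dwell means; brief awakenings (1-2 epochs)
#' are inserted at `waso_rate` events per hour of sleep, never in the first
#' sleep epoch. Deterministic given `params` and `seed`.
#'
#' @param params from [hypnogram_params()].
#' @param seed integer seed.
#' @return a `hypnogram`.
#' @export
simulate_hypnogram <- function(params = hypnogram_params(), seed = 1) {
  p <- do.call(hypnogram_params, params[names(params) %in%
                 names(formals(hypnogram_params))])
  with_seed(substream_seed(seed, 101L), {
    epw <- function(minutes) max(0L, as.integer(round(minutes * 2)))
    bout <- function(stage, mean_min) {
      n <- max(1L, stats::rgeom(1, 1 / max(1, mean_min * 2)) + 1L)
      rep(stage, n)
    }
    seqs <- rep("W", epw(p$wake_onset_minutes))
    nrem_ep <- epw(p$cycle_minutes * (1 - p$rem_fraction))
    rem_ep <- max(1L, epw(p$cycle_minutes * p$rem_fraction))
    for (cyc in seq_len(p$n_cycles)) {
      blk <- bout("N1", p$stage_dwell[["N1"]])
      nxt <- "N2"
      while (length(blk) < nrem_ep) {
        blk <- c(blk, bout(nxt, p$stage_dwell[[nxt]]))
        nxt <- if (nxt == "N2") "N3" else "N2"
      }
      blk <- blk[seq_len(nrem_ep)]
      seqs <- c(seqs, blk, rep("R", rem_ep))
    }
    # brief awakenings within sleep (never the first sleep epoch)
    sleep_idx <- which(seqs != "W")
    if (p$waso_rate > 0 && length(sleep_idx) > 2) {
      hours <- length(sleep_idx) / 120
      n_ev <- stats::rpois(1, p$waso_rate * hours)
      if (n_ev > 0) {
        pos <- sample(sleep_idx[-1], min(n_ev, length(sleep_idx) - 1L))
        for (i in pos) {
          len <- sample(1:2, 1)
          seqs[i:min(length(seqs), i + len - 1L)] <- "W"
        }
      }
    }
    hypnogram(seqs)
  })
}
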