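# Sleep macro-architecture: hypnogram-level summary metrics and NREM/REM
# cycle detection.
#
# Definitions (standard AASM-style conventions, config-switchable where the
# field uses several):
#   sleep onset  = first epoch scored N1/N2/N3/R
#   TST          = minutes scored N1/N2/N3/R
#   sleep period = onset .. last sleep epoch (inclusive)
#   SME          = TST / sleep-period minutes
#   WASO         = wake minutes within the sleep period
#   SFI          = transitions from N2/N3/R to W or N1, per hour of TST
#   R latency    = minutes from sleep onset to first R epoch
#   TI NR-R      = number of boundaries between maximal NREM segments and R
#                  segments (both directions), a raw count

#' Sleep macro-architecture metrics
#'
#' @param hyp a [hypnogram()].
#' @return a list of class `macro_metrics`: `tst` (min), `sme` (proportion),
#'   `waso` (min), `sfi` (events/h), `stage_minutes`, `stage_proportion`
#'   (over N1/N2/N3/R), `rem_latency` (min, `NA` if no R), `n_cycles`,
#'   `mean_cycle_minutes`, `ti_nr_r`.
#' @export
compute_macro <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  st <- as.character(hyp)
  ep_min <- attr(hyp, "epoch_s") / 60
  sleep <- st %in% SLEEP_STAGES
  if (!any(sleep)) stop("no sleep epochs in hypnogram")
  onset <- which(sleep)[1]
  last_sleep <- max(which(sleep))
  span <- st[onset:last_sleep]

  tst <- sum(sleep) * ep_min
  waso <- sum(span == "W") * ep_min
  sme <- tst / (length(span) * ep_min)

  stage_minutes <- vapply(c("N1", "N2", "N3", "R"),
                          function(s) sum(st == s) * ep_min, numeric(1))
  stage_proportion <- stage_minutes / tst

  # fragmentation: shifts from consolidated sleep (N2/N3/R) to W or N1
  frm <- span[-length(span)]
  to <- span[-1]
  n_frag <- sum(frm %in% c("N2", "N3", "R") & to %in% c("W", "N1"))
  sfi <- n_frag / (tst / 60)

  rem_latency <- if (any(st == "R")) {
    (which(st == "R")[1] - onset) * ep_min
  } else NA_real_

  # NREM<->R transition index on the sleep-period sequence, wake ignored
  sl <- span[span != "W"]
  is_r <- sl == "R"
  ti_nr_r <- sum(is_r[-1] != is_r[-length(is_r)])

  cyc <- detect_nrem_cycles(hyp)
  structure(list(
    tst = tst, sme = sme, waso = waso, sfi = sfi,
    stage_minutes = stage_minutes, stage_proportion = stage_proportion,
    rem_latency = rem_latency,
    n_cycles = nrow(cyc),
    mean_cycle_minutes = if (nrow(cyc)) mean(cyc$duration_min) else NA_real_,
    ti_nr_r = ti_nr_r
  ), class = "macro_metrics")
}

#' @export
print.macro_metrics <- function(x, ...) {
  cat(sprintf(
    "<macro_metrics> TST %.1f min | SME %.3f | WASO %.1f min | SFI %.2f/h\n",
    x$tst, x$sme, x$waso, x$sfi))
  cat(sprintf("  R latency %.1f min | cycles %d (mean %.1f min) | TI NR-R %d\n",
              x$rem_latency, x$n_cycles,
              x$mean_cycle_minutes %||% NA_real_, x$ti_nr_r))
  invisible(x)
}

#' Detect NREM/REM sleep cycles
#'
#' Adapted Feinberg & Floyd rules: a cycle is an NREM period of at least
#' `min_nrem_min` (15) minutes followed by an R period of at least
#' `min_rem_min` (5) minutes; the first R period is exempt from the 5-min
#' minimum; NREM interludes shorter than 15 min inside an R period do not
#' start a new cycle; a terminal NREM period of at least 15 min without a
#' following R period counts as a final cycle. Wake epochs interrupt
#' nothing.
#'
#' @param hyp a [hypnogram()].
#' @param min_nrem_min,min_rem_min rule minima in minutes.
#' @return data.frame with one row per cycle: `start_epoch`, `end_epoch`
#'   (1-based, inclusive), `nrem_min`, `rem_min`, `duration_min`.
#' @export
detect_nrem_cycles <- function(hyp, min_nrem_min = 15, min_rem_min = 5) {
  st <- as.character(hyp)
  ep_min <- attr(hyp, "epoch_s") / 60
  sleep_idx <- which(st %in% SLEEP_STAGES)
  out0 <- data.frame(start_epoch = integer(0), end_epoch = integer(0),
                     nrem_min = numeric(0), rem_min = numeric(0),
                     duration_min = numeric(0))
  if (!length(sleep_idx)) return(out0)
  r <- rle(st[sleep_idx[1]:max(sleep_idx)])
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  off <- sleep_idx[1] - 1L

  cycles <- list()
  cur <- list(start = NA_integer_, nrem = 0, r = 0, end = NA_integer_)
  phase <- "NREM"
  pending <- 0; pending_start <- NA_integer_

  close_cycle <- function(end_epoch) {
    cycles[[length(cycles) + 1L]] <<- data.frame(
      start_epoch = cur$start + off, end_epoch = end_epoch + off,
      nrem_min = cur$nrem, rem_min = cur$r,
      duration_min = (end_epoch - cur$start + 1L) * ep_min)
  }

  for (k in seq_along(r$values)) {
    stg <- r$values[k]
    mins <- r$lengths[k] * ep_min
    if (stg == "W") next
    if (stg %in% c("N1", "N2", "N3")) {
      if (phase == "NREM") {
        if (is.na(cur$start)) cur$start <- seg_start[k]
        cur$nrem <- cur$nrem + mins
      } else {
        if (is.na(pending_start)) pending_start <- seg_start[k]
        pending <- pending + mins
        if (pending >= min_nrem_min) {
          if (cur$r >= min_rem_min || length(cycles) == 0L) {
            close_cycle(pending_start - 1L)
            cur <- list(start = pending_start, nrem = pending, r = 0,
                        end = NA_integer_)
          } else {
            # R period too short to end the cycle: keep accumulating NREM
            cur$nrem <- cur$nrem + pending
          }
          phase <- "NREM"
          pending <- 0; pending_start <- NA_integer_
        }
      }
    } else { # R
      if (phase == "NREM") {
        phase <- "REM"
        cur$r <- cur$r + mins
      } else {
        cur$nrem <- cur$nrem + pending   # short interlude stays in-cycle
        pending <- 0; pending_start <- NA_integer_
        cur$r <- cur$r + mins
      }
    }
  }
  last_ep <- seg_end[length(seg_end)]
  if (phase == "REM") {
    close_cycle(last_ep)
  } else if (!is.na(cur$start) &&
             (cur$r > 0 || cur$nrem >= min_nrem_min)) {
    close_cycle(last_ep)
  }
  if (!length(cycles)) return(out0)
  do.call(rbind, cycles)
}
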