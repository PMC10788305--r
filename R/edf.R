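# Minimal EDF (European Data Format) reader/writer for continuous
# multichannel signals: 16-bit samples, one-second data records, physical
# units enforced to uV on read. Covers the subset of EDF that PSG exports
# in this pipeline use; EDF+ annotation signals are not handled.

.pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n)
}

.num8 <- function(x) .pad(formatC(x, format = "g", digits = 7), 8)

#' Write a recording to an EDF file
#'
#' 16-bit EDF with 1-s data records and physical dimension uV. Quantization
#' uses the per-channel physical range, so a write/read round trip agrees
#' with the source to within (range / 65535).
#'
#' @param rec a [psg_recording()].
#' @param path output file.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "psg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- length(rec$channels)
  n_rec <- floor(nrow(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  dat <- rec$data[seq_len(n_rec * fs), , drop = FALSE]

  pmin_ <- apply(dat, 2, min)
  pmax_ <- apply(dat, 2, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(.pad("0", 8))
  wr(.pad("X X X X", 80))
  wr(.pad("Startdate X X X X", 80))
  wr("01.01.00"); wr("00.00.00")
  wr(.num8(256 * (ns + 1)))
  wr(.pad("", 44))
  wr(.num8(n_rec)); wr(.num8(1)); wr(.pad(ns, 4))
  for (s in rec$channels) wr(.pad(paste("EEG", s), 16))
  for (s in rec$channels) wr(.pad("", 80))
  for (s in rec$channels) wr(.pad("uV", 8))
  for (v in pmin_) wr(.num8(v))
  for (v in pmax_) wr(.num8(v))
  for (s in rec$channels) wr(.num8(dmin))
  for (s in rec$channels) wr(.num8(dmax))
  for (s in rec$channels) wr(.pad("", 80))
  for (s in rec$channels) wr(.num8(fs))
  for (s in rec$channels) wr(.pad("", 32))

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ci in seq_len(ns)) {
      d <- round((dat[idx, ci] - pmin_[ci]) * scale[ci] + dmin)
      d <- pmin(pmax(d, dmin), dmax)
      writeBin(as.integer(d), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file.
#' @return a [psg_recording()] in uV (mV and V physical dimensions are
#'   converted).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes (recomputed)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  vapply(seq_len(ns), function(i) rd(80), character(1))
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(80), character(1))
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(32), character(1))

  if (length(unique(spr / rec_dur)) != 1)
    stop("EDF reader supports a single common sampling rate only")
  fs <- spr[1] / rec_dur

  out <- matrix(0, n_rec * spr[1], ns)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ci in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[ci], size = 2, signed = TRUE,
                   endian = "little")
      out[((r - 1) * spr[ci] + 1):(r * spr[ci]), ci] <-
        (d - dmin[ci]) * scale[ci] + pmin_[ci]
    }
  }
  # enforce uV
  unit_mult <- vapply(dims, function(d) {
    switch(tolower(d), "uv" = 1, "µv" = 1, "mv" = 1000, "v" = 1e6, 1)
  }, numeric(1))
  out <- sweep(out, 2, unit_mult, `*`)
  labels <- normalize_channel_labels(labels)
  psg_recording(out, fs, labels, reference = "as recorded")
}

# Strip modality prefixes / reference suffixes: "EEG F3-M2" -> "F3".
normalize_channel_labels <- function(labels) {
  l <- toupper(trimws(labels))
  l <- sub("^EEG[ _]*", "", l)
  l <- sub("[-_ ](M1|M2|A1|A2|REF)$", "", l)
  l
}

#' Read a PSG recording with its stage annotations
#'
#' @param edf_path EDF file with channels F3, F4, C3, C4, O1, O2 (mastoids
#'   M1/M2 optional for re-referencing).
#' @param stage_path stage TSV (see [read_stages()]).
#' @return list(recording, hypnogram). The recording is truncated to whole
#'   30-s epochs; a stage/record duration mismatch above 30 s is an error.
#' @export
read_psg <- function(edf_path, stage_path) {
  rec <- read_edf(edf_path)
  hyp <- read_stages(stage_path)
  need <- EEG_CHANNELS
  if (!all(need %in% rec$channels))
    stop("missing required channel(s) ",
         paste(setdiff(need, rec$channels), collapse = ", "),
         "; found: ", paste(rec$channels, collapse = ", "))
  rec_s <- nrow(rec$data) / rec$fs
  hyp_s <- length(hyp) * 30
  if (abs(rec_s - hyp_s) > 30)
    stop(sprintf("stage file covers %.0f s but record is %.0f s",
                 hyp_s, rec_s))
  n_ep <- min(floor(rec_s / 30), length(hyp))
  rec$data <- rec$data[seq_len(n_ep * 30 * rec$fs), , drop = FALSE]
  list(recording = rec, hypnogram = hypnogram(hyp[seq_len(n_ep)]))
}
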