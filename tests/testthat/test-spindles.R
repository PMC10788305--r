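# Envelope construction helper for threshold-boundary tests: a baseline
# of 1 with rectangular bumps, long enough that the envelope mean stays
# ~1 and the 2x / 4.5x thresholds sit near 2 and 4.5.
bump_envelope <- function(fs, total_s = 600, bumps) {
  env <- rep(1, total_s * fs)
  for (b in bumps) {
    i0 <- round(b$at * fs) + 1
    env[i0:(i0 + round(b$dur * fs) - 1)] <- b$level
  }
  env
}

test_that("wavelet envelope is flat for a pure tone and zero for silence", {
  fs <- 128
  x <- sin(2 * pi * 15 * (0:(fs * 60 - 1)) / fs)
  env <- cwt_envelope(x, fs, 15)
  core <- env[(2 * fs):(58 * fs)]
  expect_lt(stats::sd(core) / mean(core), 0.05)
  expect_equal(mean(core), 1, tolerance = 0.05)  # unit-amplitude scaling
  expect_equal(max(cwt_envelope(rep(0, fs * 30), fs, 15)), 0)
  expect_error(cwt_envelope(rnorm(50), fs, 15), "short")
})

test_that("envelope peak localizes an isolated burst center", {
  fs <- 128
  w <- spindle_waveform(fs, 1, 11, 0, 10)
  x <- c(rep(0, 10 * fs), w, rep(0, 10 * fs))
  env <- cwt_envelope(x, fs, 11)
  expect_lt(abs((which.max(env) - 1) / fs - (10 + 0.5)), 0.05)
})

test_that("core-duration rule: 4.5x for 300 ms required, 250 ms rejected", {
  fs <- 128
  env_no <- bump_envelope(fs, bumps = list(
    list(at = 100, dur = 0.8, level = 3),
    list(at = 100.2, dur = 0.25, level = 6)))
  expect_equal(nrow(detect_spindles(env_no, fs)), 0)
  env_yes <- bump_envelope(fs, bumps = list(
    list(at = 100, dur = 0.8, level = 3),
    list(at = 100.2, dur = 0.35, level = 6)))
  expect_equal(nrow(detect_spindles(env_yes, fs)), 1)
})

test_that("envelope-duration rule: 2x for 500 ms required", {
  fs <- 128
  env_short <- bump_envelope(fs, bumps = list(
    list(at = 100, dur = 0.45, level = 6)))
  expect_equal(nrow(detect_spindles(env_short, fs)), 0)
  env_ok <- bump_envelope(fs, bumps = list(
    list(at = 100, dur = 0.55, level = 6)))
  expect_equal(nrow(detect_spindles(env_ok, fs)), 1)
})

test_that("intervals over 3 s are rejected", {
  fs <- 128
  env <- bump_envelope(fs, bumps = list(list(at = 100, dur = 3.3, level = 6)))
  expect_equal(nrow(detect_spindles(env, fs)), 0)
})

test_that("merge rule: within 500 ms merged unless the result exceeds 3 s", {
  fs <- 128
  env_merge <- bump_envelope(fs, bumps = list(
    list(at = 100, dur = 0.8, level = 6),
    list(at = 101.2, dur = 0.8, level = 6)))  # gap 0.4, span 2.0
  got <- detect_spindles(env_merge, fs)
  expect_equal(nrow(got), 1)
  expect_equal(got$duration, 2.0, tolerance = 0.05)
  env_two <- bump_envelope(fs, bumps = list(
    list(at = 100, dur = 1.4, level = 6),
    list(at = 101.8, dur = 1.4, level = 6)))  # gap 0.4, span 3.2
  expect_equal(nrow(detect_spindles(env_two, fs)), 2)
  env_far <- bump_envelope(fs, bumps = list(
    list(at = 100, dur = 0.8, level = 6),
    list(at = 101.4, dur = 0.8, level = 6)))  # gap 0.6 -> no merge
  expect_equal(nrow(detect_spindles(env_far, fs)), 2)
})

test_that("detection is invariant to amplitude scale", {
  fs <- 128
  env <- bump_envelope(fs, bumps = list(
    list(at = 50, dur = 0.8, level = 6),
    list(at = 200, dur = 1.2, level = 5)))
  a <- detect_spindles(env, fs)
  b <- detect_spindles(env * 7.3, fs)
  expect_equal(a$start_s, b$start_s)
  expect_equal(a$stop_s, b$stop_s)
  expect_error(detect_spindles(rep(0, fs * 60), fs), "degenerate")
})

test_that("detector achieves high recall and precision on implants", {
  hyp <- n2_hypnogram(10)
  stats <- t(vapply(1:5, function(s) {
    dens <- c(0.5, 1.5, 3)[(s %% 3) + 1]
    spec <- event_spec("fast_spindle", density = dens, amplitude = 15,
                       channels = "C3")
    cr <- clean_record(hyp, list(spec), seed = 600 + s)
    res <- detect_spindle_events(cr$ep, "C3", "fast")
    m <- match_events(res$events$peak_rec,
                      retained_truth(cr$ep, cr$out$truth$events, "C3"))
    c(m, est = res$summary$density, dens = dens)
  }, numeric(5)))
  # recall and precision pooled over the record set (counts per record
  # are small at the low end of the density grid)
  expect_gte(sum(stats[, "tp"]) / sum(stats[, "n_truth"]), 0.9)
  expect_gte(sum(stats[, "tp"]) / sum(stats[, "n_det"]), 0.9)
  expect_lte(mean(abs(stats[, "est"] - stats[, "dens"]) / stats[, "dens"]),
             0.15)
})

test_that("slow and fast detectors separate 11 and 15 Hz implants", {
  hyp <- n2_hypnogram(10)
  spec_s <- event_spec("slow_spindle", density = 2, amplitude = 15,
                       channels = "C3")
  cr <- clean_record(hyp, list(spec_s), seed = 71)
  slow <- detect_spindle_events(cr$ep, "C3", "slow")
  fast <- detect_spindle_events(cr$ep, "C3", "fast")
  expect_gte(nrow(slow$events), 0.85 * nrow(cr$out$truth$events))
  expect_lte(nrow(fast$events), 0.05 * nrow(cr$out$truth$events) + 0.5)
})

test_that("QC passes clean bursts, fails broadband artifacts, ties pass", {
  fs <- 128
  set.seed(2)
  x <- rnorm(fs * 600, 0, 3)
  w <- spindle_waveform(fs, 1, 15, 0, 25)
  x[(100 * fs):(100 * fs + length(w) - 1)] <- x[(100 * fs):(100 * fs + length(w) - 1)] + w
  # broadband 100 uV artifact
  x[(200 * fs):(201 * fs)] <- x[(200 * fs):(201 * fs)] + 100
  ev <- data.frame(start_s = c(100, 200), stop_s = c(101, 201),
                   peak_s = c(100.5, 200.5), amplitude = c(25, 100),
                   duration = c(1, 1))
  q <- spindle_qc(ev, x, fs, 15)
  expect_true(q$qc_pass[1])
  expect_false(q$qc_pass[2])
})

test_that("chirp is recovered from frequency ramps and null for none", {
  hyp <- n2_hypnogram(15)
  ch_ramp <- vapply(1:3, function(s) {
    spec <- event_spec("fast_spindle", density = 2, amplitude = 45,
                       duration = 0.8, ramp = -1, channels = "C3")
    cr <- clean_record(hyp, list(spec), seed = 800 + s)
    detect_spindle_events(cr$ep, "C3", "fast")$summary$chirp
  }, numeric(1))
  expect_lt(abs(mean(ch_ramp) - (-0.5)), 0.12)
  ch0 <- vapply(1:3, function(s) {
    spec <- event_spec("fast_spindle", density = 2, amplitude = 45,
                       duration = 0.8, ramp = 0, channels = "C3")
    cr <- clean_record(hyp, list(spec), seed = 900 + s)
    detect_spindle_events(cr$ep, "C3", "fast")$summary$chirp
  }, numeric(1))
  expect_lt(abs(mean(ch0)), 0.08)
})

test_that("density arithmetic uses retained minutes", {
  ev <- data.frame(start_s = 1:6, stop_s = 1:6 + 0.5, peak_s = 1:6 + 0.2,
                   amplitude = 10, duration = 0.5, qc_pass = TRUE,
                   qc_reason = "")
  res <- spindle_metrics(ev, rnorm(128 * 60), 128, 15, retained_minutes = 3)
  expect_equal(res$summary$density, 2)
})
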