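test_that("Hjorth parameters match closed forms", {
  # sinusoid mobility: 2 sin(pi f / fs)
  x <- sin(2 * pi * 10 * (0:5999) / 200)
  h <- hjorth(x)
  expect_equal(h$mobility, 2 * sin(pi * 10 / 200), tolerance = 0.01)
  # white-noise activity ~ variance 1
  set.seed(1)
  hw <- hjorth(rnorm(6000))
  expect_equal(hw$activity, 1, tolerance = 0.1)
  # constant signal -> degenerate zeros
  hc <- hjorth(rep(3, 100))
  expect_true(hc$degenerate)
  expect_equal(c(hc$activity, hc$mobility, hc$complexity), c(0, 0, 0))
})

test_that("amplitude, flat and clipped epochs are flagged with reasons", {
  hyp <- n2_hypnogram(10)
  out <- synthesize_record(subject_profile("s", 8), hyp, list(),
                           fs = 128, seed = 4)
  spec <- data.frame(channel = c("C3", "C3"), epoch = c(7, 12),
                     kind = c("high_amplitude", "flatline"))
  inj <- inject_artifacts(out$recording, spec, seed = 1)
  ep <- reject_artifacts(epoch_psg(inj$recording, hyp))
  q <- ep$qc
  r7 <- q[q$epoch == 7 & q$channel == "C3", ]
  expect_false(r7$kept)
  expect_match(r7$reasons, "amp_gt_200")
  r12 <- q[q$epoch == 12 & q$channel == "C3", ]
  expect_false(r12$kept)
  expect_match(r12$reasons, "flat")
})

test_that("a fully flat channel is dropped via the 50% rule", {
  hyp <- n2_hypnogram(6)
  out <- synthesize_record(subject_profile("s", 8), hyp, list(),
                           fs = 128, seed = 5)
  rec <- out$recording
  rec$data[, "O2"] <- 0
  ep <- reject_artifacts(epoch_psg(rec, hyp))
  expect_true(all(!ep$qc$kept[ep$qc$channel == "O2"]))
  expect_true(mean(ep$qc$kept[ep$qc$channel == "C3"]) > 0.5)
})

test_that("rejection keeps most clean epochs and is idempotent", {
  n_flagged <- vapply(1:8, function(s) {
    hyp <- n2_hypnogram(10)
    out <- synthesize_record(subject_profile("s", 8), hyp, list(),
                             fs = 128, seed = 300 + s)
    ep <- reject_artifacts(epoch_psg(out$recording, hyp))
    mean(!ep$qc$kept)
  }, numeric(1))
  expect_lt(mean(n_flagged), 0.08)

  # idempotence: re-running on the cleaned object flags nothing new
  hyp <- n2_hypnogram(10)
  out <- synthesize_record(subject_profile("s", 8), hyp, list(),
                           fs = 128, seed = 311)
  ep1 <- reject_artifacts(epoch_psg(out$recording, hyp))
  ep2 <- reject_artifacts(ep1)
  expect_true(all(ep1$qc$kept >= ep2$qc$kept | ep1$qc$kept == ep2$qc$kept))
})

test_that("masks are monotone in the amplitude threshold", {
  hyp <- n2_hypnogram(8)
  out <- synthesize_record(subject_profile("s", 8), hyp, list(),
                           fs = 128, seed = 6)
  spec <- data.frame(channel = "C3", epoch = 4, kind = "high_amplitude")
  inj <- inject_artifacts(out$recording, spec, seed = 1)
  ep_hi <- reject_artifacts(epoch_psg(inj$recording, hyp),
                            artifact_thresholds(max_amp_uv = 300))
  ep_lo <- reject_artifacts(epoch_psg(inj$recording, hyp),
                            artifact_thresholds(max_amp_uv = 150))
  amp_hi <- grepl("amp", ep_hi$qc$reasons)
  amp_lo <- grepl("amp", ep_lo$qc$reasons)
  expect_true(all(amp_lo >= amp_hi))
})

test_that("polarity statistic is odd and thresholds act as documented", {
  hyp <- n2_hypnogram(12)
  spec <- event_spec("so", density = 5, amplitude = 80, duration = 0.6,
                     pos_duration = 0.5)
  out <- synthesize_record(subject_profile("s", 8), hyp, list(spec),
                           fs = 128, seed = 6)
  ep <- reject_artifacts(epoch_psg(out$recording, hyp))
  pol <- resolve_polarity(ep)
  expect_equal(pol$record, "normal")
  neg <- out$recording; neg$data <- -neg$data
  epn <- reject_artifacts(epoch_psg(neg, hyp))
  poln <- resolve_polarity(epn)
  expect_equal(poln$record, "flipped")
  expect_equal(poln$t_diff, -pol$t_diff, tolerance = 1e-6)
})

test_that("symmetric noise is classified polarity-ambiguous", {
  hyp <- n2_hypnogram(12)
  amb <- vapply(1:12, function(s) {
    out <- synthesize_record(subject_profile("s", 8), hyp, list(),
                             fs = 128, seed = 500 + s)
    ep <- reject_artifacts(epoch_psg(out$recording, hyp))
    resolve_polarity(ep)$record == "ambiguous"
  }, logical(1))
  expect_gte(mean(amb), 0.9)
  # insufficient N2 -> ambiguous by default
  hyp_r <- hypnogram(rep("R", 12))
  out <- synthesize_record(subject_profile("s", 8), hyp_r, list(),
                           fs = 128, seed = 1)
  ep <- reject_artifacts(epoch_psg(out$recording, hyp_r))
  expect_equal(resolve_polarity(ep)$record, "ambiguous")
})

test_that("record exclusion rules populate the documented reasons", {
  r <- apply_record_exclusions(179, c(N2 = 100, N3 = 50, R = 30))
  expect_false(r$record_kept)
  expect_equal(r$reasons, "tst_lt_180")
  r2 <- apply_record_exclusions(400, c(N2 = 100, N3 = 50, R = 9))
  expect_true("stage_epochs_lt_10" %in% r2$reasons)
  r3 <- apply_record_exclusions(400, c(N2 = 100, N3 = 50, R = 30),
                                polarity = "ambiguous",
                                spk_z = c(C3 = 6), p1hz_z = c(C3 = -5),
                                p25hz_z = c(C3 = 2))
  expect_setequal(r3$reasons, c("spk_gt_5sd", "power_outlier_1hz",
                                "polarity_ambiguous"))
  r4 <- apply_record_exclusions(400, c(N2 = 100, N3 = 50, R = 30))
  expect_true(r4$record_kept)
  expect_length(r4$reasons, 0)
})

test_that("SPK measure isolates mains-band excess", {
  freqs <- seq(0, 64, 0.25)
  psd <- rep(1, length(freqs))
  expect_equal(spk_measure(freqs, psd), 1, tolerance = 1e-9)
  psd[freqs >= 59.5 & freqs <= 60.5] <- 50
  expect_gt(spk_measure(freqs, psd), 10)
})
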