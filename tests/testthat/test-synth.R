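test_that("event counts follow density bookkeeping exactly", {
  hyp <- n2_hypnogram(20)  # 20 min N2
  spec <- event_spec("fast_spindle", density = 2, amplitude = 20,
                     channels = "C3")
  out <- synthesize_record(subject_profile("s", 8), hyp, list(spec),
                           fs = 128, seed = 3)
  expect_equal(nrow(out$truth$events), 40)  # 2/min * 20 min
  expect_true(all(out$truth$events$stop_s <= length(hyp) * 30))
  expect_true(all(out$truth$events$start_s >= 0))
})

test_that("same seed reproduces signals and logs bit-identically", {
  hyp <- n2_hypnogram(5)
  spec <- event_spec("so", density = 4, amplitude = 70)
  a <- synthesize_record(subject_profile("s", 8), hyp, list(spec),
                         fs = 128, seed = 11)
  b <- synthesize_record(subject_profile("s", 8), hyp, list(spec),
                         fs = 128, seed = 11)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("noise-free record equals the analytic event waveform", {
  hyp <- n2_hypnogram(5)
  spec <- event_spec("fast_spindle", density = 0.2, amplitude = 20,
                     duration = 1, channels = "C3")
  out <- synthesize_record(subject_profile("s", 8), hyp, list(spec),
                           noise = silent_noise(), fs = 128, seed = 2)
  ev <- out$truth$events
  expect_equal(nrow(ev), 1)
  i0 <- round(ev$start_s * 128) + 1
  w <- spindle_waveform(128, 1, 15, 0, 20)
  expect_equal(out$recording$data[i0:(i0 + length(w) - 1), "C3"], w)
  # all other samples zero
  expect_equal(sum(abs(out$recording$data[, "C3"])) ,
               sum(abs(w)), tolerance = 1e-10)
  expect_equal(sum(abs(out$recording$data[, "F3"])), 0)
})

test_that("coupled spindle peaks follow the requested von Mises phase", {
  hyp <- n2_hypnogram(20)
  specs <- list(
    event_spec("so", density = 6, amplitude = 80, duration = 0.6,
               pos_duration = 0.5, channels = "C3"),
    event_spec("fast_spindle", density = 2.5, amplitude = 25,
               coupling_phase = 0, coupling_kappa = 50, channels = "C3"))
  out <- synthesize_record(subject_profile("s", 8), hyp, specs,
                           fs = 128, seed = 5)
  ph <- out$truth$events$phase_at_peak
  ph <- ph[!is.na(ph)]
  expect_gte(length(ph), 40)
  d <- circ_mean_deg(ph)
  expect_lt(min(d, 360 - d), 5)
})

test_that("same-class events never overlap and are fully logged", {
  hyp <- n2_hypnogram(15)
  spec <- event_spec("so", density = 8, amplitude = 70, duration = 0.6,
                     pos_duration = 0.5, channels = "C3")
  out <- synthesize_record(subject_profile("s", 8), hyp, list(spec),
                           fs = 128, seed = 8)
  ev <- out$truth$events[order(out$truth$events$start_s), ]
  expect_equal(nrow(ev), 8 * 15)
  expect_true(all(diff(ev$start_s) >= 0))
  expect_true(all(ev$start_s[-1] >= ev$stop_s[-nrow(ev)] - 1e-9))
})

test_that("infeasible density errors with the stage named", {
  hyp <- n2_hypnogram(2)
  spec <- event_spec("so", density = 60, amplitude = 70, channels = "C3")
  expect_error(
    synthesize_record(subject_profile("s", 8), hyp, list(spec),
                      fs = 128, seed = 1),
    "N2")
})

test_that("spindle waveform implements the linear frequency ramp", {
  fs <- 256
  w <- spindle_waveform(fs, 1, 15, ramp = -1, amplitude = 1)
  # analytic IF of the noise-free waveform spans 15.5 -> 14.5
  ph <- Arg(analytic_signal(w))
  dph <- (diff(ph) + pi) %% (2 * pi) - pi
  inst <- dph * fs / (2 * pi)
  core <- inst[round(0.25 * fs):round(0.75 * fs)]
  expect_equal(mean(core[seq_len(length(core) / 2)]) -
                 mean(core[(length(core) / 2 + 1):length(core)]),
               0.25, tolerance = 0.05)
  expect_equal(max(abs(w)), 1, tolerance = 0.01)
})

test_that("artifact injection applies only to logged targets", {
  hyp <- n2_hypnogram(10)
  out <- synthesize_record(subject_profile("s", 8), hyp, list(),
                           fs = 128, seed = 4)
  # empty spec -> identity
  same <- inject_artifacts(out$recording, NULL)
  expect_identical(same$recording$data, out$recording$data)
  spec <- data.frame(channel = c("C3", "F3"), epoch = c(7, NA),
                     kind = c("line60", "polarity_flip"))
  inj <- inject_artifacts(out$recording, spec, seed = 1)
  d <- inj$recording$data - out$recording$data
  ep_n <- 30 * 128
  expect_true(all(d[-(((7 - 1) * ep_n + 1):(7 * ep_n)), "C3"] == 0))
  expect_true(any(d[((7 - 1) * ep_n + 1):(7 * ep_n), "C3"] != 0))
  expect_equal(inj$recording$data[, "F3"], -out$recording$data[, "F3"])
  expect_error(inject_artifacts(out$recording,
                                data.frame(channel = "C3", epoch = 1,
                                           kind = "nope")),
               "unknown artifact kind")
})

test_that("sigma power rises monotonically with implanted spindle density", {
  hyp <- n2_hypnogram(10)
  dens <- c(0.5, 1, 1.5, 2, 3)
  pow <- vapply(dens, function(d) {
    spec <- event_spec("fast_spindle", density = d, amplitude = 25,
                       channels = "C3")
    out <- synthesize_record(subject_profile("s", 8), hyp, list(spec),
                             fs = 128, seed = 42)
    psd <- welch_psd(out$recording$data[, "C3"], 128)
    bp <- band_powers(psd)
    bp$absolute[bp$band == "sigma"]
  }, numeric(1))
  expect_equal(cor(dens, pow, method = "spearman"), 1)
})
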