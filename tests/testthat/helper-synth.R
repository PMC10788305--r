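# Shared fixtures: small synthetic records built in code at test time.

# An all-N2 hypnogram of `minutes` minutes.
n2_hypnogram <- function(minutes = 10) hypnogram(rep("N2", minutes * 2))

# Noise-free generator settings (events only).
silent_noise <- function() {
  list(alpha = c(W = 1, N1 = 1, N2 = 1, N3 = 1, R = 1),
       rms = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0),
       sigma_rms = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0),
       stage_osc = FALSE)
}

# Synthesize, epoch and clean a record in one step.
clean_record <- function(hyp, specs, fs = 128, seed = 1,
                         noise = default_noise_params()) {
  out <- synthesize_record(subject_profile("t1", 8), hyp, specs,
                           noise = noise, fs = fs, seed = seed)
  ep <- reject_artifacts(epoch_psg(out$recording, hyp))
  list(out = out, ep = ep)
}

# Match detected peaks to ground-truth peaks within a tolerance (s);
# returns c(tp, n_detected, n_truth).
match_events <- function(detected_peaks, truth_peaks, tol = 0.25) {
  tp <- sum(vapply(detected_peaks, function(p)
    any(abs(truth_peaks - p) < tol), logical(1)))
  c(tp = tp, n_det = length(detected_peaks), n_truth = length(truth_peaks))
}

# Ground-truth peaks lying in epochs retained for (stage, channel) -- the
# events the detector can actually see.
retained_truth <- function(ep, truth, ch, stage = "N2") {
  kept <- ep$qc$epoch[ep$qc$kept & ep$qc$channel == ch &
                        ep$qc$stage == stage]
  tr <- truth[truth$channel == ch, ]
  tr$peak_s[(floor(tr$peak_s / 30) + 1) %in% kept]
}
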