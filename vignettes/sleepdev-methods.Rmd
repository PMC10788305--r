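---
title: "Pediatric sleep-EEG architecture and brain age: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pediatric sleep-EEG architecture and brain age: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`sleepdev` implements a complete analysis chain for pediatric overnight
EEG (polysomnography): preprocessing and artifact rejection, sleep
macro-architecture, Welch band power, slow/fast sleep-spindle detection,
slow-oscillation (SO) detection, permutation-calibrated SO–spindle
coupling, and a linear brain-age model whose gap (predicted minus
chronological age) flags atypical development. Because clinical PSG
repositories are access-controlled, the package ships a ground-truthed
synthetic PSG generator; every stage of the pipeline is validated against
implanted events and analytic oracles rather than against private data.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions taken where
the methodology was genuinely open — in the spirit of a methods section
a maintainer can audit.

# The synthetic generator

A record is the sum of three parts, per channel (F3, F4, C3, C4, O1, O2,
in µV):

1. **Aperiodic background**: Gaussian noise spectrally shaped to
   $1/f^\alpha$, with stage-dependent exponent and RMS (defaults: N2
   $\alpha = 1.5$, 15 µV; N3 $\alpha = 2.0$, 25 µV; R $\alpha = 1.2$,
   12 µV). The exponents are conventions for sleep EEG, not fitted
   claims.
2. **A sigma-activity floor**: band-limited (11–16 Hz) noise at 2 µV RMS
   in N2. Real NREM sleep shows continuous sigma-band activity outside
   discrete spindles; a pure power law is unrealistically quiet there,
   which would make relative spindle thresholds degenerate (a detector
   normalised by the mean sigma envelope would fire on noise ripples)
   and would let implanted events dominate epoch variance and be
   rejected as Hjorth outliers. Mild deterministic stage colourings
   (posterior alpha in W, slow delta in N3, theta in R) are added at
   small amplitudes.
3. **Implanted events**, every one logged in the ground truth:
   - *Spindles*: Hann-windowed sinusoids. The instantaneous frequency
     ramps linearly by `ramp` Hz across the event, symmetric about the
     carrier, which matches the definition of chirp as the
     frequency difference between the last and first halves
     (measured chirp of such an event is `ramp/2`).
   - *SOs*: biphasic raised cosines — a negative half-wave (0.3–1.5 s)
     followed by a positive half-wave (≤ 1 s) — so detectability under
     the zero-crossing detector's temporal criteria is controllable.
   - *Coupling*: when a spindle spec has concentration
     $\kappa > 0$, each spindle peak is placed at an SO phase drawn from
     von Mises($\mu$, $\kappa$), mapped piecewise-linearly onto the SO's
     two half-waves (phase convention: 0° at the SO positive peak,
     180° at the negative peak, increasing in time). $\kappa = 0$ places
     spindles uniformly in the stage, independent of SOs.

Events of the same class never overlap; placement rejection-samples
within eligible stage runs. All randomness flows from one integer seed
through fixed integer-mix substreams (subject → event class → channel →
event), so regenerating one subject of a cohort is stable.

**What the generator does not emulate**: K-complexes, scored arousals,
EMG/EOG, respiratory channels, topographic gradients beyond per-channel
event lists, infant EEG, and non-stationarities within a stage run.
Passing tests therefore demonstrate correctness of the algorithms under
the stated statistical structure, not clinical performance on real
recordings.

## Age trajectories

The cohort-level defaults encode reported pediatric N2 trends: fast
spindle density rising 0.9 → 1.9 events/min from age 4 to 16; slow
spindle density following an inverted U peaking near age 10; SO
amplitude declining steeply (negative peak 85 → 40 µV over the same
span, peak-to-peak ≈ 1.6×) while the true SO event rate rises (default
4 → 8 events/min). Subjects deviate from the curves through a shared
latent "developmental age" (age + Gaussian noise, default SD 1 year) —
the quantity a brain-age model can at best recover — plus independent
per-feature measurement noise. A delayed clinical group is constructed
by evaluating every curve at age + `trajectory_offset` (e.g. −2 years).

# Preprocessing

Channels are re-referenced to the contralateral mastoid (F3/C3/O1 − M2,
F4/C4/O2 − M1) when mastoids are present; rates above 200 Hz are
polyphase-resampled to 200 Hz and lower rates kept; mains interference
is removed by spectrum interpolation (the amplitude spectrum inside
mains ± 1 Hz and its first harmonic is replaced by log-linear
interpolation of the flanking amplitudes, phase preserved); finally a
zero-phase 0.5–35 Hz band-pass is applied.

All "band-pass" filters in the package are cascades of an order-4
Butterworth high-pass and an order-4 low-pass, each run
forward–backward. A direct-form order-4 band-pass with a 0.5 Hz edge at
sleep-EEG sampling rates is numerically fragile; the cascade is stable
and exactly zero-phase, which the coupling analysis (phase at spindle
peak) depends on.

## Artifact rejection

Per stage and channel, 30-s epochs are flagged when (a) any sample
exceeds 200 µV; (b) the signal is flat (first difference < 0.05 µV) or
clipped (at the channel's recorded extrema) for more than 10% of the
epoch; or (c–e) any Hjorth parameter (activity = variance, mobility,
complexity) lies more than 3 SD from the pooled all-channel mean, or
more than 4 SD from the same-channel or pooled means, for that stage.
The Hjorth rules run twice, recomputing reference statistics on
survivors; a channel is dropped for a stage when more than half of its
epochs are flagged. "Mean of all channels" is interpreted
stage-specifically (pooling stages would mix N3 delta variance into N2
references). On clean synthetic records these rules flag well under 8%
of epochs.

## Polarity and record exclusions

SO and coupling analyses are polarity-sensitive. The polarity statistic
`T_DIFF` is defined here as the standardized mean (mean/SD, a
Cohen's-d-like effect size) of per-epoch skewness of the 0.5–4 Hz N2
signal. Physiologic SOs give dominant negative deflections, hence
negative skewness and `T_DIFF < -1` (normal); a flipped record gives
`T_DIFF > 1` (flip the channel set); the closed interval [−1, 1] marks
the record ambiguous. An effect size rather than a t statistic is used
deliberately: a t statistic is unit-normal under the symmetric-noise
null whatever the epoch count, so fixed ±1 cutoffs could never classify
most noise records as ambiguous, while the effect size concentrates
within the cutoffs under the null and exceeds them with real SOs.

Record-level exclusions: total sleep time < 180 min; fewer than 10
retained epochs in an analysed stage; and, in cohort mode, a
line-noise score (mean power in mains ± 0.5 Hz over median 45–55 Hz
power, z-scored across the cohort, excluded above 5 SD) and spectral
power outliers at 1 Hz (±4 SD) or 25 Hz (upper 4 SD). Single-record
runs skip the cohort-referenced rules.

# Macro-architecture

Sleep onset is the first epoch scored N1/N2/N3/R; TST is total sleep
minutes; SME is TST over the onset-to-last-sleep span; WASO is wake
within that span; the fragmentation index counts transitions from
consolidated sleep (N2/N3/R) to W or N1 per hour of TST. NREM/REM
cycles follow adapted Feinberg–Floyd rules: an NREM period of ≥ 15 min
followed by an R period of ≥ 5 min (first R exempt); NREM interludes
< 15 min stay inside the current R period; a terminal NREM period of
≥ 15 min without R counts as a final cycle. These conventions are
config-switchable (`detect_nrem_cycles(min_nrem_min, min_rem_min)`),
since the field uses several variants.

# Spectral power

Welch's method on 30-s epochs: 4-s segments (0.25 Hz resolution),
Tukey (50%) taper, 50% overlap; segment periodograms averaged within
epochs, then across retained epochs. The normalization contract is
one-sided density in µV²/Hz with taper power compensated, so
rectangular band integration recovers signal variance (Parseval) —
this is what the spectral tests assert. Bands: slow 0.5–1, delta 1–4,
theta 4–8, alpha 8–12, sigma 12–15, beta 15–30, total 0.5–35 Hz;
band membership is half-open [lo, hi), boundaries belonging to the
higher band. Absolute power is natural-log transformed for analysis;
non-positive values are masked rather than propagated as −Inf.

# Spindle detection

Slow (11 Hz) and fast (15 Hz) spindles are detected on the smoothed
(0.1 s moving average) magnitude of a 7-cycle complex Morlet transform
of the concatenated retained N2 signal, per channel. The wavelet is
scaled so a unit sinusoid at the center frequency yields envelope ≈ 1,
making amplitudes interpretable in µV. A candidate is a maximal run
above 2× the envelope mean lasting ≥ 0.5 s that contains a sub-run
above 4.5× the mean lasting ≥ 0.3 s (the core is required to lie
inside the envelope run); candidates over 3 s are rejected; candidates
closer than 0.5 s are merged unless the merged span would exceed 3 s.
Both thresholds are relative, so detection is invariant to gain.

The QC step compares the event window's relative increase in delta,
theta and beta activity against the spindle band (fc ± 2 Hz); the event
fails when the largest non-spindle ratio strictly exceeds the
spindle-band ratio. Band activity is measured as the variance of the
zero-phase band-filtered signal evaluated in the window: a short-window
periodogram would suffer severe leakage at sub-second windows (a slow
drift masquerades as delta power), which was observed to reject half of
clean implanted spindles before this choice was made.

## Frequency and chirp

Per event, the unwrapped Hilbert phase of the high-pass-filtered signal
(cutoff fc − 7 Hz; event padded 0.5 s) is fit with a quadratic in time,
weighted by squared envelope over samples above 30% of the event's
envelope peak. The fitted first-order coefficient gives the frequency
at the event center; the second-order coefficient gives the frequency
slope, and chirp = slope × duration / 2 (the frequency difference
between the event's halves; negative = deceleration).

Two estimator choices deserve emphasis:

- *No narrow band-pass.* Filtering a sub-second enveloped chirp through
  a tight band (e.g. fc ± 2 Hz) genuinely compresses its frequency
  excursion — on a clean 1-s event with a −1 Hz ramp, a
  median-of-halves Hilbert estimator after fc ± 2 filtering recovers
  −0.35 instead of −0.50. The quadratic phase fit after high-pass-only
  filtering is exact (−0.50) on the clean event.
- *Known attenuation in noise.* On full synthetic records the recovered
  chirp is attenuated by ~10–15%: the detected interval is slightly
  shorter than the true event support, and the coherent sigma-band
  background floor biases the fitted slope toward zero (verified by
  component-wise simulation: the 1/f background alone is unbiased; the
  sigma floor alone shrinks the mean from −0.49 to −0.45). This is a
  property any phase-based chirp estimator shares on real EEG, and it
  is quantified rather than hidden: at typical pediatric morphology
  (0.8 s, 45 µV events) the pooled recovered chirp for implanted
  −1 Hz ramps is ≈ −0.44, within the −0.5 ± 0.1 validation band, and
  constant-frequency implants recover |chirp| < 0.05.

# SO detection

Zero crossings of the 0.5–4 Hz filtered signal define candidates
anchored at a down-going crossing: negative half-wave 0.3–1.5 s,
positive half-wave ≤ 1 s. Amplitude criteria come in two modes:
relative (default; negative peak and peak-to-peak must strictly exceed
2× their respective means over all temporal-criteria-passing
candidates — a two-pass design so thresholds do not depend on the
selection) and absolute (negative peak < −40 µV and peak-to-peak
> 75 µV, strict). Relative-mode means are computed separately for the
two quantities; event duration spans both half-waves; slope is
peak-to-peak amplitude over the negative-to-positive peak interval.

The two modes can disagree about age trends, and the package's cohort
defaults reproduce the phenomenon: with the true SO rate rising and
amplitudes declining through the absolute cutoffs, relative-mode
density rises with age while absolute-mode density falls. Exploration
of the generative space showed the 2×-mean relative threshold is
strongly self-scaling — it passes essentially all implanted SOs and
admits almost no background half-waves under any purely proportional
amplitude decline — so a rising relative-mode density requires a true
event-rate increase, which is also the reading most consistent with
reported developmental SO trajectories.

# Coupling

A spindle overlaps an SO iff its envelope peak falls inside the SO's
[down-crossing, end-crossing) interval. Reported per channel and
class: gross overlap proportion; the circular mean SO phase at
overlapping spindle peaks (filter–Hilbert phase, 0° = SO positive
peak); and the inter-trial phase clustering (ITPC), the magnitude of
the mean unit phasor. Overlap and ITPC are z-transformed against
permutation nulls (default 10,000 permutations):

- *Overlap null*: all spindle peaks are circularly shifted by one
  uniform offset over the stage timeline per permutation — preserving
  the numbers of spindles and SOs and the spindle spacing structure.
- *ITPC null*: each overlapping spindle is reassigned a uniform time
  inside an SO interval chosen with probability proportional to its
  length (uniform over the union of SO time) — preserving counts and
  the gross overlap. Length-weighted interval choice matters: uniform
  choice over intervals would mis-weight long SOs and mis-calibrate
  the null when durations vary.

With independent spindles the z-scores are approximately standard
normal (null mean within ±0.2, |z| > 1.96 in 2.5–8% of runs);
$\kappa = 5$ coupling with ≥ 50 overlapping spindles is detected
(itpc z > 1.96) in ≥ 95% of runs, and the preferred phase is recovered
within a few degrees at $\kappa = 20$ when SO half-waves are short
enough (≈ 0.6 + 0.5 s) that the 0.5 Hz high-pass does not reshape the
waveform around its positive peak.

# The brain-age model

The statistical layer operates on a subject × feature table. Features
are cleaned of outliers (per feature, > 3 SD from the mean of currently
unmasked values, two rounds). Per-feature age associations are linear
models `feature ~ age + sex + race` with the unadjusted Pearson r, a
quadratic comparison (ΔAIC/ΔBIC = quadratic − linear; negative favours
curvature), and Benjamini–Hochberg FDR across the tested set.

The model itself is ordinary least squares of chronological age on
z-scored features plus covariates, in the classic R modelling idiom: a
fitting function returning a classed object with `print`, `summary`,
`coef` and `predict` methods. Features are first pruned greedily in
fixed catalogue order (drop when |r| > 0.9 with a retained feature);
z-scoring parameters are frozen from the training sample and reused
verbatim for every prediction set; missing values are imputed at the
training mean. Performance is estimated by 10-fold cross-validation
(per-fold R² and MAE, mean ± SD across folds) and on held-out data by
r, MAE and ME (= mean gap). Under the generator's construction
(latent developmental noise SD 1 year, 40 informative features) the
held-out MAE approaches the normal-residual oracle
$\sigma\sqrt{2/\pi} \approx 0.80$ years, and a −2-year delayed group
shows ME ≈ −2.

Group analyses resample the non-delayed pool into 70/30
training/held-out splits (default 100 rounds; the clinical groups stay
fixed), refit per round, and report mean/min/max MAE and ME per group
plus the median p of two-sample t-tests of the group's gaps against the
held-out gaps. The median-p convention is anticonservative (it ignores
the dependence between rounds sharing subjects) and is treated as a
summary, not a calibrated test; the type-I behaviour of the whole
procedure is exercised separately in the tests. The age-bin similarity
profile z-scores all features by the comparison sample, bins the
comparison sample (2-year bins centered 3–13, 4-year bins centered
16–80, bins with < 10 subjects dropped) and reports the mean absolute
difference between bin means and group means — its minimum marks the
age the group most resembles.

# Problem sizes and determinism

The validation suite runs on deliberately small problems — 10–20-minute
single-stage records at 128 Hz, cohorts of a few hundred subjects,
1,000–2,000 permutations where the analysis default is 10,000 — chosen
so the full suite completes in minutes while keeping every Monte-Carlo
margin comfortable; the same code paths scale to full nights at 200 Hz
unchanged. Every stochastic step takes an explicit integer seed, and
identical configuration plus seed reproduces every output byte for
byte (`write_features_tsv` serializes at fixed precision for exactly
this reason).

# Known limitations

- The generator's spindles and SOs are stereotyped waveforms; real
  events vary in envelope shape and symmetry, and detector performance
  on real data will be lower than on implants.
- Chirp estimates are attenuated ~10–15% by background sigma activity
  (quantified above); between-subject comparisons are unaffected but
  absolute chirp values are conservative.
- The SPK line-noise score and the T_DIFF polarity statistic are
  declared substitutes for external-tool outputs of the same role;
  their thresholds follow the published values but the statistics
  themselves are this package's definitions.
- Aperiodic/oscillatory decomposition, individualized sigma peaks,
  sleep staging and arousal scoring are out of scope.
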