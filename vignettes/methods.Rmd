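---
title: "Methods: attentional focus to complex soundscapes in EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attentional focus to complex soundscapes in EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

`attnscape` analyzes how the *attentional focus* of a listener changes the
neural processing of a complex, workplace-like soundscape. The paradigm it
supports is a within-subject design with two conditions that share an
identical soundscape — a continuous background bed plus five discrete
stimulus streams (an alarm, a quiet beep, two irrelevant monitor-like
sounds, and spoken instructions) — and differ only in which sound is the
target: under a **narrow** focus the listener attends a loud alarm from a
fixed direction, under a **wide** focus a quiet beep embedded in any of the
streams, which forces monitoring of the whole scene.

Two complementary EEG measures quantify the difference:

* **Event-related potentials (ERPs)** to the discrete stimuli, focusing on
  the frontocentral N1 (~100 ms, negative) and the parietal P3 (~300–400 ms,
  positive, target-related). Target status should raise the P3; the N1 to
  irrelevant sounds indexes how much of the scene is processed.
* A **temporal response function (TRF)** — a linear kernel mapping the
  soundscape's amplitude envelope to the continuous EEG, estimated by ridge
  regression over time lags — quantifies tracking of the scene *as a
  whole*, with target responses excised so the contrast is not driven by
  the targets themselves.

# The analysis pipeline

## Preprocessing (fixed stage order)

`preprocess_recording()` applies, in this order: Hamming-window FIR
filtering (high-pass passband edge 0.1 Hz, low-pass 30 Hz), polyphase
resampling to 250 Hz, spherical-spline interpolation of bad channels,
deterministic ocular-artifact removal, and linked-mastoid (TP9/TP10)
re-referencing. Stimulus onsets are shifted by the constant 19 ms latency
between the sound marker and the physical sound (`correct_marker_delay()`);
key presses are captured in real time and are not shifted.

**FIR design.** The transition bandwidth is
`max(0.25 × edge, min(2 Hz, edge))` and the −6 dB cutoff sits half a
transition band *into the stopband* (below the edge for the high-pass,
above it for the low-pass), so the passband edge keeps approximately unity
gain; the order is `ceiling(3.3 / normalized TBW)` rounded to even. The
high-pass is built by spectral inversion of the complementary low-pass
renormalized to unit DC gain, which puts an exact null at DC. Filters are
applied in one zero-phase pass (odd-reflection edge padding, FFT
convolution, group-delay compensation). Inside `preprocess_recording()` the
band kernel and the resampler's anti-alias kernel are convolved into a
single kernel before the one pass; this is algebraically identical to
applying the stages in sequence and is covered by a unit test comparing
both paths.

**Bad channels.** The screening step that is visual in practice is
automated: a channel is flagged when its total range is below a flat-line
tolerance or when the robust z-score of its log robust variance (squared
MAD) exceeds a threshold (default 4). MAD-based variance is used so sparse
transients (blinks) do not masquerade as broken channels, and the spread
estimate has a floor of 0.2 log-units so a homogeneous montage is not
flagged on sampling noise alone. Flags should be unioned across the two
conditions. Flagged channels are replaced by order-4 spherical-spline
interpolation (50-term Legendre expansion, 1e-5 diagonal regularization),
which reproduces constant fields exactly.

**Ocular artifacts.** Component decomposition (ICA with automatic
labeling) is stochastic and externally defined, so the pipeline ships a
deterministic regression fallback and a `hook` point through which an
external decomposition with the same `recording -> recording` contract can
be substituted. The fallback detects blinks on the 50 ms-smoothed mean of
the most frontal channels (robust z > 6), separates overlapping blinks by
matching pursuit with a 350 ms squared-sine template, and removes them by
joint least squares with one template column per blink and channel.
Blink-free data pass through unchanged.

**Epoch rejection.** For each epoch and channel the within-epoch amplitude
SD is computed; the *local* statistic standardizes it across epochs per
channel and the *global* statistic standardizes the channel-mean SD across
epochs. An epoch is rejected when either |z| exceeds the threshold (2 SD
for continuous cleaning, 3 SD for ERP epochs). The statistic is
scale-equivariant, and zero-variance cells yield z = 0 so identical epochs
are never rejected. The procedure this implements names the thresholds in SDs but not the
statistic; this is the simplest reading consistent with "global or local".

## ERP analysis

Epochs span −200..800 ms on a half-open sample grid (the onset sample at
t = 0 is included; 1 s at 250 Hz is exactly 250 samples) with −200..0 ms
baseline subtraction per trial and channel. Only non-overlapping
presentations enter ERP analyses, and for targets only hit trials (a hit is
a press within 3 s after the target; each press is consumed by at most one
target, earliest first; the window is open at the onset and closed at
onset + 3 s).

Component windows are individualized: an unweighted average of the two
condition means (so unbalanced trial counts cannot bias the peak) over the
component's channel set — Fz, FC1, FC2, Cz, C3, C4 for the N1; Pz, P3, P4,
CPz, CP1, CP2 for the P3 — is searched for the signed extremum (negative
50–150 ms for N1; positive 300–400 ms for P3). The window is the peak
±25 ms (N1) or ±50 ms (P3), clipped to the epoch. Design choices that the
procedure leaves open were resolved as: the extremum is the signed extreme
value, not a local-peak detector; a range-edge extremum is accepted with a
logged warning; ties resolve to the earliest latency. Trial-level mean
amplitudes over the individual window feed the mixed model.

## TRF analysis

The envelope is the modulus of the analytic (Hilbert-transformed) audio,
low-pass filtered at 30 Hz with the same FIR design, resampled to 250 Hz,
and clipped at zero. Alarm and beep responses are excised — the half-open
interval [onset, onset + 1 s) for every alarm and beep in both conditions,
overlapping zones merged — leaving segments of unequal length; segments are
then dropped shortest-first from whichever condition is longer until the
total-length difference is below 60 s. EEG is multiplied by the
normalization constant 0.0313 (treated as an opaque configured constant of
the standard recipe).

The forward model solves, per channel, `(X'X + λI) w = X'y`, where X has
one column per lag (−200..800 ms; 251 lags at 250 Hz), zero-padded at
segment edges, plus an unpenalized intercept; covariance is accumulated
across segments so data are never concatenated across excision gaps, and
λ = 0.1. Segments shorter than the lag span are skipped with a warning
(they cannot support the full lag structure). The fitted weights are
baseline corrected by subtracting the per-channel mean over lags
−100..0 ms; the correction is idempotent.

**Window detection.** Condition-averaged participant TRFs are tested
against zero at every (lag, channel) in 0–450 ms with one-sample t
statistics, family-wise corrected by the permutation distribution of the
maximum |t| under random participant sign flips (2000 permutations by
default, seeded). Because a sign flip leaves squared values unchanged, only
the permuted means need recomputing, which keeps the permutation loop a
single matrix product. Corrected p-values are `(1 + #{max-t ≥ |t|}) /
(n_perm + 1)`; a lag is significant when *any* channel reaches p ≤ α (the
union rule is the only reading that yields single time intervals), and
contiguous significant lags merge into windows.

**Quantification.** The global field power (GFP) is the *population* SD
across channels per lag (the standard definition of the
measure; sample-SD conventions differ only by a constant factor). Within each significant window, each
participant's condition-averaged GFP peak is located and the FWHM window —
the maximal contiguous lag run at or above half the peak, clipped to the
significant window — defines the individual window; each condition's own
GFP is averaged over it. A fixed group-window variant (the same significant
window for everyone) supports the sensitivity re-analysis, as does
re-running after excluding participants; with no exclusions and individual
windows the rerun is bit-identical to the base analysis.

## Statistics

With the condition coded narrow = 0, wide = 1:

* Trial-level ERP amplitudes:
  `AMP ~ condition + (condition | participant) + (1 | channel)`, REML,
  Satterthwaite degrees of freedom for two-tailed p-values and CIs. When
  the channel variance estimates to zero (singular fit) the term is
  dropped, the refit reported, and the event recorded in `singular_terms`.
* Window GFP: `GFP ~ condition + (1 | participant)`, likewise.
* Intraclass correlations from intercept-only models; each grouping's share
  of the total variance, proportions summing to one and invariant to
  rescaling the response.
* Hit rate: binomial GLMM with logit link,
  `hit ~ condition + (condition | participant)` (Laplace), condition
  contrast by Wald chi-square. Complete separation falls back to adjusted
  empirical logits, flagged as not converged.
* Reaction times (hits only): inverse-Gaussian GLMM with the *inverse*
  link — the family is fixed by the positive skew of RTs, and among the
  family's links the inverse one is most consistent with reported
  response-scale means near `1 / intercept`; condition means are reported
  on the response scale. If the random slope cannot be fit the model falls
  back to a random intercept and says so.
* Per-participant scores (workload, completed layers, followed
  instructions): `score ~ condition + (1 | participant)`; on balanced data
  the estimate equals the mean paired difference exactly, which is used as
  a closed-form check.

Where Satterthwaite df are unavailable (GLMMs) the Wald normal
approximation is used and flagged in `df_method` — never silently.

# The synthetic-data generator

`simulate_study()` draws complete two-condition studies with known ground
truth ([ground_truth()]), used for parameter-recovery validation:

* **Schedule**: each of the five categories is presented `n_per_category`
  times in random interleaved order with inter-onset intervals uniform in
  3–6 s (unstated by the design; the density matches ~48 presentations per
  category in a ~18 min run). The beep can be embedded into (co-onset
  with) another stimulus; overlapped events are re-added until each
  category has exactly `n_per_category` non-overlapping presentations.
* **Audio**: deterministic stimulus waveforms (long loud two-harmonic
  alarm; short quiet beep; noise burst and sweep; speech-like AM complex;
  all carriers below 900 Hz so low test rates remain valid) mixed over a
  continuous 1/f background bed, spatialized by constant-power stereo gain
  panning of the azimuth (−135°, −90°, 0°, +45°; panning preserves the
  envelope semantics that the analysis actually uses, head-related impulse-response
  convolution would add only spatial cues that the analysis ignores). Stimulus levels sit a few dB above
  the bed so the scene envelope has a realistic dynamic range (z-scores of
  roughly ±4); an early version with a near-silent bed produced 40-SD
  envelope spikes, whose excision-boundary misattribution dominated the
  fitted TRF at long lags — a useful reminder that the excision step
  assumes a bounded envelope dynamic range.
* **EEG** (24 channels, 500 Hz): per event, Gaussian-lobe ERP kernels — N1
  (100 ms, 20–40 ms SD) and P2 (200 ms) through a frontocentral Gaussian
  topography; P3 (350 ms, 60 ms SD) through a parietal one, its amplitude
  raised by `p3_target_gain` (default 4 µV, a typical task-relevance
  effect for this component) when the event is the condition's target. The
  whole-soundscape response convolves the z-scored envelope with a
  three-lobe lag kernel (~60/150/320 ms, −/+/−) whose late lobe is scaled
  by `wide_gain` (default 1.5) under the wide condition; lobe gains are
  integrated (µV·s) and sized so the envelope-driven response is a 10–15%
  variance share against the default 1/f noise (8 µV per channel, spectral
  exponent 1, 20% white floor). Stereotyped 120 µV blinks occur at 0.15 Hz
  at frontal sites. Participant-level variation: log-normal amplitude
  scale (SD 0.2), ±10 ms latency jitter, hit-logit jitter (SD 0.5) and RT
  scale jitter.
* **Behavior**: targets are hit with condition probabilities 0.962
  (narrow) and 0.68 (wide); hit RTs are inverse-Gaussian (means 0.814 s
  and 0.81 s, shape 3 s), truncated to the 3 s response window — the RT
  model family matches the analysis model so the GLMM is well-specified
  for recovery tests. Scores (workload 60.6 vs 71.45, etc.) are Gaussian
  with participant random intercepts.
* The event files store *marker* times, 19 ms before the simulated sound,
  so the pipeline's delay correction is exercised rather than bypassed.

**What the generator does not emulate**: realistic speech or game play,
eye movements/EMG beyond stereotyped blinks, non-stationary noise,
electrode drift or impedance changes, spatially correlated background EEG,
and motor potentials from the key presses. Passing recovery tests therefore
demonstrate that the *analysis machinery* is correct and well-calibrated
under the stated noise model — not that real recordings will be as
well-behaved.

# Validation experiments and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`, recomputed by
`scripts/acceptance.R`) runs:

1. **Oracle equivalence**: the accumulated-covariance ridge solver at λ = 0
   against an independently constructed dense lagged matrix and direct
   normal-equation solve on one 30 s white-envelope segment (relative error
   below 1e-8).
2. **Kernel recovery**: 20 seeds of a 240 s envelope-only simulation at the
   default SNR with a broadband probe envelope; the topography-weighted
   recovered kernel must correlate r ≥ 0.9 with the injected kernel over
   lags 0–450 ms in at least 18 seeds. A broadband probe is used because
   kernel recovery is a property of the estimator, and the 30 Hz-limited
   soundscape envelope leaves the high-lag-frequency directions of the
   design matrix identified only through the ridge (the full-soundscape
   path is validated separately by the end-to-end experiment).
3. **Permutation validity**: 1000 null simulations (15 participants × 251
   lags × 8 channels, 500 sign-flip permutations) with the family-wise
   false-positive rate required to land in [0.03, 0.07] at α = 0.05.
4. **ERP window machinery**: on noiseless data the detected P3 peak equals
   the injected kernel peak exactly, and window means of a linear ramp
   match the closed form to one sample's tolerance.
5. **End-to-end recovery**: 10 study-level seeds, each a full pipeline run
   on a 20-participant study at reduced size (12 non-overlapping
   presentations per category, 1 kHz audio, 400 permutations). At least
   9 of 10 seeds must recover all four injected contrasts with the correct
   sign at p < 0.05: negative alarm-P3 and positive beep-P3 condition
   effects, a positive wide-minus-narrow GFP contrast in the significant
   window overlapping the late lag range the most, and a negative wide
   hit-rate logit. The sizes are the package's validation sizes: 20
   participants matches the full design; presentations and permutation
   counts are reduced so a replicate completes in under two minutes on one
   core. The presentation count matters non-linearly for the TRF contrast:
   the GFP of a noisier TRF acquires a larger positive floor which both
   dilutes the late-lobe contrast and adds between-participant noise, and
   the pilot power analysis put the knee of that curve below ~10
   presentations per category — hence 12, the smallest size at which all
   four contrasts are comfortably powered.
6. **CI calibration**: 1000 replicates of a well-specified random-intercept
   design; the 95% CI for the condition effect must cover the truth at
   95% ± 3% (Satterthwaite-based intervals).

# Known limitations

* The ocular fallback removes stereotyped blinks only; real recordings
  with rich ocular/muscle artifact profiles should substitute an external
  decomposition via the hook.
* λ = 0.1 with the standard scaling leaves the TRF lightly regularized;
  with short recordings the per-lag weights are noisy and the GFP acquires
  a positive noise floor. The group-level window test and the
  window-averaged GFP contrasts remain calibrated (experiments 3 and 5),
  but single-participant TRFs from a few minutes of data should be read
  with that floor in mind.
* Bad-channel flagging is a conservative automated stand-in for visual
  screening; thresholds are configurable and every flag is logged.
* The equalization tolerance (60 s) is the full-scale value; at strongly
  reduced study sizes it rarely binds.
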