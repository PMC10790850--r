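# attnscape

EEG analysis of the **auditory attentional focus** in complex,
workplace-like soundscapes — for cognitive-neuroscience researchers who
study how much of an acoustic scene a listener processes while doing a
demanding task, and who want a tested, reproducible pipeline rather than a
pile of analysis scripts.

The supported paradigm is a within-subject design: the same soundscape (a
continuous background bed plus five discrete streams — alarm, quiet beep,
two irrelevant sounds, spoken instructions) is heard under two
instructions. Under a **narrow** focus the target is a loud alarm from a
fixed direction; under a **wide** focus it is a quiet beep embedded in any
stream, which forces monitoring of the whole scene.

Two measures quantify the difference:

* **Event-related potentials.** Stimulus-locked epochs (−200..800 ms,
  −200..0 ms baseline) give trial-level mean amplitudes over
  *individualized* component windows — the N1 (negative extremum in
  50–150 ms ± 25 ms over Fz, FC1, FC2, Cz, C3, C4) and the P3 (positive
  extremum in 300–400 ms ± 50 ms over Pz, P3, P4, CPz, CP1, CP2) —
  analyzed with

  `AMP ~ condition + (condition | participant) + (1 | channel)`

  (REML, Satterthwaite df; the channel term is dropped, and reported, when
  its variance estimates to zero).

* **Temporal response functions.** The forward model
  `EEG(t) = Σ_τ w(τ) · env(t − τ) + b` is estimated by ridge regression
  over lags −200..800 ms (λ = 0.1, EEG scaled by 0.0313, target responses
  excised, condition lengths equalized). Condition-independent significant
  lag windows come from a max-|t| sign-flip permutation test over
  0–450 ms; within each window the global field power (population SD
  across channels) is averaged over each participant's FWHM window around
  the GFP peak and analyzed with `GFP ~ condition + (1 | participant)`.
  Intraclass correlations, a binomial hit-rate GLMM, an inverse-Gaussian
  reaction-time GLMM and paired score models complete the statistics.

A fully parameterized synthetic-study generator (schedules, stereo audio,
EEG with known ERP/TRF kernels and 1/f noise, behavior) provides ground
truth for end-to-end parameter-recovery validation.

## Worked example

Simulate a small study and analyze it end to end:

```r
library(attnscape)

study <- simulate_study(12, n_per_category = 8, audio_srate_hz = 1000,
                        seed = 42)
cfg <- pipeline_config(n_permutations = 500, rng_seed = 42)
report <- analyze_study(study, cfg)
subset(report$results, term == "cond",
       select = c(model, estimate, se, p, n_obs))
```

```
                model  estimate       se        p n_obs
2            alarm_p3 -3.480361 0.586477 6.54e-05  1134
4             beep_p3  1.688789 1.161654 1.73e-01   900
6       irrelevant_n1  0.315088 0.791668 6.98e-01  2274
8          trf_gfp_w1  0.059787 0.022577 2.27e-02    24
10         trf_gfp_w2  0.000534 0.000954 5.87e-01    24
12         trf_gfp_w3 -0.000227 0.001072 8.34e-01    24
14         trf_gfp_w4  0.001863 0.000710 2.37e-02    24
16         trf_gfp_w5  0.003025 0.000801 3.07e-03    24
18           hit_rate -3.085295 0.697964 9.85e-06   253
20      reaction_time  0.079197 0.127272 5.34e-01   191
22 score_instructions -1.331671 1.003296 2.11e-01    24
24       score_layers -1.754275 1.140591 1.52e-01    24
26     score_workload 14.338381 4.625110 1.01e-02    24
```

Reading the key rows of this (deliberately small) example: the alarm's P3
drops by ~3.5 µV when it stops being the target (`alarm_p3` is the wide −
narrow contrast in µV; the beep's +1.7 µV gain trends the right way but 12
participants × 8 presentations is underpowered for it); envelope tracking
in the late significant lag window, `trf_gfp_w5` = lags 0.252–0.392 s from
`report$trf_stage$windows`, is stronger under the wide focus (+0.0030 in
scaled GFP units, p = 0.003); the embedded beep is missed far more often
than the alarm (`hit_rate`, −3.1 on the logit scale) at indistinguishable
reaction times, and perceived workload rises by ~14 points. All of these
are the generator's injected effects, recovered from raw simulated
recordings; `report$erp_icc` holds the variance decompositions and
`write_report()` writes the TSV/JSON bundle.

The same pipeline runs from the shell on an on-disk study
(`inst/scripts/attnscape simulate|all`), reading EEG as a TSV matrix with a
JSON sidecar, events and key presses as TSV, and audio as WAV.

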