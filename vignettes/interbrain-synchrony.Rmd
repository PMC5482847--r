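---
title: "Separating speech-mediated from direct interbrain synchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating speech-mediated from direct interbrain synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The analysis problem

When two people converse, the listener's cortical oscillations entrain to the
quasi-rhythms of the speaker's voice — the amplitude envelope of connected
speech carries phrasal structure at delta rates (~1–3 Hz) and syllables at
theta rates (~4–8 Hz) — and the speaker's own brain entrains to the speech it
is producing. Any phase synchronization observed *between* the two brains
(EEG hyperscanning) may therefore be a mere by-product of both brains locking
onto the same acoustic signal. `dyadsync` implements the full analysis chain
that quantifies interbrain phase synchronization in speaker–listener dyads and
statistically separates the part explained by the shared speech envelope from
the part that is not.

The design it targets: dyads alternate speaker/listener roles across
conversation topics, giving per participant five 90-second speaking epochs,
five listening epochs and one resting epoch, recorded at 250 Hz from a
27-channel 10–20 montage. Each dyad contributes two analysis cases (one per
role assignment), so 15 dyads give a 30-case sample.

## The synchrony measure

All coupling is quantified by the single-trial phase-locking value between
two phase time series $\varphi(t)$ and $\psi(t)$ of length $T$:

$$\mathrm{PLV} = \frac{1}{T}\left|\sum_{t=1}^{T} e^{i(\varphi(t) - \psi(t))}\right|$$

i.e. the modulus of the time-averaged unit phasor of the phase difference:
1 for a constant lag, about $\sqrt{\pi/4T}$ for independent phases
(≈ 0.006 at $T = 22\,500$). Phases come from zero-phase FIR band-pass
filtering (Hamming windowed-sinc, order at least three cycles of the band's
low edge, applied forward–backward) followed by the Hilbert-transform
analytic signal, in the four canonical bands delta 1–3, theta 4–8, alpha
9–12 and beta 15–20 Hz. One second is trimmed from each epoch edge before
averaging to suppress filter and Hilbert transients (`trim`, configurable;
the filters' exact orders are recorded in each run's provenance).

The stages are:

1. **Interbrain maps** — `interbrain_plv()` computes the PLV for every
   listener × speaker channel pair, band and trial (a 27 × 27 × 4 × 6 tensor
   per case: five topics plus rest). `rest_subtract_and_collapse()` subtracts
   the resting-condition PLV from each topic and averages across topics,
   removing non-specific co-presence synchrony.
2. **Envelope entrainment** — `amplitude_envelope()` extracts the speech
   amplitude envelope (short-time power spectrogram, 25-ms Hamming window,
   4-ms hop, power summed over 100–4000 Hz, square root, resampled to the
   EEG rate); `brain_envelope_plv()` computes each channel's PLV with the
   band-filtered envelope, for the listener (partner's speech) and the
   speaker (own speech); `intrabrain_correction()` subtracts, per band, the
   mean PLV over all 351 within-subject sensor pairs, removing each brain's
   global synchrony level.
3. **Surrogate nulls** — `surrogate_interbrain()` and `surrogate_envelope()`
   re-pair signals from *different* topics while preserving roles (all
   $5 \times 4 = 20$ ordered pairings, enumerated, not sampled, so the
   surrogate is deterministic), process them identically (same rest
   subtraction, same intra-brain correction) and average the pairings into
   one surrogate value per case. This destroys moment-to-moment coupling but
   preserves every marginal property of the signals.
4. **Group statistics** — `bootstrap_paired_test()` contrasts real vs
   surrogate across the 30 cases per feature with a centered-difference
   bootstrap t (10 000 resamples by default; two-sided
   $p = (1 + \#\{|t^*| \ge |t_{obs}|\})/(n_{boot}+1)$), followed by
   Benjamini–Hochberg FDR at $q = 0.05$ applied jointly across all
   729 pairs × 4 bands = 2916 interbrain tests (216 for the envelope family:
   2 roles × 27 channels × 4 bands). "Enhancement" masks additionally
   require a positive real−surrogate direction. `zscore_map()` gives the
   topographic real−surrogate difference in within-band z units.
5. **Mediation** — for every pair and band, `mediation_scan()` regresses the
   interbrain coupling $Y$ on the listener's envelope coupling $x_1$ (at the
   listener channel) and the speaker's $x_2$ (at the speaker channel) across
   the 30 cases: the full model
   $Y = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + \beta_{12} x_1 x_2 + \epsilon$
   plus the two single-predictor partial models. `exclusion_mask()` then
   removes from the significant interbrain set (i) every pair significant in
   *any* of the three models (overall-model F, $p < 0.05$ uncorrected) and
   (ii) every pair containing a channel with significant envelope
   entrainment for its role. What survives is interbrain coupling not
   explained by the shared speech signal.

`run_pipeline()` chains all stages from a `pipeline_config()` and returns a
results bundle (plus TSV/JSON outputs); the `analysis/` scripts in the
repository are thin narrative drivers over it.

## Statistical and numerical choices

* **Bootstrap null**: differences are mean-centered and resampled with
  replacement; the $(1+k)/(B+1)$ p-value convention avoids zero p. Features
  with zero-variance differences get $p = 1$ with a warning. Each feature
  uses its own resampling stream derived from the master seed, so p values
  are reproducible; being Monte-Carlo quantities they are invariant to
  feature reordering only up to resampling error.
* **Two-sided tests with reported direction**: sidedness of the original
  contrasts is not fully determined, so the conservative two-sided p is used
  and enhancement masks require direction > 0 downstream.
* **Mediation significance**: the overall-model F test at uncorrected
  $p < 0.05$ decides "explained by speech", matching one p per channel pair;
  per-coefficient criteria would be stricter. With three predictors and 30
  cases the full model has $F(3, 26)$. The partial models complement the
  full model; a pair significant in any of the three is excluded. Under the
  null this removes roughly 10–15 % of genuinely direct pairs — an inherent
  property of the uncorrected any-of-three rule, visible in the validation
  study below.
* **Zero-phase filtering** is implemented in the frequency domain as
  multiplication with $|B(f)|^2$ on reflect-padded signals (identical to
  forward–backward FIR application away from edges, and the edges are
  trimmed). High-pass filters are built by spectral inversion of a
  DC-normalised low-pass so the DC response is exactly zero. Band energies
  below $10^{-12}$ of the peak gain are truncated in the spectral product.
* **Degenerate inputs**: silent audio gives an all-zero envelope with a
  warning; missing rest epochs disable baseline subtraction with a warning;
  constant or collinear mediation predictors yield flagged fits with `NA`
  p values; bands at or above Nyquist are rejected.
* **Bad channels**: `screen_bad_channels()` offers a variance/flatline
  screen with optional interpolation by the mean of the remaining channels
  (the montage carries no geometry, so a global average stands in for
  spatial neighbours). It is off by default — synthetic data needs none,
  and real recordings are expected to arrive cleaned, since component-based
  artifact removal is outside the package's scope.

## The synthetic dyad generator

No public dataset accompanies the design, so `synth_config()` /
`generate_dyad_session()` build dyad sessions with known ground truth.

* **Channels** are 1/f background noise (spectrally synthesised, exponent 1
  by default) plus one band-limited stochastic phase oscillator per analysis
  band with amplitude 1, detuned by N(0, 0.1 Hz) per oscillator.
* **Coupling** follows a stochastic phase-oscillator model: per sample the
  phase advances by $2\pi f/f_s$ plus an attraction term
  $a\,\kappa \sin(\varphi_{driver} - \theta)$ (gain $a = 0.25$ rad/sample at
  $\kappa = 1$) plus Gaussian phase noise (SD 0.1 rad/sample; innovations
  are drawn once per 5 samples — a 50 Hz innovation rate, far above every
  analysis band — and variance-matched to the per-sample random walk, a
  runtime choice). For an interbrain-coupled pair, the listener's and the
  speaker's oscillators are attracted to a shared trial-unique driver
  (a noisy phase ramp, new in every turn), so trial-shuffled surrogates
  genuinely destroy the coupling; for envelope-entrained channels the driver
  is the band-filtered envelope phase. Under the linearised model the locked
  phase-difference variance is $\sigma^2/(a\kappa)$, so the PLV rises
  monotonically from the decoherence floor at $\kappa = 0$ (random-walk
  variance $\sigma^2 t$ swamps the epoch) to ≈ 0.98 at $\kappa = 1$; this
  dial is verified by test, not assumed.
* **Envelopes** are products of a syllabic (~5 Hz) and a slower phrasal
  (~2 Hz) rectified noisy-phase modulator, non-negative by construction,
  with the dominant fluctuation peak in the 4–8 Hz syllabic range and a
  distinct delta component — the two quasi-rhythms of connected speech.
  `synth_turn_audio()` turns an envelope into amplitude-modulated noise
  audio whose extracted envelope recovers the original.
* **Per-case variability**: envelope-coupling strengths are multiplied by a
  per-case factor drawn from `case_scale_range`. The mediation validation
  world uses [0.15, 1] so entrainment spans the responsive part of the
  $\kappa \to$ PLV curve; with saturated entrainment the regression would
  have no across-case variance to explain. The default is [1, 1].
* **Determinism**: one master seed; per-dyad and per-epoch substreams are
  derived from it through R's RNG (all Gaussian noise is drawn R-side), so
  identical configurations reproduce sessions bit-for-bit.

The generator emulates band-limited oscillatory coupling, envelope
quasi-rhythms and 1/f background. It does **not** emulate ocular/muscle
artifacts, jaw-movement contamination, volume conduction, bad channels or
breathing/cardiac coupling — so passing validation shows the *statistical
chain* recovers planted structure at realistic SNR, not that artifact
rejection on real recordings is solved (artifact handling beyond filtering
is a pass-through hook by design).

## Validation studies and problem sizes

The test suite validates the chain at these scales (chosen as the package's
standing validation design):

* **Structure**: one full-scale dyad (27 channels, 90-s epochs) must produce
  11 epochs per participant and a 27 × 27 × 4 × 6 PLV tensor; 15 dyads give
  30 cases; 5 topics give 20 surrogate pairings; the interbrain family is
  2916 jointly corrected tests.
* **Calibration**: the bootstrap's type-I error at $\alpha = 0.05$ is checked
  on 1000 Gaussian-null features × 30 cases (2000 resamples).
* **Recovery and discrimination**: twenty replicate worlds at 15 dyads ×
  90-s epochs × 4 bands on an 8 × 8 montage (montage reduced for runtime),
  each containing eight direct pairs ($\kappa = 0.85$; alpha and beta), four
  envelope-mediated theta pairs and 244 null pairs. Pooled over replicates,
  direct pairs must be detected at ≥ 90 % sensitivity with false-discovery
  proportion ≤ 0.05, mediated pairs must be flagged by the regression scan
  and excluded from the final mask (≤ 10 % leak), and direct pairs must
  survive the exclusion at ≥ 80 % — all within binomial error of the pooled
  counts. One study serves both checks because the world contains all three
  pair types at once, which is also the harder, more realistic test.

## Known limitations

* Only the trial-shuffled surrogate of the original design is implemented —
  no phase-randomised or time-shifted surrogates, and no alternative
  synchrony metrics (coherence, PLI, wPLI).
* Mediation is regression-based ("statistically explained by"), not a formal
  causal-mediation analysis: no indirect-effect estimation or Sobel tests.
* The EEG ingestion path covers the package's JSON + float64 fixture format
  (plus WAV audio); BrainVision/EDF+ files must be converted externally and
  passed in as `raw_recording` objects.
* ICA-based artifact removal and PREP-style bad-channel detection are out of
  scope; `preprocess_recording()` accepts externally cleaned data.
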