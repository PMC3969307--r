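---
title: "Multi-timescale AM analysis of rhythmic entrainment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-timescale AM analysis of rhythmic entrainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samphr)
```

## The model

Speech can be written as a fast carrier multiplied by a slowly varying
amplitude envelope. The envelope of metrically regular English speech
carries nested amplitude modulations (AMs) at three timescales, each
associated with a phonological grain size:

| Tier | Pass-band | Unit | Default |
|------|-----------|------|---------|
| Stress | 0.8–2.5 Hz | prosodic stress foot | lower edge switchable to 0.9 Hz |
| Syllable | 2.5–12 Hz | syllable | — |
| Phoneme | 12–40 Hz | phoneme-scale events | — |

`compute_envelope()` takes the magnitude of the analytic signal (FFT
Hilbert transform), low-pass filters it and resamples to 1000 Hz.
`extract_am_tiers()` band-pass filters the mean-removed envelope with
zero-phase (forward–backward) Butterworth filters, order 2 per direction.
`analytic_phase()` then yields each tier's instantaneous phase, with the
convention that 0 rad is the oscillatory peak and −π/+π the trough.

Two entrainment analyses are built on this:

* **Tapping (perception).** For each tap, the instantaneous phase of each
  tier at the tap time is read off by linearly interpolating the complex
  analytic signal and taking its angle (`phase_at_times()`). Interpolating
  the *complex* signal, not the wrapped phase, avoids artefacts at the
  ±π seam. Per sentence, the circular median of the 8 analysable tap
  phases is the participant's phase score; scores of the two same-metre
  sentences are combined by the circular mean — the only
  rotation-consistent choice. Group concentration is tested by the
  Rayleigh test (z = nR̄²); group mean angles are compared by the
  Watson–Williams test *only if both groups individually phase-lock*
  (Rayleigh p < 0.05), because a mean direction of a uniform sample is
  meaningless.
* **Production.** External synchronisation is measured by vowel-onset
  intervals (7 per 8-syllable utterance). Internal synchronisation is the
  n:m phase synchronisation index, `PSI = |⟨exp i(nθ₁ − mθ₂)⟩|`, with the
  circular mean of the generalised difference nθ₁ − mθ₂ as locking angle.
  Stress:syllable uses n:m = 2:1 by design of the stimuli;
  syllable:phoneme uses the ratio that maximises PSI over {2:1, 3:1, 4:1,
  5:1} (`select_nm()`), 3:1 for these materials.

## Tunable parameters that matter

* `am_band_config()` — band edges in Hz as above; `filter_order`
  (default 2 per pass direction). Higher orders sharpen band separation
  but lengthen edge transients.
* `compute_envelope(env_rate = 1000)` — envelope rate in samples/s; must
  be ≥ 2× the phoneme band top (80 Hz); 1000 Hz keeps phase interpolation
  cheap and accurate.
* Tap selection (`select_analysis_taps()`) — keeps taps inside the second
  and third presentation windows; if a window holds more than 4 taps,
  each expected stress beat (every `sentence_duration/4` from window
  start, i.e. 500 ms at the default 2 s sentence) keeps its single
  nearest tap. Deterministic and order-independent; idempotent.
* PSI sample selection — samples whose envelope is below −40 dB re the
  utterance maximum are excluded (silence has no defined AM phase); set
  the threshold to `NULL` to average over all time points.
* Rayleigh gate `alpha = 0.05`; Watson–Williams warns (does not fail)
  when the pooled resultant length is below 0.45, where its concentration
  assumption becomes doubtful.
* Heatmaps (`phase_heatmap()`) — 24 bins per axis (width 2π/24 ≈ 0.08π);
  per-column percentage normalisation by default (each syllable-phase
  column sums to 100%), with a global mode.
* Compass histograms — 14 equal bins on [−π, π], left-closed, last bin
  closed.

## The synthetic world

The generators produce every input the pipelines need, with exact ground
truth, so that a green test means "the pipeline recovers what was
planted".

**Stimulus (`synth_stimulus()`).** An 8-syllable sentence analogue at a
4 Hz syllable rate and 2 Hz stress rate (syllables every 250 ms, stressed
syllables every 500 ms; sentence duration 2 s). The envelope is an
*additive* sum of raised-cosine components on a shared syllable phase
clock: a small base, a stress-rate term, a syllable-rate term and a
phoneme-rate term locked 3:1 to the syllable cycle at a configurable
coupling angle (default π: phoneme trough on the syllable peak, the
convention seen in real speech). The stress term's weight is set so
stressed and unstressed syllable peaks stand in the stated 2:1 amplitude
ratio. Trochaic and iambic metres differ only by a half-cycle shift of
the stress term, so their modulation spectra are identical and their
stress beats differ by one syllable period.

Why additive rather than multiplicative nesting: a product of modulators
generates intermodulation components (stress×syllable at 6 Hz, phoneme
sidebands at 8–10 Hz) *inside* the syllable analysis band, which bends
the extracted tier's instantaneous phase by up to ~0.07π and makes the
generator's own phase arithmetic false. With additive components each
analysis band contains a single pure component and planted phases are
exact. This was measured, not assumed, before the tests were frozen.

**Taps (`synth_tap_train()`).** One tap per stress beat, continued
through the silent gaps (participants are instructed to keep tapping), so
a 3-presentation trial carries up to 20 taps of which 8 are analysable.
The mean tap phase is planted on the target tier and jittered by von
Mises(κ) phase noise; misses and extras are injected at stated rates.
Two placement rules exist: `"phase"` (default) inverts the stimulus's
true tier-phase function, so a planted +0.40π is recovered as +0.40π;
`"time"` shifts tap times by `offset/(2πf)`. These differ slightly
because the order-2 syllable band-pass attenuates the 2 Hz stress
component by only ~8 dB — true of real speech too — so the tier phase at
a fixed *time* offset deviates from the nominal angle by a few hundredths
of π. The phase rule is the ground-truth-closure reading of "taps at a
known tier phase"; the time rule is kept for P-centre-style experiments.

**Production (`synth_production()`).** Five repetitions whose vowel
onsets follow a target interval (default 250 ms) with optional Gaussian
jitter; the phoneme term is locked 3:1 at a configurable coupling angle;
a 2 Hz pacing metronome is returned. Only repetitions 3–5 are analysed.

**Cohorts (`synth_cohort()`).** Defaults: 22 controls and 21 dyslexics.
Each participant's latent mean tap phase is drawn von Mises about the
group offset (defaults +0.40π and +0.09π on the syllable tier —
the published control/dyslexic contrast for trochaic sentences), with
between-participant concentration κ = 2.4, chosen once so that the
circular SD of participant scores is ≈ 0.30π, the dispersion reported for
syllable-tier tapping scores. Within-participant tap jitter is κ = 10.
Behaviour scores follow `score = a + b·cos(phase − φ₀) + noise` with
WRAT-like defaults (a = 110, b = 8, sd = 6, φ₀ = +0.40π), planting a
circular–linear correlation of roughly 0.5 at the cohort's size.

**What a green test does not establish.** The generators emulate the
*timing* structure of metrical speech, not speech itself: no formants,
F0, coarticulation, amplitude asymmetries of real syllables
(rise-time/P-centre effects), or speaker variability. Absolute PSI values
in the synthetic world are higher than on real recordings (where ~0.2 is
typical) except at the 12 Hz band edge, where the planted phoneme line is
attenuated by design of the adjacent bands. Group-difference power
estimates transfer to real data only insofar as the planted dispersions
match real between-participant variability.

## Numerical choices

* Butterworth design is by bilinear transform of the analog prototype;
  coefficients agree with standard references to machine precision.
  Forward–backward filtering squares the magnitude response and cancels
  phase; odd-reflection padding of ≈3 cycles of the band's lower edge
  suppresses edge transients.
* The first and last 1.5 cycles of a tier's lower band edge are flagged
  low-confidence; events there are scored but marked.
* The circular median minimises the summed circular distance
  π − |π − |θ − θᵢ||; the objective is piecewise linear with breakpoints
  at the sample angles and their antipodes, so those candidates are
  searched exactly. Ties within 1e−9 are broken by the circular mean of
  the minimisers; a perfectly antipodal tie (vanishing mean vector) falls
  back deterministically to the first minimiser in candidate order.
* Rayleigh p-values use the standard finite-n approximation
  `exp(√(1+4n+4(n²−R²)) − (1+2n))`; its type-I error is 5% ± 1% at
  n = 50 over 10⁴ replicates.
* Watson–Williams applies the usual concentration correction
  K = 1 + 3/(8κ̂) with κ̂ from Fisher's inverse-A approximation.
* The circular–linear correlation uses the closed form from the pairwise
  Pearson correlations of x with cos θ and sin θ; p is asymptotic
  (nr² ~ χ²₂), with an optional seeded permutation p for small n.
* Phase at arbitrary times: linear interpolation of the complex analytic
  signal, then the angle. Out-of-range events are excluded per event and
  logged, never propagated as NaN phases.
* Tier "peaks" are phase-zero crossings (`tier_peaks()`), not raw local
  maxima: magnitude ripple from neighbouring-band leakage (e.g. the
  phoneme trough carving the envelope peak at coupling π) displaces raw
  maxima by tens of ms while phase-defined peaks stay within ~1 ms of
  ground truth.
* Utterance segmentation thresholds at −40 dB re max with a 50 ms
  hangover. The timing-mode classifier counts peaks of the envelope
  low-passed at 5 Hz (DC retained, min peak distance 120 ms): a band-pass
  syllable tier cannot serve here because slow (one-syllable-per-beat)
  speech moves the syllable rate below the 2.5 Hz band edge, and the
  stress component cancels unstressed-peak maxima inside the band.
* All times are seconds internally; milliseconds appear only at reporting
  boundaries. Output tables are formatted at 12 significant digits so
  reruns are byte-identical.

## Design choices where the method was genuinely open

* Stress band lower edge: 0.8 Hz by default (the value used in the
  analysis protocol), 0.9 Hz selectable (the value quoted in overviews of
  the band structure).
* The acoustic-frequency front end (multi-band spectral decomposition
  before envelope extraction) defaults to broadband; an optional 5-band
  log-spaced decomposition over 100–7250 Hz (`spectral_band_filter()`)
  exposes the hook without reproducing the published band derivation.
* Whether per-participant PSIs are computed per repetition then averaged,
  or on concatenated repetitions: per-repetition-then-average is the
  default (`crossband_phase_analysis()` averages PSI arithmetically and
  locking angles circularly across repetitions).
* Individual phase-locking is judged by a Rayleigh test on that
  participant's pooled selected tap phases per metre at α = 0.05.
* Surplus taps in a window are assigned one-per-expected-beat by nearest
  distance — deterministic and order-independent.
* Group Rayleigh tests run on metre-averaged participant scores (the
  primary published analysis); per-sentence scores remain available from
  the per-sentence medians.

## Known limitations

* The 12 Hz boundary between the syllable and phoneme bands halves any
  component lying exactly on it; syllable:phoneme PSI values for stimuli
  with a 12 Hz phoneme line are therefore conservative.
* Watson–Williams assumes comparable, reasonably high concentrations;
  the implementation warns rather than refuses below pooled R̄ = 0.45,
  mirroring the Rayleigh pre-screen of the published protocol.
* No automatic vowel-onset detection for real recordings: onsets come
  from annotation files (delimited text or Praat TextGrid tiers).
* The WAV reader supports mono PCM 16/24-bit and float-32; stereo is
  mixed down with a warning.
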