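# samphr

Multi-timescale amplitude-modulation (AM) analysis of rhythmic entrainment
to speech, for researchers studying sensorimotor synchronisation, speech
rhythm and its disruption (e.g. in developmental dyslexia).

Metrically regular English speech carries nested amplitude modulations at
three characteristic timescales: prosodic stress (~2 Hz), syllables
(~4-5 Hz) and phonemes (>12 Hz). `samphr` demodulates a speech waveform
into this AM hierarchy, and quantifies entrainment to it in two settings:

* **Perception (tapping)** — taps to the beat of a sentence are scored by
  the instantaneous Hilbert phase of each AM tier at the tap time.
  Per-participant *phase scores* (circular medians of tap phases) are
  tested for concentration with the Rayleigh test (z = n R̄²) and compared
  between groups with the Watson–Williams test, gated on both groups
  phase-locking. Classical measures (inter-tap intervals, tap distance to
  stressed-vowel onsets / P-centres) are emitted alongside.
* **Production (speech to a metronome)** — produced utterances are scored
  by vowel-onset intervals (VOIs) and by n:m cross-frequency phase
  synchronisation between tiers, using the phase synchronisation index

      PSI = | < exp(i (n θ₁ − m θ₂)) > |

  where θ₁, θ₂ are the instantaneous phases of the slower and faster AM
  and n:m their frequency ratio (2:1 for stress:syllable, 3:1 for
  syllable:phoneme). The circular mean of the generalised phase difference
  n θ₁ − m θ₂ is the locking angle.

Phase convention throughout: 0 rad is the oscillatory peak; −π and +π both
denote the trough.

A fully seeded synthetic-data module generates metrically regular
speech-like stimuli (8 syllables, 4 Hz syllable / 2 Hz stress rates), tap
trains with controlled phase offsets and von Mises jitter, produced
utterances with planted VOIs and coupling angles, and two-group cohorts
with known ground truth — so the entire pipeline is testable without any
recordings.

## Worked example

```r
library(samphr)

# a synthetic trochaic sentence: 8 syllables at 4 Hz, stress at 2 Hz
st <- synth_stimulus(stimulus_spec(metre = "trochaic", seed = 1))
ms <- modulation_spectrum(st$envelope, fmax = 20)
ms$freq_hz[order(-ms$power)][1:2]
#> [1] 2 4          # envelope spectrum peaks at the stress and syllable rates

# a participant tapping 0.40 pi after the syllable-tier peak
tm   <- trial_timing(sentence_duration = 2)   # 3 presentations, 2 s gaps
taps <- synth_tap_train(st$stress_beats, tm,
                        response_spec(phase_offset = 0.40 * pi, kappa = 10,
                                      seed = 2),
                        tier = st$tiers$syllable)
length(taps$times)
#> [1] 20           # tapping continues through the silent gaps
attr(inter_tap_intervals(taps), "mean_iti_ms")
#> [1] 501.6346     # ~500 ms: tapping at the 2 Hz stress rate

sel <- select_analysis_taps(taps, tm)         # keep the 8 taps of reps 2-3
folded <- sel$times - vapply(sel$times, function(x)
  max(tm$repetition_starts[tm$repetition_starts <= x]), numeric(1))
ph <- phase_at_times(st$tiers$syllable, sort(folded))
circ_median(ph) / pi
#> [1] 0.3751355    # recovered tapping phase ~ +0.40 pi

phase_to_time(0.31 * pi, 4)
#> [1] 38.75        # a 0.31 pi phase difference at 4 Hz is ~39 ms

# cross-frequency coupling of a produced utterance (planted angle 1 pi)
pr  <- synth_production(stimulus_spec(seed = 1), voi_ms = 250, seed = 1)
env <- compute_envelope(pr$waveform, 1000)
h   <- extract_am_tiers(env)
r   <- psi(analytic_phase(h$syllable, 1000, "syllable")$phase,
           analytic_phase(h$phoneme,  1000, "phoneme")$phase, n = 3, m = 1)
c(psi = r$psi, angle_over_pi = r$mean_diff_angle / pi)
#>       psi  angle_over_pi
#> 0.4484570  0.9592775     # syllable:phoneme 3:1 locking near 1 pi
```

The numbers above are what the code prints at these seeds: the recovered
tap phase matches the planted +0.40 π offset, the mean inter-tap interval
sits at the 500 ms stress period, and the produced utterance's
syllable:phoneme locking angle sits near the planted π.

## Command line

```sh
Rscript inst/cli/samphr.R simulate            --seed 1 --out results/sim
Rscript inst/cli/samphr.R analyze-perception  --seed 1 --out results/perc
Rscript inst/cli/samphr.R analyze-production  --seed 1 --out results/prod
```

Each run writes tidy TSV tables (12-significant-digit formatting, so
reruns are byte-identical) and a `manifest.json` recording mode, seed,
config and outputs.

## Vignette

`vignettes/methods.Rmd` documents the model, parameter choices, the
synthetic world and its limits, and numerical decisions.
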