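# Synthetic-data generators: metrically regular speech-like stimuli, tap
# trains, produced-utterance analogues and two-group cohorts with known
# ground truth. Everything is seeded and returns the latent quantities
# needed to score pipeline recovery.

#' Stimulus specification
#'
#' Describes a metrically regular 8-syllable sentence analogue: a carrier
#' modulated by nested raised-cosine envelopes at the stress, syllable and
#' phoneme rates. Defaults emulate metronome-timed nursery-rhyme speech:
#' syllables every 250 ms (4 Hz), stressed syllables every 500 ms (2 Hz).
#'
#' @param syllable_rate Syllable rate in Hz.
#' @param stress_rate Stress rate in Hz; must equal `syllable_rate / 2`.
#' @param n_syllables Syllables per sentence.
#' @param metre `"trochaic"` (stress on odd syllables) or `"iambic"`
#'   (stress on even syllables).
#' @param phoneme_rate Phoneme-tier modulation rate in Hz; an integer
#'   multiple of `syllable_rate` for coupled mode.
#' @param coupling_angle Target generalised phase difference
#'   `n*theta_syll - m*theta_phon` (with `n = phoneme_rate/syllable_rate`,
#'   `m = 1`) planted between the syllable and phoneme tiers, radians.
#' @param stress_depth Stressed:unstressed syllable-peak amplitude ratio
#'   (default 2).
#' @param carrier `"noise"` or `"tone"` (1 kHz).
#' @param sample_rate Audio sample rate in samples/s.
#' @param seed Integer seed for the carrier noise.
#' @return A `stimulus_spec` object.
#' @export
stimulus_spec <- function(syllable_rate = 4, stress_rate = syllable_rate / 2,
                          n_syllables = 8, metre = c("trochaic", "iambic"),
                          phoneme_rate = 12, coupling_angle = pi,
                          stress_depth = 2,
                          carrier = c("noise", "tone"), sample_rate = 16000,
                          seed = 1) {
  metre <- match.arg(metre); carrier <- match.arg(carrier)
  if (abs(stress_rate - syllable_rate / 2) > 1e-9) {
    stop("stress_rate must be syllable_rate / 2", call. = FALSE)
  }
  if (abs(phoneme_rate / syllable_rate - round(phoneme_rate / syllable_rate)) > 1e-9) {
    stop("phoneme_rate must be an integer multiple of syllable_rate", call. = FALSE)
  }
  structure(list(syllable_rate = syllable_rate, stress_rate = stress_rate,
                 n_syllables = n_syllables, metre = metre,
                 phoneme_rate = phoneme_rate, coupling_angle = coupling_angle,
                 stress_depth = stress_depth, carrier = carrier,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "stimulus_spec")
}

# Nested envelope + ground-truth event times for one sentence.
#
# The envelope is an additive sum of raised-cosine components riding on a
# shared syllable phase clock: base + stress-rate + syllable-rate +
# phoneme-rate terms. Each analysis band then contains a single pure
# component, so extracted tier phases advance exactly linearly and the
# generator's phase arithmetic (tap offsets, coupling angles) is exact. A
# multiplicative nesting would instead put intermodulation products inside
# the syllable band and bend its instantaneous phase.
#
# `peaks` (syllable-peak times) may be supplied for jittered production;
# the syllable phase clock is then the monotone piecewise-linear function
# with theta = 2*pi*(j-1) at the j-th peak.
build_sentence_envelope <- function(spec, t, peaks = NULL) {
  Tsyl <- 1 / spec$syllable_rate
  if (is.null(peaks)) {
    peaks <- (seq_len(spec$n_syllables) - 1) * Tsyl + Tsyl / 2
  }
  stressed_pos <- if (spec$metre == "trochaic") {
    seq(1, spec$n_syllables, by = 2)
  } else seq(2, spec$n_syllables, by = 2)
  # syllable phase clock: 2*pi*(j-1) at peak j, linear in between and
  # extrapolated at the median cycle length beyond the ends
  Tmed <- stats::median(diff(peaks))
  theta_syl <- stats::approx(peaks, 2 * pi * (seq_along(peaks) - 1),
                             xout = t, rule = 2)$y
  pre <- t < peaks[1]; post <- t > peaks[length(peaks)]
  theta_syl[pre] <- 2 * pi * (t[pre] - peaks[1]) / Tmed
  theta_syl[post] <- 2 * pi * (length(peaks) - 1) +
    2 * pi * (t[post] - peaks[length(peaks)]) / Tmed
  theta_str <- theta_syl / 2 - if (spec$metre == "iambic") pi else 0
  n_ratio <- round(spec$phoneme_rate / spec$syllable_rate)
  theta_phon <- n_ratio * theta_syl - spec$coupling_angle
  rc <- function(th) 0.5 * (1 + cos(th))
  base <- 0.1; w_syl <- 1; w_ph <- 0.4
  # stressed peaks carry the stress component's maximum; the weight is set
  # so the stressed:unstressed peak ratio equals stress_depth
  peak_rest <- base + w_syl + w_ph * rc(-spec$coupling_angle)
  w_str <- (spec$stress_depth - 1) * peak_rest
  env <- base + w_str * rc(theta_str) + w_syl * rc(theta_syl) +
    w_ph * rc(theta_phon)
  list(env = env,
       syllable_onset = peaks - Tsyl / 2,
       syllable_peak = peaks,
       vowel_onset = peaks - Tsyl / 4,
       stress_beat = peaks[stressed_pos],
       stressed_pos = stressed_pos,
       theta_syl = theta_syl)
}

#' Synthesise a metrically regular stimulus
#'
#' Builds the nested stress x syllable x phoneme envelope (raised-cosine
#' syllable pulses with metre-dependent alternating depth, phoneme-rate
#' modulator phase-locked to the syllable cycle), multiplies it onto the
#' carrier, and returns the waveform together with exact ground-truth event
#' times. The envelope modulation spectrum peaks at the stress and syllable
#' rates.
#'
#' @param spec A [stimulus_spec()].
#' @return List of class `synth_stimulus`: `waveform` ([waveform()]),
#'   `envelope` ([envelope_signal()] at 1000 Hz), and [event_series()]
#'   ground truth `syllable_onsets`, `syllable_peaks`, `vowel_onsets`,
#'   `stress_beats`, plus `spec`.
#' @export
synth_stimulus <- function(spec = stimulus_spec()) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$phoneme_rate >= 500) {
    stop("phoneme_rate must stay below the 1000 Hz envelope Nyquist", call. = FALSE)
  }
  dur <- spec$n_syllables / spec$syllable_rate
  t <- seq(0, dur - 1 / spec$sample_rate, by = 1 / spec$sample_rate)
  parts <- build_sentence_envelope(spec, t)
  old <- .Random.seed_save()
  set.seed(spec$seed)
  car <- if (spec$carrier == "noise") stats::rnorm(length(t)) else
    sin(2 * pi * 1000 * t)
  .Random.seed_restore(old)
  w <- waveform(parts$env * car, spec$sample_rate,
                sprintf("synthetic %s sentence", spec$metre))
  tt <- seq(0, dur - 1e-3, by = 1e-3)
  env1k <- envelope_signal(build_sentence_envelope(spec, tt)$env, 1000)
  # latent true tier phases (from the noiseless envelope), part of the
  # ground truth: lets tap generators place events at an exact tier phase
  h <- extract_am_tiers(env1k)
  tiers <- list(
    stress = analytic_phase(h$stress, h$rate, "stress", band = h$band_config$stress),
    syllable = analytic_phase(h$syllable, h$rate, "syllable",
                              band = h$band_config$syllable),
    phoneme = analytic_phase(h$phoneme, h$rate, "phoneme",
                             band = h$band_config$phoneme))
  ev <- function(x, kind) event_series(x, kind, metre = spec$metre,
                                       sentence = w$label)
  structure(list(
    waveform = w, envelope = env1k, tiers = tiers,
    syllable_onsets = ev(parts$syllable_onset, "vowel_onset"),
    syllable_peaks = ev(parts$syllable_peak, "vowel_onset"),
    vowel_onsets = ev(parts$vowel_onset, "vowel_onset"),
    stress_beats = ev(parts$stress_beat, "metronome"),
    spec = spec), class = "synth_stimulus")
}

#' Tapping response specification
#'
#' @param tier_target Tier whose cycle the phase offset refers to
#'   (`"syllable"` or `"stress"`).
#' @param phase_offset Mean tap phase on the target tier cycle, radians
#'   (positive: taps after the oscillatory peak).
#' @param kappa von Mises concentration of the per-tap phase jitter.
#' @param miss_rate,extra_rate Probabilities of dropping a tap / inserting
#'   a spurious tap per expected beat.
#' @param seed Integer seed.
#' @return A `response_spec` object.
#' @export
response_spec <- function(tier_target = c("syllable", "stress"),
                          phase_offset = 0, kappa = 10,
                          miss_rate = 0, extra_rate = 0, seed = 1) {
  tier_target <- match.arg(tier_target)
  stopifnot(kappa >= 0, miss_rate >= 0, miss_rate < 1,
            extra_rate >= 0, extra_rate < 1)
  structure(list(tier_target = tier_target, phase_offset = phase_offset,
                 kappa = kappa, miss_rate = miss_rate,
                 extra_rate = extra_rate, seed = as.integer(seed)),
            class = "response_spec")
}

#' Synthesise a tap train for one trial
#'
#' Places one tap near each stress beat of every sentence presentation, at
#' a controlled phase of the target AM tier, jittered by von Mises(`kappa`)
#' phase noise; misses and extras are injected at the stated rates.
#' Tapping continues through the silent gaps between presentations
#' (`fill_gaps`), extrapolating the stress beat, as participants are
#' instructed to do -- a default 3-presentation trial therefore carries up
#' to 20 taps, of which only the 8 in presentations 2-3 survive
#' [select_analysis_taps()]. Identical specs and seeds give identical
#' output.
#'
#' Two placement rules are available. `"phase"` (default, requires `tier`)
#' inverts the stimulus's true tier-phase function around each beat, so a
#' planted offset of +0.40 pi is recovered as +0.40 pi by the analysis
#' pipeline: this is the ground-truth-closure construction. `"time"`
#' shifts tap times by `phase_offset / (2 pi tier_freq)`; because the
#' extracted syllable tier of a realistic stimulus also carries attenuated
#' stress-rate energy, the tier phase actually sampled then deviates
#' slightly (a few hundredths of pi) from the nominal offset.
#'
#' @param stress_beats An [event_series()] of stress-beat times within one
#'   sentence presentation (seconds from sentence start).
#' @param timing A [trial_timing()].
#' @param rspec A [response_spec()].
#' @param tier_freq Frequency of the target tier cycle in Hz (4 for the
#'   syllable tier of the default stimulus).
#' @param tier An [analytic_phase()] object for the target tier of the
#'   stimulus (e.g. `synth_stimulus()$tiers$syllable`); required for
#'   `placement = "phase"`.
#' @param placement `"phase"` or `"time"` (see Details).
#' @param fill_gaps Continue tapping through the silent gaps between
#'   presentations at the extrapolated stress period.
#' @param participant,group,sentence,metre Labels stamped on the output.
#' @return A tap [event_series()].
#' @export
synth_tap_train <- function(stress_beats, timing, rspec = response_spec(),
                            tier_freq = 4, tier = NULL,
                            placement = c("phase", "time"),
                            fill_gaps = TRUE,
                            participant = "p1",
                            group = NA_character_, sentence = NA_character_,
                            metre = NA_character_) {
  stopifnot(inherits(stress_beats, "event_series"), inherits(timing, "trial_timing"))
  placement <- match.arg(placement)
  if (placement == "phase" && is.null(tier)) placement <- "time"
  old <- .Random.seed_save()
  set.seed(rspec$seed)
  if (placement == "phase") {
    # unwrapped tier phase on the envelope grid, for inverse lookup
    tg <- (seq_along(tier$phase) - 1) / tier$rate
    dph <- wrap_phase(diff(tier$phase))
    theta_u <- cumsum(c(tier$phase[1], dph))
  }
  tap_time <- function(b, angle) {
    if (placement == "time") return(b + angle / (2 * pi * tier_freq))
    # invert the unwrapped phase locally (within +/- 0.75 cycles of the
    # beat, where it is monotone)
    win <- which(abs(tg - b) <= 0.75 / tier_freq)
    ib <- win[which.min(abs(tg[win] - b))]
    target <- theta_u[ib] + wrap_phase(angle - tier$phase[ib])
    stats::approx(theta_u[win], tg[win], xout = target, rule = 2)$y
  }
  Tbeat <- if (length(stress_beats$times) >= 2) {
    stats::median(diff(stress_beats$times))
  } else 1 / (tier_freq / 2)
  taps <- numeric(0)
  nw <- length(timing$repetition_starts)
  for (r in seq_len(nw)) {
    w0 <- timing$repetition_starts[r]
    for (b in stress_beats$times) {
      if (stats::runif(1) < rspec$miss_rate) next
      ang <- rspec$phase_offset + rvonmises(1, 0, rspec$kappa)
      taps <- c(taps, w0 + tap_time(b, ang))
    }
    n_extra <- stats::rbinom(1, length(stress_beats$times), rspec$extra_rate)
    if (n_extra > 0) {
      taps <- c(taps, w0 + stats::runif(n_extra, 0, timing$sentence_duration))
    }
    if (fill_gaps && r < nw) {
      # continue at the extrapolated stress period through the silent gap;
      # no tier is defined in silence, so placement is by time arithmetic
      last_b <- w0 + max(stress_beats$times)
      gap_beats <- seq(last_b + Tbeat,
                       timing$repetition_starts[r + 1] + min(stress_beats$times) -
                         Tbeat / 2,
                       by = Tbeat)
      offs <- rspec$phase_offset / (2 * pi * tier_freq)
      for (gb in gap_beats) {
        if (stats::runif(1) < rspec$miss_rate) next
        jit <- rvonmises(1, 0, rspec$kappa) / (2 * pi * tier_freq)
        taps <- c(taps, gb + offs + jit)
      }
    }
  }
  .Random.seed_restore(old)
  taps <- sort(unique(pmax(taps, 0)))
  event_series(taps, "tap", participant = participant, group = group,
               sentence = sentence, metre = metre)
}

#' Synthesise a metronome-timed production recording
#'
#' Five repetitions of an 8-syllable utterance whose vowel onsets follow
#' the target interval (with optional Gaussian jitter) and whose
#' phoneme-tier envelope is phase-locked 3:1 to the syllable tier at the
#' requested generalised-difference angle.
#'
#' @param spec A [stimulus_spec()] (its rates, metre and carrier are used).
#' @param voi_ms Target vowel-onset interval in ms.
#' @param coupling_angle Planted syllable:phoneme locking angle, radians.
#' @param jitter_sd_ms Gaussian onset jitter, ms.
#' @param n_repetitions Number of repetitions.
#' @param gap_s Silence between repetitions, seconds.
#' @param seed Integer seed.
#' @param participant,group Labels.
#' @return List of class `synth_production`: `waveform`, `vowel_onsets`
#'   ([event_series()] across all repetitions), `metronome`
#'   ([event_series()] at the stress rate), `repetition_windows` (data
#'   frame), `truth` (planted values).
#' @export
synth_production <- function(spec = stimulus_spec(), voi_ms = 250,
                             coupling_angle = pi, jitter_sd_ms = 0,
                             n_repetitions = 5, gap_s = 0.5, seed = 1,
                             participant = "p1", group = NA_character_) {
  stopifnot(voi_ms > 0)
  spec$coupling_angle <- coupling_angle
  fs <- spec$sample_rate
  Tsyl <- voi_ms / 1000
  utt_dur <- spec$n_syllables * Tsyl
  rep_starts <- (seq_len(n_repetitions) - 1) * (utt_dur + gap_s)
  total <- rep_starts[n_repetitions] + utt_dur + gap_s / 2
  t <- seq(0, total - 1 / fs, by = 1 / fs)
  env <- numeric(length(t))
  onset_list <- list()
  old <- .Random.seed_save()
  set.seed(seed)
  spec_local <- spec
  spec_local$syllable_rate <- 1 / Tsyl
  spec_local$stress_rate <- spec_local$syllable_rate / 2
  spec_local$phoneme_rate <- spec_local$syllable_rate *
    round(spec$phoneme_rate / spec$syllable_rate)
  for (r in seq_len(n_repetitions)) {
    peaks <- rep_starts[r] + (seq_len(spec$n_syllables) - 1) * Tsyl + Tsyl / 2 +
      stats::rnorm(spec$n_syllables, 0, jitter_sd_ms / 1000)
    peaks <- sort(peaks)
    parts <- build_sentence_envelope(spec_local, t, peaks = peaks)
    # gate the component to its repetition window with 50 ms cosine ramps
    # so repetitions are separated by true silence
    w0 <- peaks[1] - Tsyl / 2; w1 <- peaks[length(peaks)] + Tsyl / 2
    ramp <- 0.05
    g <- rep(0, length(t))
    inw <- t >= w0 & t <= w1
    g[inw] <- 1
    up <- t >= w0 - ramp & t < w0
    g[up] <- 0.5 * (1 + cos(pi * (w0 - t[up]) / ramp))
    dn <- t > w1 & t <= w1 + ramp
    g[dn] <- 0.5 * (1 + cos(pi * (t[dn] - w1) / ramp))
    env <- env + parts$env * g
    onset_list[[r]] <- data.frame(repetition = r, onset_s = parts$vowel_onset)
  }
  car <- if (spec$carrier == "noise") stats::rnorm(length(t)) else
    sin(2 * pi * 1000 * t)
  .Random.seed_restore(old)
  w <- waveform(env * car, fs, "synthetic production")
  onsets_df <- do.call(rbind, onset_list)
  # the pacing metronome is a property of the experiment (stress rate of
  # the target stimulus), not of the produced syllable rate
  met <- event_series(seq(0, total - 0.25, by = 1 / spec$stress_rate),
                      "metronome", participant = participant)
  structure(list(
    waveform = w, envelope = envelope_signal(pmax(env[seq(1, length(env),
      by = max(1, round(fs / 1000)))], 0), 1000),
    vowel_onsets = event_series(onsets_df$onset_s, "vowel_onset",
                                participant = participant, group = group,
                                metre = spec$metre),
    onsets_by_repetition = onsets_df,
    metronome = met,
    repetition_windows = data.frame(repetition = seq_len(n_repetitions),
                                    start_s = rep_starts,
                                    end_s = rep_starts + utt_dur),
    truth = list(voi_ms = voi_ms, coupling_angle = coupling_angle,
                 nm = c(round(spec$phoneme_rate / spec$syllable_rate), 1))),
    class = "synth_production")
}

#' Cohort specification
#'
#' @param n_control,n_dyslexic Group sizes (study defaults 22 and 21).
#' @param group_phase_offsets Named numeric: mean syllable-tier tap phase
#'   per group, radians.
#' @param kappa_between Between-participant concentration of individual
#'   mean phases about the group mean (default 2.4, chosen so the circular
#'   SD of participant scores is about 0.30 pi, the dispersion reported
#'   for syllable-tier tapping in metrical speech).
#' @param kappa_within Within-participant tap-phase concentration.
#' @param behaviour_model List `a` (intercept), `b` (amplitude), `phi0`
#'   (phase of best performance) and `sd` (noise) for the linear link
#'   `score = a + b cos(phase - phi0) + noise` used for each of reading,
#'   spelling and phonology.
#' @param seed Integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_control = 22, n_dyslexic = 21,
                        group_phase_offsets = c(control = 0.40 * pi,
                                                dyslexic = 0.09 * pi),
                        kappa_between = 2.4, kappa_within = 10,
                        behaviour_model = list(a = 110, b = 8,
                                               phi0 = 0.40 * pi, sd = 6),
                        seed = 1) {
  stopifnot(n_control >= 2, n_dyslexic >= 2)
  structure(list(n_control = n_control, n_dyslexic = n_dyslexic,
                 group_phase_offsets = group_phase_offsets,
                 kappa_between = kappa_between, kappa_within = kappa_within,
                 behaviour_model = behaviour_model, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Synthesise a two-group tapping cohort
#'
#' Per participant: a latent mean tap phase drawn von Mises about the group
#' offset, tap trains for two trochaic and two iambic sentence trials, and
#' behaviour scores generated from the stated circular-linear link so
#' planted correlations are recoverable.
#'
#' @param cspec A [cohort_spec()].
#' @param spec A [stimulus_spec()] describing the (trochaic) stimulus;
#'   the iambic variant is derived from it.
#' @param timing A [trial_timing()]; defaults to the stimulus duration
#'   with an equal silent gap.
#' @param stimuli Optional precomputed stimulus set (from a previous
#'   [synth_cohort()] call with the same `spec`); the four stimuli depend
#'   only on `spec`, so reusing them avoids regenerating identical audio
#'   when simulating many cohorts.
#' @return List of class `cohort_dataset`: `participants` (data frame with
#'   latent `true_phase`), `taps` (list keyed `participant.sentence`),
#'   `behaviour` (data frame), `stimuli` (named list of [synth_stimulus()]
#'   results, one per sentence), `metre_by_sentence`, `timing`, `spec`.
#' @export
synth_cohort <- function(cspec = cohort_spec(), spec = stimulus_spec(),
                         timing = NULL, stimuli = NULL) {
  stopifnot(inherits(cspec, "cohort_spec"), inherits(spec, "stimulus_spec"))
  sentences <- c(tro1 = "trochaic", tro2 = "trochaic",
                 iam1 = "iambic", iam2 = "iambic")
  if (is.null(stimuli)) {
    stimuli <- list()
    for (sn in names(sentences)) {
      sp <- spec
      sp$metre <- sentences[[sn]]
      sp$seed <- spec$seed + match(sn, names(sentences))
      stimuli[[sn]] <- synth_stimulus(sp)
    }
  }
  if (is.null(timing)) {
    dur <- spec$n_syllables / spec$syllable_rate
    timing <- trial_timing(dur)
  }
  old <- .Random.seed_save()
  set.seed(cspec$seed)
  groups <- c(rep("control", cspec$n_control), rep("dyslexic", cspec$n_dyslexic))
  ids <- sprintf("%s%02d", ifelse(groups == "control", "c", "d"),
                 c(seq_len(cspec$n_control), seq_len(cspec$n_dyslexic)))
  true_phase <- vapply(groups, function(g) {
    rvonmises(1, cspec$group_phase_offsets[[g]], cspec$kappa_between)
  }, numeric(1))
  bm <- cspec$behaviour_model
  beh <- data.frame(participant = ids, group = groups)
  for (me in c("reading", "spelling", "phonology")) {
    beh[[me]] <- bm$a + bm$b * cos(true_phase - bm$phi0) +
      stats::rnorm(length(ids), 0, bm$sd)
  }
  tap_seeds <- sample.int(2^30, length(ids) * length(sentences))
  .Random.seed_restore(old)
  taps <- list()
  k <- 0
  for (i in seq_along(ids)) {
    for (sn in names(sentences)) {
      k <- k + 1
      rs <- response_spec(tier_target = "syllable",
                          phase_offset = true_phase[i],
                          kappa = cspec$kappa_within, seed = tap_seeds[k])
      taps[[paste(ids[i], sn, sep = ".")]] <- synth_tap_train(
        stimuli[[sn]]$stress_beats, timing, rs,
        tier_freq = spec$syllable_rate,
        tier = stimuli[[sn]]$tiers$syllable, placement = "phase",
        participant = ids[i],
        group = groups[i], sentence = sn, metre = sentences[[sn]])
    }
  }
  structure(list(
    participants = data.frame(participant = ids, group = groups,
                              true_phase = true_phase),
    taps = taps, behaviour = beh, stimuli = stimuli,
    metre_by_sentence = sentences, timing = timing, spec = spec,
    cohort_spec = cspec), class = "cohort_dataset")
}

#' Score a synthetic cohort through the perception pipeline
#'
#' Convenience wrapper: selects analysable taps, measures tier phases and
#' returns the stacked per-participant phase-score table for a
#' [synth_cohort()] dataset.
#'
#' @param cohort A `cohort_dataset`.
#' @param tiers_by_sentence Optional precomputed named list of tier sets
#'   (as built by [cohort_tiers()]); computed from the cohort's stimuli
#'   when omitted.
#' @return A `phase_scores` data frame covering all participants.
#' @export
cohort_phase_scores <- function(cohort, tiers_by_sentence = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (is.null(tiers_by_sentence)) tiers_by_sentence <- cohort_tiers(cohort)
  scores <- list()
  for (pid in cohort$participants$participant) {
    tl <- list()
    for (sn in names(cohort$metre_by_sentence)) {
      tp <- cohort$taps[[paste(pid, sn, sep = ".")]]
      sel <- select_analysis_taps(tp, cohort$timing)
      # fold trial time back to sentence time for phase lookup
      sel$times <- fold_to_sentence(sel$times, cohort$timing)
      sel$times <- sort(sel$times)
      if (length(sel$times)) tl[[sn]] <- sel
    }
    if (length(tl) == 0) next
    scores[[pid]] <- participant_phase_scores(tl, tiers_by_sentence,
                                              cohort$metre_by_sentence)
  }
  out <- do.call(rbind, scores)
  rownames(out) <- NULL
  class(out) <- c("phase_scores", "data.frame")
  out
}

#' Precompute analytic tiers for each cohort stimulus
#'
#' Uses each stimulus's stored noiseless-envelope tiers; recompute from the
#' waveform instead (via [compute_envelope()] + [extract_am_tiers()]) to
#' exercise the full acoustic path.
#'
#' @param cohort A `cohort_dataset`.
#' @param from_waveform Recompute tiers from the audio rather than reusing
#'   the generator's envelope tiers.
#' @return Named list (per sentence) of named lists of [analytic_phase()]
#'   tiers.
#' @export
cohort_tiers <- function(cohort, from_waveform = FALSE) {
  lapply(cohort$stimuli, function(st) {
    if (!from_waveform) return(st$tiers)
    h <- extract_am_tiers(compute_envelope(st$waveform, 1000))
    list(stress = analytic_phase(h$stress, h$rate, "stress",
                                 band = h$band_config$stress),
         syllable = analytic_phase(h$syllable, h$rate, "syllable",
                                   band = h$band_config$syllable),
         phoneme = analytic_phase(h$phoneme, h$rate, "phoneme",
                                  band = h$band_config$phoneme))
  })
}

# map trial-time tap times into sentence time (offset within the
# presentation window they fall in)
fold_to_sentence <- function(times, timing) {
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    w <- max(timing$repetition_starts[timing$repetition_starts <= times[i]])
    out[i] <- times[i] - w
  }
  out
}
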