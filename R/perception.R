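# Experiment-1 pipeline: tap selection, inter-tap intervals, P-centre
# distances, per-participant AM phase scores and group phase-locking tests.

#' Timestamped event series
#'
#' Point events (taps, vowel onsets, metronome beats) with participant,
#' group, sentence, metre and repetition labels.
#'
#' @param times Strictly ascending event times in seconds (>= 0).
#' @param kind `"tap"`, `"vowel_onset"` or `"metronome"`.
#' @param participant,sentence,repetition Free-text labels.
#' @param group `"control"` or `"dyslexic"` (or `NA`).
#' @param metre `"trochaic"` or `"iambic"` (or `NA`).
#' @return An `event_series` object.
#' @export
event_series <- function(times, kind = c("tap", "vowel_onset", "metronome"),
                         participant = NA_character_, group = NA_character_,
                         sentence = NA_character_, metre = NA_character_,
                         repetition = NA) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("event times must be finite and >= 0", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("event times must be strictly ascending", call. = FALSE)
  }
  if (!is.na(group) && !group %in% c("control", "dyslexic")) {
    stop("group must be 'control' or 'dyslexic'", call. = FALSE)
  }
  if (!is.na(metre) && !metre %in% c("trochaic", "iambic")) {
    stop("metre must be 'trochaic' or 'iambic'", call. = FALSE)
  }
  structure(list(times = times, kind = kind, participant = participant,
                 group = group, sentence = sentence, metre = metre,
                 repetition = repetition),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series: %d %s events%s>\n", length(x$times), x$kind,
              if (!is.na(x$participant)) paste0(", participant ", x$participant) else ""))
  invisible(x)
}

#' Trial timing for a tapping trial
#'
#' One trial presents a sentence three times with a silent gap equal to the
#' sentence duration between repetitions.
#'
#' @param sentence_duration Sentence length in seconds.
#' @param gap_duration Silent gap in seconds (defaults to the sentence
#'   duration).
#' @param n_repetitions Number of presentations (default 3).
#' @param start Onset of the first presentation in seconds.
#' @return A `trial_timing` object with `repetition_starts`.
#' @export
trial_timing <- function(sentence_duration, gap_duration = sentence_duration,
                         n_repetitions = 3, start = 0) {
  stopifnot(sentence_duration > 0, gap_duration >= 0)
  starts <- start + (seq_len(n_repetitions) - 1) * (sentence_duration + gap_duration)
  structure(list(sentence_duration = sentence_duration,
                 gap_duration = gap_duration,
                 repetition_starts = starts,
                 n_stress_beats = 4),
            class = "trial_timing")
}

#' Select analysable taps from a trial
#'
#' Discards taps produced during the first presentation and during silent
#' gaps; keeps taps falling within the second and third presentation
#' windows. If a window holds more than the expected number of stress
#' beats' worth of taps, each expected beat (every
#' `sentence_duration / 4` from the window start) keeps its single nearest
#' tap. At most 8 taps are returned.
#'
#' @param taps An [event_series()] of taps for one trial.
#' @param t A [trial_timing()].
#' @return The selected [event_series()]; attribute `excluded_trial` is
#'   `TRUE` when no tap survives.
#' @export
select_analysis_taps <- function(taps, t) {
  stopifnot(inherits(taps, "event_series"), inherits(t, "trial_timing"))
  beat_period <- t$sentence_duration / t$n_stress_beats
  keep <- numeric(0)
  for (w in t$repetition_starts[-1][seq_len(min(2, length(t$repetition_starts) - 1))]) {
    inwin <- taps$times[taps$times >= w & taps$times <= w + t$sentence_duration]
    if (length(inwin) > t$n_stress_beats) {
      beats <- w + beat_period * (seq_len(t$n_stress_beats) - 1)
      picked <- vapply(beats, function(b) inwin[which.min(abs(inwin - b))], numeric(1))
      inwin <- sort(unique(picked))
    }
    keep <- c(keep, inwin)
  }
  out <- taps
  out$times <- sort(unique(keep))
  if (length(out$times) == 0) {
    message("participant-trial excluded: no analysable taps (participant ",
            taps$participant, ", sentence ", taps$sentence, ")")
    attr(out, "excluded_trial") <- TRUE
  } else {
    attr(out, "excluded_trial") <- FALSE
  }
  out
}

#' Inter-tap intervals
#'
#' Successive tap-time differences in milliseconds, the durational
#' isochrony measure for a tapping response (ideal value 500 ms for a 2 Hz
#' stress beat).
#'
#' @param taps An [event_series()] with >= 2 taps.
#' @return Data frame with columns `participant`, `sentence`, `iti_ms`;
#'   attribute `mean_iti_ms`. With < 2 taps an empty flagged table is
#'   returned.
#' @export
inter_tap_intervals <- function(taps) {
  stopifnot(inherits(taps, "event_series"))
  if (length(taps$times) < 2) {
    out <- data.frame(participant = character(0), sentence = character(0),
                      iti_ms = numeric(0))
    attr(out, "insufficient_taps") <- TRUE
    return(out)
  }
  iti <- diff(taps$times) * 1000
  out <- data.frame(participant = taps$participant, sentence = taps$sentence,
                    iti_ms = iti)
  attr(out, "mean_iti_ms") <- mean(iti)
  attr(out, "insufficient_taps") <- FALSE
  out
}

#' Tap distances to stressed-vowel onsets (P-centre analysis)
#'
#' Pairs each tap with its nearest stressed vowel onset and reports the
#' signed distance `tap - onset` in ms (positive: tap after the onset).
#'
#' @param taps Selected taps ([event_series()]).
#' @param vowel_onsets Stressed-vowel onsets ([event_series()]).
#' @param expected_per_window Expected onsets per repetition window (4);
#'   a mismatch warns but pairing proceeds.
#' @return Data frame `participant`, `sentence`, `tap_s`, `onset_s`,
#'   `distance_ms`; attribute `mean_distance_ms`.
#' @export
pcentre_distances <- function(taps, vowel_onsets, expected_per_window = 4) {
  stopifnot(inherits(taps, "event_series"), inherits(vowel_onsets, "event_series"))
  on <- vowel_onsets$times
  if (length(on) == 0) stop("no vowel onsets supplied", call. = FALSE)
  if (length(on) %% expected_per_window != 0) {
    warning("vowel onset count (", length(on),
            ") is not a multiple of the expected ", expected_per_window,
            " per repetition window")
  }
  nearest <- vapply(taps$times, function(tt) on[which.min(abs(on - tt))], numeric(1))
  d <- (taps$times - nearest) * 1000
  out <- data.frame(participant = taps$participant, sentence = taps$sentence,
                    tap_s = taps$times, onset_s = nearest, distance_ms = d)
  attr(out, "mean_distance_ms") <- mean(d)
  out
}

#' Per-participant AM phase scores
#'
#' For each sentence and tier, the circular median of the selected taps'
#' instantaneous tier phases; per metre and tier, the circular mean of the
#' two same-metre sentence medians. `locked` reports an individual-level
#' Rayleigh test (alpha = `alpha`) on that participant's pooled tap phases
#' for the metre.
#'
#' @param taps_by_sentence Named list of selected tap [event_series()]
#'   (one per sentence; names are sentence ids).
#' @param tiers_by_sentence Named list (same names); each element a named
#'   list of [analytic_phase()] tiers (`stress`, `syllable`, `phoneme`).
#' @param metre_by_sentence Named character vector mapping sentence id to
#'   `"trochaic"`/`"iambic"`.
#' @param alpha Significance level for the lock criterion.
#' @return Data frame of class `phase_scores`: `participant`, `group`,
#'   `metre`, `tier`, `phase`, `n_taps`, `locked`, `single_sentence`
#'   (fallback flag when only one sentence of a metre was scorable).
#' @export
participant_phase_scores <- function(taps_by_sentence, tiers_by_sentence,
                                     metre_by_sentence, alpha = 0.05) {
  stopifnot(length(taps_by_sentence) >= 1,
            all(names(taps_by_sentence) %in% names(tiers_by_sentence)))
  tiers <- c("stress", "syllable", "phoneme")
  per_sentence <- list()
  for (sn in names(taps_by_sentence)) {
    tp <- taps_by_sentence[[sn]]
    if (length(tp$times) == 0) next
    at <- tiers_by_sentence[[sn]]
    if (!all(tiers %in% names(at))) stop("missing tier for sentence ", sn, call. = FALSE)
    for (ti in tiers) {
      ph <- phase_at_times(at[[ti]], tp$times)
      ph <- ph[is.finite(ph)]
      if (length(ph) == 0) next
      per_sentence[[length(per_sentence) + 1]] <- data.frame(
        participant = tp$participant, group = tp$group, sentence = sn,
        metre = unname(metre_by_sentence[sn]), tier = ti,
        median_phase = circ_median(ph), n_taps = length(ph),
        phases = I(list(ph)))
    }
  }
  if (length(per_sentence) == 0) stop("no scorable sentences", call. = FALSE)
  ps <- do.call(rbind, per_sentence)
  out <- list()
  for (m in unique(ps$metre)) {
    for (ti in tiers) {
      sel <- ps[ps$metre == m & ps$tier == ti, ]
      if (nrow(sel) == 0) next
      score <- if (nrow(sel) == 1) sel$median_phase else
        circ_mean_resultant(sel$median_phase)$mean_angle
      pooled <- unlist(sel$phases)
      locked <- if (length(pooled) >= 4) rayleigh_test(pooled)$p < alpha else NA
      out[[length(out) + 1]] <- data.frame(
        participant = sel$participant[1], group = sel$group[1], metre = m,
        tier = ti, phase = score, n_taps = length(pooled), locked = locked,
        single_sentence = nrow(sel) == 1)
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("phase_scores", "data.frame")
  out
}

#' Group phase-locking tests
#'
#' Two-step gate used for group comparison of entrained phase: per tier and
#' metre, a Rayleigh test on each group's participant phase scores; the
#' Watson-Williams comparison of group mean angles runs only when *both*
#' groups phase-lock (Rayleigh p < `alpha`).
#'
#' @param scores A `phase_scores` table covering both groups (stacked rows
#'   from [participant_phase_scores()]).
#' @param alpha Gate significance level.
#' @return Data frame: `tier`, `metre`, per-group Rayleigh `z`/`p`/mean
#'   angle, `ww_F`, `ww_p` (NA when gated out) and `ww_reason`.
#' @export
group_entrainment_tests <- function(scores, alpha = 0.05) {
  stopifnot(inherits(scores, "data.frame"))
  res <- list()
  for (ti in unique(scores$tier)) {
    for (m in unique(scores$metre)) {
      sub <- scores[scores$tier == ti & scores$metre == m, ]
      gc <- sub$phase[sub$group == "control"]
      gd <- sub$phase[sub$group == "dyslexic"]
      if (length(gc) < 4 || length(gd) < 4) {
        res[[length(res) + 1]] <- data.frame(
          tier = ti, metre = m, rayleigh_z_control = NA, rayleigh_p_control = NA,
          mean_phase_control = NA, rayleigh_z_dyslexic = NA,
          rayleigh_p_dyslexic = NA, mean_phase_dyslexic = NA,
          ww_F = NA, ww_p = NA, ww_reason = "group absent or too small")
        next
      }
      rc <- rayleigh_test(gc); rd <- rayleigh_test(gd)
      gate_open <- rc$p < alpha && rd$p < alpha
      if (gate_open) {
        ww <- watson_williams(list(control = gc, dyslexic = gd))
        wwF <- ww$F; wwp <- ww$p; reason <- "gate open"
      } else {
        wwF <- NA_real_; wwp <- NA_real_
        reason <- "failed phase-locking gate"
      }
      res[[length(res) + 1]] <- data.frame(
        tier = ti, metre = m,
        rayleigh_z_control = rc$z, rayleigh_p_control = rc$p,
        mean_phase_control = rc$mean_angle,
        rayleigh_z_dyslexic = rd$z, rayleigh_p_dyslexic = rd$p,
        mean_phase_dyslexic = rd$mean_angle,
        ww_F = wwF, ww_p = wwp, ww_reason = reason)
    }
  }
  do.call(rbind, res)
}

#' Phase-literacy correlation table
#'
#' Circular-linear correlations between participant phase scores (per tier
#' and metre) and behavioural measures, computed across all participants
#' and within each group. P-values are uncorrected for the multiple
#' comparisons (3 tiers x 2 metres x 3 measures x 3 strata = 54 cells at
#' the defaults) and flagged as such.
#'
#' @param scores A `phase_scores` table.
#' @param behaviour Data frame keyed by `participant` with behavioural
#'   columns (default `reading`, `spelling`, `phonology`).
#' @param measures Column names of `behaviour` to correlate.
#' @return Data frame: `tier`, `metre`, `measure`, `stratum`, `r`, `p`,
#'   `n`; attribute `p_adjusted = FALSE`.
#' @export
phase_literacy_correlations <- function(scores, behaviour,
                                        measures = c("reading", "spelling", "phonology")) {
  stopifnot("participant" %in% names(behaviour),
            all(measures %in% names(behaviour)))
  merged <- merge(scores, behaviour, by = "participant")
  dropped <- setdiff(unique(scores$participant), unique(behaviour$participant))
  if (length(dropped)) {
    message("dropping ", length(dropped), " participant(s) without behaviour rows")
  }
  strata <- list(all = c("control", "dyslexic"),
                 control = "control", dyslexic = "dyslexic")
  out <- list()
  for (ti in unique(merged$tier)) for (m in unique(merged$metre)) {
    cell <- merged[merged$tier == ti & merged$metre == m, ]
    for (me in measures) for (st in names(strata)) {
      sub <- cell[cell$group %in% strata[[st]], ]
      row <- data.frame(tier = ti, metre = m, measure = me, stratum = st,
                        r = NA_real_, p = NA_real_, n = nrow(sub))
      if (nrow(sub) >= 6 && stats::sd(sub[[me]]) > 0) {
        cl <- circ_linear_corr(sub$phase, sub[[me]])
        row$r <- cl$r; row$p <- cl$p; row$n <- cl$n
      }
      out[[length(out) + 1]] <- row
    }
  }
  out <- do.call(rbind, out)
  attr(out, "p_adjusted") <- FALSE
  out
}

#' Compass histogram of phase scores
#'
#' Bins phase scores into equal-width bins spanning \[-pi, pi\] (14 by
#' convention for compass plots). Bins are left-closed, right-open, the
#' last bin closed.
#'
#' @param phases Numeric phases in radians (or a `phase_scores` table,
#'   whose `phase` column is used).
#' @param nbins Number of bins.
#' @return List of class `compass_histogram`: `bin_edges` (length
#'   `nbins + 1`), `counts`.
#' @export
compass_histogram <- function(phases, nbins = 14) {
  if (inherits(phases, "data.frame")) phases <- phases$phase
  phases <- wrap_phase(phases[is.finite(phases)])
  if (length(phases) == 0) stop("no phases supplied", call. = FALSE)
  edges <- seq(-pi, pi, length.out = nbins + 1)
  idx <- pmin(findInterval(phases, edges, rightmost.closed = TRUE), nbins)
  counts <- tabulate(idx, nbins)
  structure(list(bin_edges = edges, counts = counts), class = "compass_histogram")
}
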