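# Experiment-2 pipeline: vowel-onset intervals (external synchronisation)
# and n:m cross-frequency phase synchronisation between AM tiers (internal
# synchronisation).

#' Vowel-onset intervals
#'
#' Successive differences between vowel-onset times: an 8-onset utterance
#' yields 7 VOIs. The mean VOI is the produced-syllable-rate measure
#' (target 250 ms for 2 syllables per 2 Hz metronome beat).
#'
#' @param onsets An [event_series()] of vowel onsets for one utterance.
#' @param expected_onsets Expected onsets per utterance (default 8); a
#'   mismatch flags the utterance but available intervals are still used.
#' @return Data frame `participant`, `sentence`, `repetition`, `voi_ms`;
#'   attributes `mean_voi_ms` and `onset_count_flag`.
#' @export
vowel_onset_intervals <- function(onsets, expected_onsets = 8) {
  stopifnot(inherits(onsets, "event_series"))
  flag <- length(onsets$times) != expected_onsets
  if (flag) {
    warning("utterance has ", length(onsets$times), " onsets, expected ",
            expected_onsets, "; using available intervals")
  }
  if (length(onsets$times) < 2) {
    out <- data.frame(participant = character(0), sentence = character(0),
                      repetition = integer(0), voi_ms = numeric(0))
    attr(out, "onset_count_flag") <- flag
    return(out)
  }
  voi <- diff(onsets$times) * 1000
  out <- data.frame(participant = onsets$participant, sentence = onsets$sentence,
                    repetition = if (is.na(onsets$repetition[1])) NA_integer_ else onsets$repetition,
                    voi_ms = voi)
  attr(out, "mean_voi_ms") <- mean(voi)
  attr(out, "onset_count_flag") <- flag
  out
}

#' n:m phase synchronisation index
#'
#' Strength and angle of phase-locking between two oscillations at an n:m
#' frequency ratio. The generalised phase difference `n*phi1 - m*phi2` is
#' wrapped to \[-pi, pi\]; the PSI is the modulus of its mean unit vector
#' (0 = no synchronisation, 1 = perfect synchronisation) and the locking
#' angle is that vector's argument.
#'
#' @param phi1,phi2 Equal-length phase sequences in radians.
#' @param n,m Positive integer frequency multipliers (`n` applies to
#'   `phi1`, the slower oscillation).
#' @param min_samples Minimum required length (contractual default 100;
#'   lower it explicitly for toy inputs).
#' @return List of class `psi_result`: `n`, `m`, `psi`, `mean_diff_angle`,
#'   `diff_resultant` (= `psi`), `n_samples`.
#' @examples
#' t <- seq(0, 10, by = 1e-3)
#' p1 <- wrap_phase(2 * pi * 2 * t); p2 <- wrap_phase(2 * pi * 4 * t)
#' psi(p1, p2, n = 2, m = 1)$psi  # 1: perfect 2:1 locking
#' @export
psi <- function(phi1, phi2, n = 1, m = 1, min_samples = 100) {
  if (length(phi1) != length(phi2)) stop("phase sequences differ in length", call. = FALSE)
  keep <- is.finite(phi1) & is.finite(phi2)
  phi1 <- phi1[keep]; phi2 <- phi2[keep]
  if (length(phi1) < min_samples) {
    stop("need at least ", min_samples, " paired samples", call. = FALSE)
  }
  stopifnot(n >= 1, m >= 1, n == round(n), m == round(m))
  z <- mean(exp(1i * (n * phi1 - m * phi2)))
  structure(list(n = as.integer(n), m = as.integer(m),
                 psi = min(Mod(z), 1), mean_diff_angle = Arg(z),
                 diff_resultant = min(Mod(z), 1), n_samples = length(phi1)),
            class = "psi_result")
}

#' Select the dominant n:m coupling ratio
#'
#' Computes the PSI for each candidate ratio and returns the ratio with the
#' highest PSI; ties (within `tie_tol`) are broken toward the smaller `n`
#' with a warning, and a near-tie across all candidates (uncoupled input)
#' also warns.
#'
#' @param phi1,phi2 Phase sequences (slower oscillation first).
#' @param candidates List of `c(n, m)` integer pairs.
#' @param tie_tol Absolute PSI difference treated as a tie.
#' @param ... Passed to [psi()].
#' @return List: `n`, `m`, `psi`, and `table` (data frame of all
#'   candidates).
#' @export
select_nm <- function(phi1, phi2,
                      candidates = list(c(2, 1), c(3, 1), c(4, 1), c(5, 1)),
                      tie_tol = 0.02, ...) {
  if (length(candidates) < 2) stop("need at least 2 candidate ratios", call. = FALSE)
  tab <- do.call(rbind, lapply(candidates, function(nm) {
    r <- psi(phi1, phi2, nm[1], nm[2], ...)
    data.frame(n = r$n, m = r$m, psi = r$psi, mean_diff_angle = r$mean_diff_angle)
  }))
  tab <- tab[order(tab$n, tab$m), ]
  best <- max(tab$psi)
  tied <- which(tab$psi >= best - tie_tol)
  if (length(tied) > 1) {
    warning("near-tied PSI among candidate ratios; choosing the smallest n")
  }
  win <- tab[tied[1], ]
  list(n = win$n, m = win$m, psi = win$psi, table = tab)
}

#' Joint phase heatmap
#'
#' Binned joint distribution of two concurrent phase sequences, the
#' visualisation convention for n:m coupling: x-axis is the slower
#' (syllable) phase mapped to \[0, 2 pi\], y-axis the faster (phoneme)
#' phase in \[-pi, pi\], 24 bins per axis (width 2 pi / 24 = 0.08 pi rad).
#' A constant generalised difference of 1 pi puts the mass on the main
#' diagonal.
#'
#' @param phi_x,phi_y Equal-length phase sequences (radians).
#' @param nbins Bins per axis.
#' @param normalise `"column"` (percent within each x-bin, default) or
#'   `"global"` (percent of all samples).
#' @return List of class `phase_heatmap`: `x_edges` (\[0, 2 pi\]),
#'   `y_edges` (\[-pi, pi\]), `freq` (nbins x nbins, %), `normalise`.
#' @export
phase_heatmap <- function(phi_x, phi_y, nbins = 24,
                          normalise = c("column", "global")) {
  normalise <- match.arg(normalise)
  if (length(phi_x) != length(phi_y)) stop("phase sequences differ in length", call. = FALSE)
  keep <- is.finite(phi_x) & is.finite(phi_y)
  phi_x <- phi_x[keep]; phi_y <- phi_y[keep]
  x <- wrap_phase(phi_x) %% (2 * pi)          # [0, 2pi)
  y <- wrap_phase(phi_y)                       # [-pi, pi]
  x_edges <- seq(0, 2 * pi, length.out = nbins + 1)
  y_edges <- seq(-pi, pi, length.out = nbins + 1)
  ix <- pmin(findInterval(x, x_edges, rightmost.closed = TRUE), nbins)
  iy <- pmin(findInterval(y, y_edges, rightmost.closed = TRUE), nbins)
  freq <- matrix(0, nbins, nbins)
  tab <- table(factor(iy, levels = 1:nbins), factor(ix, levels = 1:nbins))
  freq <- matrix(as.numeric(tab), nbins, nbins)
  if (normalise == "column") {
    cs <- colSums(freq)
    cs[cs == 0] <- 1
    freq <- sweep(freq, 2, cs, "/") * 100
  } else {
    freq <- freq / sum(freq) * 100
  }
  structure(list(x_edges = x_edges, y_edges = y_edges, freq = freq,
                 normalise = normalise),
            class = "phase_heatmap")
}

#' Segment a multi-repetition production recording
#'
#' Finds utterance boundaries by an energy threshold on the smoothed
#' envelope (default -40 dB re the maximum, with a 50 ms hangover),
#' indexes the repetitions, and classifies each utterance's timing mode by
#' comparing the detected syllable-peak rate against the metronome rate
#' (ratio >= 1.5 means two syllables per beat). Repetitions 1-2 and
#' one-syllable-per-beat utterances are marked `included = FALSE`.
#'
#' @param recording A [waveform()] holding all repetitions.
#' @param metronome An [event_series()] of metronome beats (used for the
#'   timing-mode classification).
#' @param n_expected Expected number of repetitions (default 5).
#' @param threshold_db Energy threshold re max, in dB.
#' @param hangover_s Gap shorter than this does not split an utterance.
#' @param min_peak_dist_s Minimum syllable-peak spacing for the
#'   peak-picking classifier.
#' @param smooth_hz Low-pass cutoff for the syllable-landmark envelope;
#'   must lie between the syllable rate and the phoneme rate of the
#'   slowest expected utterance (5 Hz covers both one- and two-syllable-
#'   per-beat productions against a 2 Hz metronome).
#' @return Data frame of class `utterance_set`: `repetition`, `start_s`,
#'   `end_s`, `syllable_peaks`, `timing_mode`, `included`, `reason`.
#' @export
segment_utterances <- function(recording, metronome, n_expected = 5,
                               threshold_db = -40, hangover_s = 0.05,
                               min_peak_dist_s = 0.12, smooth_hz = 5) {
  stopifnot(inherits(recording, "waveform"), inherits(metronome, "event_series"))
  env <- compute_envelope(recording, env_rate = min(1000, recording$rate))
  rate <- env$rate
  # smooth over 20 ms
  k <- max(1, round(0.02 * rate))
  sm <- stats::filter(env$values, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  thr <- max(sm) * 10^(threshold_db / 20)
  active <- sm > thr
  # hangover: close gaps shorter than hangover_s
  gap <- round(hangover_s * rate)
  r <- rle(active)
  idx <- which(!r$values & r$lengths < gap)
  # interior short gaps only
  idx <- idx[idx > 1 & idx < length(r$values)]
  r$values[idx] <- TRUE
  active <- inverse.rle(r)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  segs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge segments separated by less than half the median inter-segment gap?
  if (nrow(segs) < n_expected) {
    warning("detected ", nrow(segs), " utterances, expected ", n_expected,
            "; best-effort indexing")
  }
  if (nrow(segs) > n_expected) {
    # keep the n_expected longest segments, in temporal order
    lens <- segs$end - segs$start
    segs <- segs[order(-lens)[seq_len(n_expected)], ]
    segs <- segs[order(segs$start), ]
  }
  met_rate <- if (length(metronome$times) >= 2) 1 / stats::median(diff(metronome$times)) else NA
  out <- list()
  for (i in seq_len(nrow(segs))) {
    s0 <- (segs$start[i] - 1) / rate; s1 <- (segs$end[i] - 1) / rate
    seg_env <- envelope_signal(env$values[segs$start[i]:segs$end[i]], rate)
    n_peaks <- NA_integer_; mode <- NA_character_
    if (length(seg_env$values) / rate > 0.5) {
      # syllable landmarks: peaks of the syllable-rate-smoothed envelope.
      # DC is retained so unstressed syllables keep a local maximum even
      # when slow speech moves the syllable rate below the 2.5-12 Hz band;
      # the cutoff suppresses phoneme-rate ripple for both speaking modes.
      d <- butter_design(2, smooth_hz, rate, "low")
      sm2 <- filtfilt_ba(d$b, d$a, seg_env$values,
                         padlen = min(length(seg_env$values) - 1, rate))
      pk <- find_peaks(sm2, rate, min_dist_s = min_peak_dist_s,
                       min_height = 0.2 * max(sm2))
      n_peaks <- length(pk)
      if (!is.na(met_rate)) {
        syl_rate <- n_peaks / (s1 - s0)
        mode <- if (syl_rate / met_rate >= 1.5) "two_syllables_per_beat"
                else "one_syllable_per_beat"
      }
    }
    included <- i >= max(1, nrow(segs) - 2) &&
      (is.na(mode) || mode == "two_syllables_per_beat")
    reason <- if (i < max(1, nrow(segs) - 2)) "early repetition"
      else if (!is.na(mode) && mode == "one_syllable_per_beat") "syllable-timed utterance"
      else "included"
    out[[i]] <- data.frame(repetition = i, start_s = s0, end_s = s1,
                           syllable_peaks = n_peaks, timing_mode = mode,
                           included = included, reason = reason)
  }
  out <- do.call(rbind, out)
  class(out) <- c("utterance_set", "data.frame")
  out
}

# simple local-maximum peak picking with a minimum-distance constraint
find_peaks <- function(x, rate, min_dist_s = 0.12, min_height = NULL) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (is.null(min_height)) min_height <- 0.1 * max(x)
  cand <- cand[x[cand] > min_height]
  if (length(cand) == 0) return(numeric(0))
  cand <- cand[order(-x[cand])]
  sel <- integer(0)
  min_dist <- min_dist_s * rate
  for (c0 in cand) {
    if (all(abs(c0 - sel) >= min_dist)) sel <- c(sel, c0)
  }
  sort(sel - 1) / rate
}

#' Cross-frequency phase analysis across a set of utterances
#'
#' For each included utterance, extracts the AM hierarchy, computes the PSI
#' and locking angle for the requested tier pairs restricted to
#' above-threshold (voiced) samples, averages per participant across
#' repetitions, and compares groups: PSI strength by a two-sample t-test
#' and locking angle by a Rayleigh-gated Watson-Williams test.
#'
#' @param utterances List; each element a list with `waveform` (a
#'   [waveform()]), `participant`, `group`, `sentence`, `metre`,
#'   `repetition`, `included` (logical).
#' @param pairs List of tier pairs; each `list(tiers = c(slow, fast), n, m)`.
#'   Defaults: stress:syllable at 2:1 and syllable:phoneme at 3:1.
#' @param energy_threshold_db Samples whose envelope is below this level re
#'   the utterance maximum are excluded from the PSI average (silence has
#'   undefined AM phase); `NULL` keeps all samples.
#' @param alpha Rayleigh gate level for the angle comparison.
#' @param welch Use Welch's t-test for the strength comparison.
#' @return List: `per_participant` (tidy PSI table), `group_tests`
#'   (per pair x metre strength and angle comparisons), `exclusions`.
#' @export
crossband_phase_analysis <- function(utterances,
                                     pairs = list(
                                       list(tiers = c("stress", "syllable"), n = 2, m = 1),
                                       list(tiers = c("syllable", "phoneme"), n = 3, m = 1)),
                                     energy_threshold_db = -40,
                                     alpha = 0.05, welch = FALSE) {
  rows <- list(); excl <- list()
  for (u in utterances) {
    if (!isTRUE(u$included)) {
      excl[[length(excl) + 1]] <- data.frame(
        participant = u$participant, sentence = u$sentence,
        repetition = u$repetition,
        reason = if (is.null(u$reason)) "excluded" else u$reason)
      next
    }
    env <- compute_envelope(u$waveform, env_rate = min(1000, u$waveform$rate))
    tiers <- extract_am_tiers(env)
    keep <- rep(TRUE, length(env$values))
    if (!is.null(energy_threshold_db)) {
      keep <- env$values > max(env$values) * 10^(energy_threshold_db / 20)
    }
    for (p in pairs) {
      a1 <- analytic_phase(tiers[[p$tiers[1]]], tiers$rate, tier = p$tiers[1])
      a2 <- analytic_phase(tiers[[p$tiers[2]]], tiers$rate, tier = p$tiers[2])
      r <- psi(a1$phase[keep], a2$phase[keep], p$n, p$m)
      rows[[length(rows) + 1]] <- data.frame(
        participant = u$participant, group = u$group, sentence = u$sentence,
        metre = u$metre, repetition = u$repetition,
        pair = paste(p$tiers, collapse = ":"), n = p$n, m = p$m,
        psi = r$psi, angle = r$mean_diff_angle, n_samples = r$n_samples)
    }
  }
  if (length(rows) == 0) stop("no included utterances", call. = FALSE)
  tab <- do.call(rbind, rows)
  # per participant x pair x metre: mean PSI, circular mean angle
  agg <- list()
  sp <- split(tab, interaction(tab$participant, tab$pair, tab$metre, drop = TRUE))
  for (s in sp) {
    agg[[length(agg) + 1]] <- data.frame(
      participant = s$participant[1], group = s$group[1], metre = s$metre[1],
      pair = s$pair[1], psi = mean(s$psi),
      angle = circ_mean_resultant(s$angle)$mean_angle,
      diff_resultant = circ_mean_resultant(s$angle)$resultant_length,
      n_utterances = nrow(s))
  }
  agg <- do.call(rbind, agg)
  tests <- list()
  for (pr in unique(agg$pair)) for (m in unique(agg$metre)) {
    sub <- agg[agg$pair == pr & agg$metre == m, ]
    gc <- sub[sub$group == "control", ]; gd <- sub[sub$group == "dyslexic", ]
    if (nrow(gc) < 4 || nrow(gd) < 4) next
    tt <- stats::t.test(gc$psi, gd$psi, var.equal = !welch)
    rc <- rayleigh_test(gc$angle); rd <- rayleigh_test(gd$angle)
    gate <- rc$p < alpha && rd$p < alpha
    ww <- if (gate) watson_williams(list(gc$angle, gd$angle)) else NULL
    tests[[length(tests) + 1]] <- data.frame(
      pair = pr, metre = m,
      psi_control = mean(gc$psi), psi_dyslexic = mean(gd$psi),
      t = unname(tt$statistic), t_p = tt$p.value,
      angle_control = rc$mean_angle, angle_dyslexic = rd$mean_angle,
      rayleigh_p_control = rc$p, rayleigh_p_dyslexic = rd$p,
      ww_F = if (gate) ww$F else NA_real_,
      ww_p = if (gate) ww$p else NA_real_,
      ww_reason = if (gate) "gate open" else "failed phase-locking gate")
  }
  list(per_participant = agg, per_utterance = tab,
       group_tests = if (length(tests)) do.call(rbind, tests) else NULL,
       exclusions = if (length(excl)) do.call(rbind, excl) else NULL)
}
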