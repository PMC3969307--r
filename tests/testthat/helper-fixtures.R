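# shared fixtures and small oracles, all built in code

# absolute circular difference in radians
circ_diff <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))

expect_angle_equal <- function(object, expected, tol) {
  expect_lt(circ_diff(object, expected), tol)
}

# pure sinusoidal tone waveform
tone <- function(f, dur = 2, rate = 1000, amp = 1, phase = 0) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  waveform(amp * cos(2 * pi * f * t + phase), rate, sprintf("tone%g", f))
}

# amplitude-modulated 1 kHz carrier
am_carrier <- function(fm, depth = 1, dur = 2, rate = 8000) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  waveform((1 + depth * cos(2 * pi * fm * t)) * sin(2 * pi * 1000 * t), rate)
}

# in-band fraction of a tier's spectral energy (band edges scaled by
# [lo_scale, hi_scale])
band_energy_fraction <- function(x, rate, band, lo_scale = 0.5, hi_scale = 2) {
  X <- Mod(stats::fft(x - mean(x)))^2
  n <- length(x)
  f <- (seq_len(n) - 1) * rate / n
  half <- f <= rate / 2
  inband <- half & f >= band[1] * lo_scale & f <= band[2] * hi_scale
  sum(X[inband]) / sum(X[half & f > 0])
}

# brute-force circular median over a fine grid (independent oracle)
grid_circ_median_cost <- function(angles, grid = seq(-pi, pi, by = 0.001)) {
  cost <- vapply(grid, function(m) {
    d <- abs(m - angles) %% (2 * pi)
    sum(pi - abs(pi - d))
  }, numeric(1))
  list(grid = grid, cost = cost, min = min(cost))
}

# lean per-seed cohort scoring for Monte-Carlo properties: syllable-tier
# metre scores only, via the package's own selection/phase/median ops
quick_syllable_scores <- function(cohort, metre = "trochaic") {
  tiers <- cohort$stimuli
  sns <- names(cohort$metre_by_sentence)[cohort$metre_by_sentence == metre]
  ids <- cohort$participants$participant
  out <- numeric(length(ids))
  for (i in seq_along(ids)) {
    med <- numeric(0)
    for (sn in sns) {
      tp <- cohort$taps[[paste(ids[i], sn, sep = ".")]]
      sel <- select_analysis_taps(tp, cohort$timing)
      if (length(sel$times) == 0) next
      tt <- sel$times - vapply(sel$times, function(x) {
        max(cohort$timing$repetition_starts[cohort$timing$repetition_starts <= x])
      }, numeric(1))
      ph <- suppressMessages(phase_at_times(tiers[[sn]]$tiers$syllable, tt))
      ph <- ph[is.finite(ph)]
      if (length(ph)) med <- c(med, circ_median(ph))
    }
    out[i] <- if (length(med)) circ_mean_resultant(med)$mean_angle else NA
  }
  data.frame(participant = ids, group = cohort$participants$group,
             score = out)
}
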