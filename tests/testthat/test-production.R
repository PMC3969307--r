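# Experiment-2 pipeline: vowel-onset intervals, PSI, n:m selection,
# heatmaps, utterance segmentation and cross-band group analysis

test_that("vowel_onset_intervals computes the 7 VOIs of an 8-onset utterance", {
  on <- event_series(seq(0, 1.75, by = 0.25), "vowel_onset", participant = "p")
  v <- vowel_onset_intervals(on)
  expect_identical(nrow(v), 7L)
  expect_equal(attr(v, "mean_voi_ms"), 250, tolerance = 1e-9)
  expect_false(attr(v, "onset_count_flag"))

  v2 <- vowel_onset_intervals(event_series(seq(0, 3.5, by = 0.5), "vowel_onset"))
  expect_equal(attr(v2, "mean_voi_ms"), 500, tolerance = 1e-9)

  # hand-checked arithmetic
  on3 <- event_series(c(0, 240, 470, 720, 960, 1210, 1450, 1700) / 1000,
                      "vowel_onset")
  v3 <- vowel_onset_intervals(on3)
  expect_equal(v3$voi_ms, c(240, 230, 250, 240, 250, 240, 250), tolerance = 1e-9)
  expect_equal(attr(v3, "mean_voi_ms"), mean(c(240, 230, 250, 240, 250, 240, 250)),
               tolerance = 1e-9)

  expect_warning(v4 <- vowel_onset_intervals(
    event_series(seq(0, 1.25, by = 0.25), "vowel_onset")), "expected 8")
  expect_identical(nrow(v4), 5L)
  expect_true(attr(v4, "onset_count_flag"))
})

test_that("VOI and ITI agree on identical event lists", {
  times <- c(0, 0.26, 0.50, 0.77, 1.01, 1.24, 1.50, 1.73)
  v <- vowel_onset_intervals(event_series(times, "vowel_onset"))
  i <- inter_tap_intervals(event_series(times, "tap"))
  expect_equal(v$voi_ms, i$iti_ms, tolerance = 1e-12)
})

test_that("psi matches its definition and bounds", {
  t <- seq(0, 10, by = 1e-3)
  p2 <- wrap_phase(2 * pi * 2 * t)
  p4 <- wrap_phase(2 * pi * 4 * t)
  r <- psi(p2, p4, n = 2, m = 1)
  expect_equal(r$psi, 1, tolerance = 1e-9)

  # constant lag pi at 1:1: psi 1, angle at the trough
  r2 <- psi(p2, wrap_phase(p2 - pi), n = 1, m = 1)
  expect_equal(r2$psi, 1, tolerance = 1e-9)
  expect_gt(abs(r2$mean_diff_angle), 0.999 * pi)

  # independent uniform phases: E[psi] ~ sqrt(pi/4)/sqrt(N)
  set.seed(41)
  N <- 100000
  r3 <- psi(runif(N, -pi, pi), runif(N, -pi, pi), 1, 1)
  expect_lt(r3$psi, 0.01)

  expect_error(psi(p2, p4[-1]), "differ in length")
  expect_error(psi(p2[1:10], p4[1:10]), "at least")
})

test_that("psi equals the circular summary of the wrapped differences", {
  set.seed(42)
  p1 <- runif(500, -pi, pi); p2 <- runif(500, -pi, pi)
  r <- psi(p1, p2, n = 3, m = 1)
  s <- circ_mean_resultant(wrap_phase(3 * p1 - p2))
  expect_equal(r$psi, s$resultant_length, tolerance = 1e-12)
  expect_equal(r$mean_diff_angle, s$mean_angle, tolerance = 1e-12)
})

test_that("psi is rotation invariant with the stated angle shift", {
  set.seed(43)
  p1 <- rvonmises(1000, 0, 2); p2 <- wrap_phase(2 * p1 + rvonmises(1000, 0, 5))
  base <- psi(p1, p2, 2, 1)
  c1 <- 0.7; c2 <- -1.2
  shifted <- psi(wrap_phase(p1 + c1), wrap_phase(p2 + c2), 2, 1)
  expect_equal(shifted$psi, base$psi, tolerance = 1e-12)
  expect_angle_equal(shifted$mean_diff_angle,
                     base$mean_diff_angle + 2 * c1 - 1 * c2, 1e-9)
})

test_that("psi recovers the von Mises concentration law", {
  # when the generalised difference is von Mises(mu, kappa), psi estimates
  # I1(kappa)/I0(kappa) and the angle estimates mu
  set.seed(44)
  t <- seq_len(10000)
  for (kappa in c(2, 5)) {
    mu <- 0.9
    base <- runif(10000, -pi, pi)
    d <- rvonmises(10000, mu, kappa)
    p1 <- base
    p2 <- wrap_phase(2 * base - d)   # so 2*p1 - p2 = d
    r <- psi(p1, p2, 2, 1)
    expect_lt(abs(r$psi - besselI(kappa, 1) / besselI(kappa, 0)), 0.02)
    expect_angle_equal(r$mean_diff_angle, mu, 0.02)
  }
})

test_that("select_nm picks the planted coupling ratio", {
  t <- seq(0, 10, by = 1e-3)
  syl <- wrap_phase(2 * pi * 4 * t)
  # 12 Hz phoneme coupled 3:1
  phon12 <- wrap_phase(3 * (2 * pi * 4 * t) - 0.9 * pi)
  s <- select_nm(syl, phon12)
  expect_identical(s$n, 3L)
  expect_identical(s$m, 1L)
  expect_equal(s$psi, 1, tolerance = 1e-9)
  expect_identical(nrow(s$table), 4L)

  # 8 Hz phoneme: winner 2:1
  phon8 <- wrap_phase(2 * (2 * pi * 4 * t) - 0.2)
  expect_identical(select_nm(syl, phon8)$n, 2L)

  # uncoupled noise: near-tied small PSIs with a warning
  set.seed(45)
  expect_warning(s3 <- select_nm(runif(5000, -pi, pi), runif(5000, -pi, pi)),
                 "near-tied")
  expect_lt(s3$psi, 0.1)

  expect_error(select_nm(syl, phon12, candidates = list(c(2, 1))), "2 candidate")
})

test_that("phase_heatmap uses the documented axes, bins and normalisation", {
  t <- seq(0, 60, by = 1e-3)
  syl <- wrap_phase(2 * pi * 4 * t)
  # constant generalised difference 1 pi with n:m = 3:1 -> diagonal mass
  phon <- wrap_phase(3 * syl - pi)
  hm <- phase_heatmap(syl, phon)
  expect_identical(dim(hm$freq), c(24L, 24L))
  expect_equal(diff(hm$x_edges)[1], 2 * pi / 24, tolerance = 1e-12)
  # 2 pi / 24 = 0.0833 pi, printed as 0.08 pi at two decimals
  expect_equal(round(diff(hm$x_edges)[1] / pi, 2), 0.08)
  expect_true(all(abs(colSums(hm$freq) - 100) < 1e-9))
  # the occupied y-bin in each column follows y = wrap(3x - pi): check a
  # few columns directly
  for (cx in c(3, 9, 15, 21)) {
    xc <- (hm$x_edges[cx] + hm$x_edges[cx + 1]) / 2
    yc_expect <- wrap_phase(3 * xc - pi)
    iy <- which.max(hm$freq[, cx])
    yc_got <- (hm$y_edges[iy] + hm$y_edges[iy + 1]) / 2
    expect_angle_equal(yc_got, yc_expect, 0.09 * pi)
  }

  # difference 0.92 pi shifts the mass by ~1 bin (0.92 pi - 1 pi = -0.08 pi,
  # just under the 0.0833 pi bin width, so the per-column argmax moves by
  # one bin in most columns)
  hm2 <- phase_heatmap(syl, wrap_phase(3 * syl - 0.92 * pi))
  shifts <- vapply(1:24, function(cx) {
    d <- which.max(hm2$freq[, cx]) - which.max(hm$freq[, cx])
    ((d + 12) %% 24) - 12  # circular bin shift
  }, numeric(1))
  expect_gt(mean(abs(shifts)), 0.5)
  expect_lt(mean(abs(shifts)), 1.5)

  # independent phases: approximately flat under global normalisation
  set.seed(46)
  hm3 <- phase_heatmap(runif(200000, -pi, pi), runif(200000, -pi, pi),
                       normalise = "global")
  expect_equal(sum(hm3$freq), 100, tolerance = 1e-9)
  expect_lt(max(abs(hm3$freq - 100 / 576)), 0.08)
})

test_that("segment_utterances finds repetitions and classifies timing mode", {
  pr <- synth_production(stimulus_spec(seed = 5), jitter_sd_ms = 0, seed = 5)
  segs <- segment_utterances(pr$waveform, pr$metronome)
  expect_identical(nrow(segs), 5L)
  expect_identical(segs$included, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # 8 syllables at 4 Hz against a 2 Hz metronome: two syllables per beat
  expect_true(all(segs$timing_mode == "two_syllables_per_beat"))
  # segment boundaries near the true repetition windows
  expect_equal(segs$start_s, pr$repetition_windows$start_s, tolerance = 0.15)

  # slow speaker: one syllable per beat, excluded
  pr2 <- synth_production(stimulus_spec(seed = 6), voi_ms = 500, seed = 6)
  segs2 <- segment_utterances(pr2$waveform, pr2$metronome)
  expect_true(all(segs2$timing_mode == "one_syllable_per_beat", na.rm = TRUE))
  expect_false(any(segs2$included))
})

test_that("crossband_phase_analysis recovers planted coupling and nulls", {
  mk_utts <- function(ang_c, ang_d, n_per_group = 5, seed0 = 100) {
    utts <- list()
    k <- 0
    for (g in c("control", "dyslexic")) {
      ang <- if (g == "control") ang_c else ang_d
      for (i in seq_len(n_per_group)) {
        k <- k + 1
        pr <- synth_production(stimulus_spec(seed = seed0 + k),
                               coupling_angle = ang, jitter_sd_ms = 3,
                               n_repetitions = 1, gap_s = 0.2,
                               seed = seed0 + k)
        utts[[k]] <- list(waveform = pr$waveform, participant = sprintf("%s%d", g, i),
                          group = g, sentence = "s1", metre = "trochaic",
                          repetition = 3, included = TRUE)
      }
    }
    utts
  }
  res <- crossband_phase_analysis(mk_utts(0.94 * pi, 0.88 * pi))
  sp <- res$per_participant[res$per_participant$pair == "syllable:phoneme", ]
  # per-participant locking angles recover the planted angles
  ctrl <- sp$angle[sp$group == "control"]; dys <- sp$angle[sp$group == "dyslexic"]
  expect_angle_equal(circ_mean_resultant(ctrl)$mean_angle, 0.94 * pi, 0.05 * pi)
  expect_angle_equal(circ_mean_resultant(dys)$mean_angle, 0.88 * pi, 0.05 * pi)
  # coupled audio keeps a clearly non-zero PSI (the 12 Hz component sits
  # on the phoneme band edge, so perfect locking is not expected; on real
  # recordings PSI values around 0.2 are typical)
  expect_true(all(sp$psi > 0.3))
  gt <- res$group_tests[res$group_tests$pair == "syllable:phoneme", ]
  expect_identical(gt$ww_reason, "gate open")
  # group contrast has the correct sign (controls at a larger angle)
  expect_gt(wrap_phase(gt$angle_control - gt$angle_dyslexic), 0)

  # excluded utterances are logged with reasons
  utts <- mk_utts(pi, pi, n_per_group = 2, seed0 = 300)
  utts[[1]]$included <- FALSE
  utts[[1]]$reason <- "early repetition"
  res2 <- crossband_phase_analysis(utts)
  expect_identical(res2$exclusions$reason, "early repetition")
})
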