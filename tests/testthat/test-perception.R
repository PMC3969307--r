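# Experiment-1 pipeline: tap selection, ITIs, P-centre distances, phase
# scores, group gates, correlations, compass binning

make_trial <- function() trial_timing(2)  # 2 s sentence, 2 s gap, 3 reps

test_that("select_analysis_taps keeps only windows 2-3, one tap per beat", {
  tm <- make_trial()
  # ideal tapping every 500 ms across the whole trial
  taps <- event_series(seq(0, 9.5, by = 0.5), "tap", participant = "p1")
  sel <- select_analysis_taps(taps, tm)
  expect_length(sel$times, 8)
  expect_true(all((sel$times >= 4 & sel$times <= 6) |
                    (sel$times >= 8 & sel$times <= 10)))
  expect_false(attr(sel, "excluded_trial"))

  # taps only in silent gaps: trial excluded
  gap_taps <- event_series(c(2.5, 3.0, 6.5, 7.0), "tap")
  expect_message(sel0 <- select_analysis_taps(gap_taps, tm), "excluded")
  expect_length(sel0$times, 0)
  expect_true(attr(sel0, "excluded_trial"))

  # double tap near one beat: the nearer one is kept
  tt <- c(4.0, 4.5, 4.58, 5.0, 5.5, 8.0, 8.5, 9.0, 9.5)
  sel2 <- select_analysis_taps(event_series(tt, "tap"), tm)
  expect_true(4.5 %in% sel2$times)
  expect_false(4.58 %in% sel2$times)
  expect_length(sel2$times, 8)

  # idempotence
  sel3 <- select_analysis_taps(sel2, tm)
  expect_equal(sel3$times, sel2$times)
})

test_that("inter_tap_intervals computes successive differences in ms", {
  taps <- event_series(c(0, 0.5, 1.0, 1.5), "tap", participant = "p")
  iti <- inter_tap_intervals(taps)
  expect_equal(iti$iti_ms, c(500, 500, 500))
  expect_equal(attr(iti, "mean_iti_ms"), 500)

  # control-like tempo: mean 525 ms
  iti2 <- inter_tap_intervals(event_series(c(0, 0.525, 1.050), "tap"))
  expect_equal(attr(iti2, "mean_iti_ms"), 525)

  # unsorted input violates the event-series invariant upstream
  expect_error(event_series(c(1, 0.5), "tap"), "ascending")

  one <- inter_tap_intervals(event_series(0.3, "tap"))
  expect_identical(nrow(one), 0L)
  expect_true(attr(one, "insufficient_taps"))
})

test_that("pcentre_distances uses the signed tap - onset convention", {
  onsets <- event_series(seq(0, 3.5, by = 0.5), "vowel_onset")
  taps0 <- event_series(seq(0, 3.5, by = 0.5) + 1e-9, "tap")
  d0 <- pcentre_distances(taps0, onsets)
  expect_true(all(abs(d0$distance_ms) < 1e-5))

  # every tap 30 ms late: mean +30 ms (positive = after the onset)
  taps30 <- event_series(seq(0, 3.5, by = 0.5) + 0.030, "tap")
  d30 <- pcentre_distances(taps30, onsets)
  expect_equal(attr(d30, "mean_distance_ms"), 30, tolerance = 1e-9)

  # symmetric early/late cancel
  tsym <- event_series(c(0.5 - 0.02, 1.0 + 0.02), "tap")
  dsym <- pcentre_distances(tsym, onsets)
  expect_equal(attr(dsym, "mean_distance_ms"), 0, tolerance = 1e-9)

  expect_warning(pcentre_distances(taps30, event_series(c(0, 0.5, 1), "vowel_onset")),
                 "not a multiple")
})

test_that("participant_phase_scores recovers planted phases and averages metres", {
  rate <- 1000
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)
  tiers <- list(
    stress = analytic_phase(cos(2 * pi * 2 * t), rate, "stress"),
    syllable = analytic_phase(cos(2 * pi * 4 * t), rate, "syllable"),
    phoneme = analytic_phase(cos(2 * pi * 12 * t), rate, "phoneme"))
  tiers_by_sentence <- list(s1 = tiers, s2 = tiers)
  metre <- c(s1 = "trochaic", s2 = "trochaic")

  # taps at syllable phase +0.40 pi: peaks at 0.25k, +0.40pi -> +50 ms
  tap_t <- seq(0.25, 1.75, by = 0.25) + 0.05
  taps <- list(
    s1 = event_series(tap_t, "tap", participant = "p1", group = "control",
                      sentence = "s1", metre = "trochaic"),
    s2 = event_series(tap_t, "tap", participant = "p1", group = "control",
                      sentence = "s2", metre = "trochaic"))
  sc <- participant_phase_scores(taps, tiers_by_sentence, metre)
  syl <- sc[sc$tier == "syllable", ]
  expect_angle_equal(syl$phase, 0.40 * pi, 0.02 * pi)
  expect_true(syl$locked)
  expect_false(syl$single_sentence)

  # uniformly spread taps are not locked
  taps_u <- list(s1 = event_series(seq(0.05, 1.95, length.out = 16), "tap",
                                   participant = "p2", sentence = "s1"))
  sc_u <- participant_phase_scores(taps_u, tiers_by_sentence, metre)
  expect_false(any(sc_u$locked[sc_u$tier == "syllable"]))
  expect_true(all(sc_u$single_sentence))

  # metre score is the circular mean of the two sentence medians
  taps_mix <- list(
    s1 = event_series(seq(0.25, 1.75, by = 0.25), "tap", participant = "p3",
                      sentence = "s1"),                      # phase 0
    s2 = event_series(seq(0.25, 1.75, by = 0.25) + 0.0625, "tap",
                      participant = "p3", sentence = "s2"))  # phase pi/2
  sc_m <- participant_phase_scores(taps_mix, tiers_by_sentence, metre)
  expect_angle_equal(sc_m$phase[sc_m$tier == "syllable"], pi / 4, 0.03 * pi)

  expect_error(participant_phase_scores(taps, list(s1 = tiers["stress"],
                                                   s2 = tiers["stress"]),
                                        metre), "missing tier")
})

test_that("group_entrainment_tests gates Watson-Williams on both groups locking", {
  set.seed(31)
  mk_scores <- function(ph_c, ph_d, kappa_d = 8) {
    rbind(
      data.frame(participant = sprintf("c%02d", 1:22), group = "control",
                 metre = "trochaic", tier = "syllable",
                 phase = rvonmises(22, ph_c, 8), n_taps = 16, locked = TRUE,
                 single_sentence = FALSE),
      data.frame(participant = sprintf("d%02d", 1:21), group = "dyslexic",
                 metre = "trochaic", tier = "syllable",
                 phase = rvonmises(21, ph_d, kappa_d), n_taps = 16,
                 locked = TRUE, single_sentence = FALSE))
  }
  # both groups concentrated at different angles: gate open, WW computed
  g1 <- group_entrainment_tests(mk_scores(0.40 * pi, 0.09 * pi))
  expect_identical(g1$ww_reason, "gate open")
  expect_false(is.na(g1$ww_F))
  expect_lt(g1$rayleigh_p_control, 0.05)

  # one group uniform: WW suppressed with the gating reason
  sc2 <- mk_scores(0.40 * pi, 0, kappa_d = 0)
  g2 <- group_entrainment_tests(sc2)
  if (g2$rayleigh_p_dyslexic >= 0.05) {
    expect_identical(g2$ww_reason, "failed phase-locking gate")
    expect_true(is.na(g2$ww_p))
  }

  # planted 0.31 pi offset at study-scale n rejects in most runs
  rej <- vapply(1:50, function(i) {
    g <- group_entrainment_tests(mk_scores(0.40 * pi, 0.09 * pi))
    !is.na(g$ww_p) && g$ww_p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.7)
})

test_that("phase_literacy_correlations produces the full 54-cell table", {
  set.seed(32)
  ph <- runif(43, -pi, pi)
  groups <- c(rep("control", 22), rep("dyslexic", 21))
  ids <- sprintf("p%02d", 1:43)
  scores <- do.call(rbind, lapply(c("stress", "syllable", "phoneme"), function(ti)
    do.call(rbind, lapply(c("trochaic", "iambic"), function(m)
      data.frame(participant = ids, group = groups, metre = m, tier = ti,
                 phase = ph, n_taps = 16, locked = TRUE,
                 single_sentence = FALSE)))))
  behaviour <- data.frame(participant = ids,
                          reading = cos(ph) + rnorm(43, 0, 0.1),
                          spelling = rnorm(43),
                          phonology = rnorm(43))
  tab <- phase_literacy_correlations(scores, behaviour)
  expect_identical(nrow(tab), 54L)
  expect_false(attr(tab, "p_adjusted"))
  # planted dependence: reading correlates strongly in the 'all' stratum
  r_read <- tab$r[tab$measure == "reading" & tab$stratum == "all"]
  expect_true(all(r_read > 0.8))
  # independent measure: small r on average
  r_spell <- tab$r[tab$measure == "spelling" & tab$stratum == "all"]
  expect_lt(mean(r_spell), 0.3)

  # participants missing behaviour rows are dropped with a message
  expect_message(
    tab2 <- phase_literacy_correlations(scores, behaviour[-(1:3), ]),
    "dropping")
  expect_true(all(tab2$n[tab2$stratum == "all"] == 40))
})

test_that("compass_histogram bins phases into 14 equal bins", {
  edges <- seq(-pi, pi, length.out = 15)
  centres <- (head(edges, -1) + edges[-1]) / 2
  h <- compass_histogram(centres)
  expect_identical(h$counts, rep(1L, 14))
  expect_equal(diff(h$bin_edges)[1], 2 * pi / 14, tolerance = 1e-12)

  h2 <- compass_histogram(rep(0.3, 9))
  expect_identical(max(h2$counts), 9L)
  expect_identical(sum(h2$counts), 9L)
  # boundary values land in the last (closed) bin
  h3 <- compass_histogram(c(-pi, pi))
  expect_identical(sum(h3$counts), 2L)
})

test_that("delaying all taps rotates tier phase scores and preserves ITIs", {
  rate <- 1000
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)
  tiers <- list(
    stress = analytic_phase(cos(2 * pi * 2 * t), rate, "stress"),
    syllable = analytic_phase(cos(2 * pi * 4 * t), rate, "syllable"),
    phoneme = analytic_phase(cos(2 * pi * 12 * t), rate, "phoneme"))
  metre <- c(s1 = "trochaic")
  base_t <- seq(0.25, 1.5, by = 0.25)
  for (dt in c(0.013, 0.031)) {
    sc0 <- participant_phase_scores(
      list(s1 = event_series(base_t, "tap", participant = "p")),
      list(s1 = tiers), metre)
    sc1 <- participant_phase_scores(
      list(s1 = event_series(base_t + dt, "tap", participant = "p")),
      list(s1 = tiers), metre)
    for (ti in c("stress", "syllable", "phoneme")) {
      f <- c(stress = 2, syllable = 4, phoneme = 12)[[ti]]
      expect_angle_equal(sc1$phase[sc1$tier == ti],
                         sc0$phase[sc0$tier == ti] + 2 * pi * f * dt,
                         0.02 * pi)
    }
    iti0 <- inter_tap_intervals(event_series(base_t, "tap"))
    iti1 <- inter_tap_intervals(event_series(base_t + dt, "tap"))
    expect_equal(iti0$iti_ms, iti1$iti_ms, tolerance = 1e-9)
  }
})

test_that("P-centre distance and syllable phase agree for offset taps", {
  # pure 4 Hz tier; onsets at tier peaks; taps a fixed 30 ms later:
  # mean distance +30 ms and phase 30/250 * 2 pi = +0.24 pi, jointly
  rate <- 1000
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)
  tiers <- list(
    stress = analytic_phase(cos(2 * pi * 2 * t), rate, "stress"),
    syllable = analytic_phase(cos(2 * pi * 4 * t), rate, "syllable"),
    phoneme = analytic_phase(cos(2 * pi * 12 * t), rate, "phoneme"))
  onset_t <- seq(0.25, 1.5, by = 0.25)
  taps <- event_series(onset_t + 0.030, "tap", participant = "p")
  d <- pcentre_distances(taps, event_series(onset_t, "vowel_onset"),
                         expected_per_window = 6)
  expect_equal(attr(d, "mean_distance_ms"), 30, tolerance = 1e-9)
  sc <- participant_phase_scores(list(s1 = taps), list(s1 = tiers),
                                 c(s1 = "trochaic"))
  expect_angle_equal(sc$phase[sc$tier == "syllable"], 0.24 * pi, 0.02 * pi)
})
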