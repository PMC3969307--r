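# Amplitude-modulation hierarchy: envelope demodulation, modulation
# spectrum, three-tier band-pass decomposition and instantaneous phase.

#' Band configuration for the AM hierarchy
#'
#' Pass-bands for the three nested amplitude-modulation tiers. Defaults
#' follow the modulation statistics of metrical English speech: prosodic
#' stress 0.8-2.5 Hz, syllable 2.5-12 Hz, phoneme 12-40 Hz. The stress
#' lower edge is sometimes quoted as 0.9 Hz; use `stress_lo = 0.9` for that
#' convention.
#'
#' @param stress_band,syllable_band,phoneme_band Numeric `(lo, hi)` pairs
#'   in Hz.
#' @param filter_order Butterworth order per pass direction (filtering is
#'   forward-backward, so the effective magnitude response is squared).
#' @return An `am_band_config` object.
#' @export
am_band_config <- function(stress_band = c(0.8, 2.5),
                           syllable_band = c(2.5, 12),
                           phoneme_band = c(12, 40),
                           filter_order = 2) {
  bands <- list(stress = stress_band, syllable = syllable_band,
                phoneme = phoneme_band)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2]) {
      stop(nm, " band must satisfy 0 < lo < hi", call. = FALSE)
    }
  }
  ctr <- vapply(bands, function(b) sqrt(b[1] * b[2]), numeric(1))
  if (is.unsorted(ctr, strictly = TRUE)) {
    stop("band centre frequencies must be ordered stress < syllable < phoneme",
         call. = FALSE)
  }
  structure(c(bands, list(filter_order = as.integer(filter_order))),
            class = "am_band_config")
}

#' Envelope signal container
#'
#' @param values Nonnegative envelope values.
#' @param rate Envelope sampling rate in samples/s.
#' @return An `envelope_signal` object.
#' @export
envelope_signal <- function(values, rate) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty envelope", call. = FALSE)
  if (any(values < -1e-12)) stop("envelope values must be nonnegative", call. = FALSE)
  structure(list(values = pmax(values, 0), rate = rate), class = "envelope_signal")
}

#' Demodulate a waveform into its amplitude envelope
#'
#' Computes the magnitude of the analytic signal (Hilbert envelope),
#' low-pass filters it below the target Nyquist frequency, and resamples to
#' `env_rate`.
#'
#' @param w A [waveform()].
#' @param env_rate Envelope sampling rate in samples/s. Must not exceed
#'   `w$rate` and should be at least twice the highest AM band edge
#'   (>= 80 Hz recommended; the default 1000 Hz keeps phase interpolation
#'   cheap).
#' @param min_band_hi Highest AM band edge the envelope must support;
#'   `env_rate < 2 * min_band_hi` is a configuration error.
#' @return An [envelope_signal()].
#' @examples
#' t <- seq(0, 1, by = 1 / 8000)
#' w <- waveform((1 + cos(2 * pi * 4 * t)) * sin(2 * pi * 1000 * t), 8000)
#' e <- compute_envelope(w, 1000)
#' @export
compute_envelope <- function(w, env_rate = 1000, min_band_hi = 40) {
  stopifnot(inherits(w, "waveform"))
  if (env_rate > w$rate) stop("env_rate exceeds the waveform rate", call. = FALSE)
  if (env_rate < 2 * min_band_hi) {
    stop("env_rate too low for the configured phoneme band (need >= ",
         2 * min_band_hi, " Hz)", call. = FALSE)
  }
  env <- Mod(analytic_signal_fft(w$samples))
  if (env_rate < w$rate) {
    # anti-alias below the new Nyquist, then linear-interpolate onto the grid
    d <- butter_design(4, 0.45 * env_rate, w$rate, "low")
    env <- filtfilt_ba(d$b, d$a, env)
    t_old <- (seq_along(env) - 1) / w$rate
    n_new <- floor(duration(w) * env_rate)
    t_new <- (seq_len(n_new) - 1) / env_rate
    env <- stats::approx(t_old, env, xout = t_new, rule = 2)$y
  }
  envelope_signal(pmax(env, 0), env_rate)
}

#' Envelope modulation spectrum
#'
#' Power spectrum of the mean-removed amplitude envelope, truncated at
#' `fmax`. For metronome-timed 8-syllable sentences the spectrum peaks at
#' the stress (~2 Hz) and syllable (~4 Hz) rates.
#'
#' @param e An [envelope_signal()].
#' @param fmax Upper frequency limit in Hz (must not exceed Nyquist).
#' @return A data frame with columns `freq_hz` and `power`, class
#'   `mod_spectrum`.
#' @export
modulation_spectrum <- function(e, fmax = 20) {
  stopifnot(inherits(e, "envelope_signal"))
  if (fmax <= 0 || fmax > e$rate / 2) {
    stop("fmax must lie in (0, rate/2]", call. = FALSE)
  }
  x <- e$values - mean(e$values)
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * e$rate / n
  keep <- freqs <= fmax
  out <- data.frame(freq_hz = freqs[keep], power = (Mod(X)^2 / n)[keep])
  class(out) <- c("mod_spectrum", "data.frame")
  out
}

#' Extract the three-tier AM hierarchy
#'
#' Zero-phase band-pass filters the mean-removed envelope into stress,
#' syllable and phoneme tiers. Forward-backward Butterworth filtering is
#' used so tier peaks stay aligned with envelope peaks (no group delay).
#'
#' @param e An [envelope_signal()].
#' @param cfg An [am_band_config()].
#' @param spectral_band_index Bookkeeping tag: which acoustic-frequency
#'   band the envelope came from (`"broadband"` when no front-end
#'   decomposition was applied).
#' @return An `am_hierarchy` with elements `stress`, `syllable`, `phoneme`
#'   (numeric tiers at `e$rate`), `rate`, `band_config`,
#'   `spectral_band_index`.
#' @export
extract_am_tiers <- function(e, cfg = am_band_config(),
                             spectral_band_index = "broadband") {
  stopifnot(inherits(e, "envelope_signal"), inherits(cfg, "am_band_config"))
  if (e$rate < 2 * cfg$phoneme[2]) {
    stop("envelope rate below twice the phoneme band edge", call. = FALSE)
  }
  x <- e$values - mean(e$values)
  one <- function(band) {
    d <- butter_design(cfg$filter_order, band, e$rate, "pass")
    padlen <- min(length(x) - 1, ceiling(3 * e$rate / band[1]))
    filtfilt_ba(d$b, d$a, x, padlen = padlen)
  }
  structure(list(stress = one(cfg$stress), syllable = one(cfg$syllable),
                 phoneme = one(cfg$phoneme), rate = e$rate,
                 band_config = cfg,
                 spectral_band_index = spectral_band_index),
            class = "am_hierarchy")
}

#' Instantaneous phase and magnitude of an AM tier
#'
#' Computes the analytic signal of a band-limited tier by the Hilbert
#' transform and returns its wrapped instantaneous phase and magnitude.
#' Phase convention: 0 rad at the oscillatory peak; -pi and +pi both denote
#' the trough.
#'
#' @param tier_values Band-limited, mean-removed numeric tier.
#' @param rate Sampling rate of the tier in samples/s.
#' @param tier Tier label (`"stress"`, `"syllable"` or `"phoneme"`).
#' @param band Optional `(lo, hi)` pass-band in Hz; when given, the first
#'   and last 1.5 cycles of the band's lower edge are flagged as
#'   low-confidence (`edge_guard_s`).
#' @return An `analytic_tier` with `phase` (radians in \[-pi, pi\]),
#'   `magnitude`, `analytic` (complex), `rate`, `tier`, `edge_guard_s`.
#' @export
analytic_phase <- function(tier_values, rate,
                           tier = c("syllable", "stress", "phoneme"),
                           band = NULL) {
  tier <- match.arg(tier)
  tier_values <- as.numeric(tier_values)
  if (length(tier_values) == 0 || all(tier_values == 0)) {
    stop("phase undefined for an all-zero tier", call. = FALSE)
  }
  z <- analytic_signal_fft(tier_values)
  guard <- if (!is.null(band)) 1.5 / band[1] else 0
  structure(list(phase = Arg(z), magnitude = Mod(z), analytic = z,
                 rate = rate, tier = tier, edge_guard_s = guard),
            class = "analytic_tier")
}

#' Instantaneous tier phase at arbitrary times
#'
#' Interpolates the complex analytic signal (not the wrapped phase, which
#' would break at the -pi/pi seam) linearly at the requested times and
#' returns its angle. Out-of-range times yield `NA` and are reported via
#' the `"excluded"` attribute.
#'
#' @param a An [analytic_phase()] result.
#' @param times Numeric vector of times in seconds.
#' @return Numeric vector of phases in \[-pi, pi\] with attributes
#'   `excluded` (indices of out-of-range times) and `low_confidence`
#'   (logical, within the edge guard).
#' @export
phase_at_times <- function(a, times) {
  stopifnot(inherits(a, "analytic_tier"))
  if (length(times) == 0) return(numeric(0))
  dur <- (length(a$analytic) - 1) / a$rate
  bad <- which(times < 0 | times > dur | !is.finite(times))
  t_grid <- (seq_along(a$analytic) - 1) / a$rate
  re <- stats::approx(t_grid, Re(a$analytic), xout = times)$y
  im <- stats::approx(t_grid, Im(a$analytic), xout = times)$y
  ph <- atan2(im, re)
  ph[bad] <- NA_real_
  if (length(bad)) {
    message(length(bad), " event(s) outside the recording were excluded")
  }
  attr(ph, "excluded") <- bad
  attr(ph, "low_confidence") <- times < a$edge_guard_s | times > dur - a$edge_guard_s
  ph
}

#' Oscillatory peak times of an AM tier
#'
#' The method defines a tier's peak as instantaneous phase 0 (and the
#' trough as +/- pi), so peak times are the ascending zero crossings of
#' the wrapped phase. Unlike raw local maxima of the tier signal, these
#' are robust to magnitude ripple from neighbouring-band leakage.
#'
#' @param a An [analytic_phase()] result.
#' @return Numeric vector of peak times in seconds.
#' @export
tier_peaks <- function(a) {
  stopifnot(inherits(a, "analytic_tier"))
  ph <- a$phase
  n <- length(ph)
  # ascending zero crossing: phase goes from negative to positive without
  # wrapping (jump smaller than pi)
  cross <- which(ph[-n] < 0 & ph[-1] >= 0 & (ph[-1] - ph[-n]) < pi)
  if (length(cross) == 0) return(numeric(0))
  frac <- -ph[cross] / (ph[cross + 1] - ph[cross])
  (cross - 1 + frac) / a$rate
}

#' Acoustic-frequency band decomposition (S-AMPH style front end)
#'
#' Splits a waveform into adjacent acoustic-frequency bands before
#' envelope extraction, mimicking a spectral amplitude-modulation phase
#' hierarchy front end. The default is five log-spaced bands spanning
#' 100-7250 Hz. `edges = "broadband"` bypasses the decomposition.
#'
#' @param w A [waveform()].
#' @param edges Ascending band-edge frequencies in Hz (>= 2 values), or
#'   `"broadband"`.
#' @param n_bands Number of log-spaced bands when `edges` is `NULL`.
#' @param f_range Frequency span of the default edges.
#' @return A list of [waveform()] objects, one per band.
#' @export
spectral_band_filter <- function(w, edges = NULL, n_bands = 5,
                                 f_range = c(100, 7250)) {
  stopifnot(inherits(w, "waveform"))
  if (identical(edges, "broadband")) return(list(w))
  if (is.null(edges)) {
    edges <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_bands + 1))
  }
  if (length(edges) < 2) stop("need at least 2 band edges", call. = FALSE)
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be ascending", call. = FALSE)
  if (edges[1] <= 0 || edges[length(edges)] >= w$rate / 2) {
    stop("edges must lie inside (0, rate/2)", call. = FALSE)
  }
  lapply(seq_len(length(edges) - 1), function(i) {
    d <- butter_design(2, c(edges[i], edges[i + 1]), w$rate, "pass")
    waveform(filtfilt_ba(d$b, d$a, w$samples,
                         padlen = min(length(w$samples) - 1,
                                      ceiling(3 * w$rate / edges[i]))),
             w$rate, sprintf("%s[band %d]", w$label, i))
  })
}
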