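# Polynomial with given roots, real coefficients (roots come in conjugate
# pairs; small imaginary residue from arithmetic is dropped).
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  if (max(abs(Im(p))) > 1e-8 * max(abs(p), 1)) {
    warning("polynomial coefficients not numerically real")
  }
  Re(p)
}

#' Butterworth IIR filter design
#'
#' Designs digital Butterworth low-, high- or band-pass filters via the
#' analog prototype and the bilinear transform, returning transfer-function
#' coefficients in the same `b`/`a` convention as Matlab/Octave/scipy.
#'
#' @param n Filter order (for `"pass"` the resulting polynomial order is
#'   `2 * n`).
#' @param w Critical frequency or frequencies in Hz (length 2 for `"pass"`).
#' @param fs Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"pass"`.
#' @return List with numerator `b` and denominator `a` coefficient vectors.
#' @keywords internal
butter_design <- function(n, w, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (n < 1) stop("filter order must be >= 1")
  if (any(w <= 0) || any(w >= fs / 2)) {
    stop("critical frequencies must lie strictly inside (0, fs/2)")
  }
  # analog Butterworth prototype: n poles on the unit circle, no zeros
  k <- seq_len(n)
  pa <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 2
  warped <- 2 * fs2 * tan(pi * (2 * w / fs) / fs2)

  if (type == "low") {
    p <- pa * warped
    z <- complex(0)
    gain <- warped^n
  } else if (type == "high") {
    p <- warped / pa
    z <- rep(0 + 0i, n)
    gain <- 1 / Re(prod(-pa))
  } else {
    if (length(w) != 2) stop("band-pass design needs two edge frequencies")
    bw <- warped[2] - warped[1]
    wo <- sqrt(warped[1] * warped[2])
    ph <- pa * bw / 2
    p <- c(ph + sqrt(ph^2 - wo^2), ph - sqrt(ph^2 - wo^2))
    z <- rep(0 + 0i, n)
    gain <- bw^n
  }

  # bilinear transform s -> 2*fs2*(z-1)/(z+1)
  fs2x2 <- 2 * fs2
  zd <- (fs2x2 + z) / (fs2x2 - z)
  pd <- (fs2x2 + p) / (fs2x2 - p)
  # zeros at infinity map to z = -1
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  gd <- gain * Re(prod(fs2x2 - z) / prod(fs2x2 - p))

  b <- gd * poly_from_roots(zd)
  a <- poly_from_roots(pd)
  list(b = b, a = a)
}

# Direct-form IIR filtering built on stats::filter (C-level loops):
# convolution with b, then the recursive part with -a[-1].
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies an IIR filter forward and backward so the net phase response is
#' zero and the magnitude response is squared. Edge transients are reduced
#' by odd-reflection padding before filtering.
#'
#' @param b,a Transfer-function coefficients as from [butter_design()].
#' @param x Numeric signal.
#' @param padlen Number of samples of odd-reflection padding at each end;
#'   defaults to `3 * (max(length(a), length(b)) - 1)` but should be
#'   increased (several cycles of the lowest frequency of interest) for
#'   narrow low-frequency bands.
#' @return Filtered signal, same length as `x`.
#' @keywords internal
filtfilt_ba <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 3 * (max(length(a), length(b)) - 1)
  padlen <- min(padlen, n - 1)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    xe <- c(pre, x, post)
  } else {
    xe <- x
  }
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}

# Complex frequency response of b/a at frequencies f (Hz) for sample rate fs.
freq_response <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  zi <- exp(-1i * w)
  H <- outer(zi, seq_along(b) - 1, `^`) %*% b /
    (outer(zi, seq_along(a) - 1, `^`) %*% a)
  as.complex(H)
}

# Analytic signal via the FFT Hilbert transform method.
analytic_signal_fft <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
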