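# Circular descriptive statistics and tests. All angles are radians; wrapped
# values live in [-pi, pi] with 0 at the oscillatory peak.

#' Wrap angles to \[-pi, pi\]
#' @param theta Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_phase <- function(theta) {
  out <- atan2(sin(theta), cos(theta))
  out
}

# circular distance between two angles: pi - |pi - |a - b| mod 2pi|
circ_dist_abs <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pi - abs(pi - d)
}

#' Circular mean and resultant length
#'
#' @param angles Angles in radians (n >= 1).
#' @return List of class `circ_summary`: `mean_angle` in \[-pi, pi\],
#'   `resultant_length` in \[0, 1\], `n`.
#' @examples
#' circ_mean_resultant(c(0, pi / 2))  # mean pi/4, R = sqrt(2)/2
#' @export
circ_mean_resultant <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (length(angles) == 0) stop("no angles supplied", call. = FALSE)
  z <- mean(exp(1i * angles))
  structure(list(mean_angle = Arg(z), resultant_length = min(Mod(z), 1),
                 n = length(angles)),
            class = "circ_summary")
}

#' Circular median
#'
#' The angle minimising the summed circular distance to the sample. The
#' objective is piecewise linear with breakpoints at the sample angles and
#' their antipodes, so the exact minimiser is found by evaluating those
#' candidates; ties (within `tol`) are broken by the circular mean of all
#' minimisers.
#'
#' @param angles Angles in radians (n >= 1).
#' @param tol Tie tolerance on the summed distance.
#' @return The circular median in \[-pi, pi\].
#' @export
circ_median <- function(angles, tol = 1e-9) {
  angles <- wrap_phase(angles[is.finite(angles)])
  if (length(angles) == 0) stop("no angles supplied", call. = FALSE)
  if (length(angles) == 1) return(angles)
  cand <- unique(wrap_phase(c(angles, angles + pi)))
  cost <- vapply(cand, function(m) sum(circ_dist_abs(m, angles)), numeric(1))
  winners <- cand[cost <= min(cost) + tol]
  if (length(winners) == 1) return(winners)
  # tie-break: circular mean of minimisers; if they are perfectly
  # antipodal the mean vector vanishes and the first candidate in sample
  # order is returned deterministically.
  s <- circ_mean_resultant(winners)
  if (s$resultant_length < 1e-9) return(winners[1])
  s$mean_angle
}

#' Rayleigh test of circular uniformity
#'
#' Tests a sample of angles for unimodal concentration against the uniform
#' null. The statistic is `z = n * R^2` with `R` the mean resultant
#' length; the p-value uses the standard finite-n approximation.
#'
#' @param angles Angles in radians (n >= 4).
#' @return List of class `rayleigh_test`: `z`, `p`, `n`, `resultant_length`,
#'   `mean_angle`.
#' @export
rayleigh_test <- function(angles) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 4) stop("Rayleigh test needs n >= 4", call. = FALSE)
  s <- circ_mean_resultant(angles)
  R <- n * s$resultant_length
  z <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  structure(list(z = z, p = min(max(p, .Machine$double.xmin), 1), n = n,
                 resultant_length = s$resultant_length,
                 mean_angle = s$mean_angle),
            class = "rayleigh_test")
}

# Fisher's approximation for the inverse of A(kappa) = I1(kappa)/I0(kappa).
kappa_from_r <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal mean directions
#'
#' Circular analogue of the one-way ANOVA. Assumes the samples are drawn
#' from von Mises distributions with a common, reasonably large
#' concentration; when the pooled mean resultant length is below 0.45 the
#' result carries a warning flag rather than an error.
#'
#' @param groups List of >= 2 numeric vectors of angles (each n >= 5).
#' @return List of class `watson_williams`: `F`, `df1`, `df2`, `p`,
#'   `kappa`, `rw` (pooled within-group resultant length), `warning`
#'   (character or `NA`).
#' @export
watson_williams <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  ns <- lengths(groups)
  if (any(ns < 5)) stop("each group needs n >= 5", call. = FALSE)
  k <- length(groups)
  N <- sum(ns)
  Ri <- vapply(groups, function(g) Mod(sum(exp(1i * g))), numeric(1))
  Rall <- Mod(sum(exp(1i * unlist(groups))))
  rw <- sum(Ri) / N
  warn <- NA_character_
  if (rw < 0.45) {
    warn <- "pooled resultant length < 0.45; concentration assumption doubtful"
  }
  kap <- kappa_from_r(rw)
  K <- 1 + 3 / (8 * kap)
  Fstat <- K * ((N - k) * (sum(Ri) - Rall)) / ((k - 1) * (N - sum(Ri)))
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  structure(list(F = Fstat, df1 = as.integer(k - 1), df2 = as.integer(N - k), p = p,
                 kappa = kap, rw = rw, warning = warn),
            class = "watson_williams")
}

#' Circular-linear correlation
#'
#' Correlation between an angular and a linear variable, computed from the
#' pairwise Pearson correlations of `x` with `cos(theta)` and `sin(theta)`:
#' `r = sqrt((rxc^2 + rxs^2 - 2 rxc rxs rcs) / (1 - rcs^2))`. The p-value
#' uses the large-sample chi-squared approximation (`n r^2 ~ chisq(2)`);
#' an optional permutation p-value is available for small samples.
#'
#' @param angles Angles in radians.
#' @param x Linear covariate, same length, nonzero variance.
#' @param n_perm Number of permutations for the optional permutation
#'   p-value (0 to skip).
#' @param seed Seed for the permutation draw.
#' @return List of class `circ_lin_corr`: `r`, `p`, `n`, and `p_perm` when
#'   requested.
#' @export
circ_linear_corr <- function(angles, x, n_perm = 0, seed = 1) {
  keep <- is.finite(angles) & is.finite(x)
  angles <- angles[keep]; x <- x[keep]
  n <- length(angles)
  if (n != length(x)) stop("length mismatch", call. = FALSE)
  if (n < 6) stop("need n >= 6", call. = FALSE)
  if (stats::sd(x) == 0) stop("x has zero variance", call. = FALSE)
  rfun <- function(th, xx) {
    rxc <- stats::cor(xx, cos(th)); rxs <- stats::cor(xx, sin(th))
    rcs <- stats::cor(cos(th), sin(th))
    r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
    sqrt(max(min(r2, 1), 0))
  }
  r <- rfun(angles, x)
  p <- stats::pchisq(n * r^2, df = 2, lower.tail = FALSE)
  out <- list(r = r, p = p, n = n)
  if (n_perm > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    rp <- vapply(seq_len(n_perm), function(i) rfun(angles, sample(x)), numeric(1))
    .Random.seed_restore(old)
    out$p_perm <- (1 + sum(rp >= r)) / (n_perm + 1)
  }
  structure(out, class = "circ_lin_corr")
}

# save/restore the RNG state so helpers with internal seeding do not
# disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Convert a phase difference to a time difference
#'
#' `delta_phase / (2 pi) * 1000 / f` -- e.g. 0.31 pi rad on a 4 Hz cycle is
#' 38.75 ms (~39 ms).
#'
#' @param delta_phase Phase difference in radians.
#' @param f Cycle frequency in Hz (> 0).
#' @return Time difference in milliseconds.
#' @export
phase_to_time <- function(delta_phase, f) {
  if (any(f <= 0)) stop("frequency must be positive", call. = FALSE)
  delta_phase / (2 * pi) * 1000 / f
}

#' von Mises random deviates
#'
#' Best-Fisher rejection sampler; `kappa = 0` gives the circular uniform
#' distribution.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration (>= 0).
#' @return Angles in \[-pi, pi\].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa < 1e-6) return(wrap_phase(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  wrap_phase(mu + out)
}
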