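# Shared numerical helpers.

#' Numerical gradient on a possibly non-uniform grid
#'
#' Second-order central differences in the interior and second-order one-sided
#' stencils at both ends, matching the behaviour of a standard numerical
#' gradient routine on a uniform grid.
#'
#' @param y numeric vector of samples.
#' @param x numeric vector of sample positions (default: unit spacing).
#' @return numeric vector of the same length as `y`.
#' @export
num_gradient <- function(y, x = seq_along(y)) {
  n <- length(y)
  stopifnot(length(x) == n, n >= 3L, all(diff(x) > 0))
  g <- numeric(n)
  # interior: second-order accurate for non-uniform spacing
  for (i in 2:(n - 1L)) {
    hs <- x[i] - x[i - 1L]
    hd <- x[i + 1L] - x[i]
    g[i] <- (hs^2 * y[i + 1L] - hd^2 * y[i - 1L] + (hd^2 - hs^2) * y[i]) /
      (hs * hd * (hs + hd))
  }
  # one-sided second-order stencils at the ends (assumes locally uniform h)
  h1 <- x[2L] - x[1L]
  hn <- x[n] - x[n - 1L]
  g[1L] <- (-3 * y[1L] + 4 * y[2L] - y[3L]) / (2 * h1)
  g[n] <- (3 * y[n] - 4 * y[n - 1L] + y[n - 2L]) / (2 * hn)
  g
}

#' Trapezoidal integration
#' @param x positions, strictly increasing.
#' @param y values at `x`.
#' @return the integral of the piecewise-linear interpolant.
#' @export
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' Minimum-maximum normalization to [0, 1]
#' @param x numeric vector.
#' @return `(x - min) / (max - min)`; errors on zero range.
#' @export
minmax_norm <- function(x) {
  r <- range(x, finite = TRUE)
  if (!is.finite(r[1L]) || r[2L] - r[1L] <= 0) {
    stop("minmax_norm: zero or non-finite range, cannot normalize")
  }
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Windowed-sinc low-pass FIR kernel (Hamming window)
#'
#' Linear-phase type-I FIR; applied centred it is zero-phase.
#'
#' @param cutoff_hz cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (kernel has `order + 1` taps; must be even).
#' @return numeric kernel of length `order + 1`, summing to 1.
#' @export
fir_lowpass_kernel <- function(cutoff_hz, fs, order = 60L) {
  stopifnot(order %% 2L == 0L, cutoff_hz > 0, cutoff_hz < fs / 2)
  m <- order
  n <- 0:m
  fc <- cutoff_hz / fs                   # cycles per sample
  centred <- n - m / 2
  h <- ifelse(centred == 0, 2 * pi * fc, sin(2 * pi * fc * centred) / centred)
  w <- 0.54 - 0.46 * cos(2 * pi * n / m) # Hamming
  h <- h * w
  h / sum(h)
}

#' Zero-phase FIR filtering
#'
#' Convolves with a symmetric kernel, centre-aligned, with edge replication
#' padding so the output has the input length and no group delay.
#'
#' @param x signal.
#' @param kernel symmetric odd-length kernel (see [fir_lowpass_kernel()]).
#' @return filtered signal, same length as `x`.
#' @export
filter_zero_phase <- function(x, kernel) {
  k <- length(kernel)
  stopifnot(k %% 2L == 1L)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::convolve(xp, rev(kernel), type = "filter"))
}

#' Canonical double-gamma hemodynamic response function
#'
#' Peak at 6 s, undershoot at 16 s, undershoot ratio 1/6; unit peak.
#'
#' @param t time points in seconds.
#' @return HRF samples at `t`.
#' @export
hrf_double_gamma <- function(t) {
  a1 <- 6; a2 <- 16; b <- 1; ratio <- 1 / 6
  h <- stats::dgamma(t, shape = a1, rate = b) -
    ratio * stats::dgamma(t, shape = a2, rate = b)
  h[t < 0] <- 0
  h / max(h)
}

# internal: convolve a stimulus time course with the HRF at sampling dt
convolve_hrf <- function(stim, dt) {
  t <- seq(0, 32, by = dt)
  h <- hrf_double_gamma(t)
  full <- stats::convolve(stim, rev(h), type = "open")
  full[seq_along(stim)] * dt
}
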