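# Digital Butterworth band-pass design and zero-phase (double-pass) filtering.
# Design route: analog low-pass prototype poles -> low-pass-to-band-pass
# transform -> bilinear transform with frequency prewarping.  Coefficients
# are validated in the test suite against an independently computed
# reference design.

poly_from_roots <- function(r) {
  # expand prod(z - r_k); returns real coefficients (roots in conj pairs)
  p <- 1 + 0i
  for (rk in r) p <- c(p, 0) - c(0, p * rk)
  Re(p)
}

#' Design a digital Butterworth band-pass filter
#'
#' Returns the `b`/`a` transfer-function coefficients of a Butterworth
#' band-pass filter of prototype order `order` (the resulting transfer
#' function has order `2 * order`), discretized with the bilinear transform
#' and frequency prewarping.  The default (order 2, 20--400 Hz) is the
#' standard surface-EMG analysis band.
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Prototype (per-edge) order; default 2.
#' @return List with numeric vectors `b` and `a` (`a[1] == 1`).
#' @export
butter_bandpass <- function(low_hz, high_hz, fs, order = 2) {
  if (!(is.numeric(low_hz) && is.numeric(high_hz) && is.numeric(fs))) {
    stop("band edges and fs must be numeric", call. = FALSE)
  }
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("require 0 < low_hz < high_hz < fs/2 (Nyquist)", call. = FALSE)
  }
  n <- as.integer(order)
  stopifnot(n >= 1)
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # prewarped analog band edges
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each prototype pole maps to a pair
  ps <- p_proto * bw / 2
  disc <- sqrt(ps^2 - w0^2 + 0i)
  poles_a <- c(ps + disc, ps - disc)
  zeros_a <- rep(0 + 0i, n)          # n analog zeros at s = 0
  gain_a <- bw^n
  # bilinear transform s -> 2*fs*(z-1)/(z+1)
  fs2 <- 2 * fs
  poles_z <- (fs2 + poles_a) / (fs2 - poles_a)
  zeros_z <- (fs2 + zeros_a) / (fs2 - zeros_a)
  # degree mismatch adds (2n - n) zeros at z = -1
  zeros_z <- c(zeros_z, rep(-1 + 0i, length(poles_a) - length(zeros_a)))
  gain_z <- gain_a * Re(prod(fs2 - zeros_a) / prod(fs2 - poles_a))
  b <- gain_z * poly_from_roots(zeros_z)
  a <- poly_from_roots(poles_z)
  list(b = b / a[1], a = a / a[1])
}

#' Squared magnitude of the double-pass filter response
#'
#' Evaluates `|H(e^{i 2 pi f / fs})|^2`, the effective amplitude gain of
#' forward-backward (zero-phase) filtering, at frequencies `f_hz`.
#'
#' @param coef List with `b`, `a` as from [butter_bandpass()].
#' @param f_hz Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of double-pass gains.
#' @export
filter_gain_double_pass <- function(coef, f_hz, fs) {
  vapply(f_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    zp <- z^(seq_along(coef$b) - 1)
    h <- sum(coef$b * zp) / sum(coef$a * z^(seq_along(coef$a) - 1))
    Mod(h)^2
  }, numeric(1))
}

# Direct-form II transposed IIR filtering, single pass, zero initial
# conditions (compiled kernel).
iir_filter <- function(b, a, x) {
  iir_filter_cpp(b, a, x)
}

#' Zero-phase (forward-backward) filtering of one signal
#'
#' Applies the filter forward, reverses, applies it again, and reverses
#' back, giving zero net phase shift and the squared magnitude response.
#' Edge transients are mitigated by odd (point-reflected) extension of the
#' signal at both ends before filtering, as is standard practice.
#'
#' @param coef List with `b`, `a` coefficient vectors.
#' @param x Numeric signal vector.
#' @param pad_len Extension length in samples at each end (default 250,
#'   several times the filter's longest time constant at the default
#'   20 Hz edge and 2 kHz sampling).
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_signal <- function(coef, x, pad_len = 250L) {
  filtfilt_cpp(coef$b, coef$a, x, as.integer(pad_len))
}
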