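#' @useDynLib trunkgait, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Remove mean and best-fit linear trend from a signal
#'
#' @param x numeric vector.
#' @return numeric vector of the same length with the least-squares linear
#'   trend (intercept and slope) removed.
#' @keywords internal
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) return(x - mean(x))
  t <- seq_len(n)
  t_c <- t - mean(t)
  slope <- sum(t_c * x) / sum(t_c^2)
  x - mean(x) - slope * t_c
}

#' Design a windowed-sinc low-pass FIR filter
#'
#' Linear-phase type-I FIR (odd length \code{order + 1}), Hamming window.
#'
#' @param order filter order (even; taps = order + 1).
#' @param cutoff cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return numeric vector of \code{order + 1} coefficients summing to ~1.
#' @keywords internal
fir_lowpass_design <- function(order, cutoff, fs) {
  stopifnot(order %% 2L == 0L, cutoff > 0, cutoff < fs / 2)
  m <- order
  n <- 0:m
  fc <- cutoff / fs                      # normalized (cycles/sample)
  h <- 2 * fc * sinc_(2 * fc * (n - m / 2))
  w <- 0.54 - 0.46 * cos(2 * pi * n / m) # Hamming
  h <- h * w
  h / sum(h)                             # unit DC gain
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Apply a linear-phase FIR filter with group-delay compensation
#'
#' Convolves and shifts back by \code{(length(h)-1)/2} samples so that the
#' output is time-aligned with the input (zero phase for symmetric taps).
#' Edges are padded by reflection to suppress transients.
#'
#' @param x signal.
#' @param h FIR coefficients (odd length, symmetric).
#' @return filtered signal, same length as \code{x}.
#' @keywords internal
fir_apply_zerophase <- function(x, h) {
  n <- length(x)
  d <- (length(h) - 1L) %/% 2L
  if (n <= 2L * d) stop("signal too short for FIR filter (need > ", 2L * d,
                        " samples, got ", n, ")", call. = FALSE)
  # reflect-pad both ends by the group delay
  xp <- c(rev(x[2:(d + 1L)]), x, rev(x[(n - d):(n - 1L)]))
  y <- stats::filter(xp, h, method = "convolution", sides = 2L)
  as.numeric(y[(d + 1L):(d + n)])
}

#' Zero-phase low-pass Butterworth filter (frequency-domain)
#'
#' Applies the squared magnitude response of an analog Butterworth prototype,
#' \eqn{|H(f)|^2 = 1 / (1 + (f/f_c)^{2n})}, via FFT. Zero phase by
#' construction; the squared magnitude matches a forward-backward
#' (\code{filtfilt}) application of the same order filter up to edge
#' transients, which reflection padding suppresses.
#'
#' @param x signal.
#' @param fs sampling rate (Hz).
#' @param cutoff cutoff frequency (Hz), must be < fs/2.
#' @param order filter order n (default 4).
#' @return filtered signal, same length.
#' @keywords internal
butter_lowpass_zerophase <- function(x, fs, cutoff, order = 4L) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  n <- length(x)
  pad <- min(n - 1L, max(32L, round(fs)))  # ~1 s reflection padding
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  np <- length(xp)
  f <- c(0:(np %/% 2), -((np - np %/% 2 - 1):1)) * (fs / np)
  gain <- 1 / (1 + (abs(f) / cutoff)^(2 * order))  # |H|^2 of order-n filter
  y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / np
  y[(pad + 1L):(pad + n)]
}

#' Continuous wavelet transform with a Gaussian first-derivative wavelet
#'
#' Single-scale CWT using the gaus1 mother wavelet
#' \eqn{\psi(t) = -t e^{-t^2/2}} (first derivative of a Gaussian).
#' Convolving a signal with gaus1 at scale \eqn{s} yields a smoothed
#' derivative: for slowly varying f, the output is proportional to
#' \eqn{-f'(t)} smoothed by a Gaussian of width \eqn{s}.
#'
#' @param x signal.
#' @param scale wavelet scale in samples.
#' @return numeric vector, same length as x.
#' @keywords internal
cwt_gauss1 <- function(x, scale = 9) {
  half <- ceiling(5 * scale)
  t <- (-half):half
  u <- t / scale
  psi <- -u * exp(-u^2 / 2)
  psi <- psi / sqrt(scale)             # L2-style scale normalization
  n <- length(x)
  if (n <= 2L * half) stop("signal too short for CWT at scale ", scale,
                           call. = FALSE)
  xp <- c(rev(x[2:(half + 1L)]), x, rev(x[(n - half):(n - 1L)]))
  y <- stats::filter(xp, rev(psi), method = "convolution", sides = 2L)
  as.numeric(y[(half + 1L):(half + n)])
}

#' Cumulative trapezoidal integral
#'
#' @param x samples; @param dt sample spacing.
#' @return vector of the same length; first element 0.
#' @keywords internal
cumtrapz_ <- function(x, dt) {
  n <- length(x)
  c(0, cumsum((x[-1] + x[-n]) / 2)) * dt
}

#' Trapezoidal integral
#' @keywords internal
trapz_ <- function(y, dt) sum((y[-1] + y[-length(y)]) / 2) * dt

#' Central-difference derivative
#'
#' Central differences in the interior, one-sided at the ends.
#' @keywords internal
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples for a derivative", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}
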