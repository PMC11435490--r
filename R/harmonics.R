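#' Stride-locked harmonic spectrum
#'
#' Amplitudes of the first \code{n_harmonics} harmonics of the stride
#' frequency, computed by discrete Fourier transform on the exact stride
#' window (no zero padding, no tapering), so the harmonics sit exactly on
#' frequency bins. For a window of N samples, the amplitude of harmonic k
#' is \eqn{2 |X_k| / N} where \eqn{X_k} is the DFT coefficient at k cycles
#' per window; a pure tone \eqn{\sin(2\pi k t/T)} of unit amplitude thus
#' yields \eqn{A_k = 1}.
#'
#' @param x acceleration samples within one stride window.
#' @param n_harmonics number of harmonics (default 20).
#' @return numeric vector of harmonic amplitudes \code{A_1..A_n}.
#' @export
stride_spectrum <- function(x, n_harmonics = 20L) {
  n <- length(x)
  if (n < 40L)
    stop("stride window shorter than 40 samples", call. = FALSE)
  if (n_harmonics >= n / 2)
    stop("stride too short for ", n_harmonics, " harmonics", call. = FALSE)
  X <- stats::fft(x - mean(x))
  2 * Mod(X[2:(n_harmonics + 1L)]) / n
}

#' Harmonic ratio of one stride spectrum
#'
#' For the anterior-posterior and vertical axes, the ratio of the summed
#' even-harmonic amplitudes to the summed odd-harmonic amplitudes (the
#' first ten of each); the convention flips for the medio-lateral axis,
#' whose fundamental period during gait is the stride, making odd harmonics
#' the "in-phase" content. Higher values indicate a more symmetric gait.
#' The denominator is floored at 1e-12 and the result capped at 1e6 so
#' degenerate spectra stay finite.
#'
#' @param amplitudes spectrum from [stride_spectrum()] (length >= 20).
#' @param axis "AP", "V", or "ML".
#' @return scalar harmonic ratio.
#' @export
#' @examples
#' a <- numeric(20); a[1] <- 1; a[2] <- 2
#' harmonic_ratio(a, "V")   # 2.0
#' harmonic_ratio(a, "ML")  # 0.5
harmonic_ratio <- function(amplitudes, axis = c("V", "ML", "AP")) {
  axis <- match.arg(axis)
  if (length(amplitudes) < 20L || any(amplitudes < 0))
    stop("need >= 20 nonnegative harmonic amplitudes", call. = FALSE)
  even <- sum(amplitudes[seq(2L, 20L, by = 2L)])
  odd <- sum(amplitudes[seq(1L, 19L, by = 2L)])
  r <- if (axis == "ML") odd / max(even, 1e-12) else even / max(odd, 1e-12)
  min(r, 1e6)
}

#' Harmonic ratios of a walk
#'
#' Applies the 20 Hz noise filter to each axis (direction per config),
#' computes the per-stride harmonic ratios over the retained stride
#' windows, and averages them.
#'
#' @param trace an [accel_trace()].
#' @param events a [gait_events()] object for the same walk.
#' @param config a [trunkgait_config()].
#' @return list of class \code{hr_result}: per-axis mean and SD of the
#'   per-stride harmonic ratios, plus the per-stride values.
#' @export
walk_hr <- function(trace, events, config = trunkgait_config()) {
  win <- events$stride_windows
  if (nrow(win) < config$min_strides)
    stop("insufficient-strides error for harmonic ratios", call. = FALSE)
  filt <- function(x) {
    if (config$hr_filter_direction == "lowpass")
      butter_lowpass_zerophase(x, trace$fs, config$hr_cutoff, order = 4L)
    else x - butter_lowpass_zerophase(x, trace$fs, config$hr_cutoff,
                                      order = 4L)
  }
  axes <- list(ap = filt(trace$ap), ml = filt(trace$ml), v = filt(trace$v))
  conv <- c(ap = "AP", ml = "ML", v = "V")
  per_stride <- list(ap = numeric(0), ml = numeric(0), v = numeric(0))
  skipped <- 0L
  for (i in seq_len(nrow(win))) {
    i0 <- round(win$start[i] * trace$fs) + 1L
    i1 <- round(win$end[i] * trace$fs)      # exclusive of next stride start
    if (i1 - i0 + 1L < 40L) {
      warning("stride ", i, " shorter than 40 samples; skipped")
      skipped <- skipped + 1L
      next
    }
    for (ax in names(axes)) {
      amps <- stride_spectrum(axes[[ax]][i0:i1], config$n_harmonics)
      per_stride[[ax]] <- c(per_stride[[ax]],
                            harmonic_ratio(amps, conv[[ax]]))
    }
  }
  if (!length(per_stride$v))
    stop("empty-result error: all strides skipped", call. = FALSE)
  structure(list(
    hr_ap = mean(per_stride$ap), hr_ml = mean(per_stride$ml),
    hr_v = mean(per_stride$v),
    hr_ap_sd = stats::sd(per_stride$ap), hr_ml_sd = stats::sd(per_stride$ml),
    hr_v_sd = stats::sd(per_stride$v),
    per_stride = per_stride, n_strides = length(per_stride$v),
    n_skipped = skipped), class = "hr_result")
}

#' @export
print.hr_result <- function(x, ...) {
  cat(sprintf(
    "harmonic ratios over %d strides: V %.2f (%.2f)  ML %.2f (%.2f)  AP %.2f (%.2f)\n",
    x$n_strides, x$hr_v, x$hr_v_sd, x$hr_ml, x$hr_ml_sd, x$hr_ap,
    x$hr_ap_sd))
  invisible(x)
}
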