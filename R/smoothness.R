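#' Log-dimensionless jerk of an acceleration profile
#'
#' Scale-free (negative) smoothness measure of an acceleration segment:
#' \deqn{\lambda = -\ln\left[\frac{t_2 - t_1}{a_{peak}^2}
#'   \int_{t_1}^{t_2} \left(\frac{da}{dt}\right)^2 dt\right]}
#' with \eqn{a_{peak} = \max |a(t)|} over the segment. The derivative is
#' taken by central differences and the integral by the trapezoid rule.
#' Values closer to zero indicate smoother movement. The signal is low-pass
#' filtered (zero-phase Butterworth, 20 Hz, order 4 by default) before
#' differentiation unless \code{filter = FALSE}.
#'
#' @param a acceleration samples (m/s^2).
#' @param fs sampling rate (Hz).
#' @param t1,t2 segment start/stop (s) relative to the first sample
#'   (defaults: whole signal).
#' @param cutoff,order smoothness-filter parameters.
#' @param filter apply the low-pass filter (default TRUE).
#' @return scalar, dimensionless.
#' @export
#' @examples
#' fs <- 1000; t <- seq(0, 2, by = 1 / fs)
#' ldlj(sin(2 * pi * t), fs, filter = FALSE)  # closed form: -4.369
ldlj <- function(a, fs, t1 = 0, t2 = (length(a) - 1) / fs, cutoff = 20,
                 order = 4L, filter = TRUE) {
  if (t2 <= t1) stop("t2 must exceed t1", call. = FALSE)
  if (filter) a <- butter_lowpass_zerophase(a, fs, cutoff, order)
  i0 <- round(t1 * fs) + 1L
  i1 <- round(t2 * fs) + 1L
  i1 <- min(i1, length(a))
  seg <- a[i0:i1]
  a_peak <- max(abs(seg))
  if (a_peak == 0)
    stop("degenerate-signal error: zero acceleration segment",
         call. = FALSE)
  jerk <- central_diff(seg, 1 / fs)
  -log((t2 - t1) / a_peak^2 * trapz_(jerk^2, 1 / fs))
}

#' Temporal symmetry index
#'
#' Percent difference of a gait parameter between the paretic and
#' non-paretic side, normalized by the side mean:
#' \deqn{SI = \frac{V_p - V_{np}}{0.5 (V_p + V_{np})} \times 100.}
#' Zero for perfect symmetry; antisymmetric under side swap; bounded by
#' \eqn{\pm 200}.
#'
#' @param v_paretic,v_nonparetic mean parameter values (s), both > 0.
#' @return percent.
#' @export
#' @examples
#' symmetry_index(0.6, 0.4)  # 40
symmetry_index <- function(v_paretic, v_nonparetic) {
  if (any(c(v_paretic, v_nonparetic) <= 0))
    stop("domain error: symmetry index requires positive durations",
         call. = FALSE)
  (v_paretic - v_nonparetic) / (0.5 * (v_paretic + v_nonparetic)) * 100
}

#' Smoothness and symmetry indexes of a walk
#'
#' LDLJ per axis over the retained-stride span (first retained initial
#' contact to last), and the four temporal symmetry indexes (stance,
#' swing, double support, single support). For healthy subjects (no
#' paretic side) the symmetry indexes are omitted with a warning.
#'
#' @param trace an [accel_trace()].
#' @param events a [gait_events()] object.
#' @param temporal a [temporal_parameters()] result.
#' @param config a [trunkgait_config()].
#' @return list: \code{ldlj_v/ml/ap} and \code{si_stance, si_swing,
#'   si_double, si_single} (NA for subjects without a paretic side).
#' @export
walk_smoothness_symmetry <- function(trace, events, temporal,
                                     config = trunkgait_config()) {
  t1 <- min(events$stride_windows$start)
  t2 <- max(events$stride_windows$end)
  out <- list(
    ldlj_ap = ldlj(trace$ap, trace$fs, t1, t2, cutoff = config$ldlj_cutoff,
                   order = config$ldlj_order),
    ldlj_ml = ldlj(trace$ml, trace$fs, t1, t2, cutoff = config$ldlj_cutoff,
                   order = config$ldlj_order),
    ldlj_v = ldlj(trace$v, trace$fs, t1, t2, cutoff = config$ldlj_cutoff,
                  order = config$ldlj_order))
  if (is.null(temporal[["paretic"]])) {
    warning("no paretic side: symmetry indexes omitted")
    out[c("si_stance", "si_swing", "si_double", "si_single")] <- NA_real_
  } else {
    p <- temporal[["paretic"]]; np <- temporal[["nonparetic"]]
    out$si_stance <- symmetry_index(p[["stance"]], np[["stance"]])
    out$si_swing <- symmetry_index(p[["swing"]], np[["swing"]])
    out$si_double <- symmetry_index(p[["double_support"]],
                                    np[["double_support"]])
    out$si_single <- symmetry_index(p[["single_support"]],
                                    np[["single_support"]])
  }
  out
}
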