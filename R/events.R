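#' Preprocess the vertical acceleration for event detection
#'
#' Removes mean and linear trend, then low-pass filters with a linear-phase
#' FIR (Hamming windowed-sinc) applied with group-delay compensation so
#' event times are unbiased.
#'
#' @param v vertical acceleration samples (m/s^2).
#' @param fs sampling rate (Hz).
#' @param cutoff low-pass cutoff (Hz), default 3.2.
#' @param order FIR order, default 128.
#' @return filtered, zero-mean signal of the same length.
#' @export
preprocess_vertical <- function(v, fs, cutoff = 3.2, order = 128L) {
  if (length(v) < 4L * order)
    stop("length error: signal shorter than 4 x FIR order", call. = FALSE)
  if (cutoff >= fs / 2) stop("cutoff must be < fs/2", call. = FALSE)
  h <- fir_lowpass_design(order, cutoff, fs)
  fir_apply_zerophase(detrend_linear(v), h)
}

# Detection signal: numerically integrate the filtered vertical acceleration,
# then differentiate with a Gaussian first-derivative CWT (scale 9 at
# 100 Hz). The chain amounts to Gaussian smoothing of the acceleration with
# a sign flip from the wavelet convention; initial contacts sit at the
# extrema between zero-crossings.
detection_signal <- function(pre, fs, scale = 9, polarity = "negative") {
  integ <- detrend_linear(cumtrapz_(pre, 1 / fs))
  d1 <- cwt_gauss1(integ, scale = scale)
  if (polarity == "negative") d1 else -d1
}

#' Detect initial contacts from preprocessed vertical acceleration
#'
#' The filtered signal is numerically integrated and differentiated with a
#' Gaussian continuous wavelet transform (gaus1, scale 9). Initial contacts
#' are the dominant extrema of this signal between successive
#' zero-crossings, one per step; shallow lobes are rejected against the
#' median lobe depth, events closer than half a step are merged, and events
#' within half a mean step of the trace edges are discarded.
#'
#' @param pre output of [preprocess_vertical()].
#' @param fs sampling rate (Hz).
#' @param config a [trunkgait_config()] (wavelet scale, polarity).
#' @return list with \code{ic_idx} (sample indices) and \code{ic_times} (s).
#' @export
detect_initial_contacts <- function(pre, fs, config = trunkgait_config()) {
  s <- detection_signal(pre, fs, scale = config$cwt_scale,
                        polarity = config$ic_polarity)
  if (stats::sd(s) == 0)
    stop("insufficient-gait error: flat detection signal", call. = FALSE)
  sgn <- sign(s)
  sgn[sgn == 0] <- 1
  cross <- which(diff(sgn) != 0)
  if (length(cross) < 5L)
    stop("insufficient-gait error: fewer than 5 zero-crossings",
         call. = FALSE)
  # negative lobes of s (ICs are minima after polarity normalization)
  bounds <- c(0L, cross, length(s))
  cand_idx <- integer(0); cand_depth <- numeric(0)
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i] + 1L; hi <- bounds[i + 1L]
    seg <- s[lo:hi]
    if (min(seg) < 0) {
      k <- lo - 1L + which.min(seg)
      cand_idx <- c(cand_idx, k)
      cand_depth <- c(cand_depth, -s[k])
    }
  }
  keep <- cand_depth >= 0.25 * stats::median(cand_depth)
  cand_idx <- cand_idx[keep]; cand_depth <- cand_depth[keep]
  if (length(cand_idx) >= 3L) {
    # merge events closer than half the median inter-event interval
    med_step <- stats::median(diff(cand_idx))
    i <- 2L
    while (i <= length(cand_idx)) {
      if (cand_idx[i] - cand_idx[i - 1L] < 0.5 * med_step) {
        drop <- if (cand_depth[i] < cand_depth[i - 1L]) i else i - 1L
        cand_idx <- cand_idx[-drop]; cand_depth <- cand_depth[-drop]
      } else i <- i + 1L
    }
  }
  if (length(cand_idx) >= 3L) {
    # discard events within half a mean step of either edge
    med_step <- mean(diff(cand_idx))
    ok <- cand_idx > 0.5 * med_step &
      cand_idx <= length(s) - 0.5 * med_step
    cand_idx <- cand_idx[ok]
  }
  if (length(cand_idx) < 5L)
    stop("insufficient-gait error: fewer than 5 steps detected",
         call. = FALSE)
  iv <- diff(cand_idx)
  # gait step intervals are highly regular (CV <~ 0.25 even with marked
  # timing asymmetry); low-pass filtered noise produces CV >~ 0.35
  if (stats::sd(iv) / mean(iv) > 0.3)
    stop("insufficient-gait error: irregular step intervals (CV > 0.3)",
         call. = FALSE)
  list(ic_idx = cand_idx,
       ic_times = (cand_idx - 1L + parabolic_offset(s, cand_idx)) / fs)
}

# sub-sample refinement of an extremum by parabolic interpolation
parabolic_offset <- function(x, idx) {
  vapply(idx, function(k) {
    if (k <= 1L || k >= length(x)) return(0)
    den <- x[k - 1L] - 2 * x[k] + x[k + 1L]
    if (den == 0) return(0)
    max(-0.5, min(0.5, 0.5 * (x[k - 1L] - x[k + 1L]) / den))
  }, 0)
}

#' Assign left/right labels to initial contacts
#'
#' Labels alternate between feet; the polarity (which foot starts) is chosen
#' from the sign of the medio-lateral acceleration averaged over a short
#' window after each contact, under the convention that positive ML after an
#' initial contact marks a left step. If fewer than 80\% of steps match a
#' strict alternation, a side-ambiguity warning is raised and labels fall
#' back to alternation from the first step (left first).
#'
#' @param ic_idx initial-contact sample indices.
#' @param ml medio-lateral acceleration samples.
#' @param fs sampling rate (Hz).
#' @return character vector of "left"/"right", one per contact.
#' @export
assign_sides <- function(ic_idx, ml, fs) {
  n <- length(ic_idx)
  if (n < 2L) stop("need at least 2 initial contacts", call. = FALSE)
  win <- max(1L, round(0.15 * fs * stats::median(diff(ic_idx)) / fs))
  ml0 <- ml - mean(ml)
  obs <- vapply(ic_idx, function(k) {
    mean(ml0[k:min(length(ml0), k + win)])
  }, 0)
  hyp_left_first <- rep_len(c(1, -1), n)      # +ML = left
  score <- mean(sign(obs) == hyp_left_first)
  best <- if (score >= 0.5) "left" else "right"
  agreement <- max(score, 1 - score)
  if (all(abs(obs) < 1e-12)) agreement <- 0   # flat ML carries no side cue
  if (agreement < 0.8) {
    warning("side-ambiguity: ML polarity non-alternating in ",
            sprintf("%.0f%%", 100 * (1 - agreement)),
            " of steps; assigning by strict alternation from the first step")
    best <- "left"
  }
  if (best == "left") rep_len(c("left", "right"), n)
  else rep_len(c("right", "left"), n)
}

#' Detect final contacts between successive initial contacts
#'
#' Toe-off (push-off) produces a brief high-frequency transient in the
#' vertical trunk acceleration, well above the locomotor harmonics. The
#' detector band-passes the raw vertical axis around the expected
#' transient band (centred on \code{fc_harmonic} times the stride
#' frequency estimated from the initial contacts, half-width
#' \code{fc_bw} Hz), takes the smoothed envelope, and places one final
#' contact at the envelope peak in the first 55\% of each inter-IC
#' interval (double support is ~10-35\% of a step). The contact found
#' between \eqn{IC_j} and \eqn{IC_{j+1}} ends the stance of the foot
#' opposite to \eqn{IC_j}. Intervals whose envelope peak does not rise
#' above 1.5x the interval median yield no contact (the affected stride is
#' later dropped).
#'
#' @param v raw vertical acceleration samples.
#' @param fs sampling rate (Hz).
#' @param ic_idx initial-contact sample indices.
#' @param config a [trunkgait_config()].
#' @return list with \code{fc_idx}, \code{fc_times}, and \code{after_ic}
#'   (index into \code{ic_idx} of the interval each FC falls in).
#' @export
detect_final_contacts <- function(v, fs, ic_idx,
                                  config = trunkgait_config()) {
  stride_est <- 2 * stats::median(diff(ic_idx)) / fs
  f0 <- config$fc_harmonic / stride_est
  hi_cut <- min(f0 + config$fc_bw, 0.45 * fs)
  lo_cut <- max(f0 - config$fc_bw, 2)
  bp <- butter_lowpass_zerophase(v - mean(v), fs, hi_cut, order = 4L) -
    butter_lowpass_zerophase(v - mean(v), fs, lo_cut, order = 4L)
  # smoothed envelope (Gaussian RMS, SD 15 ms: wide enough to remove the
  # carrier's double-frequency ripple, which otherwise biases the peak)
  half <- max(2L, round(0.015 * fs) * 3L)
  kern <- exp(-0.5 * ((-half):half / (0.015 * fs))^2)
  kern <- kern / sum(kern)
  n <- length(bp)
  xp <- c(rev(bp[2:(half + 1L)]^2), bp^2, rev(bp[(n - half):(n - 1L)]^2))
  env <- sqrt(pmax(0, as.numeric(
    stats::filter(xp, kern, sides = 2L)[(half + 1L):(half + n)])))
  fc_idx <- integer(0); after <- integer(0)
  for (j in seq_len(length(ic_idx) - 1L)) {
    lo <- ic_idx[j]; hi <- ic_idx[j + 1L]
    if (hi - lo < 8L) next
    a <- lo + max(2L, round(0.05 * (hi - lo)))
    b <- lo + round(0.55 * (hi - lo))
    seg <- env[a:b]
    k <- which.max(seg)
    if (seg[k] < 1.5 * stats::median(env[lo:hi])) next
    fc_idx <- c(fc_idx, a + k - 1L)
    after <- c(after, j)
  }
  list(fc_idx = fc_idx,
       fc_times = (fc_idx - 1L + parabolic_offset(env, fc_idx)) / fs,
       after_ic = after)
}

#' Segment strides from same-foot contacts and trim the walk ends
#'
#' A stride spans two successive initial contacts of the same foot. The
#' first and last \code{trim} strides are removed to keep the steady-state
#' portion; fewer than \code{min_strides} remaining is an error.
#'
#' @param ic_times initial-contact times (s).
#' @param sides per-contact side labels.
#' @param config a [trunkgait_config()] (\code{trim}, \code{min_strides}).
#' @return data.frame with \code{start}, \code{end}, \code{side} per
#'   retained stride, in time order.
#' @export
segment_and_trim <- function(ic_times, sides, config = trunkgait_config()) {
  lead <- sides[1]
  lead_idx <- which(sides == lead)
  n_str <- length(lead_idx) - 1L
  if (n_str < 1L) stop("insufficient-strides error: 0 strides", call. = FALSE)
  start <- ic_times[lead_idx[-length(lead_idx)]]
  end <- ic_times[lead_idx[-1L]]
  keep <- seq_len(n_str)
  tr <- config$trim
  if (n_str - 2L * tr < config$min_strides)
    stop(sprintf("insufficient-strides error: %d < %d after trimming",
                 max(0L, n_str - 2L * tr), config$min_strides),
         call. = FALSE)
  keep <- keep[(tr + 1L):(n_str - tr)]
  data.frame(start = start[keep], end = end[keep], side = lead,
             stringsAsFactors = FALSE)
}

#' Detect gait events for a whole walk
#'
#' Runs the full chain: preprocessing, initial- and final-contact
#' detection, side labelling, stride segmentation and trimming.
#'
#' @param trace an [accel_trace()].
#' @param config a [trunkgait_config()].
#' @return an object of class \code{gait_events}: initial/final contact
#'   times and sides, retained stride windows, and bookkeeping counts.
#' @export
gait_events <- function(trace, config = trunkgait_config()) {
  validate_config(config, trace$fs)
  pre <- preprocess_vertical(trace$v, trace$fs, cutoff = config$event_cutoff,
                             order = config$fir_order)
  ics <- detect_initial_contacts(pre, trace$fs, config)
  sides <- assign_sides(ics$ic_idx, trace$ml, trace$fs)
  fcs <- detect_final_contacts(trace$v, trace$fs, ics$ic_idx, config)
  fc_sides <- ifelse(sides[fcs$after_ic] == "left", "right", "left")
  # stride windows stay on the integer sample grid (exact-period DFT
  # windows); the sub-sample refined times serve the temporal parameters
  windows <- segment_and_trim((ics$ic_idx - 1L) / trace$fs, sides, config)
  structure(list(
    ic_times = ics$ic_times, ic_idx = ics$ic_idx, ic_sides = sides,
    fc_times = fcs$fc_times, fc_idx = fcs$fc_idx, fc_sides = fc_sides,
    stride_windows = windows,
    n_detected_strides = sum(sides == sides[1]) - 1L,
    n_retained = nrow(windows), fs = trace$fs,
    subject_id = trace$subject_id, timepoint = trace$timepoint),
    class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf(
    "gait_events: %d ICs, %d FCs, %d strides detected, %d retained (%s lead)\n",
    length(x$ic_times), length(x$fc_times), x$n_detected_strides,
    x$n_retained, x$stride_windows$side[1]))
  invisible(x)
}

#' Temporal gait parameters and gait speed
#'
#' Per-side stance, swing, single-support and double-support durations
#' averaged over the retained strides, plus the stride time and gait speed.
#' Stance of a foot runs from its initial contact to its final contact;
#' swing is the remainder of the stride; double support of one side is its
#' loading-response interval (own initial contact to the contralateral
#' final contact; the two per-stride intervals sum to the total double
#' support); single support of one side equals the contralateral swing. Gait speed defaults to corridor
#' distance divided by the walk duration (first to last initial contact,
#' before trimming).
#'
#' @param events a [gait_events()] object.
#' @param walk_distance corridor length (m).
#' @param paretic_side "left", "right", or "none"; when given, the output
#'   also carries paretic/non-paretic means for the symmetry indexes.
#' @return list of class \code{temporal_params}.
#' @export
temporal_parameters <- function(events, walk_distance = 30,
                                paretic_side = "none") {
  ic <- events$ic_times; ics <- events$ic_sides
  fc <- events$fc_times; fcs <- events$fc_sides
  win <- events$stride_windows
  t0 <- min(win$start); t1 <- max(win$end)
  per_side <- function(side) {
    idx <- which(ics == side & ic >= t0 - 1e-9 & ic < t1 - 1e-9)
    stance <- swing <- stride <- ds <- numeric(0)
    for (i in idx) {
      nxt_same <- which(ics == side & ic > ic[i] + 1e-9)
      if (!length(nxt_same)) next
      stride_t <- ic[nxt_same[1]] - ic[i]
      f <- which(fcs == side & fc > ic[i] + 1e-9 & fc < ic[nxt_same[1]])
      if (!length(f)) next
      st <- fc[f[1]] - ic[i]
      # loading-response double support of this side: own IC to the first
      # contralateral FC (the two per-stride intervals sum to total DS)
      fc_contra <- which(fcs != side & fc > ic[i] & fc < ic[nxt_same[1]])
      ds_i <- if (length(fc_contra)) fc[fc_contra[1]] - ic[i] else NA
      stance <- c(stance, st); stride <- c(stride, stride_t)
      swing <- c(swing, stride_t - st)
      ds <- c(ds, ds_i)
    }
    if (!length(stance))
      stop("insufficient events for temporal parameters on the ", side,
           " side", call. = FALSE)
    c(stance = mean(stance), swing = mean(swing),
      stride = mean(stride), double_support = mean(ds, na.rm = TRUE),
      n = length(stance))
  }
  L <- per_side("left"); R <- per_side("right")
  out <- list(
    stance = c(left = unname(L["stance"]), right = unname(R["stance"])),
    swing = c(left = unname(L["swing"]), right = unname(R["swing"])),
    stride_time = mean(c(L["stride"], R["stride"])),
    double_support = c(left = unname(L["double_support"]),
                       right = unname(R["double_support"])),
    single_support = c(left = unname(R["swing"]), right = unname(L["swing"])),
    gait_speed = walk_distance / (max(ic) - min(ic)),
    paretic_side = paretic_side)
  if (out$gait_speed <= 0 || out$gait_speed >= 3)
    warning("gait speed ", signif(out$gait_speed, 3),
            " m/s outside the 0-3 m/s sanity range")
  if (paretic_side %in% c("left", "right")) {
    np <- if (paretic_side == "left") "right" else "left"
    out$paretic <- vapply(
      c("stance", "swing", "double_support", "single_support"),
      function(p) out[[p]][[paretic_side]], 0)
    out$nonparetic <- vapply(
      c("stance", "swing", "double_support", "single_support"),
      function(p) out[[p]][[np]], 0)
  }
  class(out) <- "temporal_params"
  out
}
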