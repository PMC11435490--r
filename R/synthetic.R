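#' Specification of one synthetic trunk-acceleration walk
#'
#' The signal family is harmonic-plus-impulse: each axis is a stride-locked
#' sum of the first 8 stride harmonics; the vertical axis additionally
#' carries one positive Gaussian pulse per initial contact and one negative
#' pulse per final contact. Because a periodic Gaussian pulse train has
#' closed-form Fourier coefficients, the true harmonic amplitudes of the
#' noise-free signal -- and hence the true harmonic ratios -- are analytic.
#' Step-timing asymmetry \code{delta} shifts the right-foot events by a
#' fraction of the stride; per-side stance fractions place the final
#' contacts; stride-time variability, per-stride amplitude jitter, and
#' additive white noise drive the stability (divergence) of the trace.
#'
#' @param stride_time mean stride duration T (s).
#' @param n_strides number of strides (default 26; 22 survive trimming).
#' @param fs sampling rate (Hz).
#' @param hr_v,hr_ml,hr_ap target harmonic ratios (even/odd for V and AP,
#'   odd/even for ML).
#' @param delta step-timing asymmetry: the right initial contact falls at
#'   phase \code{0.5 + delta} of the stride (|delta| < 0.2).
#' @param stance_left,stance_right stance fractions of the stride per side.
#' @param sigma_t stride-time coefficient of variation.
#' @param sigma_n motor-wobble SD (m/s^2) at stride end, applied to every
#'   axis. The wobble is a within-stride Brownian path that resets at each
#'   stride start: the heel-strike impact re-anchors the trunk state and
#'   instability accumulates over the cycle. Nearby trajectories (matched
#'   at similar stride phase) therefore genuinely diverge, and the
#'   divergence exponent rises with \code{sigma_n}, while the fixed white
#'   measurement noise \code{sigma_w} only sets the neighbour-distance
#'   floor.
#' @param sigma_w white measurement-noise SD (m/s^2, default 0.04; a
#'   sensor property, not a subject property, and the floor against which
#'   the wobble-driven divergence is measured).
#' @param wobble_vap wobble scale of the V and AP axes relative to ML
#'   (default 0.45): vertical and fore-aft trunk motion is mechanically
#'   constrained by limb support, while medio-lateral balance is actively
#'   controlled and so carries most of the instability.
#' @param sigma_a per-stride amplitude jitter SD (relative).
#' @param amp_v,amp_ml,amp_ap harmonic amplitude scales (m/s^2).
#' @param pulse_ic,pulse_fc pulse amplitudes on V (m/s^2); \code{pulse_fc}
#'   is applied with negative sign.
#' @param step_width SD (fraction of stride) of the broad per-step trunk
#'   oscillation bump; carries the even-harmonic content and follows the
#'   actual (asymmetry-shifted) step times.
#' @param fc_burst amplitude (m/s^2) of the brief high-frequency push-off
#'   vibration emitted at each final contact. The burst carrier sits at the
#'   24th stride harmonic: above the 20 counted harmonics and above the
#'   20 Hz index filters, so it leaves the harmonic ratios, smoothness and
#'   event low-pass chains untouched while giving final contacts a clean
#'   spectral signature.
#' @param pulse_width initial-contact pulse SD as a fraction of the stride.
#' @param fc_width final-contact pulse SD as a fraction of the stride
#'   (sharper than the heel-strike pulse).
#' @param lead_in quiet padding before the first and after the last initial
#'   contact (s).
#' @param speed walked speed (m/s); fixes the corridor distance so that
#'   distance / walk duration reproduces it.
#' @param paretic_side "left", "right" or "none".
#' @param seed integer seed; same spec => identical trace.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(stride_time = 1.2, n_strides = 26L, fs = 100,
                           hr_v = 2.0, hr_ml = 1.8, hr_ap = 1.9,
                           delta = 0, stance_left = 0.6, stance_right = 0.6,
                           sigma_t = 0, sigma_n = 0, sigma_a = 0,
                           sigma_w = 0.04, wobble_vap = 0.45,
                           amp_v = 1.0, amp_ml = 0.8, amp_ap = 0.9,
                           pulse_ic = 2.5, pulse_fc = 0.15,
                           pulse_width = 0.05, fc_width = 0.03,
                           step_width = 0.09, fc_burst = 0.9,
                           lead_in = 1.5,
                           speed = 0.75, paretic_side = "none",
                           seed = 1L) {
  spec <- as.list(environment())
  spec$n_strides <- as.integer(n_strides)
  if (stride_time <= 0) stop("stride_time must be > 0", call. = FALSE)
  if (abs(delta) >= 0.2) stop("|delta| must be < 0.2", call. = FALSE)
  if (sigma_t < 0 || sigma_n < 0 || sigma_a < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  if (any(c(stance_left, stance_right) <= 0.5 + delta) ||
      any(c(stance_left, stance_right) >= 1))
    stop("stance fractions must lie in (0.5 + delta, 1)", call. = FALSE)
  class(spec) <- "synthetic_spec"
  spec
}

# Fourier coefficient magnitude of a unit-amplitude periodic Gaussian pulse
# (SD sigma, in stride-phase units) at harmonic k.
pulse_coef <- function(k, sigma) 2 * sigma * sqrt(2 * pi) *
  exp(-2 * pi^2 * k^2 * sigma^2)

# Complex stride-harmonic coefficients (k = 1..n) of the V-axis pulse
# trains: positive IC pulses at phases 0 (left, amplitude a_l) and
# 0.5 + delta (right, amplitude a_r), negative FC pulses at stance_left
# and 0.5 + delta + stance_right.
v_pulse_coefs <- function(spec, a_l, a_r, n = 20L) {
  k <- seq_len(n)
  g <- pulse_coef(k, spec$pulse_width)
  gf <- pulse_coef(k, spec$fc_width)
  fc_phase <- exp(-2i * pi * k * spec$stance_left) +
    exp(-2i * pi * k * (0.5 + spec$delta + spec$stance_right))
  ic <- g * (a_l + a_r * exp(-2i * pi * k * (0.5 + spec$delta)))
  fc <- -spec$pulse_fc * gf * fc_phase
  # push-off burst: Gaussian envelope (SD 0.012 strides) on a carrier at
  # the 24th harmonic; its k-spectrum is a Gaussian pair centred at -+24,
  # wide enough (SD ~13 harmonics) to reach the counted bins
  sb <- 0.012
  gb <- spec$fc_burst * sb * sqrt(2 * pi) *
    (exp(-2 * pi^2 * sb^2 * (k - 24)^2) +
       exp(-2 * pi^2 * sb^2 * (k + 24)^2))
  ic + fc + gb * fc_phase
}

# Solve the V-axis odd-harmonic background so the analytic spectrum
# (even base + equal-amplitude step pulses + final-contact pulses + odd
# background) meets the target even/odd ratio. Both steps keep full pulse
# strength -- asymmetry lives in the odd background, which has zero slope
# at the step phases and therefore does not displace the detection
# extrema. Returns base coefficients and the complex pulse coefficients.
solve_v_axis <- function(spec, odd_phases = rep(0, 4)) {
  sh <- harmonic_shapes("v")
  k <- 1:20
  # broad per-step oscillation bumps at the true step times: even-dominant
  # content that follows the asymmetry shift delta
  bumps <- spec$amp_v * pulse_coef(k, spec$step_width) *
    (1 + exp(-2i * pi * k * (0.5 + spec$delta)))
  pulses <- v_pulse_coefs(spec, spec$pulse_ic, spec$pulse_ic) + bumps
  ph <- exp(1i * odd_phases)
  odd_at <- function(s) {
    cc <- complex(real = numeric(20))
    cc[c(1, 3, 5, 7)] <- s * spec$amp_v * sh$odd * ph
    cc
  }
  ratio_at <- function(s) {
    A <- Mod(odd_at(s) + pulses)
    sum(A[seq(2, 20, 2)]) / sum(A[seq(1, 19, 2)])
  }
  f <- function(s) ratio_at(s) - spec$hr_v
  s <- if (f(1e-8) < 0) 1e-8
  else stats::uniroot(f, lower = 1e-8, upper = 1e4, tol = 1e-10)$root
  list(c_base = odd_at(s)[1:8], a_l = spec$pulse_ic, a_r = spec$pulse_ic,
       pulses = pulses)
}

# Base harmonic shapes (at k = 2,4,6,8 even / 1,3,5,7 odd). The even
# (step-locked) envelope decays geometrically. For the V and AP axes the
# odd (asymmetry) content sits mainly in the higher odd harmonics -- the
# sharp, jerky left/right differences of pathological gait -- which the
# harmonic ratio counts in full but the 3.2 Hz event filter removes, so
# low-symmetry walks remain detectable. The ML axis keeps its odd content
# at the stride fundamental (lateral sway alternates with the stepping
# foot), which side assignment relies on.
harmonic_shapes <- function(axis = c("v", "ml", "ap")) {
  axis <- match.arg(axis)
  even <- 0.5^(0:3)
  odd <- if (axis == "ml") c(1, 0.4, 0.15, 0.05) else c(0.1, 0.35, 1, 0.8)
  list(even = even / sum(even), odd = odd / sum(odd))
}

# Solve the odd-group scaling so that the total (base + pulse) spectrum of
# the axis meets the target even/odd ratio. Returns the real base
# coefficients c[1..8].
solve_axis_coefs <- function(target, amp, pulses = NULL, ml = FALSE,
                             axis = if (ml) "ml" else "ap") {
  sh <- harmonic_shapes(axis)
  c_base <- numeric(8)
  ratio_at <- function(s) {
    cc <- c_base
    cc[c(2, 4, 6, 8)] <- amp * sh$even
    cc[c(1, 3, 5, 7)] <- s * amp * sh$odd
    A <- Mod(c(cc, numeric(12)) + if (is.null(pulses)) 0 else pulses)
    even <- sum(A[seq(2, 20, 2)]); odd <- sum(A[seq(1, 19, 2)])
    if (ml) odd / even else even / odd
  }
  # ratio is monotone in s: increasing for ML (odd on top), decreasing else
  f <- function(s) ratio_at(s) - target
  s <- stats::uniroot(f, lower = 1e-8, upper = 1e6, tol = 1e-12)$root
  cc <- c_base
  cc[c(2, 4, 6, 8)] <- amp * sh$even
  cc[c(1, 3, 5, 7)] <- s * amp * sh$odd
  cc
}

# Analytic harmonic amplitudes A_1..A_20 of an axis (base + pulses).
axis_true_amplitudes <- function(c_base, pulses = NULL) {
  Mod(c(c_base, numeric(12)) + if (is.null(pulses)) 0 else pulses)
}

true_hr <- function(A, ml = FALSE) {
  even <- sum(A[seq(2, 20, 2)]); odd <- sum(A[seq(1, 19, 2)])
  if (ml) odd / even else even / odd
}

#' Generate a synthetic trunk-acceleration trace with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @param subject_id,timepoint metadata for the returned trace.
#' @return list with \code{trace} (an [accel_trace()]) and \code{truth}:
#'   true initial/final contact times and sides, analytic harmonic ratios,
#'   true temporal parameters and symmetry indexes, and the walked speed.
#' @export
generate_trace <- function(spec, subject_id = "synth", timepoint = "T0") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  fs <- spec$fs; Tm <- spec$stride_time; ns <- spec$n_strides
  # stride durations (truncated at +/- 3 CV)
  eps <- pmin(pmax(stats::rnorm(ns, 0, spec$sigma_t), -3 * spec$sigma_t),
              3 * spec$sigma_t)
  Tn <- Tm * (1 + eps)
  starts <- spec$lead_in + c(0, cumsum(Tn))   # left ICs, length ns + 1
  ic_left <- starts
  ic_right <- starts[1:ns] + (0.5 + spec$delta) * Tn
  fc_left <- starts[1:ns] + spec$stance_left * Tn
  fc_right <- starts[1:ns] + (0.5 + spec$delta + spec$stance_right) * Tn
  total <- starts[ns + 1] + spec$lead_in
  n_samp <- ceiling(total * fs)
  t <- (seq_len(n_samp) - 1) / fs

  # stride phase phi(t): piecewise linear, edge strides extended outward
  stride_of <- pmin(pmax(findInterval(t, starts), 1L), ns)
  phi <- (stride_of - 1) + (t - starts[stride_of]) / Tn[stride_of]

  # axis coefficients meeting the analytic harmonic-ratio targets; the
  # high odd harmonics (5, 7) of the V asymmetry background get random
  # phases (left/right differences are not phase-locked to the events),
  # while harmonics 1 and 3 -- the only odd content surviving the 3.2 Hz
  # event filter -- stay in cosine phase, which has zero slope at the step
  # times and so leaves the detected event positions unbiased
  vsol <- solve_v_axis(spec,
                       odd_phases = c(0, 0, stats::runif(2, 0, 2 * pi)))
  c_v <- vsol$c_base; pv <- vsol$pulses
  c_ml <- solve_axis_coefs(spec$hr_ml, spec$amp_ml, ml = TRUE)
  c_ap <- solve_axis_coefs(spec$hr_ap, spec$amp_ap)

  jit <- 1 + pmin(pmax(stats::rnorm(ns, 0, spec$sigma_a), -0.5), 0.5)
  q <- jit[stride_of]
  harm <- function(coefs) {
    y <- numeric(n_samp)
    for (k in 1:8) y <- y + Re(coefs[k] * exp(2i * pi * k * phi))
    y * q
  }
  gauss_pulses <- function(centers, amp, widths_s) {
    y <- numeric(n_samp)
    for (i in seq_along(centers)) {
      w <- widths_s[i]
      lo <- max(1L, floor((centers[i] - 5 * w) * fs))
      hi <- min(n_samp, ceiling((centers[i] + 5 * w) * fs))
      idx <- lo:hi
      y[idx] <- y[idx] + amp * exp(-(t[idx] - centers[i])^2 / (2 * w^2))
    }
    y
  }
  w_ic <- spec$pulse_width * c(Tn, Tn[ns])   # seconds
  w_fc <- spec$fc_width * Tn
  # push-off vibration: Gaussian-windowed carrier at the 24th stride
  # harmonic, one burst per final contact
  fc_bursts <- function(centers, Tl) {
    y <- numeric(n_samp)
    for (i in seq_along(centers)) {
      sb <- 0.012 * Tl[i]  # must match the coefficient model above
      f0 <- 24 / Tl[i]
      lo <- max(1L, floor((centers[i] - 5 * sb) * fs))
      hi <- min(n_samp, ceiling((centers[i] + 5 * sb) * fs))
      idx <- lo:hi
      y[idx] <- y[idx] + spec$fc_burst *
        exp(-(t[idx] - centers[i])^2 / (2 * sb^2)) *
        cos(2 * pi * f0 * (t[idx] - centers[i]))
    }
    y
  }
  w_step <- spec$step_width * c(Tn, Tn[ns])
  v <- harm(c_v) +
    gauss_pulses(ic_left, spec$amp_v, w_step) +
    gauss_pulses(ic_right, spec$amp_v, w_step[1:ns]) +
    gauss_pulses(ic_left, vsol$a_l, w_ic) +
    gauss_pulses(ic_right, vsol$a_r, w_ic[1:ns]) -
    gauss_pulses(fc_left, spec$pulse_fc, w_fc) -
    gauss_pulses(fc_right, spec$pulse_fc, w_fc) +
    fc_bursts(fc_left, Tn) + fc_bursts(fc_right, Tn)
  ml <- harm(c_ml)
  ap <- harm(c_ap)

  # raised-cosine on/off envelope over the quiet padding
  env <- rep(1, n_samp)
  nr <- round(spec$lead_in * fs)
  ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  env[1:nr] <- ramp
  env[(n_samp - nr + 1):n_samp] <- rev(ramp)
  v <- v * env; ml <- ml * env; ap <- ap * env
  if (spec$sigma_n > 0 || spec$sigma_w > 0) {
    # Brownian wobble within each stride, reset at stride starts; scaled
    # so its SD reaches sigma_n at stride end
    wobble <- function(sd_end) {
      w <- numeric(n_samp)
      for (si in seq_len(ns)) {
        idx <- which(stride_of == si)
        if (!length(idx)) next
        w[idx] <- cumsum(stats::rnorm(length(idx))) * sd_end /
          sqrt(length(idx))
      }
      w
    }
    v <- v + wobble(spec$wobble_vap * spec$sigma_n) +
      stats::rnorm(n_samp, 0, spec$sigma_w)
    ml <- ml + wobble(spec$sigma_n) + stats::rnorm(n_samp, 0, spec$sigma_w)
    ap <- ap + wobble(spec$wobble_vap * spec$sigma_n) +
      stats::rnorm(n_samp, 0, spec$sigma_w)
  }

  walk_span <- ic_left[ns + 1] - ic_left[1]
  trace <- accel_trace(ap = ap, ml = ml, v = v, fs = fs,
                       subject_id = subject_id, timepoint = timepoint,
                       walk_distance = spec$speed * walk_span)

  # analytic ground truth
  A_v <- axis_true_amplitudes(c_v, pv)
  A_ml <- axis_true_amplitudes(c_ml)
  A_ap <- axis_true_amplitudes(c_ap)
  sL <- spec$stance_left; sR <- spec$stance_right; d <- spec$delta
  temporal <- list(
    stance = c(left = sL * Tm, right = sR * Tm),
    swing = c(left = (1 - sL) * Tm, right = (1 - sR) * Tm),
    double_support = c(left = (sR + d - 0.5) * Tm,
                       right = (sL - 0.5 - d) * Tm),
    single_support = c(left = (1 - sR) * Tm, right = (1 - sL) * Tm),
    stride_time = Tm)
  si <- NULL
  if (spec$paretic_side %in% c("left", "right")) {
    p <- spec$paretic_side; np <- if (p == "left") "right" else "left"
    si <- vapply(c("stance", "swing", "double_support", "single_support"),
                 function(f) symmetry_index(temporal[[f]][[p]],
                                            temporal[[f]][[np]]), 0)
    names(si) <- c("si_stance", "si_swing", "si_double", "si_single")
  }
  ord <- order(c(ic_left, ic_right))
  truth <- list(
    ic_times = c(ic_left, ic_right)[ord],
    ic_sides = rep(c("left", "right"), c(ns + 1, ns))[ord],
    ic_left = ic_left, ic_right = ic_right,
    fc_left = fc_left, fc_right = fc_right,
    hr_v = true_hr(A_v), hr_ml = true_hr(A_ml, ml = TRUE),
    hr_ap = true_hr(A_ap),
    amplitudes = list(v = A_v, ml = A_ml, ap = A_ap),
    temporal = temporal, si = si, speed = spec$speed,
    stride_times = Tn, n_strides = ns)
  list(trace = trace, truth = truth)
}

#' Group presets calibrated to the study cohorts
#'
#' Named parameter bundles for healthy subjects (HS), immunocompetent
#' stroke patients (IC) and patients with stroke-induced immunosuppression
#' (SII). Harmonic-ratio and gait-speed targets are drawn from the group
#' means/SDs reported for the three cohorts; the noise and variability
#' dials (white noise, stride-time CV, amplitude jitter) were calibrated
#' once so that the pipeline's medio-lateral divergence exponent lands on
#' the reported group scale, and are ordinal ground truth (more noise =
#' less stable), not analytic.
#'
#' @param group "HS", "IC" or "SII".
#' @return named list of distribution parameters.
#' @export
group_preset <- function(group = c("HS", "IC", "SII")) {
  group <- match.arg(group)
  presets <- list(
    HS = list(hr_v = c(2.01, 0.47), hr_ml = c(1.87, 0.39),
              hr_ap = c(1.95, 0.51), speed = c(0.78, 0.19),
              sigma_n = 0.005, sigma_t = 0.010, sigma_a = 0.04,
              delta = c(0, 0.012), stance_par = c(0.60, 0.008),
              stance_np = c(0.60, 0.008),
              nihss = NULL, age = c(62.1, 8.7), p_female = 0.381,
              p_hemorrhagic = 0),
    IC = list(hr_v = c(1.68, 0.45), hr_ml = c(1.50, 0.30),
              hr_ap = c(1.64, 0.44), speed = c(0.72, 0.21),
              sigma_n = 0.100, sigma_t = 0.014, sigma_a = 0.09,
              delta = c(0.02, 0.02), stance_par = c(0.645, 0.025),
              stance_np = c(0.60, 0.012),
              nihss = c(5.15, 2.47), bi = c(57.05, 19.92),
              fim = c(86.61, 19.39), tinetti = c(18.0, 7.57),
              nlr = "ic", age = c(62.9, 15.9), p_female = 0.375,
              p_hemorrhagic = 1 / 32),
    SII = list(hr_v = c(1.36, 0.45), hr_ml = c(1.24, 0.19),
               hr_ap = c(1.41, 0.48), speed = c(0.66, 0.26),
               sigma_n = 0.180, sigma_t = 0.022, sigma_a = 0.12,
               delta = c(0.025, 0.022), stance_par = c(0.650, 0.027),
               stance_np = c(0.60, 0.013),
               nihss = c(7.86, 5.96), bi = c(40.71, 18.80),
               fim = c(77.33, 23.23), tinetti = c(15.9, 9.12),
               nlr = "sii", age = c(71.1, 14.2), p_female = 0.429,
               p_hemorrhagic = 2 / 14))
  presets[[group]]
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

draw_subject_spec <- function(group, seed, timepoint = "T0") {
  p <- group_preset(group)
  set.seed(seed)
  t1 <- timepoint == "T1"
  # longitudinal improvements (patients only), on the reported scale
  d_hr <- if (t1) c(v = 0.33, ml = 0.26, ap = 0.30) else c(v = 0, ml = 0,
                                                           ap = 0)
  d_speed <- if (t1) 0.20 else 0
  noise_scale <- if (t1) 0.88 else 1
  hr_v <- rtrunc_norm(1, p$hr_v[1] + d_hr["v"], p$hr_v[2], 0.4, 4.5)
  hr_ml <- rtrunc_norm(1, p$hr_ml[1] + d_hr["ml"], p$hr_ml[2], 0.4, 4.5)
  hr_ap <- rtrunc_norm(1, p$hr_ap[1] + d_hr["ap"], p$hr_ap[2], 0.4, 4.5)
  speed <- rtrunc_norm(1, p$speed[1] + d_speed, p$speed[2], 0.25, 1.5)
  stride_len <- rtrunc_norm(1, 0.95, 0.10, 0.6, 1.4)
  stride_time <- min(max(stride_len / speed, 0.9), 1.7)
  delta <- rtrunc_norm(1, p$delta[1], p$delta[2], -0.12, 0.12)
  paretic <- if (group == "HS") "none" else
    sample(c("left", "right"), 1, prob = c(0.391, 0.609))
  st_par <- rtrunc_norm(1, p$stance_par[1], p$stance_par[2], 0.55, 0.72)
  st_np <- rtrunc_norm(1, p$stance_np[1], p$stance_np[2], 0.55, 0.72)
  st_par <- max(st_par, 0.52 + delta)
  st_np <- max(st_np, 0.52 + delta)
  if (paretic == "right" || paretic == "none") {
    stance_left <- st_np; stance_right <- st_par
  } else {
    stance_left <- st_par; stance_right <- st_np
  }
  sigma_n <- p$sigma_n * exp(stats::rnorm(1, 0, 0.22)) * noise_scale
  sigma_t <- p$sigma_t * exp(stats::rnorm(1, 0, 0.20)) * noise_scale
  sigma_a <- p$sigma_a * exp(stats::rnorm(1, 0, 0.20)) * noise_scale
  synthetic_spec(stride_time = stride_time,
                 n_strides = sample(25:28, 1),
                 hr_v = hr_v, hr_ml = hr_ml, hr_ap = hr_ap,
                 delta = delta,
                 stance_left = stance_left, stance_right = stance_right,
                 sigma_t = sigma_t, sigma_n = sigma_n, sigma_a = sigma_a,
                 speed = speed, paretic_side = paretic,
                 seed = (seed + 7919L) %% 2147483647L)
}

draw_nlr <- function(group) {
  if (group == "SII") 5 + stats::rexp(1, rate = 1 / 1.68)
  else if (group == "IC") rtrunc_norm(1, 2.70, 0.98, 0.3, 4.99)
  else NA_real_
}

#' Generate a synthetic cohort with manifest and ground truth
#'
#' Draws per-subject walk specifications from the group presets, generates
#' the traces, and returns the cohort manifest (group, NLR, paretic side,
#' demographics, clinical scores), the traces, and a table of per-subject
#' ground-truth indexes. With \code{include_t1 = TRUE}, patients also
#' receive a discharge (T1) walk with the reported group-level
#' improvements applied.
#'
#' @param n_hs,n_ic,n_sii group sizes (defaults 42/32/14).
#' @param seed cohort seed; subjects receive distinct derived sub-seeds.
#' @param include_t1 also generate T1 walks for patients (default FALSE).
#' @return list with \code{manifest} (data.table), \code{traces} (named
#'   list of [accel_trace()]), and \code{truth} (data.table).
#' @export
generate_cohort <- function(n_hs = 42L, n_ic = 32L, n_sii = 14L, seed = 1L,
                            include_t1 = FALSE) {
  if (n_hs + n_ic + n_sii <= 0L) stop("empty cohort", call. = FALSE)
  groups <- rep(c("HS", "IC", "SII"), c(n_hs, n_ic, n_sii))
  # deterministic ischemic/hemorrhagic composition matching cohort rates
  n_hem <- c(HS = 0L, IC = round(n_ic / 32), SII = round(2 * n_sii / 14))
  manifest <- list(); traces <- list(); truth <- list()
  counters <- c(HS = 0L, IC = 0L, SII = 0L)
  for (i in seq_along(groups)) {
    g <- groups[i]
    counters[g] <- counters[g] + 1L
    sid <- sprintf("%s%03d", g, counters[g])
    sub_seed <- (seed * 10007L + 97L * i) %% 2147483647L
    p <- group_preset(g)
    set.seed(sub_seed)
    nlr <- draw_nlr(g)
    age <- round(rtrunc_norm(1, p$age[1], p$age[2], 18, 95))
    sex <- if (stats::runif(1) < p$p_female) "F" else "M"
    stroke_type <- if (g == "HS") NA_character_ else
      if (counters[g] <= n_hem[g]) "hemorrhagic" else "ischemic"
    scores <- if (g == "HS") rep(NA_real_, 4) else vapply(
      list(p$nihss, p$bi, p$fim, p$tinetti),
      function(ms) round(rtrunc_norm(1, ms[1], ms[2], 0, 130)), 0)
    tps <- if (include_t1 && g != "HS") c("T0", "T1") else "T0"
    for (tp in tps) {
      spec <- draw_subject_spec(g, sub_seed + (tp == "T1") * 31L, tp)
      gen <- generate_trace(spec, subject_id = sid, timepoint = tp)
      key <- paste0(sid, "_", tp)
      traces[[key]] <- gen$trace
      manifest[[key]] <- data.table::data.table(
        subject_id = sid, group = g, nlr = nlr,
        paretic_side = spec$paretic_side, timepoint = tp,
        age = age, sex = sex, stroke_type = stroke_type,
        nihss = scores[1], bi = scores[2], fim = scores[3],
        tinetti = scores[4], trace_path = NA_character_)
      truth[[key]] <- data.table::data.table(
        subject_id = sid, group = g, timepoint = tp,
        hr_v = gen$truth$hr_v, hr_ml = gen$truth$hr_ml,
        hr_ap = gen$truth$hr_ap, speed = gen$truth$speed,
        si_stance = if (is.null(gen$truth$si)) NA_real_ else
          gen$truth$si[["si_stance"]],
        sigma_n = spec$sigma_n, sigma_t = spec$sigma_t,
        sigma_a = spec$sigma_a, stride_time = spec$stride_time,
        n_strides = spec$n_strides)
    }
  }
  list(manifest = data.table::rbindlist(manifest),
       traces = traces,
       truth = data.table::rbindlist(truth))
}
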