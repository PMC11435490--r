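#' Time-normalize strides to a fixed grid
#'
#' Each of the first \code{n_strides} retained strides is linearly
#' resampled to \code{points} samples over its own duration and the pieces
#' are concatenated, yielding \code{n_strides * points} samples (2000 by
#' default). The raw, unfiltered axis is used: filtering would suppress
#' exactly the fluctuations the stability analysis measures.
#'
#' @param x raw acceleration samples of one axis.
#' @param fs sampling rate (Hz).
#' @param stride_windows data.frame with \code{start}, \code{end} times (s).
#' @param n_strides strides used (default 20).
#' @param points samples per normalized stride (default 100).
#' @return numeric vector of length \code{n_strides * points}.
#' @export
time_normalize <- function(x, fs, stride_windows, n_strides = 20L,
                           points = 100L) {
  if (nrow(stride_windows) < n_strides)
    stop(sprintf("insufficient-strides error: %d < %d",
                 nrow(stride_windows), n_strides), call. = FALSE)
  t_axis <- (seq_along(x) - 1) / fs
  out <- numeric(0)
  for (i in seq_len(n_strides)) {
    t0 <- stride_windows$start[i]; t1 <- stride_windows$end[i]
    grid <- seq(t0, t1, length.out = points + 1L)[1:points]
    out <- c(out, stats::approx(t_axis, x, xout = grid)$y)
  }
  out
}

#' Embedding delay from the first minimum of average mutual information
#'
#' AMI is estimated with equiprobable binning (\code{ceiling(sqrt(N/5))}
#' bins at quantile edges). The delay is the first local minimum of AMI
#' within the search range, where a minimum must be prominent (drop of at
#' least 10\% of the curve range from the preceding lag, after light
#' smoothing) so that estimator wiggles do not masquerade as structure; a
#' flat curve (range < 0.1 bits, e.g. iid noise) has no meaningful
#' minimum. If no qualifying minimum falls in the range, the argmin over
#' the range is returned (documented fallback).
#'
#' @param x series (length >= 500 for a stable estimate).
#' @param range candidate delays in samples (default 7:18).
#' @return list with \code{tau}, the AMI curve \code{ami} (named by lag),
#'   and \code{fallback} flag.
#' @export
ami_delay <- function(x, range = 7:18) {
  n <- length(x)
  if (n < 500L) stop("series too short for AMI (need >= 500)", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate-series error: constant input", call. = FALSE)
  lags <- max(1L, min(range) - 2L):(max(range) + 2L)
  ami_raw <- vapply(lags, function(k) ami_at_lag(x, k), 0)
  # light smoothing + a prominence requirement keep noise-level wiggles
  # from masquerading as the first minimum
  ami <- stats::filter(ami_raw, c(0.25, 0.5, 0.25), sides = 2L)
  ami[is.na(ami)] <- ami_raw[is.na(ami)]
  ami <- as.numeric(ami)
  names(ami) <- names(ami_raw) <- lags
  prom <- 0.10 * (max(ami) - min(ami))
  in_range <- which(lags %in% range)
  tau <- NA_integer_; fallback <- FALSE
  # a flat curve (range below the binning-bias scale) has no meaningful
  # minimum: e.g. iid noise, whose AMI is ~0 everywhere
  flat <- (max(ami) - min(ami)) < 0.1
  if (!flat) for (i in in_range) {
    if (i == 1L || i == length(lags)) next
    if (ami[i] < ami[i - 1L] - prom && ami[i] <= ami[i + 1L]) {
      tau <- lags[i]; break
    }
  }
  if (is.na(tau)) {
    tau <- lags[in_range][which.min(ami[in_range])]
    fallback <- TRUE
  }
  list(tau = as.integer(tau), ami = ami, fallback = fallback)
}

ami_at_lag <- function(x, k) {
  n <- length(x) - k
  a <- x[1:n]; b <- x[(k + 1):(k + n)]
  nb <- ceiling(sqrt(length(x) / 5))
  brk <- stats::quantile(x, probs = seq(0, 1, length.out = nb + 1L),
                         names = FALSE)
  brk <- unique(brk)
  if (length(brk) < 3L)
    stop("degenerate-series error: too few distinct values", call. = FALSE)
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  ia <- findInterval(a, brk, rightmost.closed = TRUE)
  ib <- findInterval(b, brk, rightmost.closed = TRUE)
  joint <- table(ia, ib) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(pa, pb)[nz]))
}

#' Embedding dimension by false nearest neighbours
#'
#' Returns the smallest dimension whose false-neighbour fraction falls
#' below 1\% (distance-ratio threshold 15, attractor-size threshold 2). If
#' the fraction never drops below the criterion up to \code{max_dim}, the
#' maximum is returned with a warning.
#'
#' @param x series.
#' @param tau embedding delay (samples).
#' @param max_dim maximum dimension tried (default 10).
#' @param rtol,atol FNN thresholds (defaults 15 and 2).
#' @param threshold false-neighbour criterion (default 0.01).
#' @return list with \code{m} and the per-dimension \code{fractions}.
#' @export
fnn_dimension <- function(x, tau, max_dim = 10L, rtol = 15, atol = 2,
                          threshold = 0.01) {
  if (stats::sd(x) == 0)
    stop("degenerate-series error: constant input", call. = FALSE)
  if (length(x) < (max_dim - 1L) * tau + 100L)
    stop("series too short for FNN up to dimension ", max_dim,
         call. = FALSE)
  frac <- .fnn_fractions_cpp(as.numeric(x), as.integer(tau),
                             as.integer(max_dim), rtol, atol,
                             as.integer(tau), threshold)
  ok <- which(!is.na(frac) & frac < threshold)
  if (length(ok)) {
    m <- ok[1]
  } else {
    warning("false-neighbour fraction never fell below ",
            threshold * 100, "%; returning max_dim = ", max_dim)
    m <- max_dim
  }
  list(m = as.integer(m), fractions = frac)
}

#' Delay-embed a series
#' @keywords internal
embed_delay <- function(x, m, tau) {
  n <- length(x) - (m - 1L) * tau
  if (n < 2L) stop("series too short to embed", call. = FALSE)
  sapply(seq_len(m), function(j) x[(1:n) + (j - 1L) * tau])
}

#' Short-term largest Lyapunov exponent (Rosenstein's algorithm)
#'
#' Delay-embeds the series, finds each point's nearest neighbour outside a
#' Theiler window, tracks the mean log Euclidean separation of the pairs
#' over increasing offsets, and fits a least-squares line over the
#' short-term window. The slope is the exponent per sample.
#'
#' @param x series (e.g. 20 time-normalized strides of 100 points).
#' @param tau embedding delay (samples).
#' @param m embedding dimension.
#' @param theiler temporal exclusion window (samples, default 100 = one
#'   normalized stride).
#' @param fit_offsets offsets (samples) of the divergence curve used in
#'   the fit (default 0:50 = half a normalized stride).
#' @return list with \code{lambda_per_sample} (slope), the divergence
#'   \code{curve}, the \code{fit_offsets}, and embedding metadata.
#' @export
rosenstein_slle <- function(x, tau, m, theiler = 100L, fit_offsets = 0:50) {
  X <- embed_delay(x, m, tau)
  if (nrow(X) < 300L)
    stop("estimation error: embedded trajectory shorter than 300 points",
         call. = FALSE)
  nn <- .nn_search_cpp(X, as.integer(theiler))
  if (all(is.na(nn$dist)))
    stop("estimation error: no neighbour pairs outside the Theiler window",
         call. = FALSE)
  # distances below this floor are numerically identical points
  d_floor <- 1e-9 * stats::sd(x)
  curve <- .divergence_curve_cpp(X, nn$idx, max(fit_offsets), d_floor)
  y <- curve[fit_offsets + 1L]
  ok <- is.finite(y)
  if (!any(ok) && any(nn$dist <= d_floor, na.rm = TRUE)) {
    # exactly periodic series: every neighbour pair sits at zero distance,
    # so trajectories do not separate at all
    warning("fully periodic series: divergence identically zero")
    return(list(lambda_per_sample = 0, curve = curve,
                fit_offsets = fit_offsets, tau = tau, m = m,
                theiler = theiler))
  }
  if (sum(ok) < 3L)
    stop("estimation error: divergence curve too short to fit",
         call. = FALSE)
  k <- fit_offsets[ok]; y <- y[ok]
  slope <- sum((k - mean(k)) * (y - mean(y))) / sum((k - mean(k))^2)
  list(lambda_per_sample = slope, curve = curve, fit_offsets = fit_offsets,
       tau = tau, m = m, theiler = theiler)
}

#' Short-term largest Lyapunov exponents of a walk
#'
#' Per-axis stability pipeline: time-normalize the first 20 retained
#' strides of the raw axis to 100 points each, select the delay (first AMI
#' minimum in 7-18), select the dimension (FNN, max 10), and estimate the
#' exponent with Rosenstein's algorithm over 0-0.5 stride, expressed per
#' normalized stride (slope per sample x 100).
#'
#' @param trace an [accel_trace()].
#' @param events a [gait_events()] object.
#' @param config a [trunkgait_config()].
#' @param axes axes to analyze (default all three).
#' @return list of class \code{slle_result}: \code{slle_v/ml/ap} plus the
#'   embedding parameters per axis.
#' @export
walk_slle <- function(trace, events, config = trunkgait_config(),
                      axes = c("v", "ml", "ap")) {
  out <- list()
  pts <- config$points_per_stride
  fit <- 0:round(config$fit_window * pts)
  for (ax in axes) {
    s <- time_normalize(trace[[ax]], trace$fs, events$stride_windows,
                        n_strides = config$slle_strides, points = pts)
    tau <- ami_delay(s, config$tau_range)$tau
    m <- fnn_dimension(s, tau, max_dim = config$fnn_max_dim)$m
    fit_r <- rosenstein_slle(s, tau, m, theiler = config$theiler,
                             fit_offsets = fit)
    out[[paste0("slle_", ax)]] <- fit_r$lambda_per_sample * pts
    out[[paste0("tau_", ax)]] <- tau
    out[[paste0("m_", ax)]] <- m
  }
  class(out) <- "slle_result"
  out
}

#' @export
print.slle_result <- function(x, ...) {
  for (ax in c("v", "ml", "ap")) {
    f <- paste0("slle_", ax)
    if (!is.null(x[[f]]))
      cat(sprintf("sLLE_%s = %.3f /stride (tau %d, m %d)\n", toupper(ax),
                  x[[f]], x[[paste0("tau_", ax)]], x[[paste0("m_", ax)]]))
  }
  invisible(x)
}
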