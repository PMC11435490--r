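#' Construct a tri-axial trunk acceleration trace
#'
#' The basic data container: three uniformly sampled acceleration channels
#' recorded at the lumbar level (anterior-posterior, medio-lateral,
#' vertical), in m/s^2.
#'
#' @param ap,ml,v numeric vectors of equal length (m/s^2).
#' @param fs sampling rate in Hz (default 100).
#' @param subject_id subject identifier.
#' @param timepoint assessment timepoint, "T0" or "T1".
#' @param walk_distance corridor length walked, metres (default 30).
#' @return an object of class \code{accel_trace}.
#' @export
#' @examples
#' tr <- accel_trace(ap = sin(1:300 / 10), ml = cos(1:300 / 10),
#'                   v = sin(1:300 / 5), fs = 100)
#' print(tr)
accel_trace <- function(ap, ml, v, fs = 100, subject_id = "anon",
                        timepoint = c("T0", "T1"), walk_distance = 30) {
  timepoint <- match.arg(timepoint)
  ap <- as.numeric(ap); ml <- as.numeric(ml); v <- as.numeric(v)
  if (length(ap) != length(ml) || length(ml) != length(v))
    stop("axes must have equal length", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (length(v) < 2 * fs)
    stop("trace too short: need at least 2 s of samples", call. = FALSE)
  if (anyNA(ap) || anyNA(ml) || anyNA(v))
    stop("missing samples in acceleration axes", call. = FALSE)
  structure(list(ap = ap, ml = ml, v = v, fs = fs,
                 subject_id = as.character(subject_id),
                 timepoint = timepoint,
                 walk_distance = walk_distance),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf(
    "accel_trace: subject %s [%s], %d samples @ %g Hz (%.1f s), %g m walk\n",
    x$subject_id, x$timepoint, length(x$v), x$fs, length(x$v) / x$fs,
    x$walk_distance))
  invisible(x)
}

#' Analysis run configuration
#'
#' Collects the fixed constants of the index pipeline. Defaults reproduce
#' the standard single-IMU protocol: 3.2 Hz FIR event filter, 20-stride
#' minimum after trimming two strides at each end, 20 stride-locked
#' harmonics, embedding delay searched over 7-18 samples, FNN capped at
#' dimension 10, 20 Hz low-pass for the smoothness filter.
#'
#' @param min_strides minimum retained strides for a valid walk (default 20).
#' @param trim strides removed at each end of the walk (default 2).
#' @param event_cutoff low-pass cutoff (Hz) for event detection (default 3.2).
#' @param fir_order FIR order for the event filter (default 128).
#' @param cwt_scale Gaussian-wavelet scale in samples (default 9).
#' @param ic_polarity "negative" (default) or "positive": sign of the
#'   CWT-derivative extremum taken as initial contact.
#' @param fc_harmonic stride-harmonic number on which the final-contact
#'   (push-off) transient band is centred (default 24).
#' @param fc_bw half-width (Hz) of the final-contact band-pass (default 8).
#' @param n_harmonics stride harmonics computed (default 20).
#' @param hr_cutoff harmonic-ratio pre-filter cutoff in Hz (default 20).
#' @param hr_filter_direction "lowpass" (default) or "highpass". The
#'   protocol description says high-pass, but a 20 Hz high-pass would remove
#'   every gait harmonic; low-pass matches the stated purpose (noise
#'   removal) and is the default.
#' @param tau_range embedding-delay search range in samples (default 7:18).
#' @param fnn_max_dim maximum embedding dimension for FNN (default 10).
#' @param points_per_stride time-normalization grid per stride (default 100).
#' @param slle_strides strides used for the stability analysis (default 20).
#' @param theiler Theiler exclusion window, samples (default 100 = 1 stride).
#' @param fit_window divergence-fit upper end, in normalized strides
#'   (default 0.5).
#' @param ldlj_cutoff smoothness-filter cutoff in Hz (default 20).
#' @param ldlj_order Butterworth order (default 4).
#' @param units input acceleration units, "ms2" (default) or "g"
#'   (converted on read, x 9.80665).
#' @param strict_sampling error on non-uniform time stamps (default TRUE).
#' @param speed_mode "corridor" (walk distance / walk duration, default) or
#'   "stride" (per-stride estimate is out of scope for a single sensor; kept
#'   as a config hook).
#' @param seed integer seed recorded in run metadata.
#' @return a list of class \code{trunkgait_config}.
#' @export
trunkgait_config <- function(min_strides = 20L, trim = 2L,
                             event_cutoff = 3.2, fir_order = 128L,
                             cwt_scale = 9, ic_polarity = c("negative", "positive"),
                             fc_harmonic = 24, fc_bw = 8,
                             n_harmonics = 20L, hr_cutoff = 20,
                             hr_filter_direction = c("lowpass", "highpass"),
                             tau_range = 7:18, fnn_max_dim = 10L,
                             points_per_stride = 100L, slle_strides = 20L,
                             theiler = 100L, fit_window = 0.5,
                             ldlj_cutoff = 20, ldlj_order = 4L,
                             units = c("ms2", "g"), strict_sampling = TRUE,
                             speed_mode = c("corridor", "stride"),
                             seed = 1L) {
  cfg <- list(min_strides = as.integer(min_strides), trim = as.integer(trim),
              event_cutoff = event_cutoff, fir_order = as.integer(fir_order),
              cwt_scale = cwt_scale, ic_polarity = match.arg(ic_polarity),
              fc_harmonic = fc_harmonic, fc_bw = fc_bw,
              n_harmonics = as.integer(n_harmonics), hr_cutoff = hr_cutoff,
              hr_filter_direction = match.arg(hr_filter_direction),
              tau_range = as.integer(tau_range),
              fnn_max_dim = as.integer(fnn_max_dim),
              points_per_stride = as.integer(points_per_stride),
              slle_strides = as.integer(slle_strides),
              theiler = as.integer(theiler), fit_window = fit_window,
              ldlj_cutoff = ldlj_cutoff, ldlj_order = as.integer(ldlj_order),
              units = match.arg(units),
              strict_sampling = isTRUE(strict_sampling),
              speed_mode = match.arg(speed_mode), seed = as.integer(seed))
  class(cfg) <- "trunkgait_config"
  cfg
}

validate_config <- function(cfg, fs) {
  for (f in c("event_cutoff", "hr_cutoff", "ldlj_cutoff"))
    if (cfg[[f]] >= fs / 2)
      stop(sprintf("%s (%g Hz) must be below the Nyquist frequency (%g Hz)",
                   f, cfg[[f]], fs / 2), call. = FALSE)
  invisible(cfg)
}

#' Read an acceleration trace from CSV
#'
#' Expects columns \code{time, acc_ap, acc_ml, acc_v} (configurable via
#' \code{col_map}); \code{time} in seconds, monotone increasing. Sampling
#' uniformity is validated: in strict mode any step deviating from the
#' nominal period by more than 10\% raises an error.
#'
#' @param path CSV file path.
#' @param fs expected sampling rate in Hz (default 100).
#' @param subject_id,timepoint,walk_distance trace metadata.
#' @param config a [trunkgait_config()]; governs units and strictness.
#' @param col_map named character vector mapping the canonical names
#'   \code{time, acc_ap, acc_ml, acc_v} to the file's column names.
#' @return an [accel_trace()].
#' @export
read_accel_csv <- function(path, fs = 100, subject_id = "anon",
                           timepoint = "T0", walk_distance = 30,
                           config = trunkgait_config(),
                           col_map = c(time = "time", acc_ap = "acc_ap",
                                       acc_ml = "acc_ml", acc_v = "acc_v")) {
  dt <- data.table::fread(path, showProgress = FALSE)
  missing_cols <- setdiff(unname(col_map), names(dt))
  if (length(missing_cols))
    stop("trace CSV format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  tm <- dt[[col_map[["time"]]]]
  if (is.unsorted(tm, strictly = TRUE))
    stop("trace CSV format error: time column not strictly increasing",
         call. = FALSE)
  period <- 1 / fs
  jitter <- abs(diff(tm) - period)
  if (any(jitter > 0.1 * period)) {
    if (config$strict_sampling)
      stop(sprintf(
        "sampling error: %d time step(s) deviate > 10%% from 1/fs = %g s",
        sum(jitter > 0.1 * period), period), call. = FALSE)
    warning("non-uniform sampling beyond tolerance; resampling to grid")
    grid <- seq(tm[1], tm[length(tm)], by = period)
    dt <- data.table::data.table(
      time = grid,
      acc_ap = stats::approx(tm, dt[[col_map[["acc_ap"]]]], grid)$y,
      acc_ml = stats::approx(tm, dt[[col_map[["acc_ml"]]]], grid)$y,
      acc_v  = stats::approx(tm, dt[[col_map[["acc_v"]]]], grid)$y)
    col_map <- c(time = "time", acc_ap = "acc_ap", acc_ml = "acc_ml",
                 acc_v = "acc_v")
  }
  k <- if (config$units == "g") 9.80665 else 1
  accel_trace(ap = k * dt[[col_map[["acc_ap"]]]],
              ml = k * dt[[col_map[["acc_ml"]]]],
              v  = k * dt[[col_map[["acc_v"]]]],
              fs = fs, subject_id = subject_id, timepoint = timepoint,
              walk_distance = walk_distance)
}

#' Write an acceleration trace to CSV
#'
#' Inverse of [read_accel_csv()]: writes \code{time, acc_ap, acc_ml, acc_v}
#' at full double precision so that a round trip reproduces the samples.
#'
#' @param trace an [accel_trace()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_accel_csv <- function(trace, path) {
  n <- length(trace$v)
  dt <- data.table::data.table(
    time = (seq_len(n) - 1) / trace$fs,
    acc_ap = trace$ap, acc_ml = trace$ml, acc_v = trace$v)
  data.table::fwrite(dt, path, scipen = 999)
  invisible(path)
}

#' Write a results table with a JSON run-metadata sidecar
#'
#' @param rows a data.frame (one row per walk or per test).
#' @param path output CSV path; the sidecar is written to
#'   \code{<path>.meta.json}.
#' @param config the run configuration to snapshot.
#' @return \code{path}, invisibly.
#' @export
write_results_table <- function(rows, path, config = trunkgait_config()) {
  if (!is.data.frame(rows)) {
    if (is.list(rows) && length(rows)) {
      cols <- lapply(rows, names)
      if (length(unique(vapply(cols, paste, "", collapse = "\r"))) > 1L)
        stop("schema error: heterogeneous columns across rows", call. = FALSE)
      rows <- data.table::rbindlist(rows)
    } else {
      rows <- data.frame()
    }
  }
  if (nrow(rows) == 0L) {
    warning("writing header-only results table")
    writeLines(paste(names(rows), collapse = ","), path)
  } else {
    data.table::fwrite(as.data.frame(rows), path)
  }
  meta <- list(config = unclass(config),
               config_hash = config_hash(config),
               seed = config$seed,
               n_rows = nrow(rows),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  s <- paste(vapply(unclass(config), function(x) paste(x, collapse = ","),
                    ""), collapse = ";")
  # cheap stable hash (djb2) -- avoids a digest dependency
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
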