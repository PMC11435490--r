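#' Compute all gait indexes for one walk
#'
#' Runs event detection, temporal parameters, harmonic ratios, stability
#' exponents, smoothness and symmetry indexes on a single trace.
#'
#' @param trace an [accel_trace()].
#' @param paretic_side "left", "right" or "none".
#' @param config a [trunkgait_config()].
#' @param slle_axes axes for the stability analysis (default all three).
#' @return one-row data.frame of indexes plus quality metadata.
#' @export
compute_walk_indexes <- function(trace, paretic_side = "none",
                                 config = trunkgait_config(),
                                 slle_axes = c("v", "ml", "ap")) {
  ev <- gait_events(trace, config)
  tp <- temporal_parameters(ev, walk_distance = trace$walk_distance,
                            paretic_side = paretic_side)
  hr <- walk_hr(trace, ev, config)
  sl <- walk_slle(trace, ev, config, axes = slle_axes)
  sm <- suppressWarnings(walk_smoothness_symmetry(trace, ev, tp, config))
  out <- data.frame(
    subject_id = trace$subject_id, timepoint = trace$timepoint,
    gait_speed = tp$gait_speed, stride_time = tp$stride_time,
    hr_v = hr$hr_v, hr_ml = hr$hr_ml, hr_ap = hr$hr_ap,
    hr_v_sd = hr$hr_v_sd, hr_ml_sd = hr$hr_ml_sd, hr_ap_sd = hr$hr_ap_sd,
    slle_v = NA_real_, slle_ml = NA_real_, slle_ap = NA_real_,
    ldlj_v = sm$ldlj_v, ldlj_ml = sm$ldlj_ml, ldlj_ap = sm$ldlj_ap,
    si_stance = sm$si_stance, si_swing = sm$si_swing,
    si_double = sm$si_double, si_single = sm$si_single,
    n_strides = ev$n_retained, stringsAsFactors = FALSE)
  for (ax in slle_axes) out[[paste0("slle_", ax)]] <- sl[[paste0("slle_", ax)]]
  out
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates (or loads) a cohort, computes per-walk indexes, and builds the
#' statistical report. Walks failing the minimum-stride rule (or any stage)
#' are excluded and listed in the run manifest, which also records the
#' configuration snapshot, seed, and exclusion bookkeeping
#' (n input = n analyzed + n excluded).
#'
#' @param n_hs,n_ic,n_sii synthetic group sizes (defaults 42/32/14).
#' @param seed cohort seed.
#' @param config a [trunkgait_config()].
#' @param include_t1 also generate and analyze discharge walks.
#' @param slle_axes axes for the stability stage.
#' @param out_dir optional directory: writes \code{indexes.csv},
#'   \code{report_baseline.csv}, \code{report_longitudinal.csv} (when
#'   available) and \code{run_manifest.json}.
#' @param cohort optional pre-built cohort (as from [generate_cohort()]);
#'   overrides the size arguments.
#' @return list with \code{indexes}, \code{report}, \code{manifest},
#'   \code{excluded}.
#' @export
run_pipeline <- function(n_hs = 42L, n_ic = 32L, n_sii = 14L, seed = 1L,
                         config = trunkgait_config(seed = seed),
                         include_t1 = FALSE,
                         slle_axes = c("v", "ml", "ap"),
                         out_dir = NULL, cohort = NULL) {
  if (is.null(cohort))
    cohort <- generate_cohort(n_hs, n_ic, n_sii, seed = seed,
                              include_t1 = include_t1)
  rows <- list(); excluded <- list()
  for (key in names(cohort$traces)) {
    tr <- cohort$traces[[key]]
    mrow <- cohort$manifest[cohort$manifest$subject_id == tr$subject_id &
                              cohort$manifest$timepoint == tr$timepoint, ]
    res <- tryCatch(
      suppressWarnings(compute_walk_indexes(
        tr, paretic_side = mrow$paretic_side[1], config = config,
        slle_axes = slle_axes)),
      error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[key]] <- data.frame(walk = key,
                                    reason = conditionMessage(res))
    } else {
      res$group <- mrow$group[1]
      rows[[key]] <- res
    }
  }
  if (!length(rows)) stop("all walks failed the pipeline", call. = FALSE)
  indexes <- data.table::rbindlist(rows)
  report <- suppressWarnings(build_report(as.data.frame(indexes)))
  manifest <- list(
    seed = seed, config = unclass(config), config_hash = config_hash(config),
    n_input = length(cohort$traces), n_analyzed = nrow(indexes),
    n_excluded = length(excluded),
    excluded = if (length(excluded))
      data.table::rbindlist(excluded) else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(indexes, file.path(out_dir, "indexes.csv"))
    data.table::fwrite(report$baseline,
                       file.path(out_dir, "report_baseline.csv"))
    if (!is.null(report$longitudinal))
      data.table::fwrite(report$longitudinal,
                         file.path(out_dir, "report_longitudinal.csv"))
    mm <- manifest
    if (!is.null(mm$excluded)) mm$excluded <- as.data.frame(mm$excluded)
    jsonlite::write_json(mm, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(indexes = indexes, report = report, manifest = manifest,
       excluded = manifest$excluded)
}
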