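#' Assign study group from the neutrophil-to-lymphocyte ratio
#'
#' Stroke patients are stratified by immune status: an NLR of 5 or more
#' defines stroke-induced immunosuppression (SII); below 5 the patient is
#' immunocompetent (IC). Healthy subjects carry no NLR.
#'
#' @param nlr numeric NLR value(s); \code{NA} for healthy subjects.
#' @return character vector: "SII", "IC", or "HS" where \code{nlr} is NA.
#' @export
#' @examples
#' assign_group_from_nlr(c(6.68, 2.70, 5, 4.999, NA))
assign_group_from_nlr <- function(nlr) {
  if (any(nlr < 0, na.rm = TRUE)) stop("NLR must be >= 0", call. = FALSE)
  ifelse(is.na(nlr), "HS", ifelse(nlr >= 5, "SII", "IC"))
}

#' Read a cohort manifest
#'
#' One row per subject and timepoint:
#' \code{subject_id, group, nlr, paretic_side, timepoint, trace_path} plus
#' optional clinical score columns (\code{nihss, bi, fim, tinetti}).
#' For patients, the group is derived from the NLR by the >= 5 rule; a
#' declared \code{group} column must agree with the derived label or an
#' inconsistency error is raised.
#'
#' @param path manifest CSV path.
#' @return a \code{data.table} with a validated \code{group} column.
#' @export
read_cohort_manifest <- function(path) {
  m <- data.table::fread(path, showProgress = FALSE)
  required <- c("subject_id", "paretic_side", "timepoint")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols))
    stop("manifest format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"nlr" %in% names(m)) m$nlr <- NA_real_
  derived <- assign_group_from_nlr(m$nlr)
  if ("group" %in% names(m)) {
    have_nlr <- !is.na(m$nlr)
    bad <- which(have_nlr)[m$group[have_nlr] != derived[have_nlr]]
    if (length(bad))
      stop(sprintf(
        "manifest inconsistency: row %d declares group %s but NLR %.3g implies %s",
        bad[1], m$group[bad[1]], m$nlr[bad[1]], derived[bad[1]]),
        call. = FALSE)
    hs_with_nlr <- which(m$group == "HS" & !is.na(m$nlr))
    if (length(hs_with_nlr))
      stop("manifest inconsistency: HS rows must not carry an NLR",
           call. = FALSE)
  }
  m$group <- derived
  if (!all(m$timepoint %in% c("T0", "T1")))
    stop("manifest format error: timepoint must be T0 or T1", call. = FALSE)
  if (!all(m$paretic_side %in% c("left", "right", "none")))
    stop("manifest format error: paretic_side must be left/right/none",
         call. = FALSE)
  m
}
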