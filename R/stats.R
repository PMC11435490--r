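#' Kruskal-Wallis omnibus test with eta-squared effect size
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value (k - 1 df) and
#' the rank eta-squared effect size \eqn{\eta^2 = (H - k + 1)/(n - k)},
#' clipped at 0.
#'
#' @param values numeric response.
#' @param groups group labels (factor or character).
#' @return list with \code{H}, \code{p}, \code{eta_sq}, \code{df}.
#' @export
#' @examples
#' kruskal_wallis_eta(1:9, rep(c("a", "b", "c"), each = 3))  # H = 7.2
kruskal_wallis_eta <- function(values, groups) {
  groups <- factor(groups)
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups); n <- length(values)
  if (k < 2L || any(table(groups) < 2L))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  kw <- stats::kruskal.test(values, groups)
  H <- unname(kw$statistic)
  list(H = H, p = kw$p.value, eta_sq = max(0, (H - k + 1) / (n - k)),
       df = unname(kw$parameter))
}

#' Dunn's pairwise post-hoc test with Holm correction
#'
#' Pairwise z statistics from pooled mid-rank mean differences with tie
#' correction, two-sided normal p-values, Holm step-down adjustment.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @return data.frame with one row per pair: \code{group1, group2, z,
#'   p, p_adj}.
#' @export
dunn_holm <- function(values, groups) {
  groups <- factor(groups)
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(groups)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[[a]] + 1 / ni[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = stats::p.adjust(p, method = "holm"),
             stringsAsFactors = FALSE)
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list with \code{chisq}, \code{p}, \code{df}.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(12, 6, 20, 8), 2))  # p = 0.73
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter))
}

#' Mann-Whitney U test
#'
#' Two-sided. Exact enumeration for small samples (both n <= 8, no ties),
#' tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric samples.
#' @return list with \code{U} (for the first sample), \code{p},
#'   \code{method}.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  exact <- length(a) <= 8 && length(b) <= 8 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal")
}

#' Nonparametric two-way (time x group) repeated-measures analysis
#'
#' Rank-based longitudinal analysis for a two-level within-subject factor
#' (time) crossed with a two-or-more-level between-subject factor (group):
#' relative treatment effects from pooled mid-ranks and ANOVA-type
#' statistics (ATS) with the Box approximation for the degrees of freedom.
#' The within-subject effects (time, interaction) are referred to
#' F(f, Inf); the between-subject effect to F(f, f0) with a
#' Satterthwaite-style denominator. Subjects missing a timepoint are
#' dropped with a warning. Optionally the response is residualized on
#' covariates before ranking (off by default; the named rank procedure has
#' no native covariate slot, so this is a pragmatic pre-adjustment and an
#' interpretation caveat).
#'
#' @param value numeric response, one observation per subject x timepoint.
#' @param subject subject identifiers.
#' @param time timepoint labels (two levels).
#' @param group between-subject group labels.
#' @param covariates optional data.frame of subject-level covariates.
#' @return list with per-effect ATS \code{statistic}, \code{df}, \code{p}
#'   for \code{time}, \code{group}, \code{interaction}; the relative
#'   effects \code{rel_effects}; and \code{posthoc_gate} (TRUE when the
#'   interaction is significant at 0.05, the stated gate for further
#'   post-hoc analysis).
#' @export
rank_repeated_measures <- function(value, subject, time, group,
                                   covariates = NULL) {
  d <- data.frame(value = value, subject = as.character(subject),
                  time = factor(time), group = factor(group),
                  stringsAsFactors = FALSE)
  if (nlevels(d$time) != 2L) stop("need exactly two timepoints",
                                  call. = FALSE)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    fit <- stats::lm(d$value ~ ., data = cv)
    d$value <- stats::residuals(fit)
  }
  cnt <- table(d$subject)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad)) {
    warning(length(bad), " subject(s) missing a timepoint; dropped")
    d <- d[!d$subject %in% bad, ]
  }
  # one group per subject
  sg <- unique(d[, c("subject", "group")])
  if (anyDuplicated(sg$subject)) stop("subject in multiple groups",
                                      call. = FALSE)
  d <- d[order(d$group, d$subject, d$time), ]
  a <- nlevels(d$group); tt <- 2L
  n_i <- as.integer(table(sg$group))
  if (any(n_i < 2L)) stop("need >= 2 subjects per group", call. = FALSE)
  N <- nrow(d)
  d$r <- rank(d$value)  # pooled mid-ranks
  # subject rank matrices per group: n_i x t
  groups <- levels(d$group)
  Rlist <- lapply(groups, function(g) {
    dg <- d[d$group == g, ]
    matrix(dg$r, ncol = tt, byrow = TRUE)  # sorted by subject, time
  })
  p_hat <- unlist(lapply(Rlist, colMeans)) / N - 0.5 / N  # (R_bar - .5)/N
  # covariance: block diagonal, V = N * diag(S_i / n_i)
  V <- matrix(0, a * tt, a * tt)
  for (i in seq_len(a)) {
    S <- stats::cov(Rlist[[i]] / N)
    idx <- ((i - 1) * tt + 1):(i * tt)
    V[idx, idx] <- N * S / n_i[i]
  }
  J <- function(k) matrix(1 / k, k, k)
  P <- function(k) diag(k) - J(k)
  M_T <- J(a) %x% P(tt)   # C'(CC')^- C for C = (1/a)1' x P_t
  M_A <- P(a) %x% J(tt)
  M_AT <- P(a) %x% P(tt)
  ats <- function(M, between = FALSE) {
    num <- N * drop(t(p_hat) %*% M %*% p_hat)
    tv <- sum(diag(M %*% V))
    stat <- num / tv
    f <- tv^2 / sum(diag(M %*% V %*% M %*% V))
    if (!between) {
      p <- stats::pf(stat, f, Inf, lower.tail = FALSE)
      list(statistic = stat, df = c(f, Inf), p = p)
    } else {
      # Satterthwaite denominator from the group-wise blocks
      denom <- 0
      for (i in seq_len(a)) {
        idx <- ((i - 1) * tt + 1):(i * tt)
        ti <- sum(diag(M[idx, idx, drop = FALSE] %*%
                         V[idx, idx, drop = FALSE]))
        denom <- denom + ti^2 / (n_i[i] - 1)
      }
      f0 <- if (denom > 0) tv^2 / denom else Inf
      p <- stats::pf(stat, f, f0, lower.tail = FALSE)
      list(statistic = stat, df = c(f, f0), p = p)
    }
  }
  res <- list(time = ats(M_T), group = ats(M_A, between = TRUE),
              interaction = ats(M_AT))
  rel <- matrix(p_hat, nrow = a, byrow = TRUE,
                dimnames = list(groups, levels(d$time)))
  res$rel_effects <- rel
  res$n <- n_i
  res$posthoc_gate <- res$interaction$p < 0.05
  res
}

#' Cross-sectional and longitudinal statistical report
#'
#' Builds the two standard report tables from a per-walk index table:
#' (i) a baseline (T0) three-group comparison per index -- group means
#' (SD), Kruskal-Wallis H, p, eta-squared, and Dunn/Holm post hocs; and
#' (ii) when T1 rows are present, a time x group rank-based
#' repeated-measures table (time, group, interaction p-values) over the
#' patient groups.
#'
#' @param indexes data.frame with columns \code{subject_id, group,
#'   timepoint} and one column per index.
#' @param index_cols index columns to analyze (default: the standard set
#'   present in the table).
#' @return list of class \code{stats_report}: \code{baseline} (data.frame),
#'   \code{posthoc} (list of data.frames), \code{longitudinal}
#'   (data.frame or NULL).
#' @export
build_report <- function(indexes, index_cols = NULL) {
  std <- c("gait_speed", "hr_v", "hr_ml", "hr_ap", "slle_v", "slle_ml",
           "slle_ap", "ldlj_v", "ldlj_ml", "ldlj_ap", "si_stance",
           "si_swing", "si_double", "si_single")
  if (is.null(index_cols)) index_cols <- intersect(std, names(indexes))
  missing_cols <- setdiff(index_cols, names(indexes))
  if (length(missing_cols))
    stop("report error: missing index column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  t0 <- indexes[indexes$timepoint == "T0", ]
  groups <- unique(t0$group)
  baseline <- list(); posthoc <- list()
  for (col in index_cols) {
    v <- t0[[col]]; g <- t0$group
    ok <- !is.na(v)
    row <- list(index = col)
    for (gr in c("IC", "SII", "HS")) {
      vv <- v[ok & g == gr]
      row[[paste0("mean_", tolower(gr))]] <-
        if (length(vv)) mean(vv) else NA_real_
      row[[paste0("sd_", tolower(gr))]] <-
        if (length(vv) > 1) stats::sd(vv) else NA_real_
    }
    gtab <- table(droplevels(factor(g[ok])))
    if (length(gtab) >= 2 && all(gtab >= 2)) {
      kw <- kruskal_wallis_eta(v[ok], g[ok])
      row$H <- kw$H; row$p <- kw$p; row$eta_sq <- kw$eta_sq
      posthoc[[col]] <- dunn_holm(v[ok], g[ok])
    } else {
      warning("index ", col, ": fewer than two groups; tests set to NA")
      row$H <- NA_real_; row$p <- NA_real_; row$eta_sq <- NA_real_
    }
    baseline[[col]] <- as.data.frame(row)
  }
  out <- list(baseline = do.call(rbind, baseline), posthoc = posthoc,
              longitudinal = NULL)
  pw <- indexes[indexes$group %in% c("IC", "SII"), ]
  if (any(pw$timepoint == "T1")) {
    lng <- list()
    for (col in index_cols) {
      ok <- !is.na(pw[[col]])
      dd <- pw[ok, ]
      both <- names(which(table(dd$subject_id) == 2L))
      dd <- dd[dd$subject_id %in% both, ]
      if (!nrow(dd)) next
      rr <- tryCatch(
        rank_repeated_measures(dd[[col]], dd$subject_id, dd$timepoint,
                               dd$group),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(rr)) next
      lng[[col]] <- data.frame(
        index = col, p_time = rr$time$p, p_group = rr$group$p,
        p_interaction = rr$interaction$p,
        posthoc_gate = rr$posthoc_gate)
    }
    if (length(lng)) out$longitudinal <- do.call(rbind, lng)
  }
  class(out) <- "stats_report"
  out
}

#' @export
print.stats_report <- function(x, digits = 3, ...) {
  cat("Baseline (T0) three-group comparison:\n")
  print(format(x$baseline, digits = digits), row.names = FALSE)
  if (!is.null(x$longitudinal)) {
    cat("\nRepeated-measures (time x group) p-values:\n")
    print(format(x$longitudinal, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
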