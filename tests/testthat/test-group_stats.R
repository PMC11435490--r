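test_that("Kruskal-Wallis H, p and eta-squared match hand computation", {
  r <- kruskal_wallis_eta(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(r$H, 7.2, tolerance = 1e-10)
  expect_equal(r$p, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$eta_sq, (7.2 - 2) / 6, tolerance = 1e-10)
  # identical distributions across groups
  r0 <- kruskal_wallis_eta(rep(1:3, 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(r0$H, 0, tolerance = 1e-12)
  expect_equal(r0$eta_sq, 0)
  # rank invariance under strictly monotone transforms
  set.seed(5)
  v <- rnorm(30); gl <- rep(c("a", "b", "c"), 10)
  expect_equal(kruskal_wallis_eta(exp(v), gl)$H,
               kruskal_wallis_eta(v, gl)$H, tolerance = 1e-12)
  expect_error(kruskal_wallis_eta(1:3, c("a", "a", "b")), ">= 2")
})

test_that("Dunn z and Holm adjustment behave as defined", {
  # hand case: pooled ranks 1..9, mean ranks 2/5/8, se = sqrt(7.5 * 2/3)
  d <- dunn_holm(1:9, rep(c("a", "b", "c"), each = 3))
  se <- sqrt((9 * 10 / 12) * (2 / 3))
  expect_equal(d$z[d$group1 == "a" & d$group2 == "c"], (2 - 8) / se,
               tolerance = 1e-10)
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], (2 - 5) / se,
               tolerance = 1e-10)
  # Holm: smallest adjusted p = 3 x smallest raw p (3 pairwise tests)
  expect_equal(min(d$p_adj), min(3 * d$p, 1), tolerance = 1e-12)
  # Holm monotonicity in raw-p order
  expect_true(all(diff(d$p_adj[order(d$p)]) >= -1e-12))
  # identical groups: everything at 1
  d0 <- dunn_holm(rep(1:4, 3), rep(c("a", "b", "c"), each = 4))
  expect_true(all(d0$p_adj == 1))
  # well-separated larger groups all significant after Holm
  set.seed(6)
  v <- c(rnorm(10), rnorm(10) + 5, rnorm(10) + 10)
  d1 <- dunn_holm(v, rep(c("a", "b", "c"), each = 10))
  expect_true(all(d1$p_adj < 0.05))
})

test_that("2x2 chi-square without continuity correction", {
  # cohort sex table: 12/20 vs 6/8
  r <- chi_square_2x2(matrix(c(12, 6, 20, 8), 2))
  expect_equal(round(r$p, 2), 0.73)
  # dysphagia table: 3/29 vs 6/8
  r2 <- chi_square_2x2(matrix(c(3, 6, 29, 8), 2))
  expect_equal(round(r2$p, 2), 0.01)
  # balanced table
  r3 <- chi_square_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r3$chisq, 0)
  expect_equal(r3$p, 1)
  # identity with the squared two-proportion z statistic
  tab <- matrix(c(12, 6, 20, 8), 2)
  p1 <- 12 / 32; p2 <- 6 / 14; pp <- 18 / 46
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 32 + 1 / 14))
  expect_equal(r$chisq, z^2, tolerance = 1e-10)
  expect_error(chi_square_2x2(matrix(c(0, 0, 1, 2), 2)), "marginal")
})

test_that("Mann-Whitney handles exact and approximate branches", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_identical(r$method, "exact")
  # U identity over random draws
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1))
    ua <- mann_whitney(a, b)$U; ub <- mann_whitney(b, a)$U
    expect_equal(unname(ua + ub), length(a) * length(b))
  }
  expect_equal(mann_whitney(rep(1:5, 2), rep(1:5, 2))$p, 1, tolerance = 1e-9)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("rank repeated-measures analysis detects the right effects", {
  set.seed(11)
  n <- 18
  subj <- rep(sprintf("s%02d", 1:(2 * n)), each = 2)
  grp <- rep(c("IC", "SII"), each = 2 * n)
  tim <- rep(c("T0", "T1"), 2 * n)
  base <- rep(rnorm(2 * n), each = 2)
  y0 <- base + rnorm(4 * n, sd = 0.5)
  r0 <- rank_repeated_measures(y0, subj, tim, grp)
  # constant added at T1: strong time effect, interaction unaffected
  y1 <- y0 + 2 * (tim == "T1")
  r1 <- rank_repeated_measures(y1, subj, tim, grp)
  expect_lt(r1$time$p, 0.01)
  expect_gt(r1$interaction$p, 0.05)
  # swapping group labels leaves the group statistic invariant
  grp_sw <- ifelse(grp == "IC", "SII", "IC")
  r_sw <- rank_repeated_measures(y1, subj, tim, grp_sw)
  expect_equal(r_sw$group$statistic, r1$group$statistic, tolerance = 1e-10)
  # relative effects flip rows under the swap
  expect_equal(unname(r_sw$rel_effects["IC", ]),
               unname(r1$rel_effects["SII", ]), tolerance = 1e-12)
  # monotone transform invariance
  r_exp <- rank_repeated_measures(exp(y1), subj, tim, grp)
  expect_equal(r_exp$time$statistic, r1$time$statistic, tolerance = 1e-10)
  # genuine interaction is detected
  y2 <- y0 + 2 * (tim == "T1") * (grp == "SII")
  r2 <- rank_repeated_measures(y2, subj, tim, grp)
  expect_lt(r2$interaction$p, 0.01)
  expect_true(r2$posthoc_gate)
})

test_that("subjects missing a timepoint are dropped with a warning", {
  subj <- c(rep("a", 2), rep("b", 2), rep("c", 2), rep("d", 2), "e",
            rep("f", 2), rep("g", 2), rep("h", 2), rep("i", 2))
  tim <- c(rep(c("T0", "T1"), 4), "T0", rep(c("T0", "T1"), 4))
  grp <- c(rep("IC", 9), rep("SII", 8))
  set.seed(3)
  y <- rnorm(length(subj))
  expect_warning(r <- rank_repeated_measures(y, subj, tim, grp),
                 "missing a timepoint")
  expect_identical(sum(r$n), 8L)
})

test_that("report builder mirrors the baseline and longitudinal layouts", {
  set.seed(13)
  n <- c(HS = 12, IC = 10, SII = 8)
  idx <- do.call(rbind, lapply(names(n), function(g) {
    data.frame(subject_id = sprintf("%s%02d", g, 1:n[[g]]), group = g,
               timepoint = "T0",
               hr_ml = rnorm(n[[g]], c(HS = 1.9, IC = 1.5, SII = 1.2)[[g]],
                             0.15),
               slle_ml = rnorm(n[[g]], c(HS = 0.5, IC = 0.75,
                                         SII = 0.9)[[g]], 0.1))
  }))
  rep1 <- build_report(idx)
  expect_s3_class(rep1, "stats_report")
  expect_identical(rep1$baseline$index, c("hr_ml", "slle_ml"))
  expect_lt(rep1$baseline[rep1$baseline$index == "hr_ml", "p"], 0.01)
  expect_true(all(c("mean_hs", "sd_sii", "H", "eta_sq") %in%
                    names(rep1$baseline)))
  expect_identical(nrow(rep1$posthoc$hr_ml), 3L)
  # longitudinal table appears when T1 rows exist
  idx_t1 <- idx[idx$group != "HS", ]
  idx_t1$timepoint <- "T1"
  idx_t1$hr_ml <- idx_t1$hr_ml + 0.3
  rep2 <- build_report(rbind(idx, idx_t1))
  expect_false(is.null(rep2$longitudinal))
  expect_lt(rep2$longitudinal[rep2$longitudinal$index == "hr_ml",
                              "p_time"], 0.05)
  # single-group input degrades with a warning, not an error
  expect_warning(rep3 <- build_report(idx[idx$group == "HS", ]),
                 "fewer than two groups")
  expect_true(is.na(rep3$baseline$H[1]))
  expect_error(build_report(idx, index_cols = "nope"), "missing index")
})

test_that("optional covariate residualization runs before ranking", {
  set.seed(21)
  n <- 16
  subj <- rep(sprintf("s%02d", 1:(2 * n)), each = 2)
  grp <- rep(c("IC", "SII"), each = 2 * n)
  tim <- rep(c("T0", "T1"), 2 * n)
  age <- rep(runif(2 * n, 50, 85), each = 2)
  y <- 0.05 * age + rnorm(4 * n, sd = 0.3) + 0.5 * (tim == "T1")
  r_adj <- rank_repeated_measures(y, subj, tim, grp,
                                  covariates = data.frame(age = age))
  expect_lt(r_adj$time$p, 0.05)
})
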