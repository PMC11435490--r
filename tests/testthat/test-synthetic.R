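test_that("generation is deterministic given the spec", {
  spec <- synthetic_spec(seed = 12, sigma_n = 0.1, sigma_t = 0.02,
                         sigma_a = 0.05)
  g1 <- generate_trace(spec)
  g2 <- generate_trace(spec)
  expect_identical(g1$trace$v, g2$trace$v)
  expect_identical(g1$truth$ic_times, g2$truth$ic_times)
})

test_that("spec validation rejects impossible worlds", {
  expect_error(synthetic_spec(delta = 0.3), "delta")
  expect_error(synthetic_spec(stride_time = -1), "stride_time")
  expect_error(synthetic_spec(sigma_n = -0.1), "noise")
  expect_error(synthetic_spec(stance_left = 0.45), "stance")
})

test_that("programmed stride count appears in the truth record", {
  g <- test_walk(seed = 2, n_strides = 26)
  expect_length(g$truth$ic_left, 27)   # 26 stride start/end pairs
  expect_length(g$truth$ic_right, 26)
  expect_identical(g$truth$n_strides, 26L)
})

test_that("noise-free pipeline estimates match analytic truth", {
  g <- test_walk(seed = 5, hr_v = 2.0, hr_ml = 1.8, hr_ap = 1.9,
                 sigma_w = 0, stance_left = 0.66, stance_right = 0.60,
                 paretic_side = "left")
  expect_equal(g$truth$hr_v, 2.0, tolerance = 1e-9)  # solver is exact
  ev <- gait_events(g$trace)
  hr <- walk_hr(g$trace, ev)
  expect_equal(hr$hr_v, 2.0, tolerance = 0.02)
  expect_equal(hr$hr_ml, 1.8, tolerance = 0.02)
  # contact times within 10 ms
  err <- vapply(ev$ic_times, function(t) min(abs(g$truth$ic_times - t)), 0)
  expect_lt(max(err), 0.010)
  # stance symmetry index within 0.5 of truth
  tp <- temporal_parameters(ev, g$trace$walk_distance, "left")
  si <- symmetry_index(tp[["paretic"]][["stance"]],
                       tp[["nonparetic"]][["stance"]])
  expect_equal(si, unname(g$truth$si["si_stance"]), tolerance = 0.5)
})

test_that("cohort generation respects sizes, NLR rule and determinism", {
  co <- generate_cohort(5, 4, 3, seed = 2)
  expect_length(co$traces, 12)
  expect_identical(as.integer(table(co$manifest$group)[c("HS", "IC", "SII")]),
                   c(5L, 4L, 3L))
  expect_true(all(co$manifest$nlr[co$manifest$group == "SII"] >= 5))
  expect_true(all(co$manifest$nlr[co$manifest$group == "IC"] < 5))
  expect_true(all(is.na(co$manifest$nlr[co$manifest$group == "HS"])))
  expect_true(all(co$manifest$paretic_side[co$manifest$group == "HS"] ==
                    "none"))
  co2 <- generate_cohort(5, 4, 3, seed = 2)
  expect_identical(co$traces[[1]]$v, co2$traces[[1]]$v)
  expect_identical(co$manifest, co2$manifest)
  expect_error(generate_cohort(0, 0, 0), "empty")
})

test_that("T1 walks exist only for patients and shift the targets", {
  co <- generate_cohort(2, 3, 2, seed = 3, include_t1 = TRUE)
  tp <- table(co$manifest$group, co$manifest$timepoint)
  expect_identical(unname(tp["HS", "T0"]), 2L)
  expect_false("T1" %in% colnames(tp) && tp["HS", "T1"] > 0)
  expect_identical(unname(tp["IC", "T1"]), 3L)
  # reported harmonic-ratio targets improve from admission to discharge
  tr <- co$truth
  expect_gt(mean(tr$hr_ml[tr$timepoint == "T1"]),
            mean(tr$hr_ml[tr$timepoint == "T0"]))
})
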