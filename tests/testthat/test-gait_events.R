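test_that("event filter preserves gait band and removes high frequencies", {
  fs <- 100
  t <- (0:4999) / fs
  lo <- sin(2 * pi * 1 * t)
  hi <- sin(2 * pi * 10 * t)
  out <- preprocess_vertical(lo + hi, fs)
  # recovered 1 Hz component within 5% (projection onto the tone)
  amp_lo <- 2 * abs(mean(out * exp(-2i * pi * 1 * t)))
  expect_gt(amp_lo, 0.95)
  expect_lt(amp_lo, 1.05)
  # 10 Hz attenuated by >= 40 dB
  amp_hi <- 2 * abs(mean(out * exp(-2i * pi * 10 * t)))
  expect_lt(amp_hi, 0.01)
  # constants and linear trends vanish
  expect_lt(max(abs(preprocess_vertical(rep(9.81, 1000), fs))), 1e-9)
  expect_lt(max(abs(preprocess_vertical(seq(0, 5, length.out = 1000), fs))),
            1e-6)
  expect_error(preprocess_vertical(rnorm(100), fs), "length error")
})

test_that("initial contacts land on programmed step times", {
  g <- test_walk(seed = 11, n_strides = 27, sigma_w = 0)
  pre <- preprocess_vertical(g$trace$v, 100)
  ics <- detect_initial_contacts(pre, 100)
  # 27 strides = 55 true contacts; edges may be discarded
  expect_gte(length(ics$ic_times), 50)
  expect_lte(length(ics$ic_times), 55)
  err <- vapply(ics$ic_times,
                function(t) min(abs(g$truth$ic_times - t)), 0)
  expect_lt(max(err), 0.030)
  # no duplicate detections within half a step
  expect_gt(min(diff(ics$ic_times)), 0.25 * 1.2)
})

test_that("degenerate inputs raise insufficient-gait errors", {
  expect_error(detect_initial_contacts(rep(0, 3000), 100),
               "insufficient-gait")
  set.seed(42)
  expect_error(detect_initial_contacts(
    preprocess_vertical(rnorm(3000), 100), 100), "insufficient-gait")
})

test_that("event detection matches truth across seeded parameter draws", {
  matched <- 0L; total <- 0L
  for (sd in 1:4) {
    for (grp in c("HS", "IC", "SII")) {
      spec <- trunkgait:::draw_subject_spec(grp, sd * 211L)
      g <- generate_trace(spec)
      ev <- suppressWarnings(gait_events(g$trace))
      err <- vapply(g$truth$ic_times, function(t)
        min(abs(ev$ic_times - t)), 0)
      # edge contacts may legitimately be dropped; count interior truth
      interior <- g$truth$ic_times > min(ev$ic_times) - 0.3 &
        g$truth$ic_times < max(ev$ic_times) + 0.3
      matched <- matched + sum(err[interior] < 0.030)
      total <- total + sum(interior)
      expect_gt(min(diff(ev$ic_times)), 0.2)  # no duplicates
    }
  }
  expect_gte(matched / total, 0.95)
})

test_that("event times are shift-equivariant and amplitude-invariant", {
  g <- test_walk(seed = 9)
  tr <- g$trace
  ev <- gait_events(tr)
  # amplitude scaling
  tr_sc <- tr
  tr_sc$v <- 3.7 * tr$v; tr_sc$ml <- 3.7 * tr$ml; tr_sc$ap <- 3.7 * tr$ap
  ev_sc <- gait_events(tr_sc)
  expect_equal(ev_sc$ic_times, ev$ic_times, tolerance = 1e-12)
  expect_equal(ev_sc$fc_times, ev$fc_times, tolerance = 1e-12)
  # shift by k samples
  k <- 37L
  tr_sh <- accel_trace(ap = tr$ap[-(1:k)], ml = tr$ml[-(1:k)],
                       v = tr$v[-(1:k)], fs = tr$fs,
                       walk_distance = tr$walk_distance)
  ev_sh <- gait_events(tr_sh)
  # compare interior contacts present in both
  common <- ev$ic_times[ev$ic_times > 3 & ev$ic_times < max(ev$ic_times) - 3]
  # sub-sample refinement interacts with boundary padding at the 1e-5 s
  # level; 0.1 ms is far below any physiological relevance
  for (tt in common[1:10]) {
    expect_lt(min(abs(ev_sh$ic_times - (tt - k / tr$fs))), 1e-4)
  }
})

test_that("side labels follow the ML axis and degrade gracefully", {
  g <- test_walk(seed = 15)
  ev <- gait_events(g$trace)
  idx <- vapply(ev$ic_times, function(t)
    which.min(abs(g$truth$ic_times - t)), 1L)
  expect_identical(ev$ic_sides, g$truth$ic_sides[idx])
  # flat ML: warning and alternation fallback
  pre <- preprocess_vertical(g$trace$v, 100)
  ics <- detect_initial_contacts(pre, 100)
  expect_warning(s <- assign_sides(ics$ic_idx, rep(0, length(g$trace$ml)),
                                   100),
                 "side-ambiguity")
  expect_identical(s, rep_len(c("left", "right"), length(s)))
})

test_that("stride segmentation trims two strides per end and enforces 20", {
  ic <- seq(0, by = 0.6, length.out = 2 * 26 + 1)  # 26 strides
  sides <- rep_len(c("left", "right"), length(ic))
  win <- segment_and_trim(ic, sides)
  expect_equal(nrow(win), 22)
  expect_true(all(diff(win$start) > 0))

  ic24 <- seq(0, by = 0.6, length.out = 2 * 24 + 1)
  expect_equal(nrow(segment_and_trim(ic24, rep_len(c("left", "right"),
                                                   length(ic24)))), 20)
  ic22 <- seq(0, by = 0.6, length.out = 2 * 22 + 1)
  expect_error(segment_and_trim(ic22, rep_len(c("left", "right"),
                                              length(ic22))),
               "18 < 20")
})

test_that("temporal parameters recover programmed stance and speed", {
  g <- test_walk(seed = 7, stride_time = 1.2, stance_left = 0.6,
                 stance_right = 0.6, speed = 0.70, sigma_w = 0)
  ev <- gait_events(g$trace)
  tp <- temporal_parameters(ev, g$trace$walk_distance)
  expect_equal(unname(tp$stance[["left"]]), 0.72, tolerance = 0.05 * 0.72)
  expect_equal(unname(tp$stance[["right"]]), 0.72, tolerance = 0.05 * 0.72)
  # symmetric gait: left and right stance within one sample
  expect_lt(abs(tp$stance[["left"]] - tp$stance[["right"]]), 0.011)
  # stance + swing = stride time
  expect_lt(abs(tp$stance[["left"]] + tp$swing[["left"]] - tp$stride_time),
            0.011)
  expect_equal(tp$gait_speed, 0.70, tolerance = 1e-3)
})
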