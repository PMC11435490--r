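test_that("stride spectrum resolves pure stride-locked tones", {
  n <- 120                     # one stride of 1.2 s at 100 Hz
  phi <- (0:(n - 1)) / n
  x <- 2 * sin(2 * pi * 2 * phi) + 1 * sin(2 * pi * 1 * phi)
  a <- stride_spectrum(x, 20)
  expect_equal(a[2], 2, tolerance = 1e-9)
  expect_equal(a[1], 1, tolerance = 1e-9)
  expect_lt(max(a[3:20]), 1e-9)

  expect_lt(max(stride_spectrum(rep(3, n), 20)), 1e-9)
  a3 <- stride_spectrum(sin(2 * pi * 3 * phi), 20)
  expect_equal(a3[3], 1, tolerance = 1e-9)
  expect_lt(max(a3[-3]), 1e-9)
  expect_error(stride_spectrum(rnorm(30)), "40 samples")
})

test_that("harmonic ratio follows the even/odd conventions", {
  a <- numeric(20); a[2] <- 2; a[1] <- 1
  expect_equal(harmonic_ratio(a, "V"), 2)
  expect_equal(harmonic_ratio(a, "AP"), 2)
  expect_equal(harmonic_ratio(a, "ML"), 0.5)
  # equal even and odd content
  expect_equal(harmonic_ratio(rep(1, 20), "V"), 1)
  # degenerate spectra hit the floor / cap
  odd_only <- numeric(20); odd_only[seq(1, 19, 2)] <- 1
  expect_equal(harmonic_ratio(odd_only, "V"), 0)
  even_only <- numeric(20); even_only[seq(2, 20, 2)] <- 1
  expect_equal(harmonic_ratio(even_only, "V"), 1e6)
  # axis-convention duality up to the floor
  set.seed(1)
  a <- runif(20, 0.1, 2)
  expect_equal(harmonic_ratio(a, "ML"), 1 / harmonic_ratio(a, "V"),
               tolerance = 1e-12)
})

test_that("adding odd power decreases HR_V; even power increases it", {
  set.seed(2)
  a <- runif(20, 0.5, 1.5)
  base <- harmonic_ratio(a, "V")
  a_odd <- a; a_odd[seq(1, 19, 2)] <- a_odd[seq(1, 19, 2)] + 0.5
  expect_lt(harmonic_ratio(a_odd, "V"), base)
  a_even <- a; a_even[seq(2, 20, 2)] <- a_even[seq(2, 20, 2)] + 0.5
  expect_gt(harmonic_ratio(a_even, "V"), base)
})

test_that("walk harmonic ratios are scale invariant and periodic-exact", {
  g <- test_walk(seed = 5, sigma_w = 0)   # strictly periodic walk
  ev <- gait_events(g$trace)
  hr <- walk_hr(g$trace, ev)
  # per-stride values identical across strides on a periodic trace
  expect_lt(stats::sd(hr$per_stride$v), 1e-6)
  expect_lt(stats::sd(hr$per_stride$ml), 1e-6)
  # walk mean is the arithmetic mean of per-stride values
  expect_equal(hr$hr_v, mean(hr$per_stride$v), tolerance = 1e-12)
  # amplitude scaling leaves every ratio unchanged
  tr2 <- g$trace
  tr2$v <- 2.5 * tr2$v; tr2$ml <- 2.5 * tr2$ml; tr2$ap <- 2.5 * tr2$ap
  hr2 <- walk_hr(tr2, gait_events(tr2))
  expect_equal(hr2$hr_v, hr$hr_v, tolerance = 1e-9)
  expect_equal(hr2$hr_ml, hr$hr_ml, tolerance = 1e-9)
})

test_that("pipeline harmonic ratios recover analytic generator truth", {
  # noise-free: near-exact agreement
  for (sd in c(5, 9)) {
    g <- test_walk(seed = sd, hr_v = 2.0, hr_ml = 1.8, hr_ap = 1.9,
                   sigma_w = 0, delta = 0.02, stance_left = 0.64)
    hr <- walk_hr(g$trace, gait_events(g$trace))
    expect_equal(hr$hr_v, g$truth$hr_v, tolerance = 0.02)
    expect_equal(hr$hr_ml, g$truth$hr_ml, tolerance = 0.02)
    expect_equal(hr$hr_ap, g$truth$hr_ap, tolerance = 0.02)
  }
  # healthy-preset noise level: within 0.15 of the subject's target
  devs <- c()
  for (sd in 1:6) {
    spec <- trunkgait:::draw_subject_spec("HS", sd * 211L)
    g <- generate_trace(spec)
    hr <- walk_hr(g$trace, suppressWarnings(gait_events(g$trace)))
    devs <- c(devs, abs(hr$hr_ml - g$truth$hr_ml))
  }
  expect_lt(max(devs), 0.15)
})
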