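test_that("afferent lead-lag filter has the stated DC and step behavior", {
  expect_identical(afferent_filter_derivative(90, 0, 90), 0)
  # first-order step response with time constant tau_p
  dt <- 0.001
  p <- 90
  for (i in seq_len(round(2.076 / dt))) {
    p <- p + dt * afferent_filter_derivative(100, 0, p, tau_p = 2.076)
  }
  expect_equal(p, 100 - 10 * exp(-1), tolerance = 1e-3)
})

test_that("set-point pressure resets linearly with workload", {
  expect_equal(set_point_pressure(0, 90, 0.242), 90)
  expect_equal(set_point_pressure(73, 90, 0.242), 107.666)
  expect_equal(set_point_pressure(73, 93, 0.3517), 118.6741)
})

test_that("afferent firing is a bounded logistic about the set point", {
  f0 <- afferent_firing(90, 90)
  expect_equal(f0, 2.52 + 47.78 / 2)
  expect_equal(afferent_firing(-1e4, 90), 2.52, tolerance = 1e-6)
  expect_equal(afferent_firing(1e4, 90), 2.52 + 47.78, tolerance = 1e-6)
  h <- 1e-4
  slope <- (afferent_firing(90 + h, 90) - afferent_firing(90 - h, 90)) / (2 * h)
  expect_equal(slope, 47.78 / (4 * 11.758), tolerance = 1e-6)
  p <- seq(0, 200, by = 5)
  expect_true(all(diff(afferent_firing(p, 90)) > 0))
})

test_that("sympathetic activity is inhibited by afferent firing and driven by
           exercise", {
  expect_equal(sympathetic_activity(1e6, 0), 2.10)
  expect_equal(sympathetic_activity(0, 0), 16.11)
  fas <- seq(0, 60, by = 5)
  expect_true(all(diff(sympathetic_activity(fas, 0)) < 0))
  expect_equal(sympathetic_activity(fas, 73) - sympathetic_activity(fas, 0),
               rep(0.12 * 73, length(fas)))
})

test_that("vagal activity interpolates between its tabulated limits and
           withdraws with workload", {
  # central value at rest: midpoint of the lower and upper limits
  fas0 <- 2.52 + 47.78 / 2
  expect_equal(vagal_activity(fas0, 0), (3.2 + 6.3) / 2)
  expect_equal(vagal_activity(1e4, 0), 6.3, tolerance = 1e-4)
  # at zero afferent firing the activity sits just above the lower limit
  expect_gt(vagal_activity(0, 0), 3.2)
  expect_lt(vagal_activity(0, 0), 3.35)
  # complete withdrawal at heavy exercise, never negative
  wl <- seq(0, 150, by = 10)
  fv <- vagal_activity(fas0, wl)
  expect_true(all(diff(fv) <= 1e-12))
  expect_true(all(fv >= 0))
  expect_identical(vagal_activity(fas0, 150), 0)
})

test_that("effector static responses vanish at the set point and follow the
           tabulated gains", {
  sp <- efferent_setpoints(load_profile("healthy"))
  expect_equal(effector_static_sympathetic(sp$fes_set, sp$fes_set, -0.09), 0)
  expect_identical(effector_static_vagal(sp$fev_set, sp$fev_set, 0.07), 0)
  expect_equal(effector_static_vagal(sp$fev_set + 1, sp$fev_set, 0.07), 0.07)
  # monotone increasing in the delayed activity for positive gain
  fes <- seq(2.2, 25, by = 0.5)
  sf <- effector_static_sympathetic(fes, sp$fes_set, 1.16)
  expect_true(all(diff(sf) > 0))
})

test_that("first-order effector dynamics follow the exponential closed form", {
  t_h <- 2
  dt <- 0.005
  d <- 0
  for (i in seq_len(round(t_h / dt))) d <- effector_dynamics(d, 1, t_h, dt)
  expect_equal(d, 1 - exp(-1), tolerance = 1e-9)
  expect_equal(effector_dynamics(0.5, 0.5, 8, 1), 0.5)
})

test_that("open-loop sweep reproduces the stimulus-response family with
           workload resetting", {
  sw <- baroreflex_curve(paa = seq(0, 200, 2), wl = c(0, 35, 61, 87))
  expect_s3_class(sw, "tbl_df")
  # heart rate falls with imposed pressure for every workload
  for (w in unique(sw$wl)) {
    expect_true(all(diff(sw$hr[sw$wl == w]) < 0))
  }
  # afferent curves at different workloads are horizontal translations
  prof <- load_profile("healthy")
  s0 <- baroreflex_curve(paa = seq(40, 160, 1), wl = 0)$fas
  s87 <- baroreflex_curve(paa = seq(40, 160, 1) + prof$a_reset * 87,
                          wl = 87)$fas
  expect_equal(s87, s0, tolerance = 1e-9)
})

test_that("single-channel heart-rate spans at the operating points match the
           reconstructed reflex", {
  vag <- baroreflex_hr_span("vagal", wl_max = 87)
  expect_equal(vag$hr_rest, 58, tolerance = 1e-6)
  expect_equal(vag$hr_max, 85.472, tolerance = 1e-3)
  sym <- baroreflex_hr_span("sympathetic", wl_max = 87)
  expect_equal(sym$hr_rest, 58, tolerance = 1e-6)
  expect_equal(sym$hr_max, 66.133, tolerance = 1e-3)
})

test_that("holding the input at the reset set point leaves every effector at
           its set-point value (closed-loop controller path)", {
  prof <- load_profile("healthy")
  sim <- simulate_exercise(rest_protocol(60), prof,
                           clamp_paa = prof$paa_set0, clamp_wl = 0)
  cyc <- utils::tail(sim$cycles, 5)
  expect_equal(mean(cyc$tc), 60 / prof$hr_set, tolerance = 1e-3)
  expect_equal(mean(cyc$elmax), prof$elmax, tolerance = 1e-3)
  expect_equal(mean(cyc$ermax), prof$ermax, tolerance = 1e-3)
  expect_equal(mean(cyc$ruba), prof$ruba_set, tolerance = 1e-3)
  expect_equal(mean(cyc$vsp0), prof$vsp0_set, tolerance = 1e-3)
})
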