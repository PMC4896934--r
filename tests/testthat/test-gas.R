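test_that("O2 dissociation curve is a monotone sigmoid with exact inverse", {
  expect_equal(o2_content(100), 19.8525, tolerance = 1e-5)
  p <- seq(1, 150, by = 1)
  cc <- o2_content(p)
  expect_true(all(diff(cc) > 0))
  expect_lt(max(cc), 21)                 # saturates just above 20 ml/dl
  for (pp in c(5, 26.6, 40, 95, 140)) {
    expect_equal(o2_partial_pressure(o2_content(pp)), pp, tolerance = 1e-6)
  }
  # analytic slope matches a numerical derivative
  h <- 1e-5
  expect_equal(o2_content_slope(40),
               (o2_content(40 + h) - o2_content(40 - h)) / (2 * h),
               tolerance = 1e-6)
  expect_error(o2_partial_pressure(25), "range")
})

test_that("CO2 content law is monotone, calibrated to blood norms, with a
           closed-form inverse", {
  expect_equal(co2_content(40), 48)
  expect_equal(co2_content(46), 52)
  expect_gt(co2_content(46), co2_content(40))
  expect_equal(co2_content_slope(40), 0.68725, tolerance = 1e-4)
  for (pp in c(20, 40, 45, 60)) {
    expect_equal(co2_partial_pressure(co2_content(pp)), pp, tolerance = 1e-9)
  }
})

test_that("shunt mixing interpolates between end-capillary and venous blood", {
  expect_identical(arterial_mixing(20, 15, 0), 20)
  expect_equal(arterial_mixing(20, 15, 0.02), 19.9)
  expect_equal(arterial_mixing(20, 15, 1 - 1e-12), 15, tolerance = 1e-9)
})

test_that("alveolar balance is stationary at full equilibrium and has the
           physiological signs", {
  # blood equilibrated with the alveoli and alveolar gas at inspired tension
  c_eq <- o2_content(150)
  d <- alveolar_derivatives(p_o2_alv = 150, p_co2_alv = 40, v_alv = 2.5,
                            v_ap = 100, q_pulm = 90, c_o2_mv = c_eq,
                            c_co2_mv = co2_content(40), vdot_a = 0.2,
                            inspiration = TRUE, pco2_i = 40)
  expect_equal(d$dp_o2, 0, tolerance = 1e-12)
  expect_equal(d$dp_co2, 0, tolerance = 1e-12)
  # expiration with equilibrated blood: single term vanishes
  d2 <- alveolar_derivatives(100, 40, 2.5, 100, 90, o2_content(100),
                             co2_content(40), 0, FALSE)
  expect_equal(d2$dp_o2, 0, tolerance = 1e-12)
  # venous blood below alveolar tension removes O2 and delivers CO2
  d3 <- alveolar_derivatives(100, 40, 2.5, 100, 90, o2_content(40),
                             co2_content(46), 0, FALSE)
  expect_lt(d3$dp_o2, 0)
  expect_gt(d3$dp_co2, 0)
  expect_gt(d3$o2_uptake, 0)
  expect_gt(d3$co2_output, 0)
  # inspiration of fresh air raises alveolar O2 and dilutes CO2
  d4 <- alveolar_derivatives(100, 40, 2.5, 100, 0, o2_content(100),
                             co2_content(40), vdot_a = 0.3,
                             inspiration = TRUE)
  expect_gt(d4$dp_o2, 0)
  expect_lt(d4$dp_co2, 0)
})

test_that("rest-condition alveolar throughput reproduces the Fick closure of
           the resting O2 uptake", {
  # steady state: uptake = (1-ps)*Q*(Ca - Cv); with the resting drive the
  # required a-v difference follows from total VO2 and perfusion
  vo2 <- sum(oxygen_uptake(0, "healthy")$vo2)          # 236.46 ml/min
  q <- 88                                              # cm3/s, ~5.3 l/min
  cv <- o2_content(100) - vo2 / ((1 - 0.02) * q * 0.6)
  d <- alveolar_derivatives(100, 40, 2.5, 100, q, cv, co2_content(46), 0,
                            FALSE)
  expect_equal(d$o2_uptake * 60, vo2, tolerance = 0.02)
})

test_that("tissue balance passes through at equilibrium and obeys Fick", {
  d <- tissue_derivatives(c_o2v = 14, c_co2v = 50, v_i = 300,
                          q_in = 20, q_out = 20, c_o2a = 14, c_co2a = 50,
                          vo2 = 0, rq = 0.9)
  expect_equal(d$dm_o2, 0)
  expect_equal(d$dc_co2, 0)
  # at steady state the a-v difference equals VO2 / Q
  q <- 25; vo2 <- 60                       # cm3/s, ml/min
  avd <- vo2 / 60 / q * 100                # ml/dl
  d2 <- tissue_derivatives(c_o2v = 19 - avd, c_co2v = 50, v_i = 300,
                           q_in = q, q_out = q, c_o2a = 19, c_co2a = 50,
                           vo2 = vo2, rq = 0.9)
  expect_equal(d2$dm_o2, 0, tolerance = 1e-12)
  expect_equal(d2$dc_o2, 0, tolerance = 1e-12)
  # CO2 production enters with the respiratory quotient
  expect_equal(d2$dm_co2, 0.9 * vo2 / 60, tolerance = 1e-12)
})
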