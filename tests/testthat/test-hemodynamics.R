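test_that("atrial pressure is linear with the expected anchors", {
  expect_identical(atrial_pressure(100, 25, 100), 0)
  expect_equal(atrial_pressure(125, 25, 100), 1)
  expect_equal(atrial_pressure(125, 25, 100, pintr = -4), -3)
  # exact linearity in volume and additivity of external pressure
  set.seed(11)
  for (i in 1:20) {
    v <- runif(2, 50, 400); cc <- runif(1, 1, 60); v0 <- runif(1, 0, 200)
    a <- runif(1); pin <- runif(1, -10, 10)
    lhs <- atrial_pressure(a * v[1] + (1 - a) * v[2], cc, v0, pin)
    rhs <- a * atrial_pressure(v[1], cc, v0, pin) +
      (1 - a) * atrial_pressure(v[2], cc, v0, pin)
    expect_equal(lhs, rhs)
  }
})

test_that("ventricular pressure recovers both end-member laws", {
  tc <- 60 / 58
  t_peak <- 0.3 * sqrt(tc) / 2          # activation = 1
  expect_equal(activation(t_peak, tc), 1)
  expect_equal(ventricular_pressure(120, t_peak, tc, 2.5, 5, 0.033, 0.034, 8),
               287.5)
  expect_equal(ventricular_pressure(5, t_peak, tc, 2.5, 5, 0.033, 0.034, 8),
               0)
  # pure passive filling (activation = 0) reproduces the exponential law
  expect_equal(activation(0.9, tc), 0)
  expect_equal(ventricular_pressure(100, 0.9, tc, 2.5, 5, 0.033, 0.034, 8),
               8.98882, tolerance = 1e-5)
  # blend is continuous at the systolic boundary
  t_sys <- 0.3 * sqrt(tc)
  expect_equal(ventricular_pressure(120, t_sys - 1e-9, tc, 2.5, 5,
                                    0.033, 0.034, 8),
               ventricular_pressure(120, t_sys, tc, 2.5, 5, 0.033, 0.034, 8),
               tolerance = 1e-4)
})

test_that("valves conduct forward only", {
  expect_equal(valve_flow(10, 5, 0.02), 250)
  expect_identical(valve_flow(5, 10, 0.02), 0)
  expect_identical(valve_flow(5, 5, 0.02), 0)
  set.seed(21)
  p <- matrix(runif(60, -20, 150), ncol = 2)
  q <- valve_flow(p[, 1], p[, 2], 0.05)
  expect_true(all(q >= 0))
  fwd <- p[, 1] > p[, 2]
  expect_equal(q[fwd], (p[fwd, 1] - p[fwd, 2]) / 0.05)
})

test_that("Starling resistor covers ohmic, waterfall and collapse regimes", {
  r <- 0.015
  expect_equal(starling_resistor_flow(8, 4, 0, r), 4 / r)
  expect_equal(starling_resistor_flow(8, 2, 4, r), 4 / r)  # waterfall
  expect_identical(starling_resistor_flow(3, 2, 5, r), 0)  # collapsed
  # flow is non-increasing in the external pressure, all else fixed
  set.seed(31)
  for (i in 1:25) {
    pin <- runif(1, 0, 20); pout <- runif(1, -5, pin)
    pext <- sort(runif(8, -10, 25))
    q <- starling_resistor_flow(pin, pout, pext, r)
    expect_true(all(diff(q) <= 1e-12))
    expect_true(all(q >= 0))
  }
})

test_that("muscle pump produces antiphase leg pressures scaling with load", {
  expect_identical(muscle_pump_pressure(0.3, 0)$left, 0)
  expect_identical(muscle_pump_pressure(0.7, 0)$right, 0)
  pk <- muscle_pump_pressure(0.25, 73, 0.562)   # sin = 1 for the left leg
  expect_equal(pk$left, 2 * 0.562 * 73)
  expect_equal(pk$left, 82.052)
  t <- seq(0, 2, by = 0.05)
  pp <- muscle_pump_pressure(t, 73, 0.562)
  expect_true(all(pp$left >= 0) && all(pp$right >= 0))
  expect_equal(pp$left + pp$right, rep(2 * 0.562 * 73, length(t)))
})

test_that("circulation derivative conserves blood volume and matches the
           independent network oracle", {
  prof <- load_profile("healthy")
  eff <- setpoint_effective_parameters(prof)
  set.seed(41)
  for (i in 1:8) {
    st <- random_circ_state(prof)
    pintr <- runif(1, -10, 2)
    pim <- runif(2, 0, 60)
    res <- circulation_derivatives(st, prof, eff, pintr, pim[1], pim[2])
    dv <- res$derivatives[1:16]
    expect_lt(abs(sum(dv)), 1e-9)
    orc <- oracle_circulation_derivs(st, prof, eff, pintr, pim[1], pim[2])
    expect_equal(unname(res$derivatives), unname(orc), tolerance = 1e-8)
    # heart and leg venous valves never conduct backward
    expect_true(all(res$flows[c("qli", "qlo", "qri", "qro",
                                "qll_out", "qrl_out")] >= 0))
  }
})

test_that("uniform-pressure state is an equilibrium of the network", {
  prof <- load_profile("healthy")
  eff <- setpoint_effective_parameters(prof)
  p0 <- 10
  vent_vol <- function(a, b, cc) log((p0 - cc) / a) / b
  st <- c(
    vla = prof$vla0 + p0 * prof$cla,
    vlv = vent_vol(prof$al, prof$bl, prof$cl),
    vra = prof$vra0 + p0 * prof$cra,
    vrv = vent_vol(prof$ar, prof$br, prof$cr),
    vaa = p0 * prof$caa, vabd = p0 * prof$cabd,
    vub = prof$vub0_set + p0 * prof$cub,
    vkid = prof$vkid0_set + p0 * prof$ckid,
    vsp = prof$vsp0_set + p0 * prof$csp,
    vll = prof$vll0_set + p0 * prof$cll,
    vrl = prof$vrl0_set + p0 * prof$crl,
    vsup = p0 * prof$csup, vinfext = p0 * prof$cinfext,
    vinfint = p0 * prof$cinfint,
    vap = prof$vap0 + p0 * prof$cap, vvp = prof$vvp0 + p0 * prof$cvp,
    qaa = 0, qap = 0,
    t_c = 0.9)                     # diastole: activation is zero
  res <- circulation_derivatives(st, prof, eff, pintr = 0)
  # every pressure equals p0 except the passive ventricles (= p0 by design)
  expect_equal(max(abs(res$derivatives[1:18])), 0, tolerance = 1e-9)
})
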