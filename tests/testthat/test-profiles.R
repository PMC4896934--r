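test_that("healthy fixture matches the tabulated parameter values", {
  p <- load_profile("healthy")
  tab <- c(
    hr_set = 58, cla = 25, cra = 25, vlv0 = 5, vrv0 = 5,
    al = 0.033, bl = 0.034, cl = 8, ar = 0.05, br = 0.04, cr = 5,
    elmax = 2.5, ermax = 1.1,
    rli = 0.02, rri = 0.02, rlo = 0.02, rro = 0.02,
    raa = 0.01, laa = 5e-5, caa = 0.8, rabd = 0.07, labd = 5e-5, cabd = 0.6,
    ruba_set = 3.52, cub = 8, rubv_set = 0.23, vub0_set = 650,
    rkida_set = 3.62, ckid = 15, rkidv_set = 0.3, vkid0_set = 150,
    rspa_set = 2.69, csp = 55, rspv_set = 0.18, vsp0_set = 1300,
    rlla_set = 12.6, rrla_set = 12.6, cll = 9.5, crl = 9.5,
    rllv_set = 0.6, rrlv_set = 0.6, vll0_set = 175, vrl0_set = 175,
    csup = 15, rsup = 0.06, cinfext = 25, cinfint = 2,
    rinfext = 0.01, rinfint = 0.015,
    rcp = 0.03, cap = 1, rap = 0.075, lap = 3.6e-5, vap0 = 90,
    rvp = 0.005, cvp = 5, vvp0 = 580, weight = 76,
    k_dv = 0.8, pco2_tr = 36.75, e_lung = 2.0, pco2_i = 0,
    pim_max = 0.562, ppl0 = 754, po2_i = 150, ps_shunt = 0.02,
    r_airways = 1, alpha = 30, beta = -0.055, gamma = 2,
    delta = 0.274, epsilon = 17.75, peak_vo2 = 34,
    a_reset = 0.242, b_reset = 0.12, c_reset = -0.041, d_reset = -0.044,
    ka = 11.758, kes = 0.0675, kev = 7.06,
    fes0 = 16.11, fes_inf = 2.10, fev0 = 3.2, fev_inf0 = 6.3,
    paa_set0 = 90, tau_p = 2.076, tau_z = 6.37,
    c_tcs = -0.09, c_tcv = 0.07, c_elmaxs = 0.61, c_ermaxs = 0.133,
    c_rubas = 1.16, c_rkidas = 1.10, c_rspas = 0.95,
    c_rllas = 2.4, c_rrlas = 2.4,
    c_rubamet = 0.73, c_rkidamet = 0.69, c_rspamet = 0.6,
    c_rllamet = 1.5, c_rrlamet = 1.5,
    c_rubvmet = 0.046, c_rkidvmet = 0.06, c_rspvmet = 0.036,
    c_rllvmet = 0.12, c_rrlvmet = 0.12,
    c_vub0s = -28.1, c_vkid0s = -6.5, c_vsp0s = -228.3,
    c_vll0s = -7.8, c_vrl0s = -7.8,
    c_o2ubv_ref = 14, c_o2kidv_ref = 17.5, c_o2spv_ref = 15,
    c_o2llv_ref = 14, c_o2rlv_ref = 14,
    k_met = 1.8, s0 = 0.27, t_met = 2,
    t_elmax = 8, t_ermax = 8, t_ris = 6, t_tcs = 2, t_tcv = 1.5, t_vis = 20)
  for (nm in names(tab)) {
    expect_identical(p[[nm]], unname(tab[nm]), label = nm)
  }
  expect_identical(p$condition, "healthy")
})

test_that("heart-failure fixture applies the tabulated overrides", {
  h <- load_profile("healthy")
  p <- load_profile("hf")
  over <- c(
    hr_set = 85, elmax = 1.5, vlv0 = 25, al = 0.031, bl = 0.031, cl = 8,
    ruba_set = 4.72, rkida_set = 4.88, rspa_set = 3.62,
    rlla_set = 8.52, rrla_set = 8.52, rap = 0.175,
    k_dv = 0.57, e_lung = 2.8, peak_vo2 = 15,
    a_reset = 0.3517, b_reset = 0.02, paa_set0 = 93,
    c_tcs = -0.0594, c_tcv = 0.0462, c_elmaxs = 0.2,
    c_rubas = 1.62, c_rkidas = 1.53, c_rspas = 1.32,
    c_rllas = 4.06, c_rrlas = 4.06, c_vkid0s = -6.1,
    c_o2ubv_ref = 12, c_o2kidv_ref = 15.5, c_o2spv_ref = 13,
    c_o2llv_ref = 12, c_o2rlv_ref = 12,
    vo2_rr_0 = 201.06, vo2_rr_slope = 2.76,
    vo2_leg_0 = 28.87, vo2_leg_slope = 3.83,
    rq_0 = 0.877, rq_slope = 0.006)
  for (nm in names(over)) {
    expect_identical(p[[nm]], unname(over[nm]), label = nm)
  }
  # parameters not overridden are shared with the healthy set
  shared <- c("cla", "caa", "rvp", "ka", "tau_p", "gamma", "k_met", "s0",
              "c_vsp0s", "c_rllamet")
  for (nm in shared) expect_identical(p[[nm]], h[[nm]], label = nm)
})

test_that("overrides replace named parameters and reject unknown names", {
  base <- load_profile("healthy")
  same <- load_profile("healthy", overrides = list(elmax = 2.5))
  expect_identical(unclass(same), unclass(base))
  up <- load_profile("healthy", overrides = list(elmax = 3.1, hr_set = 70))
  expect_identical(up$elmax, 3.1)
  expect_identical(up$hr_set, 70)
  expect_error(load_profile("healthy", overrides = list(nope = 1)),
               "unknown parameter")
  expect_error(load_profile("healthy", overrides = list(1)), "named")
})

test_that("validate_profile reports violations without raising", {
  expect_identical(nrow(validate_profile(load_profile("healthy"))), 0L)
  expect_identical(nrow(validate_profile(load_profile("hf"))), 0L)
  bad <- load_profile("healthy", overrides = list(cap = -1))
  v <- validate_profile(bad)
  expect_identical(v$parameter, "cap")
  expect_match(v$rule, "> 0")
  v2 <- validate_profile(load_profile("healthy", overrides = list(k_dv = 0)))
  expect_true("k_dv" %in% v2$parameter)
  v3 <- validate_profile(load_profile("healthy", overrides = list(s0 = 1.5)))
  expect_true("s0" %in% v3$parameter)
})

test_that("profile serialization round-trips bit-exactly", {
  p <- load_profile("hf")
  tmp <- withr::local_tempfile(fileext = ".params")
  write_profile(p, tmp)
  q <- read_profile(tmp)
  expect_identical(unclass(q)[names(p)], unclass(p))
})

test_that("tidy() lays profiles out as a parameter table", {
  td <- tidy(load_profile("healthy"))
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("parameter", "value", "group") %in% names(td)))
  expect_true("resistance" %in% td$group)
  expect_identical(td$value[td$parameter == "elmax"], 2.5)
})
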