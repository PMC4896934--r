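# Closed-loop integrator behavior: determinism, conservation, and the
# simulation object surface.  Short runs keep the suite fast; the graded
# protocol is exercised in full by the acceptance file.

short <- workload_schedule(c(0, 49), duration = c(60, 60))

test_that("identical inputs give bit-identical simulations", {
  a <- simulate_exercise(short, "healthy")
  b <- simulate_exercise(short, "healthy")
  expect_identical(a$cycles, b$cycles)
  expect_identical(a$series, b$series)
  expect_identical(a$final_state, b$final_state)
})

test_that("blood volume is conserved and valves stay unidirectional through
           an exercise transition with the muscle pump active", {
  sim <- simulate_exercise(short, "healthy")
  expect_lt(sim$diagnostics$blood_volume_drift, 1e-6)
  expect_identical(sim$diagnostics$negative_volume_events, 0L)
  expect_true(all(sim$cycles$min_valve_flow >= 0))
  expect_false(any(is.na(sim$cycles)))
  # total blood equals the weight-based setting
  expect_equal(sim$diagnostics$blood_volume_initial,
               70 * sim$profile$weight)
})

test_that("the engine derivative agrees with the R network reference during
           a live simulation state", {
  sim <- simulate_exercise(rest_protocol(20), "healthy")
  st <- sim$final_state[1:19]
  prof <- sim$profile
  eff <- setpoint_effective_parameters(prof)
  res <- circulation_derivatives(st, prof, eff, pintr = -6)
  orc <- oracle_circulation_derivs(st, prof, eff, pintr = -6)
  expect_equal(unname(res$derivatives), unname(orc), tolerance = 1e-8)
})

test_that("lung-side and tissue-side gas exchange agree at steady rest", {
  sim <- simulate_exercise(rest_protocol(180), "healthy")
  fk <- fick_check(sim)
  expect_lt(abs(fk$rel_err_lung), 0.01)
  expect_lt(abs(fk$rel_err_fick), 0.01)
  expect_identical(sim$diagnostics$o2_debt_steps, 0L)
})

test_that("steady-state summaries, tidiers and plots expose the simulation", {
  sim <- simulate_exercise(short, "healthy")
  ss <- steady_state_summary(sim)
  expect_identical(nrow(ss), 2L)
  expect_true(all(c("hr", "map", "co", "qlla", "tpr", "avdo2_central",
                    "vent", "vsp_shift", "converged") %in% names(ss)))
  expect_true(all(ss$hr > 30 & ss$hr < 200))
  expect_s3_class(tidy(sim), "tbl_df")
  g <- glance(sim)
  expect_identical(nrow(g), 1L)
  expect_identical(g$condition, "healthy")
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(plot_baroreflex(baroreflex_curve(paa = seq(40, 160, 10),
                                                   wl = c(0, 87))),
                  "ggplot")
})

test_that("exported series round-trip through CSV", {
  sim <- simulate_exercise(rest_protocol(10), "healthy")
  dir <- withr::local_tempdir()
  paths <- export_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(file.path(dir, "timeseries.csv"))
  expect_equal(nrow(back), nrow(sim$series))
  expect_equal(back$paa, sim$series$paa, tolerance = 1e-8)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_true(length(js) >= 1)
})

test_that("invalid profiles are rejected before integration", {
  expect_error(simulate_exercise(short, "healthy",
                                 overrides = list(caa = -1)),
               "invalid profile")
})
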