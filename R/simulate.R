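# Closed-loop simulation driver, steady-state summaries and exporters.

.cycle_columns <- c(
  "t_start", "t_end", "hr", "map", "rap", "co", "qlla", "qrla", "qub",
  "qkid", "qsp", "c_o2_art", "c_o2_mv", "c_co2_art", "c_co2_mv",
  "c_o2_ubv", "c_o2_kidv", "c_o2_spv", "c_o2_llv", "c_o2_rlv",
  "po2_art", "pco2_art", "vent", "freq", "tv",
  "elmax", "ermax", "tc", "ruba", "rkida", "rspa", "rlla",
  "vub0", "vkid0", "vsp0", "vsp",
  "fas", "fes", "fev", "wl", "stage", "min_valve_flow", "pintr_min",
  "o2_uptake_lung", "co2_output_lung")

.series_columns <- c(
  "t", "wl", "plv", "paa", "pabd", "pla", "pra", "pap", "qlo", "qlla",
  "vlv", "pintr", "v_lungs", "po2_alv", "pco2_alv", "po2_art", "pco2_art",
  "vent", "hr_target", "elmax", "fes", "fev", "c_o2_llv", "vsp",
  "vll", "pll", "qll_in", "qll_out")

#' Numerical settings for the closed-loop integrator
#'
#' @param dt hemodynamic integration step (s).
#' @param dt_control controller update step (s); must be a multiple of `dt`.
#' @param record_dt time-series output interval (s).
#' @param summary_cycles cardiac cycles averaged in steady-state summaries.
#' @param ss_tol relative change of consecutive cycle means of arterial
#'   pressure and cardiac output below which a stage counts as converged.
#' @return a list of settings.
#' @export
numerical_settings <- function(dt = 2.5e-4, dt_control = 5e-3,
                               record_dt = 0.01, summary_cycles = 15,
                               ss_tol = 0.005) {
  stopifnot(dt > 0, dt_control > 0, summary_cycles >= 1)
  if (abs(dt_control / dt - round(dt_control / dt)) > 1e-9) {
    rlang::abort("`dt_control` must be an integer multiple of `dt`")
  }
  list(dt = dt, dt_control = dt_control, record_dt = record_dt,
       summary_cycles = as.integer(summary_cycles), ss_tol = ss_tol)
}

.schedule_matrix <- function(schedule) {
  stopifnot(all(c("start", "duration", "watts") %in% names(schedule)))
  as.matrix(schedule[, c("start", "duration", "watts")])
}

#' Run the closed-loop cardiorespiratory simulation
#'
#' Integrates the coupled circulation, respiratory mechanics, alveolar and
#' tissue gas exchange, baroreflex, metabolic and ventilation controllers
#' over a workload schedule.  Fully deterministic: two runs with identical
#' inputs are bit-identical.
#'
#' @param protocol a `cardioresp_schedule` (see [workload_schedule()],
#'   [graded_protocol()]).
#' @param condition `"healthy"`, `"hf"`, or a `cardioresp_profile`.
#' @param overrides optional parameter overrides passed to [load_profile()]
#'   (ignored when `condition` is already a profile).
#' @param numerics settings from [numerical_settings()].
#' @param clamp_paa optional constant pressure (mmHg) imposed on the
#'   baroreflex input (open-loop reflex experiments); `NULL` for closed loop.
#' @param clamp_wl workload (W) seen by the controllers when `clamp_paa` is
#'   set.
#' @return a `cardioresp_sim` object with tibbles `cycles` (per cardiac
#'   cycle) and `series` (decimated time series), the profile, the schedule
#'   and integrator diagnostics.
#' @examples
#' \donttest{
#' sim <- simulate_exercise(rest_protocol(60), "healthy")
#' steady_state_summary(sim)
#' }
#' @export
simulate_exercise <- function(protocol = graded_protocol(),
                              condition = "healthy", overrides = NULL,
                              numerics = numerical_settings(),
                              clamp_paa = NULL, clamp_wl = 0) {
  prof <- if (inherits(condition, "cardioresp_profile")) condition
          else load_profile(condition, overrides)
  viol <- validate_profile(prof)
  if (nrow(viol) > 0) {
    rlang::abort(paste0("invalid profile: ", paste(viol$parameter,
                                                   collapse = ", ")))
  }
  num <- numerics
  if (!is.null(clamp_paa)) {
    num$clamp_paa <- as.numeric(clamp_paa)
    num$clamp_wl <- as.numeric(clamp_wl)
  }
  res <- engine_run(initial_circulation_state(prof), .profile_numeric(prof),
                    .gas_constants(), .schedule_matrix(protocol), num)
  if (isTRUE(res$nan_abort)) {
    rlang::abort("integration aborted: non-finite state encountered")
  }
  cycles <- tibble::as_tibble(as.data.frame(res$cycles))
  names(cycles) <- .cycle_columns
  series <- tibble::as_tibble(as.data.frame(res$series))
  names(series) <- .series_columns
  structure(
    list(cycles = cycles, series = series, profile = prof,
         schedule = protocol, numerics = numerics,
         diagnostics = list(
           blood_volume_initial = res$blood_volume_initial,
           blood_volume_final = res$blood_volume_final,
           blood_volume_drift = abs(res$blood_volume_final -
                                      res$blood_volume_initial) /
             res$blood_volume_initial,
           negative_volume_events = res$negative_volume_events,
           o2_debt_steps = res$o2_debt_steps,
           t_final = res$t_final),
         final_state = res$state),
    class = "cardioresp_sim")
}

#' @export
print.cardioresp_sim <- function(x, ...) {
  cat("<cardioresp_sim>", x$profile$condition, "-",
      sprintf("%.0f s simulated, %d cardiac cycles\n",
              x$diagnostics$t_final, nrow(x$cycles)))
  print(steady_state_summary(x))
  invisible(x)
}

#' Per-stage steady-state summary
#'
#' Means over the final `summary_cycles` cardiac cycles of each workload
#' stage: heart rate, mean arterial and right atrial pressure, cardiac
#' output, single-leg flow, total peripheral resistance
#' `(MAP - RAP)/CO`, single-leg resistance, central and leg arteriovenous O2
#' content differences, minute ventilation, resting-region flow and lumped
#' resistance, the splanchnic volume shift from the first stage, and the
#' effective left-ventricular elastance.  A stage is flagged converged when
#' the relative change of consecutive cycle means of arterial pressure and
#' cardiac output over the averaging window stays below the configured
#' tolerance.
#'
#' @param sim a `cardioresp_sim`.
#' @param cycles number of cycles to average (defaults to the simulation's
#'   `summary_cycles` setting).
#' @return a tibble with one row per stage.
#' @export
steady_state_summary <- function(sim, cycles = NULL) {
  stopifnot(inherits(sim, "cardioresp_sim"))
  n_avg <- if (is.null(cycles)) sim$numerics$summary_cycles else cycles
  tol <- sim$numerics$ss_tol
  cyc <- sim$cycles
  stages <- sort(unique(cyc$stage))
  rows <- lapply(stages, function(s) {
    d <- cyc[cyc$stage == s, ]
    if (nrow(d) < 2) return(NULL)
    w <- utils::tail(d, n_avg)
    m <- function(col) mean(w[[col]])
    co_cm3 <- m("co") / 0.06                        # l/min -> cm3/s
    qrr <- m("qub") + m("qkid") + m("qsp")          # resting-region flow l/min
    # trend over the averaging window (halves compared), insensitive to the
    # respiratory modulation of individual cycle means
    h1 <- seq_len(floor(nrow(w) / 2))
    h2 <- seq(floor(nrow(w) / 2) + 1, nrow(w))
    conv <- max(abs(mean(w$map[h2]) - mean(w$map[h1])) / mean(w$map),
                abs(mean(w$co[h2]) - mean(w$co[h1])) / mean(w$co))
    tibble::tibble(
      stage = s, watts = w$wl[nrow(w)],
      t_start = d$t_start[1], t_end = d$t_end[nrow(d)],
      hr = m("hr"), map = m("map"), rap = m("rap"), co = m("co"),
      qlla = m("qlla"),
      tpr = (m("map") - m("rap")) / co_cm3,
      rlla = (m("map") - m("rap")) / (m("qlla") / 0.06),
      avdo2_central = m("c_o2_art") - m("c_o2_mv"),
      avdo2_leg = m("c_o2_art") - m("c_o2_llv"),
      vent = m("vent"), freq = m("freq"), tv = m("tv"),
      q_resting = qrr,
      r_resting = (m("map") - m("rap")) / (qrr / 0.06),
      vsp = m("vsp"), elmax = m("elmax"),
      po2_art = m("po2_art"), pco2_art = m("pco2_art"),
      o2_uptake_lung = m("o2_uptake_lung"),
      co2_output_lung = m("co2_output_lung"),
      converged = conv < tol)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out$vsp_shift <- out$vsp[1] - out$vsp
  }
  out
}

#' Tidy a simulation into per-cycle observations
#'
#' @param x a `cardioresp_sim`.
#' @param ... unused.
#' @return the per-cycle tibble in long-friendly wide form.
#' @export
tidy.cardioresp_sim <- function(x, ...) x$cycles

#' One-row simulation overview
#'
#' @param x a `cardioresp_sim`.
#' @param ... unused.
#' @return a one-row tibble with condition, duration, stage count, final
#'   heart rate / cardiac output / ventilation, and conservation diagnostics.
#' @export
glance.cardioresp_sim <- function(x, ...) {
  ss <- steady_state_summary(x)
  last <- ss[nrow(ss), ]
  tibble::tibble(
    condition = x$profile$condition,
    t_final = x$diagnostics$t_final,
    n_stages = nrow(ss),
    n_cycles = nrow(x$cycles),
    hr_final = last$hr, co_final = last$co, vent_final = last$vent,
    blood_volume_drift = x$diagnostics$blood_volume_drift,
    all_converged = all(ss$converged))
}

#' Fick-principle consistency of a simulation
#'
#' For each stage, compares the O2 delivery implied by the circulation
#' (cardiac output times central arteriovenous content difference) with the
#' imposed total tissue O2 uptake, and the lung-side uptake with the same
#' total.
#'
#' @param sim a `cardioresp_sim`.
#' @return a tibble with per-stage `vo2_fick`, `vo2_drive`, `vo2_lung`
#'   (ml/min) and their relative errors.
#' @export
fick_check <- function(sim) {
  ss <- steady_state_summary(sim)
  prof <- sim$profile
  drive <- vapply(ss$watts, function(w) {
    sum(oxygen_uptake(w, prof)$vo2)
  }, 0)
  fick <- ss$co * 10 * ss$avdo2_central    # l/min * ml/dl -> ml/min
  tibble::tibble(
    stage = ss$stage, watts = ss$watts,
    vo2_drive = drive, vo2_fick = fick, vo2_lung = ss$o2_uptake_lung,
    rel_err_fick = (fick - drive) / drive,
    rel_err_lung = (ss$o2_uptake_lung - drive) / drive)
}

#' Export simulation results
#'
#' Writes the decimated time series as CSV and the per-stage steady-state
#' summary as JSON.
#'
#' @param sim a `cardioresp_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series_path <- file.path(dir, "timeseries.csv")
  cycles_path <- file.path(dir, "cycles.csv")
  summary_path <- file.path(dir, "summary.json")
  utils::write.csv(sim$series, series_path, row.names = FALSE)
  utils::write.csv(sim$cycles, cycles_path, row.names = FALSE)
  ss <- steady_state_summary(sim)
  jsonlite::write_json(
    stats::setNames(split(ss, seq_len(nrow(ss))),
                    paste0("stage_", ss$watts, "W")),
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(series_path, cycles_path, summary_path))
}

#' Plot hemodynamic and ventilatory trends of a simulation
#'
#' @param object a `cardioresp_sim`.
#' @param variables cycle-level variables to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cardioresp_sim <- function(object,
                                    variables = c("hr", "map", "co",
                                                  "qlla", "vent"), ...) {
  d <- tidyr::pivot_longer(
    object$cycles[, c("t_start", variables)],
    cols = -"t_start", names_to = "variable", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_start, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot an open-loop baroreflex sweep
#'
#' @param object a tibble from [baroreflex_curve()].
#' @param y variable to plot against imposed pressure.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_baroreflex <- function(object, y = "hr", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$paa, y = .data[[y]],
                               colour = factor(.data$wl))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object[object$at_setpoint, ], size = 2) +
    ggplot2::labs(x = "imposed aortic pressure (mmHg)", y = y,
                  colour = "workload (W)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
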