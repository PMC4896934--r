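# Exercise protocol: workload schedules and the metabolic drive (district O2
# uptakes and respiratory quotient) they impose.

#' Build a workload schedule
#'
#' @param watts workload of each stage (W), >= 0.
#' @param duration stage durations (s), recycled; stages are applied in
#'   order, each workload step is instantaneous and right-continuous.
#' @return a tibble with columns `start` (s), `duration` (s), `watts`,
#'   class `cardioresp_schedule`.
#' @examples
#' workload_schedule(c(0, 24.5), duration = c(120, 180))
#' @export
workload_schedule <- function(watts, duration = 180) {
  stopifnot(all(watts >= 0), all(duration > 0))
  duration <- rep_len(duration, length(watts))
  out <- tibble::tibble(
    start = cumsum(c(0, duration[-length(duration)])),
    duration = duration,
    watts = as.numeric(watts))
  class(out) <- c("cardioresp_schedule", class(out))
  out
}

#' Graded cycling protocol
#'
#' Rest followed by 24.5, 49 and 73 W stages (workload increments of
#' 24.5 W every 3 minutes, the isokinetic cycling protocol the simulator is
#' validated against).
#'
#' @param stage_s stage duration (s); 180 s (3 min) by default.
#' @param rest_s duration of the initial rest stage (s).
#' @return a `cardioresp_schedule` tibble.
#' @export
graded_protocol <- function(stage_s = 180, rest_s = 180) {
  workload_schedule(c(0, 24.5, 49, 73),
                    duration = c(rest_s, rep(stage_s, 3)))
}

#' Rest-only protocol
#' @param duration duration (s).
#' @return a `cardioresp_schedule` tibble.
#' @export
rest_protocol <- function(duration = 180) workload_schedule(0, duration)

#' Workload at a given time
#'
#' Piecewise-constant, right-continuous lookup; zero before the first stage
#' and the last stage's workload after the schedule ends.
#'
#' @param t time (s), >= 0.
#' @param schedule a `cardioresp_schedule`.
#' @return workload (W).
#' @export
schedule_state <- function(t, schedule) {
  stopifnot(all(t >= 0))
  vapply(t, function(tt) {
    i <- findInterval(tt, schedule$start)
    if (i < 1) 0 else schedule$watts[i]
  }, 0)
}

#' District O2 uptakes for a workload
#'
#' The resting-region uptake (`vo2_rr_0 + vo2_rr_slope * wl`, constant 196
#' ml/min in the healthy condition) is split 30/32/38% among upper body,
#' kidneys and splanchnic region; each leg consumes
#' `vo2_leg_slope * wl + vo2_leg_0`.
#'
#' @param wl workload (W), >= 0.
#' @param condition condition label or `cardioresp_profile`.
#' @return a tibble with one row per district (`ub`, `kid`, `sp`, `ll`,
#'   `rl`) and columns `district`, `vo2` (ml/min).
#' @export
oxygen_uptake <- function(wl, condition = "healthy") {
  stopifnot(length(wl) == 1L, wl >= 0)
  prof <- if (inherits(condition, "cardioresp_profile")) condition
          else load_profile(condition)
  rr <- prof$vo2_rr_0 + prof$vo2_rr_slope * wl
  leg <- prof$vo2_leg_slope * wl + prof$vo2_leg_0
  tibble::tibble(
    district = c("ub", "kid", "sp", "ll", "rl"),
    vo2 = c(rr * prof$split_ub, rr * prof$split_kid, rr * prof$split_sp,
            leg, leg))
}

#' Respiratory quotient for a workload
#'
#' Linear in workload: `rq_0 + rq_slope * wl` (0.859 + 0.0014 WL healthy;
#' 0.877 + 0.006 WL in heart failure, whose steeper slope reflects earlier
#' anaerobic metabolism).
#'
#' @param wl workload (W), >= 0.
#' @param condition condition label or `cardioresp_profile`.
#' @return respiratory quotient (dimensionless).
#' @export
respiratory_quotient <- function(wl, condition = "healthy") {
  stopifnot(all(wl >= 0))
  prof <- if (inherits(condition, "cardioresp_profile")) condition
          else load_profile(condition)
  prof$rq_0 + prof$rq_slope * wl
}
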