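# Arterial baroreflex with exercise resetting: lead-lag afferent filter,
# sigmoidal afferent firing about a workload-shifted set-point pressure,
# sympathetic and vagal efferent activities with workload offsets, and
# per-effector static + first-order dynamic responses.

#' Afferent lead-lag filter derivative
#'
#' `tau_p * dP/dt = paa + tau_z * dpaa_dt - P`; the input is the aortic
#' elastic-recoil pressure (without the intrathoracic component).
#'
#' @param paa input aortic pressure (mmHg).
#' @param dpaa_dt its time derivative (mmHg/s).
#' @param p current filter output (mmHg).
#' @param tau_p pole time constant (s), > 0.
#' @param tau_z zero time constant (s).
#' @return `dP/dt` (mmHg/s).
#' @export
afferent_filter_derivative <- function(paa, dpaa_dt, p, tau_p = 2.076,
                                       tau_z = 6.37) {
  stopifnot(all(tau_p > 0))
  (paa + tau_z * dpaa_dt - p) / tau_p
}

#' Workload-reset set-point pressure
#'
#' @param wl workload (W), >= 0.
#' @param paa_set0 set-point pressure at rest (mmHg).
#' @param a_reset rate of set-point increase (mmHg/W).
#' @return set-point pressure (mmHg).
#' @export
set_point_pressure <- function(wl, paa_set0 = 90, a_reset = 0.242) {
  stopifnot(all(wl >= 0))
  paa_set0 + a_reset * wl
}

#' Afferent baroreceptor firing
#'
#' Logistic firing between saturations: `fas_min + fas_max * e^z / (1 + e^z)`
#' with `z = (p - paa_set)/ka`; strictly increasing in pressure, central
#' value `fas_min + fas_max/2` at the set point, central slope
#' `fas_max / (4 ka)`.
#'
#' @param p filtered pressure (mmHg).
#' @param paa_set set-point pressure (mmHg).
#' @param ka slope parameter (mmHg), > 0.
#' @param fas_min,fas_max lower saturation and logistic span (spikes/s).
#' @return afferent firing rate (spikes/s).
#' @export
afferent_firing <- function(p, paa_set, ka = 11.758, fas_min = 2.52,
                            fas_max = 47.78) {
  stopifnot(all(ka > 0))
  z <- (p - paa_set) / ka
  fas_min + fas_max * stats::plogis(z)
}

#' Efferent sympathetic activity
#'
#' Exponential inhibition by afferent firing plus the progressive exercise
#' stimulation: `fes_inf + (fes0 - fes_inf) * exp(-kes * fas) + b_reset * wl`.
#'
#' @param fas afferent firing (spikes/s), >= 0.
#' @param wl workload (W).
#' @param fes0,fes_inf zero-input and asymptotic activities (spikes/s).
#' @param kes inhibition rate (s).
#' @param b_reset exercise stimulation rate (spikes/s per W).
#' @return sympathetic activity (spikes/s).
#' @export
sympathetic_activity <- function(fas, wl = 0, fes0 = 16.11, fes_inf = 2.10,
                                 kes = 0.0675, b_reset = 0.12) {
  stopifnot(all(fas >= 0))
  fes_inf + (fes0 - fes_inf) * exp(-kes * fas) + b_reset * wl
}

#' Efferent vagal activity with exercise withdrawal
#'
#' Logistic interpolation between the lower limit `fev0` and the
#' workload-lowered upper limit `fev_inf0 + d_reset * wl`, plus the direct
#' withdrawal term `c_reset * wl`, clamped at zero (complete withdrawal):
#' `max(0, (fev0 + fev_inf * e^w)/(1 + e^w) + c_reset * wl)` with
#' `w = (fas - fas0)/kev`.
#'
#' @param fas afferent firing (spikes/s).
#' @param wl workload (W).
#' @param fev0 lower limit (spikes/s).
#' @param fev_inf0 upper limit at rest (spikes/s).
#' @param kev slope parameter (spikes/s).
#' @param c_reset,d_reset withdrawal rates (spikes/s per W), <= 0.
#' @param fas0 central afferent firing (spikes/s), the value at the set-point
#'   pressure.
#' @return vagal activity (spikes/s), >= 0.
#' @export
vagal_activity <- function(fas, wl = 0, fev0 = 3.2, fev_inf0 = 6.3,
                           kev = 7.06, c_reset = -0.041, d_reset = -0.044,
                           fas0 = 2.52 + 47.78 / 2) {
  stopifnot(all(fas >= 0))
  fev_inf <- fev_inf0 + d_reset * wl
  w <- (fas - fas0) / kev
  sig <- stats::plogis(w)
  pmax(0, fev0 * (1 - sig) + fev_inf * sig + c_reset * wl)
}

#' Sympathetic and vagal set-point activities
#'
#' The rest (zero-workload) efferent activities at the central afferent
#' firing; the effector deviations are measured from these, so that at rest
#' with the pressure at its set point every controlled parameter holds its
#' set-point value.
#'
#' @param profile a `cardioresp_profile`.
#' @return list with `fas0`, `fes_set`, `fev_set` (spikes/s).
#' @export
efferent_setpoints <- function(profile) {
  p <- profile
  fas0 <- p$fas_min + p$fas_max / 2
  list(fas0 = fas0,
       fes_set = sympathetic_activity(fas0, 0, p$fes0, p$fes_inf, p$kes,
                                      p$b_reset),
       fev_set = (p$fev0 + p$fev_inf0) / 2)
}

#' Static sympathetic effector response
#'
#' Logarithmic compression of the delayed sympathetic activity about its
#' set-point value:
#' `c_hs * (log(fes - fes_inf + 1) - log(fes_set - fes_inf + 1))`.
#' Zero at the set point, monotone increasing in `fes` for positive gain.
#' The log argument is clamped just above zero for activities driven below
#' the asymptote.
#'
#' @param fes_delayed delayed sympathetic activity (spikes/s).
#' @param fes_set set-point activity (spikes/s).
#' @param c_hs effector gain (effector units per log-spike).
#' @param fes_inf sympathetic asymptote (spikes/s).
#' @return static response `sf_hs` (effector units).
#' @export
effector_static_sympathetic <- function(fes_delayed, fes_set, c_hs,
                                        fes_inf = 2.10) {
  arg <- pmax(fes_delayed - fes_inf + 1, 1e-9)
  ref <- pmax(fes_set - fes_inf + 1, 1e-9)
  c_hs * (log(arg) - log(ref))
}

#' Static vagal effector response
#'
#' Linear in the delayed vagal activity about its set point:
#' `c_hv * (fev - fev_set)`.
#'
#' @param fev_delayed delayed vagal activity (spikes/s).
#' @param fev_set set-point activity (spikes/s).
#' @param c_hv vagal gain.
#' @return static response `sf_hv`.
#' @export
effector_static_vagal <- function(fev_delayed, fev_set, c_hv) {
  c_hv * (fev_delayed - fev_set)
}

#' First-order effector dynamics (one explicit step)
#'
#' `d(delta)/dt = (sf - delta)/t_h`; the integrator uses the exact
#' exponential update over the step, whose steady state is `delta = sf`.
#'
#' @param delta current deviation.
#' @param sf static response (target deviation).
#' @param t_h time constant (s), > 0.
#' @param dt step (s), > 0.
#' @return updated deviation.
#' @export
effector_dynamics <- function(delta, sf, t_h, dt) {
  stopifnot(all(t_h > 0), all(dt > 0))
  sf + (delta - sf) * exp(-dt / t_h)
}

#' Open-loop baroreflex stimulus-response curves
#'
#' Imposes a constant aortic pressure, lets every reflex pathway reach its
#' static steady state (the lead-lag filter passes a constant unchanged and
#' each first-order effector converges to its static response), and reports
#' afferent/efferent activities and the resulting heart rate for each
#' pressure and workload.  The heart-period channels can be restricted to the
#' vagal or the sympathetic arm to isolate their contributions.
#'
#' @param paa imposed aortic pressures (mmHg), e.g. `seq(0, 200, 2)`.
#' @param wl workloads (W); the open-loop experiments use rest plus 35, 61
#'   and 87 W.
#' @param condition `"healthy"` or `"hf"`, or a `cardioresp_profile`.
#' @param channels `"both"`, `"vagal"` (sympathetic heart-period channel
#'   disabled) or `"sympathetic"` (vagal channel disabled).
#' @return a tibble with columns `paa`, `wl`, `paa_set`, `fas`, `fes`, `fev`,
#'   `tc`, `hr`, and `at_setpoint` (whether the imposed pressure equals the
#'   reset set-point for that workload).
#' @examples
#' sweep <- baroreflex_curve(paa = seq(40, 160, 5), wl = c(0, 87),
#'                           channels = "vagal")
#' @export
baroreflex_curve <- function(paa = seq(0, 200, by = 2),
                             wl = c(0, 35, 61, 87),
                             condition = "healthy",
                             channels = c("both", "vagal", "sympathetic")) {
  channels <- match.arg(channels)
  prof <- if (inherits(condition, "cardioresp_profile")) condition
          else load_profile(condition)
  sp <- efferent_setpoints(prof)
  grid <- expand.grid(paa = paa, wl = wl, KEEP.OUT.ATTRS = FALSE)
  paa_set <- set_point_pressure(grid$wl, prof$paa_set0, prof$a_reset)
  fas <- afferent_firing(grid$paa, paa_set, prof$ka, prof$fas_min,
                         prof$fas_max)
  fes <- sympathetic_activity(fas, grid$wl, prof$fes0, prof$fes_inf,
                              prof$kes, prof$b_reset)
  fev <- vagal_activity(fas, grid$wl, prof$fev0, prof$fev_inf0, prof$kev,
                        prof$c_reset, prof$d_reset, sp$fas0)
  d_tcs <- effector_static_sympathetic(fes, sp$fes_set, prof$c_tcs,
                                       prof$fes_inf)
  d_tcv <- effector_static_vagal(fev, sp$fev_set, prof$c_tcv)
  tc <- 60 / prof$hr_set +
    (if (channels != "vagal") d_tcs else 0) +
    (if (channels != "sympathetic") d_tcv else 0)
  tibble::tibble(
    paa = grid$paa, wl = grid$wl, paa_set = paa_set,
    fas = fas, fes = fes, fev = fev, tc = tc, hr = 60 / tc,
    at_setpoint = abs(grid$paa - paa_set) < 1e-9)
}

#' Heart-rate span of one reflex arm across an exercise sweep
#'
#' Convenience wrapper around [baroreflex_curve()]: evaluates the heart rate
#' at the baroreflex operating point (imposed pressure equal to the reset
#' set-point) at rest and at the highest workload, using only the requested
#' heart-period channel.
#'
#' @param channels `"vagal"` or `"sympathetic"`.
#' @param wl_max highest workload of the sweep (W).
#' @param condition condition label or profile.
#' @return list with `hr_rest`, `hr_max`, `delta_hr` (bpm).
#' @export
baroreflex_hr_span <- function(channels = c("vagal", "sympathetic"),
                               wl_max = 87, condition = "healthy") {
  channels <- match.arg(channels)
  prof <- if (inherits(condition, "cardioresp_profile")) condition
          else load_profile(condition)
  at_op <- function(w) {
    ps <- set_point_pressure(w, prof$paa_set0, prof$a_reset)
    baroreflex_curve(paa = ps, wl = w, condition = prof,
                     channels = channels)$hr
  }
  hr_rest <- at_op(0)
  hr_max <- at_op(wl_max)
  list(hr_rest = hr_rest, hr_max = hr_max, delta_hr = hr_max - hr_rest)
}
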