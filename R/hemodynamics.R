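# Cardiac chamber laws, valve and Starling-resistor elements, leg muscle pump,
# and the full circulation derivative.  The closed-loop integrator in src/
# evaluates the same network; the functions here are the package's reference
# formulas, used directly by the open-loop tools and the test suite.

#' Ventricular activation waveform
#'
#' Smooth half-sinusoid activation blending the end-systolic elastance law
#' into the passive exponential filling law: `sin^2(pi * t_c / T_sys)` for
#' `t_c < T_sys`, zero through the rest of the cycle, with systolic duration
#' `T_sys = 0.3 * sqrt(TC)`.
#'
#' @param t_c time within the cardiac cycle (s), in `[0, tc)`.
#' @param tc cardiac cycle duration (s).
#' @return activation in `[0, 1]`.
#' @export
activation <- function(t_c, tc) {
  t_sys <- 0.3 * sqrt(tc)
  ifelse(t_c < t_sys, sin(pi * t_c / t_sys)^2, 0)
}

#' Atrial (passive compliance) pressure
#'
#' @param v atrial volume (cm3).
#' @param c atrial compliance (cm3/mmHg), > 0.
#' @param v0 zero-pressure volume (cm3).
#' @param pintr intrathoracic pressure (mmHg gauge) acting on the chamber.
#' @return pressure (mmHg), `(v - v0)/c + pintr`.
#' @export
atrial_pressure <- function(v, c, v0, pintr = 0) {
  stopifnot(all(c > 0))
  (v - v0) / c + pintr
}

#' Ventricular pressure (time-varying elastance with exponential filling)
#'
#' At full activation the pressure equals the end-systolic elastance law
#' `elmax * (v - v0)`; at zero activation it equals the passive filling law
#' `a * exp(b * v) + c_fill`; in between the two are blended by the
#' [activation()] waveform.  `pintr` is added throughout (intrathoracic
#' chamber).
#'
#' @param v ventricular volume (cm3).
#' @param t_c time within the cardiac cycle (s).
#' @param tc cycle duration (s).
#' @param elmax peak systolic elastance (mmHg/cm3), possibly reflex-controlled.
#' @param v0 zero-pressure filling volume (cm3).
#' @param a,b,c_fill passive filling coefficients (mmHg, 1/cm3, mmHg).
#' @param pintr intrathoracic pressure (mmHg gauge).
#' @return pressure (mmHg).
#' @export
ventricular_pressure <- function(v, t_c, tc, elmax, v0, a, b, c_fill,
                                 pintr = 0) {
  phi <- activation(t_c, tc)
  phi * elmax * (v - v0) + (1 - phi) * (a * exp(b * v) + c_fill) + pintr
}

#' Valve (diode) flow
#'
#' @param p_up,p_down upstream and downstream pressures (mmHg).
#' @param r series resistance (mmHg.s/cm3), > 0.
#' @return flow (cm3/s): `(p_up - p_down)/r` when positive, else 0.
#' @export
valve_flow <- function(p_up, p_down, r) {
  stopifnot(all(r > 0))
  pmax(0, (p_up - p_down) / r)
}

#' Starling resistor (collapsible tube) flow
#'
#' Vascular waterfall: when the external pressure exceeds the downstream
#' pressure the flow becomes `(p_in - p_ext)/r`, independent of downstream
#' pressure; when the external pressure exceeds the upstream pressure the
#' tube collapses and flow is zero; otherwise the element is ohmic (clipped
#' at zero).
#'
#' @param p_in,p_out upstream / downstream pressures (mmHg).
#' @param p_ext external (compressing) pressure (mmHg).
#' @param r tube resistance (mmHg.s/cm3), > 0.
#' @return flow (cm3/s), never negative.
#' @export
starling_resistor_flow <- function(p_in, p_out, p_ext, r) {
  stopifnot(all(r > 0))
  pmax(0, (p_in - pmax(p_out, p_ext)) / r)
}

#' Leg intramuscular pump pressure
#'
#' Antiphase 1 Hz sinusoids (cycling at 60 rpm) whose amplitude scales with
#' the workload: `pim_max * wl * (1 + sin(2 pi t))` for the left leg and the
#' same with a half-cycle phase shift for the right leg.
#'
#' @param t absolute time (s).
#' @param wl workload (W), >= 0.
#' @param pim_max peak intramuscular pressure per workload unit (mmHg/W).
#' @return a list with components `left` and `right` (mmHg, both >= 0).
#' @export
muscle_pump_pressure <- function(t, wl, pim_max = 0.562) {
  stopifnot(all(wl >= 0))
  list(left  = pim_max * wl * (1 + sin(2 * pi * t)),
       right = pim_max * wl * (1 + sin(2 * pi * t + pi)))
}

#' Names of the circulation state variables
#'
#' Sixteen compartment volumes (cm3), two inertance flows (cm3/s) and the
#' cardiac-cycle phase (s), in the order used by the integrator.
#' @return character vector of length 19.
#' @export
circulation_state_names <- function() {
  c("vla", "vlv", "vra", "vrv", "vaa", "vabd", "vub", "vkid", "vsp",
    "vll", "vrl", "vsup", "vinfext", "vinfint", "vap", "vvp",
    "qaa", "qap", "t_c")
}

#' Names of the reflex/metabolically controlled effective parameters
#' @return character vector of length 18.
#' @export
effective_parameter_names <- function() {
  c("tc", "elmax", "ermax",
    "ruba", "rkida", "rspa", "rlla", "rrla",
    "rubv", "rkidv", "rspv", "rllv", "rrlv",
    "vub0", "vkid0", "vsp0", "vll0", "vrl0")
}

#' Effective parameters at their set-point values
#'
#' @param profile a `cardioresp_profile`.
#' @return named numeric vector in the order of [effective_parameter_names()].
#' @export
setpoint_effective_parameters <- function(profile) {
  p <- profile
  v <- c(60 / p$hr_set, p$elmax, p$ermax,
         p$ruba_set, p$rkida_set, p$rspa_set, p$rlla_set, p$rrla_set,
         p$rubv_set, p$rkidv_set, p$rspv_set, p$rllv_set, p$rrlv_set,
         p$vub0_set, p$vkid0_set, p$vsp0_set, p$vll0_set, p$vrl0_set)
  names(v) <- effective_parameter_names()
  v
}

#' Full circulation derivative
#'
#' Evaluates pressures, branch flows and `d(state)/dt` for the closed
#' systemic + pulmonary network: passive atria, time-varying elastance
#' ventricles, diode heart valves, two aortic segments with inertances,
#' five parallel peripheral districts (upper body off the ascending aorta;
#' kidneys, splanchnic region and both legs off the descending aorta),
#' superior and inferior venae cavae with a Starling resistor where the
#' inferior cava enters the chest, leg venous valves, and the two-compartment
#' pulmonary circulation.  The sum of all volume derivatives is zero by
#' construction (closed loop).
#'
#' @param state named numeric vector in the order of
#'   [circulation_state_names()].
#' @param profile a `cardioresp_profile`.
#' @param eff named vector of controlled parameters
#'   ([effective_parameter_names()]); defaults to the set-point values.
#' @param pintr intrathoracic pressure (mmHg gauge).
#' @param pim_left,pim_right leg intramuscular pump pressures (mmHg).
#' @return a list with `derivatives` (named, same order as `state`),
#'   `pressures` and `flows` (named vectors).
#' @export
circulation_derivatives <- function(state, profile,
                                    eff = setpoint_effective_parameters(profile),
                                    pintr = 0, pim_left = 0, pim_right = 0) {
  stopifnot(length(state) == 19L, length(eff) == 18L)
  res <- engine_circulation_derivatives(
    as.numeric(state), .profile_numeric(profile), as.numeric(eff),
    pintr, pim_left, pim_right)
  names(res$derivatives) <- circulation_state_names()
  res
}

#' Initial circulation state
#'
#' Compartments are filled at physiological resting pressures (arteries near
#' the set-point pressure, peripheral districts and veins at venous
#' pressures, ventricles near their resting end-diastolic volumes) and the
#' residual between the resulting total and the weight-based total blood
#' volume (`blood_per_kg * weight`) is assigned to the splanchnic compartment,
#' the largest venous reservoir, so that total volume matches exactly.
#'
#' @param profile a `cardioresp_profile`.
#' @return named numeric state vector ([circulation_state_names()]).
#' @export
initial_circulation_state <- function(profile) {
  p <- profile
  total_blood <- p$blood_per_kg * p$weight
  s <- c(
    vla = p$vla0 + 12 * p$cla,
    vlv = if (identical(p$condition, "hf")) 140 else 120,
    vra = p$vra0 + 10 * p$cra,
    vrv = 110,
    vaa = p$paa_set0 * p$caa,
    vabd = p$paa_set0 * p$cabd,
    vub = p$vub0_set + 10 * p$cub,
    vkid = p$vkid0_set + 10 * p$ckid,
    vsp = p$vsp0_set + 9 * p$csp,
    vll = p$vll0_set + 10 * p$cll,
    vrl = p$vrl0_set + 10 * p$crl,
    vsup = 5 * p$csup,
    vinfext = 5 * p$cinfext,
    vinfint = 4 * p$cinfint,
    vap = p$vap0 + 18 * p$cap,
    vvp = p$vvp0 + 9 * p$cvp,
    qaa = 0, qap = 0, t_c = 0)
  vol_idx <- 1:16
  s["vsp"] <- s["vsp"] + (total_blood - sum(s[vol_idx]))
  s
}
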