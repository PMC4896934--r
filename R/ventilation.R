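# Chemoreflex ventilation controller: minute ventilation from upper-body
# arterial gas tensions, breath pattern, and dead-space correction.

#' Minute ventilation from arterial gas tensions
#'
#' Multiplicative hypoxic drive and additive hypercapnic drive, both gated by
#' the CO2 excess above the ventilation threshold:
#' `vent = (alpha * exp(beta * p_o2) + gamma) * (p_co2 - pco2_tr)`, floored at
#' zero when the CO2 tension is at or below the threshold.
#'
#' @param p_o2,p_co2 upper-body arterial tensions (mmHg), > 0.
#' @param alpha O2 gain (l/(min.mmHg)).
#' @param beta O2 exponent (1/mmHg), negative: ventilation rises as O2 falls.
#' @param gamma CO2 gain (l/(min.mmHg)).
#' @param pco2_tr CO2 threshold (mmHg).
#' @return minute ventilation (l/min), >= 0.
#' @export
minute_ventilation <- function(p_o2, p_co2, alpha = 30, beta = -0.055,
                               gamma = 2, pco2_tr = 36.75) {
  stopifnot(all(p_o2 > 0), all(p_co2 > 0))
  pmax(0, (alpha * exp(beta * p_o2) + gamma) * (p_co2 - pco2_tr))
}

#' Breathing pattern from minute ventilation
#'
#' Frequency rises linearly with ventilation (`freq = delta * vent + epsilon`)
#' and tidal volume is the quotient `vent / freq` (zero at apnea).
#'
#' @param vent minute ventilation (l/min), >= 0.
#' @param delta slope (min/l).
#' @param epsilon intercept (1/min).
#' @return a list with `freq` (1/min) and `tv` (l).
#' @export
breathing_pattern <- function(vent, delta = 0.274, epsilon = 17.75) {
  stopifnot(all(vent >= 0))
  freq <- delta * vent + epsilon
  list(freq = freq, tv = ifelse(vent > 0, vent / freq, 0))
}

#' Effective (alveolar) tidal volume
#'
#' The tabulated `k_dv` is the fraction of the tidal volume reaching the
#' alveoli (the complement of the dead-space fraction given by
#' [dead_space_fraction()]): `tv_eff = tv * k_dv`.
#'
#' @param tv tidal volume (l).
#' @param k_dv effective fraction, in (0, 1].
#' @return effective tidal volume (l).
#' @export
effective_tidal_volume <- function(tv, k_dv) {
  stopifnot(all(k_dv > 0), all(k_dv <= 1))
  tv * k_dv
}

#' Dead-space fraction from aerobic capacity
#'
#' Empirical relation between the dead space/tidal volume ratio and peak O2
#' uptake: `-0.012 * peak_vo2 + 0.611`, clipped to (0, 1).  Its complement at
#' the shipped peak O2 uptakes (34 healthy, 15 heart failure, ml/min/kg)
#' reproduces the tabulated effective fractions (0.8 and 0.57).
#'
#' @param peak_vo2 peak O2 uptake (ml/min/kg), in (0, 50].
#' @return dead space / tidal volume fraction.
#' @export
dead_space_fraction <- function(peak_vo2) {
  stopifnot(all(peak_vo2 > 0), all(peak_vo2 <= 50))
  pmin(1 - 1e-9, pmax(1e-9, -0.012 * peak_vo2 + 0.611))
}
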