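# Blood gas dissociation curves, alveolar mass balance, shunt mixing and
# tissue gas balances.
#
# Curve constants are pinned here and are the single source for both the R
# functions and the compiled integrator (they are passed to it at run time).
# O2: Hill saturation (n = 2.7, P50 = 26.6 mmHg) on a hemoglobin capacity of
# 20.1 ml/dl plus physically dissolved O2 (0.003 ml/dl/mmHg).  CO2: monotone
# power law calibrated to the arterial and mixed-venous norms
# (40 mmHg -> 48 ml/dl, 46 mmHg -> 52 ml/dl), giving a slope of ~0.69
# ml/dl/mmHg at 40 mmHg.

O2_HILL_N <- 2.7
O2_P50 <- 26.6
O2_HB_CAPACITY <- 20.1   # ml O2/dl blood
O2_DISSOLVED <- 0.003    # ml O2/dl/mmHg
CO2_EXP <- log(52 / 48) / log(46 / 40)
CO2_COEF <- 48 / 40^CO2_EXP

# mmHg * (ml STPD / ml) conversion between gas-phase partial pressure and
# blood content flux (BTPS alveolar volume vs STPD gas amounts)
GAS_K863 <- 863

.gas_constants <- function() {
  c(o2_n = O2_HILL_N, o2_p50 = O2_P50, o2_cap = O2_HB_CAPACITY,
    o2_sol = O2_DISSOLVED, co2_exp = CO2_EXP, co2_coef = CO2_COEF,
    k863 = GAS_K863)
}

#' O2 content of blood
#'
#' Hill-type hemoglobin saturation plus dissolved O2; strictly increasing and
#' saturating just above 20 ml/dl in the physiological range.
#'
#' @param p_o2 O2 partial pressure (mmHg), > 0.
#' @return O2 content (ml O2/dl blood).
#' @export
o2_content <- function(p_o2) {
  stopifnot(all(p_o2 > 0))
  s <- p_o2^O2_HILL_N / (O2_P50^O2_HILL_N + p_o2^O2_HILL_N)
  O2_HB_CAPACITY * s + O2_DISSOLVED * p_o2
}

#' Slope of the O2 dissociation curve
#' @param p_o2 O2 partial pressure (mmHg).
#' @return `d content / d pressure` (ml/dl/mmHg).
#' @export
o2_content_slope <- function(p_o2) {
  pn <- p_o2^O2_HILL_N
  kn <- O2_P50^O2_HILL_N
  O2_HB_CAPACITY * O2_HILL_N * kn * pn / (p_o2 * (kn + pn)^2) + O2_DISSOLVED
}

#' Inverse O2 dissociation curve
#'
#' Exact functional inverse of [o2_content()], solved numerically on the
#' physiological pressure range.
#'
#' @param c_o2 O2 content (ml O2/dl blood), `0 <= c_o2 <` capacity.
#' @return O2 partial pressure (mmHg).
#' @export
o2_partial_pressure <- function(c_o2) {
  upper <- 700
  vapply(c_o2, function(cc) {
    if (!is.finite(cc) || cc < 0 || cc >= o2_content(upper)) {
      rlang::abort("O2 content outside the invertible range of the curve")
    }
    if (cc == 0) return(0)
    stats::uniroot(function(p) o2_content(p) - cc,
                   lower = 1e-9, upper = upper, tol = 1e-10)$root
  }, 0)
}

#' CO2 content of blood
#'
#' Monotone power-law content curve without a saturation plateau in the
#' physiological range.
#'
#' @param p_co2 CO2 partial pressure (mmHg), > 0.
#' @return CO2 content (ml CO2/dl blood).
#' @export
co2_content <- function(p_co2) {
  stopifnot(all(p_co2 > 0))
  CO2_COEF * p_co2^CO2_EXP
}

#' Slope of the CO2 content curve
#' @param p_co2 CO2 partial pressure (mmHg).
#' @return ml/dl/mmHg.
#' @export
co2_content_slope <- function(p_co2) {
  CO2_COEF * CO2_EXP * p_co2^(CO2_EXP - 1)
}

#' Inverse CO2 content curve (closed form)
#' @param c_co2 CO2 content (ml CO2/dl blood), > 0.
#' @return CO2 partial pressure (mmHg).
#' @export
co2_partial_pressure <- function(c_co2) {
  stopifnot(all(c_co2 > 0))
  (c_co2 / CO2_COEF)^(1 / CO2_EXP)
}

#' Systemic arterial content from pulmonary shunt mixing
#'
#' Blood leaving the lung capillaries is combined with mixed-venous blood
#' bypassing the lungs according to the shunt fraction.
#'
#' @param c_pulmonary_end end-capillary content (ml gas/dl).
#' @param c_mixed_venous mixed-venous content (ml gas/dl).
#' @param ps shunt fraction, `0 <= ps < 1`.
#' @return systemic arterial content (ml gas/dl).
#' @export
arterial_mixing <- function(c_pulmonary_end, c_mixed_venous, ps) {
  stopifnot(all(ps >= 0), all(ps < 1))
  (1 - ps) * c_pulmonary_end + ps * c_mixed_venous
}

#' Alveolar gas mass-balance derivatives
#'
#' One well-mixed alveolar compartment per gas.  The effective capacitance is
#' the current alveolar gas volume plus the blood-side storage
#' `863 * v_ap * (d content / d pressure)` of the pulmonary blood
#' equilibrating with the alveoli.  Blood flowing through the non-shunted
#' fraction of the pulmonary circulation leaves equilibrated at the alveolar
#' tension, removing O2 from (and delivering CO2 to) the alveolar store;
#' during inspiration alveolar ventilation adds fresh gas at the inspired
#' tensions (`pco2_i = 0`: CO2-free air).  During expiration the fresh-gas
#' term is absent.
#'
#' @param p_o2_alv,p_co2_alv alveolar tensions (mmHg).
#' @param v_alv current alveolar gas volume (l): end-expiratory volume plus
#'   the within-breath incremental alveolar volume.
#' @param v_ap pulmonary arterial blood volume (cm3).
#' @param q_pulm pulmonary capillary blood flow (cm3/s).
#' @param c_o2_mv,c_co2_mv mixed-venous contents entering the lung (ml/dl).
#' @param vdot_a alveolar ventilation (l/s), >= 0; used during inspiration.
#' @param inspiration logical: fresh-gas phase?
#' @param ps shunt fraction.
#' @param po2_i,pco2_i inspired tensions (mmHg).
#' @return list with `dp_o2`, `dp_co2` (mmHg/s) and the instantaneous blood
#'   gas fluxes `o2_uptake`, `co2_output` (ml STPD/s, positive into blood /
#'   out of blood respectively).
#' @export
alveolar_derivatives <- function(p_o2_alv, p_co2_alv, v_alv, v_ap, q_pulm,
                                 c_o2_mv, c_co2_mv, vdot_a, inspiration,
                                 ps = 0.02, po2_i = 150, pco2_i = 0) {
  q_l <- q_pulm / 1000                      # cm3/s -> l/s
  vap_l <- v_ap / 1000
  c_o2_eq <- o2_content(p_o2_alv) / 100     # ml/dl -> ml/ml
  c_co2_eq <- co2_content(p_co2_alv) / 100
  cap_o2 <- v_alv + GAS_K863 * vap_l * o2_content_slope(p_o2_alv) / 100
  cap_co2 <- v_alv + GAS_K863 * vap_l * co2_content_slope(p_co2_alv) / 100
  perf_o2 <- GAS_K863 * (1 - ps) * q_l * (c_o2_mv / 100 - c_o2_eq)
  perf_co2 <- GAS_K863 * (1 - ps) * q_l * (c_co2_mv / 100 - c_co2_eq)
  fresh_o2 <- if (inspiration) vdot_a * (po2_i - p_o2_alv) else 0
  fresh_co2 <- if (inspiration) vdot_a * (pco2_i - p_co2_alv) else 0
  list(dp_o2 = (perf_o2 + fresh_o2) / cap_o2,
       dp_co2 = (perf_co2 + fresh_co2) / cap_co2,
       o2_uptake = (1 - ps) * q_l * (c_o2_eq - c_o2_mv / 100) * 1000,
       co2_output = (1 - ps) * q_l * (c_co2_mv / 100 - c_co2_eq) * 1000)
}

#' Tissue-district gas balance derivatives
#'
#' Stored gas amount `M = content * volume` changes by arterial delivery,
#' venous washout and local consumption/production; tissue gas tension is
#' assumed equilibrated with the venous blood, so the compartment content is
#' the venous content.
#'
#' @param c_o2v,c_co2v district venous contents (ml gas/dl).
#' @param v_i district blood volume (cm3).
#' @param q_in,q_out arterial inflow / venous outflow (cm3/s).
#' @param c_o2a,c_co2a arterial contents (ml gas/dl).
#' @param vo2 district O2 consumption (ml/min), >= 0.
#' @param rq respiratory quotient (CO2 produced per O2 consumed).
#' @param dv_dt rate of change of the district blood volume (cm3/s).
#' @return list with amount derivatives `dm_o2`, `dm_co2` (ml gas/s) and
#'   content derivatives `dc_o2`, `dc_co2` (ml/dl/s).
#' @export
tissue_derivatives <- function(c_o2v, c_co2v, v_i, q_in, q_out, c_o2a, c_co2a,
                               vo2, rq, dv_dt = q_in - q_out) {
  stopifnot(v_i > 0, vo2 >= 0)
  dm_o2 <- c_o2a / 100 * q_in - c_o2v / 100 * q_out - vo2 / 60
  dm_co2 <- c_co2a / 100 * q_in - c_co2v / 100 * q_out + rq * vo2 / 60
  list(dm_o2 = dm_o2, dm_co2 = dm_co2,
       dc_o2 = (dm_o2 - c_o2v / 100 * dv_dt) / v_i * 100,
       dc_co2 = (dm_co2 - c_co2v / 100 * dv_dt) / v_i * 100)
}
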