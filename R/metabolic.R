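# Local metabolic control of peripheral resistance: venous-O2-driven
# sigmoidal vasodilation with first-order dynamics, venous-resistance
# control, and the combination with sympathetic vasoconstriction including
# functional sympatholysis.

#' Metabolic static function
#'
#' Sigmoid in the district venous O2 content, centred at half the reference
#' content: `1 - 1/(1 + exp(k_met * (c_o2v - c_ref/2)))`.  Approximately 1 at
#' the reference content (no vasodilation) and approximately 0 at zero
#' content (maximal vasodilation).
#'
#' @param c_o2v district venous O2 content (ml/dl), >= 0.
#' @param c_ref reference venous content (ml/dl), > 0.
#' @param k_met slope (dl/ml).
#' @return static function value in (0, 1).
#' @export
metabolic_static_function <- function(c_o2v, c_ref, k_met = 1.8) {
  stopifnot(all(c_o2v >= 0), all(c_ref > 0))
  1 - 1 / (1 + exp(k_met * (c_o2v - c_ref / 2)))
}

#' First-order metabolic dynamics (one explicit step)
#'
#' `d(delta)/dt = (c_rimet * (sf - 1) - delta)/t_met`; exact exponential
#' update whose steady state is `c_rimet * (sf - 1) <= 0` (pure
#' vasodilation).
#'
#' @param delta current resistance deviation (mmHg.s/cm3).
#' @param sf metabolic static function in (0, 1).
#' @param c_rimet metabolic gain (mmHg.s/cm3).
#' @param t_met time constant (s), > 0.
#' @param dt step (s), > 0.
#' @return updated deviation.
#' @export
metabolic_dynamics <- function(delta, sf, c_rimet, t_met = 2, dt = 0.005) {
  stopifnot(all(t_met > 0), all(dt > 0))
  target <- c_rimet * (sf - 1)
  target + (delta - target) * exp(-dt / t_met)
}

#' Venous resistance under metabolic control
#'
#' `riv = riv_set + delta_met`, floored at 5% of the set-point value (the
#' floor is never reached with the shipped gain/set-point combinations).
#'
#' @param riv_set set-point venous resistance (mmHg.s/cm3).
#' @param delta_met metabolic deviation (<= 0).
#' @return venous resistance (mmHg.s/cm3), > 0.
#' @export
venous_resistance <- function(riv_set, delta_met) {
  pmax(riv_set + delta_met, 0.05 * riv_set)
}

#' Arterial resistance combining sympathetic and metabolic control
#'
#' Functional sympatholysis: the sympathetic contribution (the controllable
#' part of the set-point resistance plus the reflex deviation) is gated by
#' the tenth power of the metabolic static function, so that sympathetic
#' vasoconstriction collapses sharply as the venous O2 content falls:
#' `ria = ria_set * s0 + (ria_set * (1 - s0) + delta_s) * sf^10 + delta_met`.
#' At `sf = 1` with no metabolic deviation this reduces to
#' `ria_set + delta_s`; as `sf -> 0` the resistance tends to the basal value
#' `ria_set * s0` plus the metabolic deviation.  A floor at 5% of the basal
#' value guards extreme overrides.
#'
#' @param ria_set set-point arterial resistance (mmHg.s/cm3).
#' @param s0 basal-resistance ratio in (0, 1).
#' @param delta_s sympathetic deviation (mmHg.s/cm3).
#' @param sf metabolic static function in (0, 1).
#' @param delta_met metabolic deviation (<= 0).
#' @return arterial resistance (mmHg.s/cm3), > 0.
#' @export
arterial_resistance_combined <- function(ria_set, s0, delta_s, sf,
                                         delta_met) {
  stopifnot(all(s0 > 0), all(s0 < 1))
  r <- ria_set * s0 + (ria_set * (1 - s0) + delta_s) * sf^10 + delta_met
  pmax(r, 0.05 * ria_set * s0)
}

#' Metabolic-control resistance sweep
#'
#' Steady-state percent change of a district's arterial resistance as its
#' venous O2 content is lowered from the reference value, either with the
#' sympathetic pathway suppressed (`ria = ria_set * s0 + delta_met`, the
#' pure metabolic response) or with a fixed sympathetic deviation gated by
#' sympatholysis.
#'
#' @param c_o2v venous O2 contents to sweep (ml/dl).
#' @param district one of `"ub"`, `"kid"`, `"sp"`, `"ll"`, `"rl"`.
#' @param mode `"no-sympathetic"` or `"with-sympathetic"`.
#' @param delta_s sympathetic deviation used in `"with-sympathetic"` mode.
#' @param condition condition label or `cardioresp_profile`.
#' @return a tibble with `c_o2v`, `sf`, `ria`, `pct_change` (percent change
#'   from the resistance at the reference content), `mode`.
#' @export
metabolic_curve <- function(c_o2v = seq(0, 16, by = 0.25),
                            district = c("ll", "ub", "kid", "sp", "rl"),
                            mode = c("no-sympathetic", "with-sympathetic"),
                            delta_s = 0, condition = "healthy") {
  district <- match.arg(district)
  mode <- match.arg(mode)
  prof <- if (inherits(condition, "cardioresp_profile")) condition
          else load_profile(condition)
  ria_set <- prof[[paste0("r", district, "a_set")]]
  gain <- prof[[paste0("c_r", district, "amet")]]
  c_ref <- prof[[paste0("c_o2", district, "v_ref")]]
  sf <- metabolic_static_function(c_o2v, c_ref, prof$k_met)
  delta_met <- gain * (sf - 1)
  ria <- if (mode == "no-sympathetic") {
    pmax(ria_set * prof$s0 + delta_met, 0.05 * ria_set * prof$s0)
  } else {
    arterial_resistance_combined(ria_set, prof$s0, delta_s, sf, delta_met)
  }
  sf_ref <- metabolic_static_function(c_ref, c_ref, prof$k_met)
  ria_ref <- if (mode == "no-sympathetic") {
    ria_set * prof$s0 + gain * (sf_ref - 1)
  } else {
    arterial_resistance_combined(ria_set, prof$s0, delta_s, sf_ref,
                                 gain * (sf_ref - 1))
  }
  tibble::tibble(c_o2v = c_o2v, sf = sf, ria = ria,
                 pct_change = 100 * (ria - ria_ref) / ria_ref,
                 mode = mode)
}
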