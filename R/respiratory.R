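# Respiratory mechanics: sinusoidal pleural-pressure drive, single-compartment
# lung volume dynamics, and the intrathoracic pressure exported to every
# cardiovascular compliance inside the chest.

# mmHg, barometric reference used to express the tabulated absolute mean
# pleural pressure on the gauge scale
PATM_MMHG <- 760

#' Pleural pressure waveform
#'
#' Sinusoid about the mean pleural pressure with amplitude `e_lung * tv / 2`:
#' `ppl0 - (e_lung * tv / 2) * sin(2 pi (freq/60) t_b)`.  Inspiration is the
#' first half of the breath (pleural pressure below its mean).
#'
#' @param t_b time within the breath (s).
#' @param tv tidal volume (l), >= 0.
#' @param freq breathing frequency (1/min), > 0.
#' @param e_lung lung elastance (mmHg/l).
#' @param ppl0 mean pleural pressure (mmHg gauge; the tabulated absolute
#'   754 mmHg is -6 mmHg gauge).
#' @return pleural pressure (mmHg gauge).
#' @export
pleural_pressure <- function(t_b, tv, freq, e_lung = 2, ppl0 = -6) {
  stopifnot(all(freq > 0), all(tv >= 0))
  ppl0 - (e_lung * tv / 2) * sin(2 * pi * (freq / 60) * t_b)
}

#' Lung volume derivative
#'
#' Airway flow from the single-compartment force balance
#' `pm - ppl = r * dV/dt + v_lungs * e_lung`.
#'
#' @param ppl pleural pressure (mmHg gauge).
#' @param v_lungs lung volume above relaxation volume (l).
#' @param r_airways airway resistance (mmHg/(l/s)), > 0.
#' @param e_lung lung elastance (mmHg/l), > 0.
#' @param pm mouth pressure (mmHg gauge; atmospheric = 0).
#' @return `dV/dt` (l/s).
#' @export
lung_volume_derivative <- function(ppl, v_lungs, r_airways = 1, e_lung = 2,
                                   pm = 0) {
  stopifnot(all(r_airways > 0), all(e_lung > 0))
  (pm - ppl - v_lungs * e_lung) / r_airways
}

#' Intrathoracic pressure
#'
#' The pleural pressure expressed relative to atmosphere; applied to both
#' atria, both ventricles, the ascending aorta, the superior vena cava, the
#' inferior vena cava inside the chest, and the pulmonary compartments.
#'
#' @param ppl pleural pressure (mmHg gauge).
#' @return intrathoracic pressure (mmHg), equal to `ppl`.
#' @export
intrathoracic_pressure <- function(ppl) ppl

#' Gauge form of the tabulated mean pleural pressure
#' @param ppl0_abs absolute mean pleural pressure (mmHg, e.g. 754).
#' @return mmHg gauge (e.g. -6).
#' @export
ppl0_gauge <- function(ppl0_abs) ppl0_abs - PATM_MMHG
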