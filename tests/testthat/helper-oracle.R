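# Independent R composition of the circulation network derivative, assembled
# from the package's formula-level primitives and the documented topology.
# Used to cross-check the compiled integrator's derivative evaluation.

# district elastic pressure with the collapse branch below unstressed volume
oracle_compliance_pressure <- function(v, v0, c) {
  if (v >= v0 || v0 <= 0) (v - v0) / c
  else (v0 / c) * log(max(v / v0, 1e-6))
}

oracle_circulation_derivs <- function(state, p, eff, pintr = 0,
                                      pim_l = 0, pim_r = 0) {
  s <- as.list(state)
  names(s) <- circulation_state_names()
  e <- as.list(eff)
  names(e) <- effective_parameter_names()

  pla <- atrial_pressure(s$vla, p$cla, p$vla0, pintr)
  pra <- atrial_pressure(s$vra, p$cra, p$vra0, pintr)
  plv <- ventricular_pressure(s$vlv, s$t_c, e$tc, e$elmax, p$vlv0,
                              p$al, p$bl, p$cl, pintr)
  prv <- ventricular_pressure(s$vrv, s$t_c, e$tc, e$ermax, p$vrv0,
                              p$ar, p$br, p$cr, pintr)
  paa <- s$vaa / p$caa + pintr
  pabd <- s$vabd / p$cabd
  pub <- oracle_compliance_pressure(s$vub, e$vub0, p$cub)
  pkid <- oracle_compliance_pressure(s$vkid, e$vkid0, p$ckid)
  psp <- oracle_compliance_pressure(s$vsp, e$vsp0, p$csp)
  pll <- oracle_compliance_pressure(s$vll, e$vll0, p$cll) + pim_l
  prl <- oracle_compliance_pressure(s$vrl, e$vrl0, p$crl) + pim_r
  psup <- s$vsup / p$csup + pintr
  pinfext <- s$vinfext / p$cinfext
  pinfint <- s$vinfint / p$cinfint + pintr
  pap <- (s$vap - p$vap0) / p$cap + pintr
  pvp <- (s$vvp - p$vvp0) / p$cvp + pintr

  qli <- valve_flow(pla, plv, p$rli)
  qlo <- valve_flow(plv, paa, p$rlo)
  qri <- valve_flow(pra, prv, p$rri)
  qro <- valve_flow(prv, pap, p$rro + p$rcp)
  qub_in <- (paa - pub) / e$ruba
  qkid_in <- (pabd - pkid) / e$rkida
  qsp_in <- (pabd - psp) / e$rspa
  qll_in <- (pabd - pll) / e$rlla
  qrl_in <- (pabd - prl) / e$rrla
  qub_out <- (pub - psup) / e$rubv
  qkid_out <- (pkid - pinfext) / e$rkidv
  qsp_out <- (psp - pinfext) / e$rspv
  qll_out <- valve_flow(pll, pinfext, e$rllv)
  qrl_out <- valve_flow(prl, pinfext, e$rrlv)
  qsup <- (psup - pra) / p$rsup
  qinf_entry <- starling_resistor_flow(pinfext, pinfint, pintr, p$rinfext)
  qinf_ra <- (pinfint - pra) / p$rinfint
  qvp <- (pvp - pla) / p$rvp

  c(vla = qvp - qli,
    vlv = qli - qlo,
    vra = qsup + qinf_ra - qri,
    vrv = qri - qro,
    vaa = qlo - s$qaa - qub_in,
    vabd = s$qaa - qkid_in - qsp_in - qll_in - qrl_in,
    vub = qub_in - qub_out,
    vkid = qkid_in - qkid_out,
    vsp = qsp_in - qsp_out,
    vll = qll_in - qll_out,
    vrl = qrl_in - qrl_out,
    vsup = qub_out - qsup,
    vinfext = qkid_out + qsp_out + qll_out + qrl_out - qinf_entry,
    vinfint = qinf_entry - qinf_ra,
    vap = qro - s$qap,
    vvp = s$qap - qvp,
    qaa = (paa - pabd - p$raa * s$qaa) / p$laa,
    qap = (pap - pvp - p$rap * s$qap) / p$lap,
    t_c = 1)
}

# random physiological-range circulation state for property tests
random_circ_state <- function(profile) {
  p <- profile
  s <- initial_circulation_state(p)
  vol <- 1:16
  s[vol] <- s[vol] * runif(16, 0.85, 1.25)
  s["qaa"] <- runif(1, -50, 250)
  s["qap"] <- runif(1, -50, 250)
  s["t_c"] <- runif(1, 0, 60 / p$hr_set * 0.99)
  s
}
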