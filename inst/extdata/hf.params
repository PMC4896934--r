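# Condition profile: chronic heart failure (rest parameterization)
# Units as tabulated: pressures mmHg, volumes cm3, resistances mmHg.s/cm3,
# compliances cm3/mmHg, inertances mmHg.s2/cm3, ventilation l and l/min,
# O2/CO2 contents ml gas/dl blood, firing rates spikes/s, time s.
condition = hf

# --- cardiac ---
hr_set = 85
cla = 25
cra = 25
vlv0 = 25
vrv0 = 5
al = 0.031
ar = 0.05
bl = 0.031
br = 0.04
cl = 8
cr = 5
elmax = 1.5
ermax = 1.1
rli = 0.02
rri = 0.02
rlo = 0.02
rro = 0.02

# --- systemic network ---
raa = 0.01
laa = 5e-5
caa = 0.8
rabd = 0.07
labd = 5e-5
cabd = 0.6
ruba_set = 4.72
cub = 8
rubv_set = 0.23
vub0_set = 650
rkida_set = 4.88
ckid = 15
rkidv_set = 0.3
vkid0_set = 150
rspa_set = 3.62
csp = 55
rspv_set = 0.18
vsp0_set = 1300
rlla_set = 8.52
rrla_set = 8.52
cll = 9.5
crl = 9.5
rllv_set = 0.6
rrlv_set = 0.6
vll0_set = 175
vrl0_set = 175
csup = 15
rsup = 0.06
cinfext = 25
cinfint = 2
rinfext = 0.01
rinfint = 0.015

# --- pulmonary ---
rcp = 0.03
cap = 1
rap = 0.175
lap = 3.6e-5
vap0 = 90
rvp = 0.005
cvp = 5
vvp0 = 580
weight = 76

# --- ventilation and muscle pump ---
k_dv = 0.57
pco2_tr = 36.75
e_lung = 2.8
pco2_i = 0
pim_max = 0.562
ppl0 = 754
po2_i = 150
ps_shunt = 0.02
r_airways = 1
alpha = 30
beta = -0.055
gamma = 2
delta = 0.274
epsilon = 17.75
peak_vo2 = 15

# --- baroreflex ---
a_reset = 0.3517
b_reset = 0.02
c_reset = -0.041
d_reset = -0.044
ka = 11.758
kes = 0.0675
kev = 7.06
fes0 = 16.11
fes_inf = 2.10
fev0 = 3.2
fev_inf0 = 6.3
paa_set0 = 93
tau_p = 2.076
tau_z = 6.37
# afferent saturations and efferent delays adopted from the underlying
# reflex model (not tabulated)
fas_min = 2.52
fas_max = 47.78
d_hs = 2
d_hv = 0.2

# --- sympathetic / vagal effector gains ---
c_tcs = -0.0594
c_tcv = 0.0462
c_elmaxs = 0.2
c_ermaxs = 0.133
c_rubas = 1.62
c_rkidas = 1.53
c_rspas = 1.32
c_rllas = 4.06
c_rrlas = 4.06
c_vub0s = -28.1
c_vkid0s = -6.1
c_vsp0s = -228.3
c_vll0s = -7.8
c_vrl0s = -7.8

# --- metabolic control ---
c_rubamet = 0.73
c_rkidamet = 0.69
c_rspamet = 0.6
c_rllamet = 1.5
c_rrlamet = 1.5
c_rubvmet = 0.046
c_rkidvmet = 0.06
c_rspvmet = 0.036
c_rllvmet = 0.12
c_rrlvmet = 0.12
c_o2ubv_ref = 12
c_o2kidv_ref = 15.5
c_o2spv_ref = 13
c_o2llv_ref = 12
c_o2rlv_ref = 12
k_met = 1.8
s0 = 0.27
t_met = 2

# --- control time constants ---
t_elmax = 8
t_ermax = 8
t_ris = 6
t_tcs = 2
t_tcv = 1.5
t_vis = 20

# --- metabolic drive of exercise (O2 uptake ml/min, RQ dimensionless) ---
vo2_rr_0 = 201.06
vo2_rr_slope = 2.76
vo2_leg_0 = 28.87
vo2_leg_slope = 3.83
rq_0 = 0.877
rq_slope = 0.006
split_ub = 0.30
split_kid = 0.32
split_sp = 0.38

# --- non-tabulated physiological settings ---
# atrial zero-pressure volumes (not printed; physiological order of magnitude)
vla0 = 30
vra0 = 30
# total blood volume per body mass (ml/kg)
blood_per_kg = 70
# end-expiratory alveolar volume (l): functional residual capacity minus dead space
v_eexp = 2.2
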