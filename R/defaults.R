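# Calibrated package defaults (see inst/scripts/calibrate-defaults.R).
# Anchors: drug-free growth 0.9 /h at zero limitation; A = omega_C/omega_R =
# 2/3, which places the growth-halving limitation ratio at exactly 2.5;
# expression units fixed by chi_max = 1 a.u.; regulation clamp at 0.4 ug/ml.
# The regulation slope puts expression exactly at the demand at the
# unperturbed growth rate (zero reserve at fast growth), so drug-free growth
# is ribosome-limited at every limitation level, as the model assumes.
.gf_defaults <- list(
  omega_R = 2 / 3,           # h
  omega_C = 4 / 9,           # h  (A = 2/3)
  K_Mc = 0.14,               # ug/ml
  chi_demand = 0.38,         # a.u.
  chi_max = 1,               # a.u. at zero growth
  slope_lambda = 0.62 / 0.9, # a.u. per (1/h): expression 0.38 at 0.9 /h
  converge_level = 0.95      # a.u. common level at c >= 0.4 ug/ml
)
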