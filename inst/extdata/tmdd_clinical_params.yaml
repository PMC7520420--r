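# Clinical TMDD model parameterizations: T-DM1 (fitted to Phase-1 PK) and
# PF-06804103 (linear PK allometrically scaled from cynomolgus monkey;
# binding measured, target turnover and complex elimination carried over
# from the T-DM1 fit). Units: volumes mL/kg, clearances mL/day/kg, KD nM,
# kon 1/nM/day, kshed nM/day, kdeg and kel_complex 1/day, ECD ng/mL.
T-DM1:
  pk: {Vc: 37.0, CL: 7.2, Vp: 30.0, Q: 12.0}
  KD: 0.1
  kon: 61.3
  kshed: 6.65
  kdeg: 33.3
  kel_complex: 32.6
  ecd_ngml: 20
  ecd_fit_range_ngml: [16, 28]
PF-06804103:
  pk: {Vc: 38.1, CL: 5.52, Vp: 20.2, Q: 14.9}
  KD: 0.1
  kon: 61.3
  kshed: 6.65
  kdeg: 33.3
  kel_complex: 32.6
  ecd_ngml: 20
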