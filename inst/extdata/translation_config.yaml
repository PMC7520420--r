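# Translation outcome-classification settings.
#
# The outcome thresholds on TV(horizon)/v0 were calibrated once against
# the published qualitative outcome classes (regression / stasis /
# regrowth across ten tumor-model x ADC cases) and are recorded here
# rather than hard-coded: regression below 0.70, regrowth above 1.2,
# stasis between. Horizon: last dose + 21 days. Initial volume: 200 mm^3
# (mid randomization window; per-model mouse values were not published).
translation:
  regression: 0.70
  regrowth: 1.2
  horizon_after_last_dose: 21
  v0_mm3: 200
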