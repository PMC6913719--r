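# AUSDRISK point values (Australian Type 2 Diabetes Risk Assessment Tool).
# Source: Chen L, Magliano DJ, Balkau B, et al. AUSDRISK: an Australian Type 2
# Diabetes Risk Assessment Tool based on demographic, lifestyle and simple
# anthropometric measures. Med J Aust 2010;192:197-202; Australian Government
# Department of Health scoring sheet. Transcribed 2026-09-26.
#
# Total score range 0-38. Standard risk bands: low <= 5, intermediate 6-11,
# high >= 12 (the screening engine houses the band cut-points in its
# threshold configuration, not here).
age_band:           # years
  under_35: 0
  35_44: 2
  45_54: 4
  55_64: 6
  65_plus: 8
sex:
  female: 0
  male: 3
high_risk_descent:  # Aboriginal, Torres Strait Islander, Pacific Islander or Maori descent
  "no": 0
  "yes": 2
high_risk_birth_region:  # born in Asia, Middle East, North Africa or Southern Europe
  "no": 0
  "yes": 2
parental_diabetes:
  "no": 0
  "yes": 3
prior_high_glucose:
  "no": 0
  "yes": 6
on_bp_lowering:
  "no": 0
  "yes": 2
current_smoker:
  "no": 0
  "yes": 2
fruit_veg_daily:    # eats vegetables or fruit every day
  "yes": 0
  "no": 1
activity_2_5h:      # at least 2.5 hours physical activity per week
  "yes": 0
  "no": 2
waist_band:         # sex- and descent-specific circumference bands (cm), below
  band_0: 0
  band_1: 4
  band_2: 7
waist_cutoffs:      # [upper bound of band_0, upper bound of band_1]
  male_standard: [102, 110]
  female_standard: [88, 100]
  male_high_risk: [90, 100]
  female_high_risk: [80, 90]
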