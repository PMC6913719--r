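# Default clinical cut-points and policy switches for the screening engine.
# Values are the Australian guideline thresholds the engine ships with;
# edit a copy of this file and pass it to read_threshold_config() to override.
calc_risk_high: 0.15        # calculated 5-year CVD risk above this => high
calc_risk_low: 0.10         # below this => low; [low, high] inclusive => medium
sbp_high: 180               # mmHg, clinically high-risk condition
dbp_high: 110               # mmHg, clinically high-risk condition
tc_high: 7.5                # mmol/L, clinically high-risk condition
diabetes_age: 60            # diabetes AND age > this => clinically high risk
min_age_for_calculated_risk: 30
bmi_obese: 30               # kg/m^2
waist_male: 102             # cm
waist_female: 88            # cm
bmi_waist_rescue: false     # if true, BMI > bmi_waist_rescue_cut also flags elevated waist
bmi_waist_rescue_cut: 40
sbp_flag: 140               # elevated blood pressure: SBP > 140 or DBP > 90
dbp_flag: 90
tc_dyslipid: 5.5            # dyslipidaemia: any of TC>5.5, HDL<1, LDL>3.5, TG>2.0
hdl_low: 1.0
ldl_high: 3.5
tg_high: 2.0
activity_min: 2.5           # hours/week; below => low-activity flag
acr_male: 2.5               # mg/mmol, albuminuria if >= threshold
acr_female: 3.5
hba1c_diabetes: 6.5         # %, possible new diabetes if >= and no known diagnosis
glucose_low: 5.5            # mmol/L, impaired glycaemia band [low, high)
glucose_high: 11.1
ausdrisk_high: 12           # AUSDRISK >= 12 => high; <= ausdrisk_low_max => low
ausdrisk_low_max: 5
hba1c_target_strict: 7      # %, diabetes treatment targets
hba1c_target_lenient: 8
cvd_diabetes_includes_detected: false  # if true, HbA1c-detected diabetes counts in clinically-high CVD rules
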