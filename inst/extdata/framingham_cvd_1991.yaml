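# Coefficients of the Framingham general cardiovascular disease risk equation
# (Weibull accelerated-failure-time form), as adopted for 5-year absolute risk
# assessment by the Australian (NVDPA) absolute CVD risk guideline.
# Source: Anderson KM, Odell PM, Wilson PWF, Kannel WB. Cardiovascular disease
# risk profiles. Am Heart J 1991;121(1 Pt 2):293-298. Transcribed 2026-09-26.
#
# Linear predictor (mu) on log failure-time scale; sex, smoking, diabetes and
# LVH enter as 0/1 indicators; age in years, SBP in mmHg, tc_hdl is the
# total-cholesterol / HDL ratio (both mmol/L). The Weibull scale is
# sigma = exp(sigma_intercept + sigma_slope * mu) and
# risk(t) = 1 - exp(-exp((log(t) - mu) / sigma)).
model: anderson_1991_general_cvd
horizon_years: 5
coefficients:
  intercept: 18.8144
  female: -1.2146
  log_age: -1.8443
  female_log_age: 0.3668
  log_sbp: -1.4032
  smoker: -0.3899
  log_tc_hdl: -0.5390
  diabetes: -0.3036
  female_diabetes: -0.1697
  lvh: -0.3362
sigma_intercept: 0.6536
sigma_slope: -0.2402
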