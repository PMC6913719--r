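cf <- framingham_coefficients()
cfg <- threshold_config()
pts <- ausdrisk_points()

test_that("risk equation agrees with an independently coded evaluator", {
  set.seed(21)
  for (i in 1:200) {
    age <- runif(1, 30, 79); sex <- sample(c("male", "female"), 1)
    sbp <- runif(1, 95, 210); tc <- runif(1, 3, 9); hdl <- runif(1, 0.6, 2.4)
    sm <- runif(1) < 0.5; dm <- runif(1) < 0.3; lvh <- runif(1) < 0.05
    expect_equal(
      framingham_risk(age, sex, sbp, tc, hdl, sm, dm, lvh, coefficients = cf),
      oracle_framingham(age, sex, sbp, tc, hdl, sm, dm, lvh, cf),
      tolerance = 1e-10
    )
  }
})

test_that("risk is a probability, increases with exposure, and needs age >= 30", {
  base <- framingham_risk(55, "male", 130, 5, 1.2, FALSE, FALSE,
                          coefficients = cf)
  expect_gt(base, 0); expect_lt(base, 1)
  expect_gt(framingham_risk(55, "male", 130, 5, 1.2, TRUE, FALSE,
                            coefficients = cf), base)
  expect_gt(framingham_risk(55, "male", 160, 5, 1.2, FALSE, FALSE,
                            coefficients = cf), base)
  expect_gt(framingham_risk(55, "male", 130, 7, 1.2, FALSE, FALSE,
                            coefficients = cf), base)
  expect_gt(framingham_risk(55, "male", 130, 5, 1.2, FALSE, TRUE,
                            coefficients = cf), base)
  expect_true(is.na(framingham_risk(55, "male", NA, 5, 1.2, FALSE, FALSE,
                                    coefficients = cf)))
  expect_error(framingham_risk(25, "male", 130, 5, 1.2, FALSE, FALSE,
                               coefficients = cf), "age")
})

test_that("CVD categories follow the guideline precedence", {
  cases <- list(
    list(rec = screening_record(age = 45, sbp = 185),
         risk = 0.05, want = "clinically_high"),
    list(rec = screening_record(age = 62, known_diabetes = TRUE),
         risk = 0.05, want = "clinically_high"),
    list(rec = screening_record(age = 50, known_diabetes = TRUE,
                                urine_acr = 4.0),
         risk = 0.05, want = "clinically_high"),
    list(rec = screening_record(age = 50, dbp = 111, sbp = 150),
         risk = 0.05, want = "clinically_high"),
    list(rec = screening_record(age = 50, total_cholesterol = 7.6),
         risk = 0.05, want = "clinically_high"),
    list(rec = screening_record(age = 25), risk = NA, want = "under_30"),
    list(rec = screening_record(age = 50), risk = 0.09, want = "low"),
    list(rec = screening_record(age = 50), risk = 0.10, want = "medium"),
    list(rec = screening_record(age = 50), risk = 0.15, want = "medium"),
    list(rec = screening_record(age = 50), risk = 0.151,
         want = "high_calculated"),
    list(rec = screening_record(age = 50), risk = NA, want = "indeterminate"),
    list(rec = screening_record(age = 45, sbp = 185, hx_chd = TRUE),
         risk = NA, want = "established_cvd")
  )
  for (cs in cases) {
    expect_equal(classify_cvd_risk(cs$rec, cs$risk, cfg), cs$want,
                 info = cs$want)
  }
})

test_that("AUSDRISK spans 0 to the table maximum and matches hand summation", {
  zero <- screening_record(age = 30, sex = "female",
                           indigenous_status = "other",
                           parental_diabetes = FALSE,
                           prior_high_glucose = FALSE,
                           on_bp_lowering = FALSE, smoking_status = "never",
                           fruit_intake_adequate = TRUE,
                           vegetable_intake_adequate = TRUE,
                           physical_activity_hours = 5, waist_cm = 70)
  expect_equal(ausdrisk_score(zero, pts), 0L)

  maxed <- screening_record(age = 70, sex = "male",
                            indigenous_status = "aboriginal_andor_tsi",
                            parental_diabetes = TRUE,
                            prior_high_glucose = TRUE,
                            on_bp_lowering = TRUE, smoking_status = "current",
                            smoking_years = 30, cigarettes_per_day = 20,
                            fruit_intake_adequate = FALSE,
                            vegetable_intake_adequate = FALSE,
                            physical_activity_hours = 0, waist_cm = 120)
  # country-of-birth item is not collected, so the achievable maximum is the
  # table maximum minus its 2 points
  expect_equal(ausdrisk_score(maxed, pts),
               as.integer(attr(pts, "max_total") - 2L))

  recs <- grid_records(300, seed = 5)
  got <- ausdrisk_score(recs, pts)
  want <- vapply(seq_len(nrow(recs)),
                 function(i) oracle_ausdrisk(recs[i, ]), integer(1))
  expect_identical(got, want)
})

test_that("diabetes categories follow the glycaemic hierarchy", {
  cases <- list(
    list(rec = screening_record(known_diabetes = TRUE, hba1c_percent = 6.0),
         want = "established_diabetes"),
    list(rec = screening_record(hba1c_percent = 6.5),
         want = "possible_new_diabetes"),
    list(rec = screening_record(hba1c_percent = 5.6, random_glucose = 7.0),
         want = "impaired_glycemia"),
    list(rec = screening_record(random_glucose = 5.5),
         want = "impaired_glycemia"),
    list(rec = screening_record(random_glucose = 11.1),
         want = NULL)  # outside the band: falls through to AUSDRISK
  )
  for (cs in cases[1:4]) {
    score <- ausdrisk_score(cs$rec, pts)
    expect_equal(classify_diabetes_risk(cs$rec, score, cfg), cs$want)
  }
  r5 <- cases[[5]]$rec
  expect_false(classify_diabetes_risk(r5, ausdrisk_score(r5, pts), cfg) %in%
                 c("impaired_glycemia", "possible_new_diabetes",
                   "established_diabetes"))
  # AUSDRISK banding when no glycaemic rule fires
  rec <- screening_record()
  expect_equal(classify_diabetes_risk(rec, 12L, cfg), "high_ausdrisk")
  expect_equal(classify_diabetes_risk(rec, 11L, cfg), "medium_ausdrisk")
  expect_equal(classify_diabetes_risk(rec, 6L, cfg), "medium_ausdrisk")
  expect_equal(classify_diabetes_risk(rec, 5L, cfg), "low_ausdrisk")
  expect_equal(classify_diabetes_risk(rec, NA_integer_, cfg), "indeterminate")
})

test_that("a very high random glucose without diabetes is flagged urgent", {
  rec <- screening_record(random_glucose = 13.0, hba1c_percent = 6.0)
  prof <- screen_cohort(rec)
  expect_true(prof$urgent_glucose_review)
  expect_false(prof$diabetes_category %in%
                 c("established_diabetes", "possible_new_diabetes",
                   "impaired_glycemia"))
  # known diabetes is never "urgent new glucose finding"
  rec2 <- screening_record(random_glucose = 13.0, known_diabetes = TRUE)
  expect_false(screen_cohort(rec2)$urgent_glucose_review)
})

test_that("CKD composite reports the criteria that fired", {
  run <- function(rec) {
    prof <- screen_cohort(rec)
    list(flag = prof$ckd_high_risk, reasons = prof$ckd_reasons)
  }
  obese <- run(screening_record(height_cm = 160, weight_kg = 80))  # BMI 31.3
  expect_true(obese$flag); expect_equal(obese$reasons, "obesity")

  lean <- run(screening_record(height_cm = 170, weight_kg = 69))   # BMI 23.9
  expect_false(lean$flag); expect_equal(lean$reasons, "")

  both <- run(screening_record(smoking_status = "current",
                               smoking_years = 10, cigarettes_per_day = 10,
                               known_diabetes = TRUE))
  expect_true(both$flag)
  expect_equal(both$reasons, "smoking,diabetes")

  # indeterminate only when every criterion is unknowable
  unk <- classify_ckd_risk(
    screening_record(height_cm = NA, weight_kg = NA, smoking_status = NA,
                     hx_chd = NA, hx_cbv = NA, hx_pvd = NA,
                     family_history_ckd = NA),
    "indeterminate", "indeterminate", cfg)
  expect_true(is.na(unk$ckd_high_risk))
})

test_that("albuminuria uses the sex-specific ACR cut-points", {
  expect_true(classify_albuminuria(2.5, "male", cfg))
  expect_false(classify_albuminuria(2.4, "male", cfg))
  expect_true(classify_albuminuria(3.5, "female", cfg))
  expect_false(classify_albuminuria(3.4, "female", cfg))
  expect_false(classify_albuminuria(0, "male", cfg))
  expect_false(classify_albuminuria(0, "female", cfg))
  expect_true(is.na(classify_albuminuria(NA, "male", cfg)))
  expect_error(classify_albuminuria(-1, "male", cfg), "non-negative")
})

test_that("lifestyle flags fire independently at their thresholds", {
  f <- lifestyle_flags(screening_record(sex = "male", waist_cm = 103), cfg)
  expect_true(f$elevated_waist)
  f <- lifestyle_flags(screening_record(sex = "female", waist_cm = 103), cfg)
  expect_true(f$elevated_waist)  # female cut is 88
  f <- lifestyle_flags(screening_record(sbp = 141, dbp = 80), cfg)
  expect_true(f$elevated_bp)
  f <- lifestyle_flags(screening_record(sbp = 120, dbp = 91), cfg)
  expect_true(f$elevated_bp)
  f <- lifestyle_flags(screening_record(total_cholesterol = 5.0, hdl = 1.2,
                                        ldl = 3.0, triglycerides = 1.5), cfg)
  expect_false(f$dyslipidaemia)
  f <- lifestyle_flags(screening_record(hdl = 0.9), cfg)
  expect_true(f$dyslipidaemia)
  f <- lifestyle_flags(screening_record(physical_activity_hours = 2.4), cfg)
  expect_true(f$low_activity)
  f <- lifestyle_flags(screening_record(physical_activity_hours = 2.5), cfg)
  expect_false(f$low_activity)
  f <- lifestyle_flags(screening_record(sbp = NA, dbp = NA), cfg)
  expect_true(is.na(f$elevated_bp))
})

test_that("the optional BMI rescue widens the waist flag only when enabled", {
  rec <- screening_record(sex = "male", waist_cm = 100,
                          height_cm = 160, weight_kg = 105)  # BMI 41
  expect_false(lifestyle_flags(rec, cfg)$elevated_waist)
  cfg_on <- threshold_config(bmi_waist_rescue = TRUE)
  expect_true(lifestyle_flags(rec, cfg_on)$elevated_waist)
})

test_that("classification is invariant to record field order", {
  recs <- grid_records(200, seed = 9)
  prof1 <- screen_cohort(recs)
  set.seed(1)
  prof2 <- screen_cohort(recs[, sample(names(recs))])
  expect_identical(prof1$cvd_category, prof2$cvd_category)
  expect_identical(prof1$diabetes_category, prof2$diabetes_category)
  expect_identical(prof1$ckd_high_risk, prof2$ckd_high_risk)
})

test_that("the engine refuses to run without complete configuration", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("model: x", "horizon_years: 5", "sigma_intercept: 0.65",
               "sigma_slope: -0.24", "coefficients:", "  intercept: 18.8"),
             bad)
  expect_error(framingham_coefficients(bad), "incomplete")
  expect_error(framingham_coefficients(tempfile()), "not found")
  expect_error(ausdrisk_points(tempfile()), "not found")
})
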