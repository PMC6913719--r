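#' Load Framingham 1991 CVD risk-equation coefficients
#'
#' Reads the coefficient set of the Framingham general cardiovascular disease
#' risk equation in its Weibull accelerated-failure-time form — the equation
#' behind Australian (NVDPA) 5-year absolute CVD risk assessment — from a
#' structured config file. The engine refuses to compute risks without a
#' complete, sane coefficient set: the loader checks every term is present and
#' that a reference profile yields a probability strictly inside (0, 1).
#'
#' @param path YAML file with the coefficients; defaults to the transcription
#'   shipped with the package.
#' @return Named list of class `"risk_coefficients"`.
#' @export
framingham_coefficients <- function(path = NULL) {
  path <- path %||% system.file("extdata", "framingham_cvd_1991.yaml",
                                package = "commscreen")
  if (!file.exists(path)) stop("coefficient file not found: ", path)
  cfg <- yaml::read_yaml(path)
  needed <- c("intercept", "female", "log_age", "female_log_age", "log_sbp",
              "smoker", "log_tc_hdl", "diabetes", "female_diabetes", "lvh")
  missing <- setdiff(needed, names(cfg$coefficients))
  if (length(missing)) {
    stop("coefficient set incomplete; missing: ",
         paste(missing, collapse = ", "))
  }
  for (nm in c("sigma_intercept", "sigma_slope", "horizon_years")) {
    if (is.null(cfg[[nm]])) stop("coefficient file missing field: ", nm)
  }
  obj <- structure(cfg, class = "risk_coefficients")
  ref <- framingham_risk(age = 50, sex = "male", sbp = 120,
                         total_cholesterol = 5.2, hdl = 1.3,
                         smoker = FALSE, diabetes = FALSE,
                         coefficients = obj)
  if (!is.finite(ref) || ref <= 0 || ref >= 1) {
    stop("coefficient set rejected: reference profile risk not in (0, 1)")
  }
  obj
}

#' Five-year absolute CVD risk (Framingham 1991 equation)
#'
#' Evaluates the Weibull accelerated-failure-time risk equation: with linear
#' predictor `mu` built from sex, log(age), log(SBP), smoking, log of the
#' total-cholesterol/HDL ratio, diabetes and LVH, and scale
#' `sigma = exp(s0 + s1 * mu)`, the probability of a first cardiovascular
#' event within `years` is `1 - exp(-exp((log(years) - mu) / sigma))`.
#'
#' All arguments are vectorised. A missing input yields `NA` (the
#' indeterminate signal); an age below `min_age` is a precondition error —
#' callers must route under-30s to their own category rather than calculate.
#'
#' @param age years; must be `>= min_age` where non-missing.
#' @param sex `"male"` or `"female"`.
#' @param sbp systolic blood pressure, mmHg.
#' @param total_cholesterol,hdl serum lipids, mmol/L.
#' @param smoker,diabetes,lvh logical flags (current smoker; diabetes;
#'   left-ventricular hypertrophy, rarely collected at screening and so
#'   defaulting to `FALSE`).
#' @param coefficients a `"risk_coefficients"` set from
#'   [framingham_coefficients()].
#' @param years risk horizon; defaults to the coefficient file's horizon (5).
#' @param min_age youngest age the equation is applied to (default 30).
#' @return Numeric vector of event probabilities in (0, 1), `NA` where any
#'   input is missing.
#' @examples
#' cf <- framingham_coefficients()
#' framingham_risk(55, "male", 140, 6.2, 1.1, smoker = TRUE,
#'                 diabetes = FALSE, coefficients = cf)
#' @export
framingham_risk <- function(age, sex, sbp, total_cholesterol, hdl,
                            smoker, diabetes, lvh = FALSE,
                            coefficients = framingham_coefficients(),
                            years = NULL, min_age = 30) {
  if (!inherits(coefficients, "risk_coefficients") &&
      is.null(coefficients$coefficients)) {
    stop("coefficients must be loaded with framingham_coefficients()")
  }
  if (any(!is.na(age) & age < min_age)) {
    stop("framingham_risk requires age >= ", min_age,
         "; route younger participants to the under-", min_age, " category")
  }
  years <- years %||% coefficients$horizon_years
  b <- coefficients$coefficients
  n <- max(length(age), length(sex), length(sbp), length(total_cholesterol),
           length(hdl), length(smoker), length(diabetes), length(lvh))
  age <- rep_len(age, n); sex <- rep_len(sex, n); sbp <- rep_len(sbp, n)
  total_cholesterol <- rep_len(total_cholesterol, n); hdl <- rep_len(hdl, n)
  smoker <- rep_len(as.logical(smoker), n)
  diabetes <- rep_len(as.logical(diabetes), n)
  lvh <- rep_len(as.logical(lvh), n)

  female <- ifelse(is.na(sex), NA, as.numeric(sex == "female"))
  mu <- b$intercept +
    b$female * female +
    b$log_age * log(age) +
    b$female_log_age * female * log(age) +
    b$log_sbp * log(sbp) +
    b$smoker * as.numeric(smoker) +
    b$log_tc_hdl * log(total_cholesterol / hdl) +
    b$diabetes * as.numeric(diabetes) +
    b$female_diabetes * female * as.numeric(diabetes) +
    b$lvh * as.numeric(lvh)
  sigma <- exp(coefficients$sigma_intercept + coefficients$sigma_slope * mu)
  1 - exp(-exp((log(years) - mu) / sigma))
}

#' Load the AUSDRISK point table
#'
#' @param path YAML file with the item point values; defaults to the
#'   transcription shipped with the package.
#' @return Named list of class `"ausdrisk_points"`, with attribute
#'   `max_total` (the maximum achievable score, 38 for the published table).
#' @export
ausdrisk_points <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ausdrisk_points.yaml",
                                package = "commscreen")
  if (!file.exists(path)) stop("AUSDRISK point table not found: ", path)
  tab <- yaml::read_yaml(path)
  items <- setdiff(names(tab), "waist_cutoffs")
  for (item in items) {
    pts <- unlist(tab[[item]])
    if (any(is.na(pts)) || any(pts < 0) || any(pts != round(pts))) {
      stop("AUSDRISK item '", item, "' has invalid point values")
    }
  }
  if (min(unlist(lapply(tab[items], function(i) min(unlist(i))))) != 0) {
    stop("AUSDRISK table: minimum achievable total must be 0")
  }
  max_total <- sum(vapply(tab[items], function(i) max(unlist(i)), numeric(1)))
  structure(tab, max_total = max_total, class = "ausdrisk_points")
}

#' AUSDRISK type 2 diabetes risk score
#'
#' Sums the configured point values over the AUSDRISK items: age band, sex,
#' high-risk descent (Aboriginal and/or Torres Strait Islander status),
#' parental diabetes, prior high blood glucose, antihypertensive use, current
#' smoking, daily fruit/vegetable intake, physical activity, and the sex- and
#' descent-specific waist circumference band. The instrument's country-of-
#' birth item is retained in the table but screening records do not collect
#' it, so it contributes 0. Any unanswerable item makes the score `NA`
#' (indeterminate).
#'
#' @param records screening cohort `data.frame`.
#' @param points an `"ausdrisk_points"` table from [ausdrisk_points()].
#' @return Integer vector of scores (0 to the table maximum), `NA` where any
#'   item is unknown.
#' @export
ausdrisk_score <- function(records, points = ausdrisk_points()) {
  records <- coerce_schema(records)
  p <- points
  n <- nrow(records)

  pick <- function(item, key) {
    # key: character vector of level names into the item's point list
    vapply(key, function(k) {
      if (is.na(k)) return(NA_real_)
      v <- p[[item]][[k]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1), USE.NAMES = FALSE)
  }

  age_key <- cut(records$age, c(-Inf, 34, 44, 54, 64, Inf),
                 labels = c("under_35", "35_44", "45_54", "55_64", "65_plus"))
  pts_age <- pick("age_band", as.character(age_key))
  pts_sex <- pick("sex", records$sex)

  descent <- ifelse(is.na(records$indigenous_status), NA,
                    records$indigenous_status == "aboriginal_andor_tsi")
  pts_descent <- pick("high_risk_descent", ifelse(descent, "yes", "no"))
  # country of birth is not collected at screening stations: scores 0
  pts_birth <- rep(p$high_risk_birth_region[["no"]], n)

  yn <- function(x) ifelse(is.na(x), NA_character_, ifelse(x, "yes", "no"))
  pts_parent <- pick("parental_diabetes", yn(records$parental_diabetes))
  pts_glucose <- pick("prior_high_glucose", yn(records$prior_high_glucose))
  pts_bpmed <- pick("on_bp_lowering", yn(records$on_bp_lowering))

  smoker <- ifelse(is.na(records$smoking_status), NA,
                   records$smoking_status == "current")
  pts_smoke <- pick("current_smoker", yn(smoker))

  fruit_veg <- records$fruit_intake_adequate | records$vegetable_intake_adequate
  pts_diet <- pick("fruit_veg_daily", yn(fruit_veg))

  active <- ifelse(is.na(records$physical_activity_hours), NA,
                   records$physical_activity_hours >= 2.5)
  pts_active <- pick("activity_2_5h", yn(active))

  cut_key <- ifelse(is.na(records$sex) | is.na(descent), NA_character_,
                    paste0(records$sex,
                           ifelse(descent, "_high_risk", "_standard")))
  pts_waist <- rep(NA_real_, n)
  for (k in unique(stats::na.omit(cut_key))) {
    cuts <- p$waist_cutoffs[[k]]
    idx <- which(!is.na(cut_key) & cut_key == k & !is.na(records$waist_cm))
    w <- records$waist_cm[idx]
    band <- ifelse(w < cuts[1], "band_0", ifelse(w <= cuts[2], "band_1", "band_2"))
    pts_waist[idx] <- vapply(band, function(bn) as.numeric(p$waist_band[[bn]]),
                             numeric(1), USE.NAMES = FALSE)
  }

  total <- pts_age + pts_sex + pts_descent + pts_birth + pts_parent +
    pts_glucose + pts_bpmed + pts_smoke + pts_diet + pts_active + pts_waist
  as.integer(total)
}

#' Classify CVD risk category
#'
#' Assigns each participant exactly one mutually exclusive cardiovascular
#' risk category, applying the rules in precedence order (first match wins):
#'
#' 1. `established_cvd` — any self-reported CVD diagnosis (coronary heart,
#'    cerebrovascular or peripheral vascular disease);
#' 2. `clinically_high` — any clinically high-risk condition: diabetes with
#'    age over 60, diabetes with albuminuria, SBP > 180 mmHg,
#'    DBP > 110 mmHg, or total cholesterol > 7.5 mmol/L;
#' 3. `under_30` — younger than the minimum age for calculated risk;
#' 4. `high_calculated` / `medium` / `low` — calculated 5-year risk > 15%,
#'    in \[10%, 15%\], or < 10%.
#'
#' A rule fires only on an affirmatively met condition; records that reach
#' the calculated-risk stage without a computable risk are `indeterminate`.
#'
#' @param records screening cohort `data.frame`.
#' @param risk numeric vector of calculated 5-year risks aligned to
#'   `records` (`NA` where not computable), e.g. from [framingham_risk()].
#' @param cfg a [threshold_config()].
#' @return Character vector of categories.
#' @export
classify_cvd_risk <- function(records, risk, cfg = threshold_config()) {
  records <- coerce_schema(records)
  n <- nrow(records)
  risk <- rep_len(risk, n)

  hx_any <- records$hx_chd | records$hx_cbv | records$hx_pvd
  diab <- records$known_diabetes
  if (cfg$cvd_diabetes_includes_detected) {
    diab <- diab | (records$hba1c_percent >= cfg$hba1c_diabetes)
  }
  alb <- classify_albuminuria(records$urine_acr, records$sex, cfg)
  clin <- (diab & records$age > cfg$diabetes_age) |
    (diab & alb) |
    records$sbp > cfg$sbp_high |
    records$dbp > cfg$dbp_high |
    records$total_cholesterol > cfg$tc_high

  out <- rep("indeterminate", n)
  band <- ifelse(is.na(risk), "indeterminate",
                 ifelse(risk > cfg$calc_risk_high, "high_calculated",
                        ifelse(risk >= cfg$calc_risk_low, "medium", "low")))
  out <- band
  under <- !is.na(records$age) & records$age < cfg$min_age_for_calculated_risk
  out[under] <- "under_30"
  out[is_true(clin)] <- "clinically_high"
  out[is_true(hx_any)] <- "established_cvd"
  out
}

#' Classify diabetes risk category
#'
#' Assigns each participant exactly one mutually exclusive diabetes category,
#' in precedence order: `established_diabetes` (self-reported known
#' diabetes), `possible_new_diabetes` (HbA1c at or above the diabetic
#' threshold, 6.5%, without a known diagnosis), `impaired_glycemia` (random
#' capillary glucose in the configured band, 5.5 to below 11.1 mmol/L), then
#' the AUSDRISK bands `high_ausdrisk` (>= 12), `medium_ausdrisk` (6-11) and
#' `low_ausdrisk` (<= 5). `indeterminate` when no rule fires and the score is
#' unavailable.
#'
#' A random glucose at or above the band's upper bound in a participant
#' without known or HbA1c-detected diabetes does not itself diagnose; such
#' records fall through to their AUSDRISK band and are flagged for urgent
#' review (see the `urgent_glucose_review` column of [screen_cohort()]).
#'
#' @inheritParams classify_cvd_risk
#' @param score integer vector of AUSDRISK scores aligned to `records`
#'   (`NA` where indeterminate), e.g. from [ausdrisk_score()].
#' @return Character vector of categories.
#' @export
classify_diabetes_risk <- function(records, score, cfg = threshold_config()) {
  records <- coerce_schema(records)
  n <- nrow(records)
  score <- rep_len(score, n)

  established <- is_true(records$known_diabetes)
  possible <- !established & is_true(records$hba1c_percent >= cfg$hba1c_diabetes)
  impaired <- !established & !possible &
    is_true(records$random_glucose >= cfg$glucose_low &
              records$random_glucose < cfg$glucose_high)

  out <- ifelse(is.na(score), "indeterminate",
                ifelse(score >= cfg$ausdrisk_high, "high_ausdrisk",
                       ifelse(score > cfg$ausdrisk_low_max, "medium_ausdrisk",
                              "low_ausdrisk")))
  out[impaired] <- "impaired_glycemia"
  out[possible] <- "possible_new_diabetes"
  out[established] <- "established_diabetes"
  out
}

#' Classify CKD risk composite
#'
#' High chronic-kidney-disease risk is any of: BMI over 30 kg/m^2, current
#' smoking, presence of CVD (an established CVD category), family history of
#' CKD, or presence of diabetes (established or possible new diagnosis). The
#' flag is `TRUE` when at least one criterion affirmatively holds, `FALSE`
#' when none holds and at least one is assessable, and `NA` only when every
#' criterion is unknowable.
#'
#' @inheritParams classify_cvd_risk
#' @param cvd_category,diabetes_category category vectors from
#'   [classify_cvd_risk()] and [classify_diabetes_risk()].
#' @return `data.frame` with `ckd_high_risk` (tri-state logical) and
#'   `ckd_reasons` (comma-separated subset of
#'   `obesity, smoking, cvd, family_history, diabetes`).
#' @export
classify_ckd_risk <- function(records, cvd_category, diabetes_category,
                              cfg = threshold_config()) {
  records <- coerce_schema(records)
  bmi <- ifelse(is.na(records$height_cm) | is.na(records$weight_kg), NA,
                derive_bmi(records$height_cm, records$weight_kg))
  crit <- data.frame(
    obesity = bmi > cfg$bmi_obese,
    smoking = ifelse(is.na(records$smoking_status), NA,
                     records$smoking_status == "current"),
    cvd = records$hx_chd | records$hx_cbv | records$hx_pvd,
    family_history = records$family_history_ckd,
    diabetes = ifelse(diabetes_category == "indeterminate", NA,
                      diabetes_category %in% c("established_diabetes",
                                               "possible_new_diabetes"))
  )
  any_true <- Reduce(`|`, crit)             # native tri-state OR
  all_na <- Reduce(`&`, lapply(crit, is.na))
  flag <- ifelse(all_na, NA, is_true(any_true))
  reasons <- apply(crit, 1, function(r) {
    paste(names(crit)[!is.na(r) & r], collapse = ",")
  })
  data.frame(ckd_high_risk = flag, ckd_reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Albuminuria from urine albumin-creatinine ratio
#'
#' Sex-specific cut-points: ACR at or above 2.5 mg/mmol for males, 3.5 for
#' females.
#'
#' @param acr urine albumin-creatinine ratio, mg/mmol (non-negative).
#' @param sex `"male"` or `"female"`.
#' @param cfg a [threshold_config()].
#' @return Tri-state logical; `NA` where ACR or sex is missing.
#' @export
classify_albuminuria <- function(acr, sex, cfg = threshold_config()) {
  if (any(!is.na(acr) & acr < 0)) stop("urine_acr must be non-negative")
  cut <- ifelse(is.na(sex), NA_real_,
                ifelse(sex == "male", cfg$acr_male, cfg$acr_female))
  ifelse(is.na(acr) | is.na(cut), NA, acr >= cut)
}

#' Lifestyle and biomedical risk-factor flags
#'
#' Each flag is set independently from its threshold: current smoking, BMI
#' over 30 kg/m^2, elevated waist circumference (over 102 cm male / 88 cm
#' female; optionally rescued by BMI over 40 when configured), under 2.5
#' hours/week physical activity, infrequent fruit or vegetable intake, blood
#' pressure over 140/90 mmHg (either bound), and dyslipidaemia (any of total
#' cholesterol > 5.5, HDL < 1, LDL > 3.5, triglycerides > 2.0 mmol/L).
#' Flags whose inputs are missing are `NA` (unassessable).
#'
#' @inheritParams classify_cvd_risk
#' @return `data.frame` of tri-state logical columns `current_smoker`,
#'   `obese`, `elevated_waist`, `low_activity`, `infrequent_fruit`,
#'   `infrequent_veg`, `elevated_bp`, `dyslipidaemia`.
#' @export
lifestyle_flags <- function(records, cfg = threshold_config()) {
  records <- coerce_schema(records)
  bmi <- ifelse(is.na(records$height_cm) | is.na(records$weight_kg), NA,
                derive_bmi(records$height_cm, records$weight_kg))
  waist_cut <- ifelse(is.na(records$sex), NA_real_,
                      ifelse(records$sex == "male",
                             cfg$waist_male, cfg$waist_female))
  elevated_waist <- records$waist_cm > waist_cut
  if (cfg$bmi_waist_rescue) {
    elevated_waist <- elevated_waist | (bmi > cfg$bmi_waist_rescue_cut)
  }
  data.frame(
    current_smoker = ifelse(is.na(records$smoking_status), NA,
                            records$smoking_status == "current"),
    obese = bmi > cfg$bmi_obese,
    elevated_waist = elevated_waist,
    low_activity = records$physical_activity_hours < cfg$activity_min,
    infrequent_fruit = !records$fruit_intake_adequate,
    infrequent_veg = !records$vegetable_intake_adequate,
    elevated_bp = records$sbp > cfg$sbp_flag | records$dbp > cfg$dbp_flag,
    dyslipidaemia = records$total_cholesterol > cfg$tc_dyslipid |
      records$hdl < cfg$hdl_low |
      records$ldl > cfg$ldl_high |
      records$triglycerides > cfg$tg_high
  )
}

#' Screen a cohort: full per-participant risk profile
#'
#' Runs the whole risk engine over a cohort: validates and cleans the records
#' ([validate_screening()], [clean_screening()]), calculates 5-year CVD risk
#' for eligible participants, scores AUSDRISK, and derives the mutually
#' exclusive CVD and diabetes categories, the CKD composite, albuminuria and
#' the lifestyle flags.
#'
#' @param records screening cohort `data.frame`.
#' @param cfg a [threshold_config()].
#' @param coefficients a [framingham_coefficients()] set.
#' @param points an [ausdrisk_points()] table.
#' @return A `data.frame` of class `"risk_profiles"`, one row per
#'   participant: identifiers, `cvd_category`, `calculated_5yr_risk`,
#'   `ausdrisk_score`, `diabetes_category`, `ckd_high_risk`, `ckd_reasons`,
#'   `albuminuria`, `urgent_glucose_review`, the lifestyle flags (prefixed
#'   `flag_`), and carried-through `sex`, `age` and `hba1c_percent`. The
#'   validation findings are attached as attribute `"findings"`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_site = 50, n_sites = 2), seed = 7)
#' prof <- screen_cohort(cohort)
#' summary(prof)
#' @export
screen_cohort <- function(records, cfg = threshold_config(),
                          coefficients = framingham_coefficients(),
                          points = ausdrisk_points()) {
  records <- coerce_schema(records)
  findings <- validate_screening(records)
  records <- clean_screening(records, findings)
  n <- nrow(records)

  eligible <- !is.na(records$age) &
    records$age >= cfg$min_age_for_calculated_risk
  risk <- rep(NA_real_, n)
  if (any(eligible)) {
    e <- records[eligible, , drop = FALSE]
    risk[eligible] <- framingham_risk(
      age = e$age, sex = e$sex, sbp = e$sbp,
      total_cholesterol = e$total_cholesterol, hdl = e$hdl,
      smoker = ifelse(is.na(e$smoking_status), NA,
                      e$smoking_status == "current"),
      diabetes = e$known_diabetes, lvh = FALSE,
      coefficients = coefficients,
      min_age = cfg$min_age_for_calculated_risk
    )
  }

  score <- ausdrisk_score(records, points)
  cvd_category <- classify_cvd_risk(records, risk, cfg)
  diabetes_category <- classify_diabetes_risk(records, score, cfg)
  ckd <- classify_ckd_risk(records, cvd_category, diabetes_category, cfg)
  alb <- classify_albuminuria(records$urine_acr, records$sex, cfg)
  flags <- lifestyle_flags(records, cfg)
  names(flags) <- paste0("flag_", names(flags))

  urgent <- is_true(records$random_glucose >= cfg$glucose_high) &
    !(diabetes_category %in% c("established_diabetes", "possible_new_diabetes"))

  out <- data.frame(
    participant_id = records$participant_id,
    event_id = records$event_id,
    sex = records$sex, age = records$age,
    cvd_category = cvd_category,
    calculated_5yr_risk = risk,
    ausdrisk_score = score,
    diabetes_category = diabetes_category,
    albuminuria = alb,
    urgent_glucose_review = urgent,
    hba1c_percent = records$hba1c_percent,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, ckd, flags)
  attr(out, "findings") <- findings
  class(out) <- c("risk_profiles", "data.frame")
  out
}

#' @export
summary.risk_profiles <- function(object, ...) {
  cat("Risk profiles for", nrow(object), "participants\n\n")
  cat("CVD risk categories:\n")
  print(table(factor(object$cvd_category, levels = cvd_category_levels())))
  cat("\nDiabetes risk categories:\n")
  print(table(factor(object$diabetes_category,
                     levels = diabetes_category_levels())))
  cat("\nHigh CKD risk:", sum(is_true(object$ckd_high_risk)),
      " Albuminuria:", sum(is_true(object$albuminuria)), "\n")
  invisible(object)
}

#' @export
print.risk_profiles <- function(x, ...) {
  cat("<risk_profiles: ", nrow(x), " participants>\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Category level sets
#'
#' The mutually exclusive category labels used by the classifiers, in report
#' display order.
#' @return Character vector of levels.
#' @export
cvd_category_levels <- function() {
  c("low", "medium", "high_calculated", "clinically_high",
    "established_cvd", "under_30", "indeterminate")
}

#' @rdname cvd_category_levels
#' @export
diabetes_category_levels <- function() {
  c("low_ausdrisk", "medium_ausdrisk", "high_ausdrisk", "impaired_glycemia",
    "possible_new_diabetes", "established_diabetes", "indeterminate")
}
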