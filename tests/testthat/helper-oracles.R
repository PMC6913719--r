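# Independent, deliberately naive re-expressions of the classification rules
# and instrument arithmetic, written as per-record if/else chains. They are
# the oracles the vectorised engine is checked against and share no code with
# it beyond the configuration files.

oracle_framingham <- function(age, sex, sbp, tc, hdl, smoker, diabetes,
                              lvh = FALSE, cf = framingham_coefficients()) {
  f <- as.numeric(sex == "female")
  b <- cf$coefficients
  x <- c(1, f, log(age), f * log(age), log(sbp), as.numeric(smoker),
         log(tc / hdl), as.numeric(diabetes), f * as.numeric(diabetes),
         as.numeric(lvh))
  beta <- c(b$intercept, b$female, b$log_age, b$female_log_age, b$log_sbp,
            b$smoker, b$log_tc_hdl, b$diabetes, b$female_diabetes, b$lvh)
  mu <- sum(beta * x)
  sigma <- exp(cf$sigma_intercept + cf$sigma_slope * mu)
  1 - exp(-exp((log(cf$horizon_years) - mu) / sigma))
}

oracle_ausdrisk <- function(r) {
  if (is.na(r$age) || is.na(r$sex) || is.na(r$indigenous_status) ||
      is.na(r$parental_diabetes) || is.na(r$prior_high_glucose) ||
      is.na(r$on_bp_lowering) || is.na(r$smoking_status) ||
      is.na(r$physical_activity_hours) || is.na(r$waist_cm)) {
    return(NA_integer_)
  }
  fruit <- r$fruit_intake_adequate
  veg <- r$vegetable_intake_adequate
  daily <- if (isTRUE(fruit) || isTRUE(veg)) TRUE
  else if (isFALSE(fruit) && isFALSE(veg)) FALSE
  else return(NA_integer_)

  pts <- 0
  pts <- pts + (if (r$age < 35) 0 else if (r$age < 45) 2
                else if (r$age < 55) 4 else if (r$age < 65) 6 else 8)
  if (r$sex == "male") pts <- pts + 3
  atsi <- r$indigenous_status == "aboriginal_andor_tsi"
  if (atsi) pts <- pts + 2
  if (r$parental_diabetes) pts <- pts + 3
  if (r$prior_high_glucose) pts <- pts + 6
  if (r$on_bp_lowering) pts <- pts + 2
  if (r$smoking_status == "current") pts <- pts + 2
  if (!daily) pts <- pts + 1
  if (r$physical_activity_hours < 2.5) pts <- pts + 2
  cuts <- if (r$sex == "male" && atsi) c(90, 100)
  else if (r$sex == "male") c(102, 110)
  else if (atsi) c(80, 90) else c(88, 100)
  pts <- pts + (if (r$waist_cm < cuts[1]) 0
                else if (r$waist_cm <= cuts[2]) 4 else 7)
  as.integer(pts)
}

oracle_cvd <- function(r, risk) {
  if (isTRUE(r$hx_chd) || isTRUE(r$hx_cbv) || isTRUE(r$hx_pvd)) {
    return("established_cvd")
  }
  alb <- if (is.na(r$urine_acr) || is.na(r$sex)) NA
  else r$urine_acr >= (if (r$sex == "male") 2.5 else 3.5)
  clin <-
    (isTRUE(r$known_diabetes) && !is.na(r$age) && r$age > 60) ||
    (isTRUE(r$known_diabetes) && isTRUE(alb)) ||
    (!is.na(r$sbp) && r$sbp > 180) ||
    (!is.na(r$dbp) && r$dbp > 110) ||
    (!is.na(r$total_cholesterol) && r$total_cholesterol > 7.5)
  if (clin) return("clinically_high")
  if (!is.na(r$age) && r$age < 30) return("under_30")
  if (is.na(risk)) return("indeterminate")
  if (risk > 0.15) return("high_calculated")
  if (risk >= 0.10) return("medium")
  "low"
}

oracle_diabetes <- function(r, score) {
  if (isTRUE(r$known_diabetes)) return("established_diabetes")
  if (!is.na(r$hba1c_percent) && r$hba1c_percent >= 6.5) {
    return("possible_new_diabetes")
  }
  if (!is.na(r$random_glucose) && r$random_glucose >= 5.5 &&
      r$random_glucose < 11.1) {
    return("impaired_glycemia")
  }
  if (is.na(score)) return("indeterminate")
  if (score >= 12) return("high_ausdrisk")
  if (score >= 6) return("medium_ausdrisk")
  "low_ausdrisk"
}

oracle_ckd <- function(r, dm_category) {
  bmi <- if (is.na(r$height_cm) || is.na(r$weight_kg)) NA
  else floor(r$weight_kg / (r$height_cm / 100)^2 * 10 + 0.5 + 1e-9) / 10
  crit <- list(
    obesity = if (is.na(bmi)) NA else bmi > 30,
    smoking = if (is.na(r$smoking_status)) NA else r$smoking_status == "current",
    cvd = r$hx_chd | r$hx_cbv | r$hx_pvd,
    family_history = r$family_history_ckd,
    diabetes = if (dm_category == "indeterminate") NA
    else dm_category %in% c("established_diabetes", "possible_new_diabetes")
  )
  vals <- unlist(crit)
  flag <- if (any(vals, na.rm = TRUE)) TRUE
  else if (all(is.na(vals))) NA else FALSE
  list(flag = flag,
       reasons = paste(names(crit)[!is.na(vals) & vals], collapse = ","))
}

# Brute-force portal sort: selection sort with an explicit pairwise comparator
oracle_priority_sort <- function(prof, followed_ids) {
  tier1 <- function(i) {
    if (prof$cvd_category[i] %in%
        c("established_cvd", "clinically_high", "high_calculated")) return(5)
    if (prof$diabetes_category[i] == "possible_new_diabetes" ||
        (prof$diabetes_category[i] == "established_diabetes" &&
         !is.na(prof$hba1c_percent[i]) && prof$hba1c_percent[i] > 8)) return(4)
    if (isTRUE(prof$albuminuria[i])) return(3)
    if (prof$diabetes_category[i] == "high_ausdrisk") return(2)
    1
  }
  before <- function(i, j) {
    fi <- prof$participant_id[i] %in% followed_ids
    fj <- prof$participant_id[j] %in% followed_ids
    if (fi != fj) return(!fi)
    ti <- tier1(i); tj <- tier1(j)
    if (ti != tj) return(ti > tj)
    prof$participant_id[i] < prof$participant_id[j]
  }
  idx <- seq_len(nrow(prof))
  for (a in seq_along(idx)) {
    best <- a
    for (b in seq_along(idx)) {
      if (b > a && before(idx[b], idx[best])) best <- b
    }
    tmp <- idx[a]; idx[a] <- idx[best]; idx[best] <- tmp
  }
  prof$participant_id[idx]
}

# Random in-range records (with missingness) spanning the rule space
grid_records <- function(n, seed = 1, na_rate = 0.08) {
  set.seed(seed)
  maybe_na <- function(x) {
    x[stats::runif(length(x)) < na_rate] <- NA
    x
  }
  tri <- function(n) maybe_na(stats::runif(n) < 0.5)
  rec <- data.frame(
    participant_id = sprintf("G%05d", seq_len(n)),
    event_id = "G1",
    age = maybe_na(sample(15:85, n, replace = TRUE)),
    sex = maybe_na(sample(c("male", "female"), n, replace = TRUE)),
    indigenous_status = maybe_na(sample(c("aboriginal_andor_tsi", "other"),
                                        n, replace = TRUE)),
    provider_1 = NA_character_, provider_2 = NA_character_,
    provider_3 = NA_character_,
    consent_to_share = TRUE,
    hx_chd = tri(n), hx_cbv = tri(n), hx_pvd = tri(n),
    known_diabetes = tri(n), family_history_ckd = tri(n),
    parental_diabetes = tri(n), prior_high_glucose = tri(n),
    on_bp_lowering = tri(n), on_lipid_lowering = tri(n),
    on_antiplatelet = tri(n), on_oral_glucose_lowering = tri(n),
    on_insulin = tri(n),
    smoking_status = maybe_na(sample(c("never", "quit_over_12m",
                                       "quit_within_12m", "current"),
                                     n, replace = TRUE)),
    smoking_years = NA_real_, cigarettes_per_day = NA_real_,
    physical_activity_hours = maybe_na(round(stats::runif(n, 0, 12), 1)),
    fruit_intake_adequate = tri(n), vegetable_intake_adequate = tri(n),
    height_cm = maybe_na(round(stats::runif(n, 145, 200), 1)),
    weight_kg = maybe_na(round(stats::runif(n, 45, 160), 1)),
    waist_cm = maybe_na(round(stats::runif(n, 60, 140), 1)),
    sbp = maybe_na(round(stats::runif(n, 90, 220))),
    dbp = maybe_na(round(stats::runif(n, 50, 120))),
    total_cholesterol = maybe_na(round(stats::runif(n, 2.5, 9.5), 1)),
    hdl = maybe_na(round(stats::runif(n, 0.5, 2.5), 2)),
    ldl = maybe_na(round(stats::runif(n, 1, 5.5), 1)),
    triglycerides = maybe_na(round(stats::runif(n, 0.4, 4), 2)),
    hba1c_percent = maybe_na(round(stats::runif(n, 4.2, 11), 1)),
    random_glucose = maybe_na(round(stats::runif(n, 3, 18), 1)),
    urine_acr = maybe_na(round(stats::runif(n, 0, 40), 1)),
    stringsAsFactors = FALSE
  )
  rec
}
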