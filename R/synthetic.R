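#' Synthetic cohort specification
#'
#' Describes the marginal structure of a screening cohort so the whole
#' pipeline can be exercised without participant data. The defaults are the
#' published community-screening conditions this engine targets: 9 sites with
#' the observed per-site attendance (total 1046), mean age 40.3 on 15-79,
#' 61.19% female, 91.49% Aboriginal and/or Torres Strait Islander,
#' sex-specific lifestyle-flag prevalences (e.g. current smoking 38.8%
#' female / 34.7% male), 16.54% known diabetes, 13.10% self-reported CVD,
#' 17.30% albuminuria, 4.30% undiagnosed diabetic-range HbA1c, and 28.87%
#' impaired glycaemia. Flags are generated independently — only marginals are
#' published — and continuous measurements are drawn from two-component
#' mixtures so that threshold-crossing probabilities equal the specified
#' prevalences exactly.
#'
#' @param n_per_site integer vector of participants per site (its length sets
#'   the number of sites), or a scalar with `n_sites`.
#' @param n_sites number of sites when `n_per_site` is scalar.
#' @param age_mean,age_sd,age_range truncated-normal age model (years).
#' @param pct_female,pct_indigenous cohort proportions in \[0, 1\].
#' @param lifestyle named list with `female` and `male` sublists of flag
#'   prevalences: `current_smoker`, `obese`, `elevated_waist`,
#'   `low_activity`, `infrequent_fruit`, `infrequent_veg`, `elevated_bp`,
#'   `dyslipidaemia`.
#' @param known_diabetes,cvd_history,albuminuria cohort prevalences.
#' @param possible_new_diabetes cohort proportion with diabetic-range HbA1c
#'   and no known diagnosis.
#' @param impaired_glycemia cohort proportion with random glucose in the
#'   impaired band (among those without known or HbA1c-detected diabetes).
#' @param quit_within_12m,family_history_ckd,parental_diabetes,
#'   prior_high_glucose,consent_to_share further prevalences.
#' @param missingness named list of per-domain missingness rates
#'   (`anthropometry`, `blood_pressure`, `lipids`, `hba1c`, `glucose`,
#'   `urine_acr`).
#' @param seed default RNG seed used by [generate_cohort()] when none is
#'   passed explicitly.
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(
    n_per_site = c(132, 114, 107, 118, 77, 119, 123, 127, 129),
    n_sites = NULL,
    age_mean = 40.3, age_sd = 16, age_range = c(15, 79),
    pct_female = 0.6119, pct_indigenous = 0.9149,
    lifestyle = list(
      female = list(current_smoker = 0.388, obese = 0.538,
                    elevated_waist = 0.761, low_activity = 0.217,
                    infrequent_fruit = 0.289, infrequent_veg = 0.822,
                    elevated_bp = 0.313, dyslipidaemia = 0.725),
      male = list(current_smoker = 0.347, obese = 0.448,
                  elevated_waist = 0.490, low_activity = 0.118,
                  infrequent_fruit = 0.246, infrequent_veg = 0.830,
                  elevated_bp = 0.456, dyslipidaemia = 0.759)
    ),
    known_diabetes = 0.1654, cvd_history = 0.1310, albuminuria = 0.1730,
    possible_new_diabetes = 0.0430, impaired_glycemia = 0.2887,
    quit_within_12m = 0.067, family_history_ckd = 0.20,
    parental_diabetes = 0.30, prior_high_glucose = 0.15,
    consent_to_share = 0.95,
    missingness = list(anthropometry = 0.01, blood_pressure = 0.02,
                       lipids = 0.08, hba1c = 0.03, glucose = 0.03,
                       urine_acr = 0.05),
    seed = 20150417) {
  if (!is.null(n_sites)) {
    stopifnot(length(n_per_site) == 1)
    n_per_site <- rep(n_per_site, n_sites)
  }
  spec <- list(
    n_per_site = as.integer(n_per_site),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    pct_female = pct_female, pct_indigenous = pct_indigenous,
    lifestyle = lifestyle,
    known_diabetes = known_diabetes, cvd_history = cvd_history,
    albuminuria = albuminuria,
    possible_new_diabetes = possible_new_diabetes,
    impaired_glycemia = impaired_glycemia,
    quit_within_12m = quit_within_12m,
    family_history_ckd = family_history_ckd,
    parental_diabetes = parental_diabetes,
    prior_high_glucose = prior_high_glucose,
    consent_to_share = consent_to_share,
    missingness = missingness, seed = seed
  )
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  if (any(spec$n_per_site < 0)) stop("n_per_site must be non-negative")
  probs <- c(spec$pct_female, spec$pct_indigenous,
             unlist(spec$lifestyle), spec$known_diabetes, spec$cvd_history,
             spec$albuminuria, spec$possible_new_diabetes,
             spec$impaired_glycemia, spec$quit_within_12m,
             spec$family_history_ckd, spec$parental_diabetes,
             spec$prior_high_glucose, spec$consent_to_share,
             unlist(spec$missingness))
  if (any(probs < 0 | probs > 1)) {
    stop("all prevalences and rates must lie in [0, 1]")
  }
  if (spec$possible_new_diabetes > 1 - spec$known_diabetes + 1e-12) {
    stop("infeasible spec: possible_new_diabetes exceeds the non-diabetic fraction")
  }
  if (spec$impaired_glycemia >
      1 - spec$known_diabetes - spec$possible_new_diabetes + 1e-12) {
    stop("infeasible spec: impaired_glycemia exceeds the remaining fraction")
  }
  if (spec$age_sd <= 0) stop("age_sd must be positive")
  if (spec$age_range[1] >= spec$age_range[2]) stop("invalid age_range")
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec: ", sum(x$n_per_site), " participants over ",
      length(x$n_per_site), " site(s); seed ", x$seed, ">\n", sep = "")
  invisible(x)
}

#' Generate a synthetic screening cohort
#'
#' Draws a cohort realising the marginal structure of a [cohort_spec()]:
#' flags are Bernoulli with the specified (sex-specific) prevalences, and
#' each continuous measurement is then drawn from the mixture component on
#' the matching side of its clinical threshold, so realized threshold
#' crossings equal the drawn flags exactly. Glycaemic state is drawn
#' hierarchically (known diabetes, then diabetic-range HbA1c, then impaired
#' glucose) with conditional probabilities back-computed from the cohort
#' proportions so the expected category mix matches the spec. Domain-wise
#' missingness is applied independently last. Identical spec and seed give
#' identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed; defaults to the spec's own.
#' @return Screening cohort `data.frame` (see [screening_columns()]).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_site = 100, n_sites = 1), seed = 1)
#' table(cohort$smoking_status)
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- sum(spec$n_per_site)
  if (n == 0) {
    return(coerce_schema(data.frame(participant_id = character())))
  }
  site <- rep(seq_along(spec$n_per_site), spec$n_per_site)

  sex <- ifelse(stats::runif(n) < spec$pct_female, "female", "male")
  indig <- ifelse(stats::runif(n) < spec$pct_indigenous,
                  "aboriginal_andor_tsi", "other")
  # place the normal's location so the *truncated* mean equals the spec mean
  age_mu <- truncnorm_location(spec$age_mean, spec$age_sd,
                               spec$age_range[1], spec$age_range[2])
  age <- round(rtruncnorm(n, age_mu, spec$age_sd,
                          spec$age_range[1], spec$age_range[2]))

  ls_p <- function(item) {
    ifelse(sex == "female", spec$lifestyle$female[[item]],
           spec$lifestyle$male[[item]])
  }
  draw <- function(p) stats::runif(n) < p

  f_smoke <- draw(ls_p("current_smoker"))
  f_obese <- draw(ls_p("obese"))
  f_waist <- draw(ls_p("elevated_waist"))
  f_lowact <- draw(ls_p("low_activity"))
  f_fruit <- draw(ls_p("infrequent_fruit"))
  f_veg <- draw(ls_p("infrequent_veg"))
  f_bp <- draw(ls_p("elevated_bp"))
  f_lipid <- draw(ls_p("dyslipidaemia"))

  # smoking status: current per flag; ex-smokers split among the rest
  smoking_status <- rep("never", n)
  smoking_status[f_smoke] <- "current"
  rest <- !f_smoke
  p_rest <- pmax(1 - ls_p("current_smoker"), 1e-12)
  u <- stats::runif(n)
  quit12 <- rest & (u < spec$quit_within_12m / p_rest)
  smoking_status[quit12] <- "quit_within_12m"
  quit_old <- rest & !quit12 & (stats::runif(n) < 0.25)
  smoking_status[quit_old] <- "quit_over_12m"

  smoker_recent <- smoking_status %in% c("current", "quit_within_12m")
  smoking_years <- ifelse(smoker_recent,
                          round(ifelse(stats::runif(n) < 0.641,
                                       stats::runif(n, 11, 40),
                                       stats::runif(n, 1, 10))), NA_real_)
  smoking_years <- pmin(smoking_years, pmax(age - 12, 1))
  cigarettes <- ifelse(smoker_recent,
                       round(ifelse(stats::runif(n) < 0.44,
                                    stats::runif(n, 11, 40),
                                    stats::runif(n, 1, 10))), NA_real_)

  activity <- round(ifelse(f_lowact, stats::runif(n, 0, 2.4),
                           stats::runif(n, 2.5, 14)), 1)

  height <- round(rtruncnorm(n, ifelse(sex == "male", 175, 162), 7, 145, 200), 1)
  bmi_target <- ifelse(f_obese, stats::runif(n, 30.3, 45),
                       stats::runif(n, 19, 29.7))
  weight <- round(bmi_target * (height / 100)^2, 1)
  waist_cut <- ifelse(sex == "male", 102, 88)
  waist <- round(ifelse(f_waist, waist_cut + stats::runif(n, 0.6, 30),
                        pmax(waist_cut - stats::runif(n, 0.6, 30), 55)), 1)

  # elevated components decay away from the threshold so extreme values
  # (SBP > 180, TC > 7.5 -- the clinically-high-risk conditions) stay rare
  sbp <- round(ifelse(f_bp, pmin(141 + stats::rexp(n, 1 / 12), 210),
                      stats::runif(n, 95, 140)))
  dbp <- round(ifelse(f_bp, stats::runif(n, 70, 110),
                      stats::runif(n, 55, 88)))
  dbp <- pmin(dbp, sbp - 10)

  tc <- round(ifelse(f_lipid, pmin(5.6 + stats::rexp(n, 1 / 0.6), 9.5),
                     stats::runif(n, 3.5, 5.4)), 1)
  hdl <- round(ifelse(f_lipid, stats::runif(n, 0.8, 1.8),
                      stats::runif(n, 1.05, 2.2)), 2)
  ldl <- round(ifelse(f_lipid, stats::runif(n, 2.5, 4.5),
                      stats::runif(n, 1.5, 3.4)), 1)
  tg <- round(ifelse(f_lipid, stats::runif(n, 0.8, 3.0),
                     stats::runif(n, 0.5, 1.9)), 2)

  f_diab <- draw(spec$known_diabetes)
  p_possible <- if (spec$known_diabetes >= 1) 0 else
    spec$possible_new_diabetes / (1 - spec$known_diabetes)
  f_possible <- !f_diab & draw(p_possible)
  rem <- 1 - spec$known_diabetes - spec$possible_new_diabetes
  p_impaired <- if (rem <= 0) 0 else spec$impaired_glycemia / rem
  f_impaired <- !f_diab & !f_possible & draw(p_impaired)

  # diabetic HbA1c: truncated normal on [5, 14] with location/scale solved so
  # 42.2% sit at or below the 7% target and 61.9% at or below 8% -- the
  # attainment pattern this kind of screening cohort shows
  hba1c <- round(ifelse(f_diab, rtruncnorm(n, 6.34, 2.65, 5, 14),
                        ifelse(f_possible, stats::runif(n, 6.5, 7.8),
                               rtruncnorm(n, 5.4, 0.4, 4.2, 6.44))), 1)
  glucose <- round(ifelse(f_diab | f_possible, stats::runif(n, 6, 16),
                          ifelse(f_impaired, stats::runif(n, 5.5, 11.04),
                                 rtruncnorm(n, 4.7, 0.5, 3.0, 5.44))), 1)

  f_alb <- draw(spec$albuminuria)
  acr_cut <- ifelse(sex == "male", 2.5, 3.5)
  acr <- round(ifelse(f_alb, acr_cut + stats::runif(n, 0, 30),
                      stats::runif(n, 0, acr_cut - 0.06)), 1)

  f_cvd <- draw(spec$cvd_history)
  which_cvd <- sample(c("chd", "cbv", "pvd"), n, replace = TRUE,
                      prob = c(0.6, 0.25, 0.15))
  hx_chd <- f_cvd & which_cvd == "chd"
  hx_cbv <- f_cvd & which_cvd == "cbv"
  hx_pvd <- f_cvd & which_cvd == "pvd"

  fam_ckd <- draw(spec$family_history_ckd)
  parent_dm <- draw(spec$parental_diabetes)
  prior_glu <- draw(spec$prior_high_glucose) | f_diab

  # medication use: a shared "well-managed" latent -- about 40% of people
  # with an indication take the guideline combination, the rest have small
  # independent uptake probabilities
  indicated <- f_cvd | f_bp | f_lipid | f_diab
  managed <- indicated & draw(0.40)
  on_bp_med <- (managed & (f_cvd | f_bp | f_diab)) |
    draw(ifelse(f_bp | f_cvd, 0.15, 0.05))
  on_lipid_med <- (managed & (f_cvd | f_lipid | f_diab)) |
    draw(ifelse(f_lipid | f_cvd, 0.10, 0.03))
  on_antiplatelet <- (managed & f_cvd) | draw(ifelse(f_cvd, 0.15, 0.03))
  on_oral <- f_diab & draw(0.804)
  on_insulin <- f_diab & draw(0.347)

  n_prov <- sample(0:3, n, replace = TRUE, prob = c(0.10, 0.50, 0.25, 0.15))
  pool <- function(s) paste0("S", s, "_", c("GP", "ACCHS", "LHD"))
  prov <- t(vapply(seq_len(n), function(i) {
    k <- n_prov[i]
    ids <- c(sample(pool(site[i]), k), rep(NA_character_, 3 - k))
    ids[1:3]
  }, character(3)))

  records <- data.frame(
    participant_id = sprintf("PT%05d", seq_len(n)),
    event_id = paste0("E", site),
    age = age, sex = sex, indigenous_status = indig,
    provider_1 = prov[, 1], provider_2 = prov[, 2], provider_3 = prov[, 3],
    consent_to_share = draw(spec$consent_to_share),
    hx_chd = hx_chd, hx_cbv = hx_cbv, hx_pvd = hx_pvd,
    known_diabetes = f_diab, family_history_ckd = fam_ckd,
    parental_diabetes = parent_dm, prior_high_glucose = prior_glu,
    on_bp_lowering = on_bp_med, on_lipid_lowering = on_lipid_med,
    on_antiplatelet = on_antiplatelet, on_oral_glucose_lowering = on_oral,
    on_insulin = on_insulin,
    smoking_status = smoking_status, smoking_years = smoking_years,
    cigarettes_per_day = cigarettes, physical_activity_hours = activity,
    fruit_intake_adequate = !f_fruit, vegetable_intake_adequate = !f_veg,
    height_cm = height, weight_kg = weight, waist_cm = waist,
    sbp = sbp, dbp = dbp,
    total_cholesterol = tc, hdl = hdl, ldl = ldl, triglycerides = tg,
    hba1c_percent = hba1c, random_glucose = glucose, urine_acr = acr,
    stringsAsFactors = FALSE
  )

  for (domain in names(spec$missingness)) {
    rate <- spec$missingness[[domain]]
    if (rate <= 0) next
    cols <- MEASUREMENT_DOMAINS[[domain]]
    hit <- draw(rate)
    records[hit, cols] <- NA
  }

  coerce_schema(records)
}

#' Generate synthetic follow-up records
#'
#' Draws a follow-up status per participant. When risk profiles are supplied,
#' the high-risk subgroup (see [high_risk_ids()]) is followed up at a rate
#' `high_risk_boost` above the others, with the others' rate back-computed so
#' the expected overall rate equals `rate` — mirroring the observation that
#' high-risk participants are followed up slightly more often.
#'
#' @param records screening cohort `data.frame`.
#' @param profiles optional `"risk_profiles"` for risk-dependent rates.
#' @param rate expected overall follow-up proportion in \[0, 1\].
#' @param high_risk_boost added probability for the high-risk subgroup.
#' @param event_date ISO date the screening event is deemed held.
#' @param seed integer RNG seed.
#' @return `data.frame` with `participant_id`, `followed_up`,
#'   `follow_up_date` (ISO-8601, `NA` when not followed up),
#'   `recording_provider`.
#' @export
generate_followups <- function(records, profiles = NULL, rate = 0.5143,
                               high_risk_boost = 0.05,
                               event_date = "2015-06-01", seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  n <- nrow(records)
  p <- rep(rate, n)
  if (!is.null(profiles) && n > 0) {
    hr <- records$participant_id %in% high_risk_ids(profiles)
    if (any(hr) && any(!hr)) {
      p_hr <- min(rate + high_risk_boost, 1)
      p_other <- (rate * n - p_hr * sum(hr)) / sum(!hr)
      p <- ifelse(hr, p_hr, min(max(p_other, 0), 1))
    }
  }
  followed <- stats::runif(n) < p
  delay <- sample(7:120, n, replace = TRUE)
  provider <- ifelse(is.na(records$provider_1), "UNASSIGNED",
                     records$provider_1)
  data.frame(
    participant_id = records$participant_id,
    followed_up = followed,
    follow_up_date = ifelse(followed,
                            format(as.Date(event_date) + delay, "%Y-%m-%d"),
                            NA_character_),
    recording_provider = ifelse(followed, provider, NA_character_),
    stringsAsFactors = FALSE
  )
}
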