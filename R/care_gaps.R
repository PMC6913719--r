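#' Care-gap assessment policy
#'
#' "Meeting guideline-recommended management goals" is a policy, not a single
#' published rule, so the definition is an explicit, configurable object that
#' every report prints alongside its rates. Defaults: people with established
#' CVD should be on blood-pressure-lowering, lipid-lowering and antiplatelet
#' therapy; people at high (clinical or calculated) CVD risk on the first two;
#' blood pressure at target means SBP <= 140 and DBP <= 90 mmHg; the diabetes
#' management goal is HbA1c at or below the strict target (7%).
#'
#' @param cvd_applicable_categories CVD categories the CVD assessment applies
#'   to.
#' @param require_antiplatelet_for_established if `TRUE`, established CVD
#'   additionally requires antiplatelet therapy for the recommended
#'   combination.
#' @param bp_target_sbp,bp_target_dbp blood-pressure target bounds (mmHg,
#'   attained at or below).
#' @param diabetes_goal `"strict"` (HbA1c <= 7%) or `"lenient"` (<= 8%).
#' @return Named list of class `"care_policy"`.
#' @export
care_policy <- function(cvd_applicable_categories = c("established_cvd",
                                                      "clinically_high",
                                                      "high_calculated"),
                        require_antiplatelet_for_established = TRUE,
                        bp_target_sbp = 140, bp_target_dbp = 90,
                        diabetes_goal = c("strict", "lenient")) {
  structure(list(
    cvd_applicable_categories = cvd_applicable_categories,
    require_antiplatelet_for_established = isTRUE(require_antiplatelet_for_established),
    bp_target_sbp = bp_target_sbp, bp_target_dbp = bp_target_dbp,
    diabetes_goal = match.arg(diabetes_goal)
  ), class = "care_policy")
}

#' Describe a care policy in one line
#' @param policy a [care_policy()].
#' @return Character scalar suitable for report headers.
#' @export
describe_care_policy <- function(policy) {
  sprintf(paste0(
    "CVD goal: BP-lowering + lipid-lowering%s for %s; BP target <=%d/%d mmHg; ",
    "diabetes goal: HbA1c <=%s%%"),
    if (policy$require_antiplatelet_for_established)
      " (+ antiplatelet if established CVD)" else "",
    paste(policy$cvd_applicable_categories, collapse = "/"),
    policy$bp_target_sbp, policy$bp_target_dbp,
    if (policy$diabetes_goal == "strict") "7" else "8")
}

#' Assess CVD management for participants with or at high risk of CVD
#'
#' Applicable to participants whose CVD category is in the policy's
#' applicable set (by default established CVD, clinically high risk, or high
#' calculated risk). The recommended combination is blood-pressure-lowering
#' AND lipid-lowering therapy, additionally AND antiplatelet therapy for
#' established CVD when the policy requires it. Unknown medication answers
#' propagate as unknown; non-applicable participants have every assessment
#' field unset.
#'
#' @param records screening cohort `data.frame`.
#' @param cvd_category category vector from [classify_cvd_risk()].
#' @param policy a [care_policy()].
#' @return `data.frame` with tri-state logical columns `cvd_applicable`,
#'   `on_bp_lowering`, `on_lipid_lowering`, `on_antiplatelet`,
#'   `on_recommended_combination`, `bp_at_target`, `meets_cvd_goals`.
#' @export
assess_cvd_management <- function(records, cvd_category,
                                  policy = care_policy()) {
  records <- coerce_schema(records)
  applicable <- cvd_category %in% policy$cvd_applicable_categories

  combo <- records$on_bp_lowering & records$on_lipid_lowering
  need_ap <- policy$require_antiplatelet_for_established &
    cvd_category == "established_cvd"
  combo <- ifelse(need_ap, combo & records$on_antiplatelet, combo)

  bp_ok <- records$sbp <= policy$bp_target_sbp &
    records$dbp <= policy$bp_target_dbp

  mask <- function(x) ifelse(applicable, x, NA)
  data.frame(
    cvd_applicable = applicable,
    on_bp_lowering = mask(records$on_bp_lowering),
    on_lipid_lowering = mask(records$on_lipid_lowering),
    on_antiplatelet = mask(records$on_antiplatelet),
    on_recommended_combination = mask(combo),
    bp_at_target = mask(bp_ok),
    meets_cvd_goals = mask(combo)
  )
}

#' Assess diabetes management for participants with established diabetes
#'
#' Applicable only to participants with an established (self-reported)
#' diabetes diagnosis. Evaluates self-reported glucose-lowering medication
#' use and HbA1c against the strict (7%) and lenient (8%) targets; the
#' overall management goal follows the policy's chosen target. Missing HbA1c
#' leaves the targets unknown.
#'
#' @param records screening cohort `data.frame`.
#' @param diabetes_category category vector from [classify_diabetes_risk()].
#' @param policy a [care_policy()].
#' @param cfg a [threshold_config()] supplying the two HbA1c target values.
#' @return `data.frame` with tri-state logical columns `dm_applicable`,
#'   `on_oral_glucose_lowering`, `on_insulin`, `hba1c_le_7pct`,
#'   `hba1c_le_8pct`, `meets_diabetes_goals`.
#' @export
assess_diabetes_management <- function(records, diabetes_category,
                                       policy = care_policy(),
                                       cfg = threshold_config()) {
  records <- coerce_schema(records)
  applicable <- diabetes_category == "established_diabetes"

  le7 <- records$hba1c_percent <= cfg$hba1c_target_strict
  le8 <- records$hba1c_percent <= cfg$hba1c_target_lenient
  goal <- if (policy$diabetes_goal == "strict") le7 else le8

  mask <- function(x) ifelse(applicable, x, NA)
  data.frame(
    dm_applicable = applicable,
    on_oral_glucose_lowering = mask(records$on_oral_glucose_lowering),
    on_insulin = mask(records$on_insulin),
    hba1c_le_7pct = mask(le7),
    hba1c_le_8pct = mask(le8),
    meets_diabetes_goals = mask(goal)
  )
}

#' Combined care-gap assessment
#'
#' Convenience wrapper running [assess_cvd_management()] and
#' [assess_diabetes_management()] over a screened cohort.
#'
#' @param records screening cohort `data.frame`.
#' @param profiles a `"risk_profiles"` object from [screen_cohort()].
#' @param policy a [care_policy()].
#' @param cfg a [threshold_config()].
#' @return `data.frame` keyed by `participant_id` with both assessments; the
#'   policy is attached as attribute `"policy"`.
#' @export
assess_care_gaps <- function(records, profiles, policy = care_policy(),
                             cfg = threshold_config()) {
  records <- coerce_schema(records)
  stopifnot(identical(records$participant_id, profiles$participant_id))
  out <- cbind(
    data.frame(participant_id = records$participant_id,
               stringsAsFactors = FALSE),
    assess_cvd_management(records, profiles$cvd_category, policy),
    assess_diabetes_management(records, profiles$diabetes_category, policy, cfg)
  )
  attr(out, "policy") <- policy
  out
}
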