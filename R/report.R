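#' Report percentage with explicit denominator
#'
#' All report percentages run through this one function: `100 * numerator /
#' denominator`, rounded half-up to `decimals`. A zero denominator returns
#' the explicit undefined marker `NA_real_` — never a silent 0.
#'
#' @param numerator,denominator non-negative counts, `numerator <=
#'   denominator`.
#' @param decimals decimal places (default 2).
#' @return Percentage on the 0-100 scale, `NA_real_` when the denominator is
#'   zero.
#' @examples
#' percentage(640, 1046)      # 61.19
#' percentage(99, 231, 1)     # 42.9
#' @export
percentage <- function(numerator, denominator, decimals = 2) {
  if (any(numerator < 0 | denominator < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  if (any(numerator > denominator, na.rm = TRUE)) {
    stop("numerator exceeds denominator")
  }
  ifelse(denominator == 0, NA_real_,
         round_half_up(100 * numerator / denominator, decimals))
}

count_true <- function(x) sum(is_true(x))

#' Follow-up rate for a cohort or subgroup
#'
#' Percentage of (filtered) participants with a recorded follow-up.
#'
#' @param records screening cohort `data.frame`.
#' @param followups follow-up `data.frame` (`participant_id`, `followed_up`,
#'   `follow_up_date`, `recording_provider`), e.g. from [read_followups()].
#' @param ids optional character vector restricting to a subgroup of
#'   participant ids.
#' @param decimals decimal places (default 2).
#' @return Percentage followed up; `NA_real_` for an empty subgroup.
#' @export
follow_up_rate <- function(records, followups, ids = NULL, decimals = 2) {
  pid <- records$participant_id
  if (!is.null(ids)) pid <- intersect(pid, ids)
  followed <- followups$participant_id[is_true(followups$followed_up)]
  percentage(sum(pid %in% followed), length(pid), decimals)
}

#' Participants with or at high risk of CVD, diabetes or CKD
#'
#' The subgroup used for high-risk follow-up reporting: union of the high CVD
#' categories (established, clinically high, high calculated), established or
#' possible new diabetes, and the high-CKD-risk composite.
#'
#' @param profiles a `"risk_profiles"` object from [screen_cohort()].
#' @return Character vector of participant ids.
#' @export
high_risk_ids <- function(profiles) {
  hi <- profiles$cvd_category %in%
    c("established_cvd", "clinically_high", "high_calculated") |
    profiles$diabetes_category %in%
    c("established_diabetes", "possible_new_diabetes") |
    is_true(profiles$ckd_high_risk)
  profiles$participant_id[hi]
}

#' Chronic-disease severity tier for the portal sort
#'
#' The default severity lattice, highest first: (5) established CVD,
#' clinically high or high calculated CVD risk; (4) possible new diabetes, or
#' established diabetes with HbA1c above 8%; (3) albuminuria; (2) high
#' AUSDRISK; (1) everyone else. Override by supplying your own tier function
#' to [prioritize_followup()].
#'
#' @param profiles a `"risk_profiles"` object.
#' @return Integer vector of tiers (5 = most severe).
#' @export
risk_tier <- function(profiles) {
  tier <- rep(1L, nrow(profiles))
  tier[profiles$diabetes_category == "high_ausdrisk"] <- 2L
  tier[is_true(profiles$albuminuria)] <- 3L
  tier[profiles$diabetes_category == "possible_new_diabetes" |
         (profiles$diabetes_category == "established_diabetes" &
            is_true(profiles$hba1c_percent > 8))] <- 4L
  tier[profiles$cvd_category %in%
         c("established_cvd", "clinically_high", "high_calculated")] <- 5L
  tier
}

#' Prioritise participants for follow-up
#'
#' The provider-portal sort: participants not yet followed up come first;
#' within each follow-up status, higher chronic-disease severity tiers come
#' first; ties are broken by `participant_id` so the order is total and
#' deterministic. A participant absent from the follow-up records counts as
#' not followed up.
#'
#' @param profiles a `"risk_profiles"` object from [screen_cohort()].
#' @param followups follow-up `data.frame`, or `NULL` (nobody followed up).
#' @param tier_fn function mapping profiles to integer severity (higher =
#'   more urgent); default [risk_tier()].
#' @return `data.frame` in priority order: `participant_id`, `followed_up`,
#'   `tier`, `cvd_category`, `diabetes_category`.
#' @export
prioritize_followup <- function(profiles, followups = NULL,
                                tier_fn = risk_tier) {
  followed_ids <- if (is.null(followups)) character() else
    followups$participant_id[is_true(followups$followed_up)]
  out <- data.frame(
    participant_id = profiles$participant_id,
    followed_up = profiles$participant_id %in% followed_ids,
    tier = tier_fn(profiles),
    cvd_category = profiles$cvd_category,
    diabetes_category = profiles$diabetes_category,
    stringsAsFactors = FALSE
  )
  out[order(out$followed_up, -out$tier, out$participant_id), , drop = FALSE]
}

#' Aggregate event report
#'
#' Builds the event-level report a program administrator sees: cohort size
#' and demographics per site and overall, lifestyle risk-factor prevalences
#' by sex, the mutually exclusive CVD and diabetes risk-category
#' distributions, CKD-risk and albuminuria rates, care-gap attainment among
#' the assessed subpopulations, follow-up rates (overall, per site, and in
#' the high-risk subgroup), and provider-nomination counts. Every percentage
#' is carried with both of its counts so it can be recomputed, and category
#' counts partition the cohort. Follow-up records with no matching
#' participant are listed in the report appendix, never dropped.
#'
#' @param records screening cohort `data.frame`.
#' @param profiles matching `"risk_profiles"` from [screen_cohort()].
#' @param caregaps optional care-gap assessment from [assess_care_gaps()].
#' @param followups optional follow-up `data.frame`.
#' @param decimals_prop decimals for cohort proportions (default 2).
#' @param decimals_care decimals for care-gap and lifestyle rates (default 1).
#' @return List of class `"event_report"`.
#' @export
event_report <- function(records, profiles, caregaps = NULL,
                         followups = NULL, decimals_prop = 2,
                         decimals_care = 1) {
  records <- coerce_schema(records)
  stopifnot(identical(records$participant_id, profiles$participant_id))
  n <- nrow(records)

  overall <- list(
    n_screened = n,
    n_sites = length(unique(records$event_id[!is.na(records$event_id)])),
    mean_age = if (n) round_half_up(mean(records$age, na.rm = TRUE), 1) else NA_real_,
    n_female = sum(records$sex == "female", na.rm = TRUE),
    pct_female = if (n) percentage(sum(records$sex == "female", na.rm = TRUE),
                                   n, decimals_prop) else NA_real_,
    n_indigenous = sum(records$indigenous_status == "aboriginal_andor_tsi",
                       na.rm = TRUE),
    pct_indigenous = if (n) percentage(
      sum(records$indigenous_status == "aboriginal_andor_tsi", na.rm = TRUE),
      n, decimals_prop) else NA_real_
  )
  overall$mean_screened_per_site <- if (overall$n_sites)
    round_half_up(n / overall$n_sites, 1) else NA_real_

  site_ids <- sort(unique(records$event_id))
  by_site <- do.call(rbind, lapply(site_ids, function(s) {
    idx <- !is.na(records$event_id) & records$event_id == s
    data.frame(
      event_id = s, n = sum(idx),
      mean_age = round_half_up(mean(records$age[idx], na.rm = TRUE), 1),
      n_female = sum(records$sex[idx] == "female", na.rm = TRUE),
      pct_female = percentage(sum(records$sex[idx] == "female", na.rm = TRUE),
                              sum(idx), decimals_care),
      follow_up_pct = if (is.null(followups)) NA_real_ else
        follow_up_rate(records[idx, , drop = FALSE], followups),
      stringsAsFactors = FALSE
    )
  }))

  flag_cols <- grep("^flag_", names(profiles), value = TRUE)
  lifestyle_by_sex <- do.call(rbind, lapply(c("female", "male"), function(sx) {
    idx <- !is.na(records$sex) & records$sex == sx
    do.call(rbind, lapply(flag_cols, function(fc) {
      data.frame(
        sex = sx, flag = sub("^flag_", "", fc),
        n = count_true(profiles[[fc]][idx]),
        denominator = sum(idx),
        pct = percentage(count_true(profiles[[fc]][idx]), sum(idx),
                         decimals_care),
        stringsAsFactors = FALSE
      )
    }))
  }))

  category_table <- function(x, levels) {
    counts <- table(factor(x, levels = levels))
    data.frame(category = levels, n = as.integer(counts),
               pct = percentage(as.integer(counts), rep(n, length(levels)),
                                decimals_prop),
               stringsAsFactors = FALSE)
  }
  cvd_categories <- category_table(profiles$cvd_category, cvd_category_levels())
  diabetes_categories <- category_table(profiles$diabetes_category,
                                        diabetes_category_levels())

  ckd <- list(n = count_true(profiles$ckd_high_risk),
              pct = if (n) percentage(count_true(profiles$ckd_high_risk), n,
                                      decimals_prop) else NA_real_)
  albuminuria <- list(n = count_true(profiles$albuminuria),
                      pct = if (n) percentage(count_true(profiles$albuminuria),
                                              n, decimals_prop) else NA_real_)

  care <- NULL
  if (!is.null(caregaps)) {
    n_cvd <- sum(caregaps$cvd_applicable)
    n_dm <- sum(caregaps$dm_applicable)
    care <- list(
      policy = describe_care_policy(attr(caregaps, "policy") %||% care_policy()),
      cvd = list(
        n_applicable = n_cvd,
        n_on_recommended = count_true(caregaps$on_recommended_combination),
        pct_on_recommended = percentage(
          count_true(caregaps$on_recommended_combination), n_cvd,
          decimals_care),
        n_bp_at_target = count_true(caregaps$bp_at_target),
        pct_bp_at_target = percentage(count_true(caregaps$bp_at_target),
                                      n_cvd, decimals_care)
      ),
      diabetes = list(
        n_applicable = n_dm,
        n_on_oral = count_true(caregaps$on_oral_glucose_lowering),
        pct_on_oral = percentage(count_true(caregaps$on_oral_glucose_lowering),
                                 n_dm, decimals_care),
        n_on_insulin = count_true(caregaps$on_insulin),
        pct_on_insulin = percentage(count_true(caregaps$on_insulin), n_dm,
                                    decimals_care),
        n_hba1c_le_7 = count_true(caregaps$hba1c_le_7pct),
        pct_hba1c_le_7 = percentage(count_true(caregaps$hba1c_le_7pct), n_dm,
                                    decimals_care),
        n_hba1c_le_8 = count_true(caregaps$hba1c_le_8pct),
        pct_hba1c_le_8 = percentage(count_true(caregaps$hba1c_le_8pct), n_dm,
                                    decimals_care)
      )
    )
  }

  followup <- NULL
  orphans <- data.frame(participant_id = character(), stringsAsFactors = FALSE)
  if (!is.null(followups)) {
    orphan_idx <- !(followups$participant_id %in% records$participant_id)
    orphans <- followups[orphan_idx, , drop = FALSE]
    hr_ids <- high_risk_ids(profiles)
    followup <- list(
      n_followed = sum(records$participant_id %in%
                         followups$participant_id[is_true(followups$followed_up)]),
      pct_followed = follow_up_rate(records, followups),
      n_high_risk = length(hr_ids),
      pct_followed_high_risk = follow_up_rate(records, followups, hr_ids)
    )
  }

  prov <- c(records$provider_1, records$provider_2, records$provider_3)
  prov <- prov[!is.na(prov)]
  providers <- if (length(prov)) {
    tab <- sort(table(prov), decreasing = TRUE)
    data.frame(provider = names(tab), n_nominations = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(provider = character(), n_nominations = integer(),
               stringsAsFactors = FALSE)
  }
  n_nominating <- sum(!is.na(records$provider_1) | !is.na(records$provider_2) |
                        !is.na(records$provider_3))

  structure(list(
    overall = overall, by_site = by_site,
    lifestyle_by_sex = lifestyle_by_sex,
    cvd_categories = cvd_categories,
    diabetes_categories = diabetes_categories,
    ckd = ckd, albuminuria = albuminuria,
    n_urgent_glucose_review = count_true(profiles$urgent_glucose_review),
    care = care, followup = followup,
    providers = providers, n_nominating = n_nominating,
    appendix = list(orphan_followups = orphans)
  ), class = "event_report")
}

#' @export
print.event_report <- function(x, ...) {
  o <- x$overall
  cat("==== Screening event report ====\n")
  cat(sprintf("Screened: %d participants at %d site(s) (mean %s per site)\n",
              o$n_screened, o$n_sites, format(o$mean_screened_per_site)))
  cat(sprintf("Mean age %s y; %d (%s%%) female; %d (%s%%) Aboriginal and/or Torres Strait Islander\n",
              format(o$mean_age), o$n_female, format(o$pct_female),
              o$n_indigenous, format(o$pct_indigenous)))
  cat("\n-- CVD risk categories --\n")
  print(x$cvd_categories, row.names = FALSE)
  cat("\n-- Diabetes risk categories --\n")
  print(x$diabetes_categories, row.names = FALSE)
  cat(sprintf("\nHigh CKD risk: %d (%s%%); albuminuria: %d (%s%%); urgent glucose review: %d\n",
              x$ckd$n, format(x$ckd$pct), x$albuminuria$n,
              format(x$albuminuria$pct), x$n_urgent_glucose_review))
  if (!is.null(x$care)) {
    cat("\n-- Care gaps --\n")
    cat("Policy:", x$care$policy, "\n")
    cv <- x$care$cvd; dm <- x$care$diabetes
    cat(sprintf("CVD (n=%d): %d (%s%%) on recommended medications; %d (%s%%) BP at target\n",
                cv$n_applicable, cv$n_on_recommended,
                format(cv$pct_on_recommended), cv$n_bp_at_target,
                format(cv$pct_bp_at_target)))
    cat(sprintf("Diabetes (n=%d): %d (%s%%) oral agents; %d (%s%%) insulin; %d (%s%%) HbA1c<=7%%; %d (%s%%) HbA1c<=8%%\n",
                dm$n_applicable, dm$n_on_oral, format(dm$pct_on_oral),
                dm$n_on_insulin, format(dm$pct_on_insulin),
                dm$n_hba1c_le_7, format(dm$pct_hba1c_le_7),
                dm$n_hba1c_le_8, format(dm$pct_hba1c_le_8)))
  }
  if (!is.null(x$followup)) {
    f <- x$followup
    cat(sprintf("\nFollow-up: %d (%s%%) overall; high-risk subgroup (n=%d): %s%%\n",
                f$n_followed, format(f$pct_followed), f$n_high_risk,
                format(f$pct_followed_high_risk)))
  }
  if (nrow(x$appendix$orphan_followups)) {
    cat(sprintf("\nAppendix: %d orphan follow-up record(s) with no matching participant\n",
                nrow(x$appendix$orphan_followups)))
  }
  invisible(x)
}

#' Write an event report
#'
#' Writes the machine-readable report as JSON and, optionally, the
#' human-readable summary as plain text.
#'
#' @param report an `"event_report"`.
#' @param path output JSON path.
#' @param txt_path optional plain-text summary path.
#' @return `path`, invisibly.
#' @export
write_event_report <- function(report, path, txt_path = NULL) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  if (!is.null(txt_path)) {
    writeLines(utils::capture.output(print(report)), txt_path)
  }
  invisible(path)
}
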