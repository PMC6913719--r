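#' @title Screening records
#' @description
#' A screening cohort is a plain `data.frame`, one row per participant, with
#' the columns listed by [screening_columns()]. Self-reported flags are
#' tri-state logicals (`TRUE` / `FALSE` / `NA` = unknown); measurements are
#' numeric with `NA` as the explicit missing marker — missingness is never
#' encoded as zero. [screening_record()] builds single rows for examples and
#' tests; [read_participants()] and [write_participants()] exchange cohorts as
#' CSV with empty cells for missing values.
#' @name screening-records
NULL

# column schema: name -> storage type
SCREENING_COLUMNS <- c(
  participant_id = "character", event_id = "character",
  age = "numeric", sex = "character", indigenous_status = "character",
  provider_1 = "character", provider_2 = "character", provider_3 = "character",
  consent_to_share = "logical",
  hx_chd = "logical", hx_cbv = "logical", hx_pvd = "logical",
  known_diabetes = "logical", family_history_ckd = "logical",
  parental_diabetes = "logical", prior_high_glucose = "logical",
  on_bp_lowering = "logical", on_lipid_lowering = "logical",
  on_antiplatelet = "logical", on_oral_glucose_lowering = "logical",
  on_insulin = "logical",
  smoking_status = "character", smoking_years = "numeric",
  cigarettes_per_day = "numeric", physical_activity_hours = "numeric",
  fruit_intake_adequate = "logical", vegetable_intake_adequate = "logical",
  height_cm = "numeric", weight_kg = "numeric", waist_cm = "numeric",
  sbp = "numeric", dbp = "numeric",
  total_cholesterol = "numeric", hdl = "numeric", ldl = "numeric",
  triglycerides = "numeric",
  hba1c_percent = "numeric", random_glucose = "numeric", urine_acr = "numeric"
)

SMOKING_LEVELS <- c("never", "quit_over_12m", "quit_within_12m", "current")
SEX_LEVELS <- c("male", "female")
INDIGENOUS_LEVELS <- c("aboriginal_andor_tsi", "other")

#' Screening record column schema
#'
#' @return Named character vector mapping column names to storage types
#'   (`"character"`, `"numeric"`, `"logical"`). Logical columns are tri-state:
#'   `NA` means the question was not answered.
#' @export
screening_columns <- function() SCREENING_COLUMNS

#' Plausibility ranges for measured fields
#'
#' Point-of-care analysers and station instruments report over bounded ranges;
#' values outside these bounds are treated as instrument or transcription
#' errors (an `error` validation finding) rather than extreme physiology. The
#' bounds are documented assumptions, not published instrument limits.
#'
#' @return Named list of `c(lower, upper)` bounds in the field's native units.
#' @export
plausibility_ranges <- function() {
  list(
    age = c(15, 120),
    height_cm = c(100, 230), weight_kg = c(25, 350), waist_cm = c(40, 250),
    sbp = c(60, 260), dbp = c(30, 160),
    total_cholesterol = c(1, 15), hdl = c(0.2, 5), ldl = c(0.2, 12),
    triglycerides = c(0.2, 20),
    hba1c_percent = c(3, 20), random_glucose = c(1, 35), urine_acr = c(0, 120),
    physical_activity_hours = c(0, 100),
    smoking_years = c(0, 100), cigarettes_per_day = c(0, 150)
  )
}

#' Build a single screening record
#'
#' Convenience constructor returning a one-row cohort `data.frame` with every
#' schema column present. Defaults describe a healthy, fully measured 45 year
#' old female; override any field by name. Useful for examples and tests.
#'
#' @param ... named field values overriding the defaults; names must be schema
#'   columns (see [screening_columns()]).
#' @return One-row `data.frame` in the screening schema.
#' @examples
#' screening_record(age = 62, known_diabetes = TRUE, hba1c_percent = 7.4)
#' @export
screening_record <- function(...) {
  rec <- list(
    participant_id = "PT00001", event_id = "E1",
    age = 45, sex = "female", indigenous_status = "aboriginal_andor_tsi",
    provider_1 = NA_character_, provider_2 = NA_character_,
    provider_3 = NA_character_,
    consent_to_share = TRUE,
    hx_chd = FALSE, hx_cbv = FALSE, hx_pvd = FALSE,
    known_diabetes = FALSE, family_history_ckd = FALSE,
    parental_diabetes = FALSE, prior_high_glucose = FALSE,
    on_bp_lowering = FALSE, on_lipid_lowering = FALSE,
    on_antiplatelet = FALSE, on_oral_glucose_lowering = FALSE,
    on_insulin = FALSE,
    smoking_status = "never", smoking_years = NA_real_,
    cigarettes_per_day = NA_real_, physical_activity_hours = 5,
    fruit_intake_adequate = TRUE, vegetable_intake_adequate = TRUE,
    height_cm = 165, weight_kg = 70, waist_cm = 80,
    sbp = 120, dbp = 75,
    total_cholesterol = 4.5, hdl = 1.4, ldl = 2.5, triglycerides = 1.2,
    hba1c_percent = 5.3, random_glucose = 4.8, urine_acr = 1.0
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(rec))
  if (length(bad)) stop("unknown screening field(s): ", paste(bad, collapse = ", "))
  rec[names(dots)] <- dots
  as.data.frame(rec, stringsAsFactors = FALSE)
}

#' Body mass index from height and weight
#'
#' @param height_cm standing height in centimetres.
#' @param weight_kg weight in kilograms.
#' @return BMI in kg/m^2, rounded to 1 decimal. Missing inputs give `NA`.
#' @examples
#' derive_bmi(170, 89.9)  # 31.1
#' @export
derive_bmi <- function(height_cm, weight_kg) {
  rng <- plausibility_ranges()
  check_range(height_cm, rng$height_cm, "height_cm")
  check_range(weight_kg, rng$weight_kg, "weight_kg")
  round_half_up(weight_kg / (height_cm / 100)^2, 1)
}

check_range <- function(x, bounds, field) {
  bad <- !is.na(x) & (x < bounds[1] | x > bounds[2])
  if (any(bad)) {
    stop(sprintf("%s outside plausible range [%s, %s]: %s",
                 field, bounds[1], bounds[2],
                 paste(utils::head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}

#' Convert HbA1c between NGSP percent and IFCC mmol/mol
#'
#' Uses the NGSP/IFCC master equation `mmol/mol = 10.929 * (percent - 2.15)`.
#' Results in mmol/mol are rounded to the nearest integer, percent to one
#' decimal, matching how the two unit systems are reported side by side
#' (6.5% is 48 mmol/mol, 7% is 53 mmol/mol, 8% is 64 mmol/mol).
#'
#' @param value HbA1c value(s).
#' @param to `"mmol_mol"` to convert percent to mmol/mol, `"percent"` for the
#'   reverse.
#' @return Converted value(s); `NA` in gives `NA` out.
#' @examples
#' convert_hba1c(7, "mmol_mol")     # 53
#' convert_hba1c(53, "percent")     # 7.0
#' @export
convert_hba1c <- function(value, to = c("mmol_mol", "percent")) {
  to <- match.arg(to)
  if (to == "mmol_mol") {
    check_range(value, c(3, 20), "hba1c_percent")
    round_half_up(10.929 * (value - 2.15), 0)
  } else {
    check_range(value, 10.929 * (c(3, 20) - 2.15), "hba1c_mmol_mol")
    round_half_up(value / 10.929 + 2.15, 1)
  }
}

# measurement domains used for validation warnings and domain-wise cleaning
MEASUREMENT_DOMAINS <- list(
  anthropometry = c("height_cm", "weight_kg", "waist_cm"),
  blood_pressure = c("sbp", "dbp"),
  lipids = c("total_cholesterol", "hdl", "ldl", "triglycerides"),
  hba1c = "hba1c_percent",
  glucose = "random_glucose",
  urine_acr = "urine_acr"
)

#' Validate a screening cohort
#'
#' Checks every record against the schema: categorical fields must take known
#' levels, measurements must fall inside [plausibility_ranges()], diastolic
#' must be below systolic, and smoking quantities are only expected for
#' current or recent smokers. Findings are returned, never thrown: `error`
#' findings mark values that must not be classified (the record is treated as
#' missing for the affected domain, see [clean_screening()]); `warning`
#' findings flag missing measurement domains that limit classification.
#'
#' @param records screening cohort `data.frame`.
#' @return `data.frame` with columns `participant_id`, `row`, `field`,
#'   `severity` (`"error"`/`"warning"`), `message`; zero rows when clean.
#' @examples
#' validate_screening(screening_record(sbp = 110, dbp = 120))
#' @export
validate_screening <- function(records) {
  records <- coerce_schema(records)
  rng <- plausibility_ranges()
  out <- list()
  add <- function(rows, field, severity, message) {
    if (!length(rows) || !any(rows)) return()
    out[[length(out) + 1]] <<- data.frame(
      participant_id = records$participant_id[rows],
      row = which(rows), field = field, severity = severity,
      message = message, stringsAsFactors = FALSE
    )
  }

  add(duplicated(records$participant_id), "participant_id", "error",
      "duplicate participant_id")
  add(is.na(records$participant_id) | records$participant_id == "",
      "participant_id", "error", "missing participant_id")
  add(!is.na(records$sex) & !(records$sex %in% SEX_LEVELS), "sex", "error",
      paste("sex must be one of:", paste(SEX_LEVELS, collapse = ", ")))
  add(is.na(records$sex), "sex", "warning", "sex missing")
  add(!is.na(records$indigenous_status) &
        !(records$indigenous_status %in% INDIGENOUS_LEVELS),
      "indigenous_status", "error", "unrecognised indigenous_status")
  add(!is.na(records$smoking_status) &
        !(records$smoking_status %in% SMOKING_LEVELS),
      "smoking_status", "error",
      paste("smoking_status must be one of:",
            paste(SMOKING_LEVELS, collapse = ", ")))
  add(is.na(records$age), "age", "warning", "age missing")

  for (field in names(rng)) {
    x <- records[[field]]
    if (is.null(x)) next
    b <- rng[[field]]
    add(!is.na(x) & (x < b[1] | x > b[2]), field, "error",
        sprintf("value outside plausible range [%s, %s]", b[1], b[2]))
  }

  add(!is.na(records$sbp) & !is.na(records$dbp) & records$dbp >= records$sbp,
      "blood_pressure", "error", "diastolic must be below systolic")

  no_smoke <- !is.na(records$smoking_status) &
    records$smoking_status %in% c("never", "quit_over_12m")
  add(no_smoke & (!is.na(records$smoking_years) |
                    !is.na(records$cigarettes_per_day)),
      "smoking_status", "warning",
      "smoking quantities reported for a non-current smoker")

  for (domain in names(MEASUREMENT_DOMAINS)) {
    cols <- MEASUREMENT_DOMAINS[[domain]]
    all_missing <- Reduce(`&`, lapply(records[cols], is.na))
    add(all_missing, domain, "warning",
        sprintf("no %s measurements; dependent classifications will be indeterminate",
                gsub("_", " ", domain)))
  }

  if (!length(out)) {
    return(data.frame(participant_id = character(), row = integer(),
                      field = character(), severity = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$row, res$field), , drop = FALSE]
}

#' Blank out values carrying error findings
#'
#' Applies the findings from [validate_screening()]: any field named in an
#' `error` finding is set to `NA` so downstream classifiers see it as missing
#' (and return `indeterminate` for the affected domain) rather than classify
#' an implausible value. Warnings leave the data untouched.
#'
#' @param records screening cohort `data.frame`.
#' @param findings optional findings `data.frame`; computed if omitted.
#' @return The cohort with error-flagged values replaced by `NA`.
#' @export
clean_screening <- function(records, findings = validate_screening(records)) {
  records <- coerce_schema(records)
  errs <- findings[findings$severity == "error", , drop = FALSE]
  for (i in seq_len(nrow(errs))) {
    field <- errs$field[i]
    row <- errs$row[i]
    cols <- if (field %in% names(MEASUREMENT_DOMAINS)) {
      MEASUREMENT_DOMAINS[[field]]
    } else if (field %in% names(records)) {
      field
    } else {
      character()
    }
    for (col in setdiff(cols, "participant_id")) {
      records[row, col] <- NA
    }
  }
  records
}

# coerce a data.frame (e.g. fresh from CSV) onto the schema types; unknown
# columns are dropped, absent columns created as NA
coerce_schema <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  out <- records[intersect(names(SCREENING_COLUMNS), names(records))]
  for (col in names(SCREENING_COLUMNS)) {
    type <- SCREENING_COLUMNS[[col]]
    x <- if (col %in% names(out)) out[[col]] else rep(NA, n)
    out[[col]] <- switch(type,
      character = {
        x <- as.character(x)
        x[!is.na(x) & trimws(x) == ""] <- NA
        x
      },
      numeric = suppressWarnings(as.numeric(x)),
      logical = if (is.logical(x)) x else parse_yesno(x)
    )
  }
  out[names(SCREENING_COLUMNS)]
}
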