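#' Read a participant CSV
#'
#' Reads a screening cohort from delimited text (UTF-8, header row, RFC-4180
#' quoting, one row per participant, empty cell = missing). Tri-state flags
#' are written as `yes`/`no`/empty. Rows whose values cannot be interpreted
#' in the schema (unknown categorical levels, non-numeric measurements) are
#' never silently dropped: they are excluded from the returned cohort and
#' collected, with line numbers and reasons, in the `"rejections"` attribute.
#'
#' @param path CSV path.
#' @return Screening cohort `data.frame` with attribute `"rejections"` (a
#'   `data.frame` of `line`, `participant_id`, `reason`; zero rows when all
#'   rows parse).
#' @seealso [write_participants()]
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("participant file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing_cols <- setdiff(names(SCREENING_COLUMNS), names(raw))
  if (length(missing_cols)) {
    stop("participant file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  reasons <- rep(NA_character_, n)
  note <- function(rows, reason) {
    fresh <- rows & is.na(reasons)
    reasons[fresh] <<- reason
  }

  for (col in names(SCREENING_COLUMNS)) {
    x <- raw[[col]]
    type <- SCREENING_COLUMNS[[col]]
    if (type == "numeric") {
      bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
      note(bad, paste0("non-numeric value in ", col))
    } else if (type == "logical") {
      bad <- !is.na(x) & is.na(parse_yesno(x))
      note(bad, paste0("unrecognised yes/no value in ", col))
    }
  }
  note(!is.na(raw$sex) & !(tolower(raw$sex) %in% SEX_LEVELS),
       "unrecognised sex")
  note(!is.na(raw$smoking_status) &
         !(raw$smoking_status %in% SMOKING_LEVELS),
       "unrecognised smoking_status")
  note(!is.na(raw$indigenous_status) &
         !(raw$indigenous_status %in% INDIGENOUS_LEVELS),
       "unrecognised indigenous_status")

  bad <- !is.na(reasons)
  rejections <- data.frame(
    line = which(bad) + 1L,  # +1 for the header row
    participant_id = raw$participant_id[bad],
    reason = reasons[bad], stringsAsFactors = FALSE
  )
  records <- coerce_schema(raw[!bad, , drop = FALSE])
  rownames(records) <- NULL
  if (nrow(rejections)) {
    warning(nrow(rejections), " row(s) rejected while reading ", path,
            "; see attr(x, 'rejections')")
  }
  attr(records, "rejections") <- rejections
  records
}

#' Write a participant CSV
#'
#' Inverse of [read_participants()]: logical flags become `yes`/`no`,
#' missing values become empty cells. `read_participants(write_participants(x))`
#' returns `x` for any schema-valid cohort.
#'
#' @param records screening cohort `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(records, path) {
  records <- coerce_schema(records)
  out <- records
  for (col in names(SCREENING_COLUMNS)) {
    if (SCREENING_COLUMNS[[col]] == "logical") {
      out[[col]] <- format_yesno(out[[col]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read follow-up records
#'
#' Delimited follow-up extract: `participant_id`, `followed_up` (yes/no),
#' `follow_up_date` (ISO-8601, empty when not followed up),
#' `recording_provider`. A dated record implies followed up; rows violating
#' that, or with unparseable dates, are rejected with line numbers (attribute
#' `"rejections"`).
#'
#' @param path CSV path.
#' @return `data.frame` with attribute `"rejections"`.
#' @export
read_followups <- function(path) {
  if (!file.exists(path)) stop("follow-up file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, na.strings = c("", "NA"))
  needed <- c("participant_id", "followed_up", "follow_up_date",
              "recording_provider")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("follow-up file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  followed <- parse_yesno(raw$followed_up)
  date_ok <- is.na(raw$follow_up_date) |
    !is.na(suppressWarnings(as.Date(raw$follow_up_date, format = "%Y-%m-%d")))
  bad_flag <- !is.na(raw$followed_up) & is.na(followed)
  dated_not_followed <- !is.na(raw$follow_up_date) & !is_true(followed)
  bad <- bad_flag | !date_ok | dated_not_followed
  reason <- ifelse(bad_flag, "unrecognised followed_up value",
                   ifelse(!date_ok, "unparseable follow_up_date (want YYYY-MM-DD)",
                          "follow_up_date present but followed_up is not 'yes'"))
  rejections <- data.frame(line = which(bad) + 1L,
                           participant_id = raw$participant_id[bad],
                           reason = reason[bad], stringsAsFactors = FALSE)
  out <- data.frame(
    participant_id = raw$participant_id,
    followed_up = followed,
    follow_up_date = raw$follow_up_date,
    recording_provider = raw$recording_provider,
    stringsAsFactors = FALSE
  )[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(rejections)) {
    warning(nrow(rejections), " follow-up row(s) rejected; see attr(x, 'rejections')")
  }
  attr(out, "rejections") <- rejections
  out
}

#' Write follow-up records
#'
#' @param followups follow-up `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_followups <- function(followups, path) {
  out <- followups
  out$followed_up <- format_yesno(out$followed_up)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full screening pipeline
#'
#' End-to-end run over files: read and validate participants, classify risk,
#' assess care gaps, build the event report and the prioritised follow-up
#' list, and write every artifact to `out_dir`:
#' `participant_summary.csv` (per-participant risk profile and care gaps),
#' `event_report.json` and `event_report.txt`, `priority_list.csv`, and
#' `validation_findings.csv`. Outputs are deterministic given identical
#' inputs; input files are never modified.
#'
#' @param participants_path participant CSV.
#' @param out_dir output directory (created if needed).
#' @param followups_path optional follow-up CSV.
#' @param cfg a [threshold_config()].
#' @param policy a [care_policy()].
#' @param coefficients a [framingham_coefficients()] set.
#' @param points an [ausdrisk_points()] table.
#' @return Invisibly, a list with `records`, `profiles`, `caregaps`,
#'   `report`, `priority`, `findings`, `rejections` and the written `paths`.
#' @export
run_pipeline <- function(participants_path, out_dir,
                         followups_path = NULL,
                         cfg = threshold_config(),
                         policy = care_policy(),
                         coefficients = framingham_coefficients(),
                         points = ausdrisk_points()) {
  records <- read_participants(participants_path)
  followups <- if (!is.null(followups_path)) read_followups(followups_path)
  if (nrow(records) == 0) warning("participant file contains no records")

  profiles <- screen_cohort(records, cfg, coefficients, points)
  caregaps <- assess_care_gaps(records, profiles, policy, cfg)
  report <- event_report(records, profiles, caregaps, followups)
  priority <- prioritize_followup(profiles, followups)
  findings <- attr(profiles, "findings")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    summary = file.path(out_dir, "participant_summary.csv"),
    report_json = file.path(out_dir, "event_report.json"),
    report_txt = file.path(out_dir, "event_report.txt"),
    priority = file.path(out_dir, "priority_list.csv"),
    findings = file.path(out_dir, "validation_findings.csv")
  )
  summary_df <- merge(as.data.frame(profiles), caregaps,
                      by = "participant_id", sort = FALSE)
  utils::write.csv(summary_df, paths$summary, row.names = FALSE, na = "")
  write_event_report(report, paths$report_json, paths$report_txt)
  utils::write.csv(priority, paths$priority, row.names = FALSE, na = "")
  utils::write.csv(findings, paths$findings, row.names = FALSE, na = "")

  message(sprintf(
    "pipeline: %d row(s) read, %d rejected, %d validated (%d error finding(s)), %d classified",
    nrow(records) + nrow(attr(records, "rejections")),
    nrow(attr(records, "rejections")), nrow(records),
    sum(findings$severity == "error"), nrow(profiles)))

  invisible(list(records = records, profiles = profiles, caregaps = caregaps,
                 report = report, priority = priority, findings = findings,
                 rejections = attr(records, "rejections"), paths = paths))
}
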