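#' Clinical threshold configuration
#'
#' Builds the set of clinical cut-points and policy switches that drive risk
#' classification and care-gap assessment. Defaults are the Australian
#' guideline values the engine ships with (see
#' `system.file("extdata", "thresholds.yaml", package = "commscreen")`):
#' high CVD risk above a calculated 15% 5-year risk, clinically high-risk
#' conditions at SBP > 180 mmHg, DBP > 110 mmHg or total cholesterol
#' > 7.5 mmol/L, AUSDRISK bands low <= 5 / intermediate 6-11 / high >= 12,
#' possible new diabetes at HbA1c >= 6.5%, impaired glycaemia at a random
#' capillary glucose in [5.5, 11.1) mmol/L, and sex-specific albuminuria
#' cut-points (>= 2.5 mg/mmol male, >= 3.5 mg/mmol female).
#'
#' @param ... named overrides of individual thresholds (see the shipped YAML
#'   for the full list of names and units).
#' @return A named list of class `"threshold_config"`.
#' @seealso [read_threshold_config()]
#' @examples
#' cfg <- threshold_config()
#' cfg$calc_risk_high
#' strict <- threshold_config(calc_risk_high = 0.10)
#' @export
threshold_config <- function(...) {
  cfg <- yaml::read_yaml(system.file("extdata", "thresholds.yaml",
                                     package = "commscreen"))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown threshold name(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  validate_threshold_config(cfg)
}

#' Read a threshold configuration from a YAML file
#'
#' @param path path to a YAML file with the same field names as the shipped
#'   default configuration.
#' @return A validated `"threshold_config"` list.
#' @export
read_threshold_config <- function(path) {
  if (!file.exists(path)) stop("threshold config not found: ", path)
  validate_threshold_config(yaml::read_yaml(path))
}

validate_threshold_config <- function(cfg) {
  required <- c(
    "calc_risk_high", "calc_risk_low", "sbp_high", "dbp_high", "tc_high",
    "diabetes_age", "min_age_for_calculated_risk", "bmi_obese", "waist_male",
    "waist_female", "sbp_flag", "dbp_flag", "tc_dyslipid", "hdl_low",
    "ldl_high", "tg_high", "activity_min", "acr_male", "acr_female",
    "hba1c_diabetes", "glucose_low", "glucose_high", "ausdrisk_high",
    "ausdrisk_low_max", "hba1c_target_strict", "hba1c_target_lenient"
  )
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("threshold config is missing: ", paste(missing, collapse = ", "))
  }
  num <- vapply(cfg[required], is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric threshold(s): ",
         paste(required[!num], collapse = ", "))
  }
  if (any(unlist(cfg[required]) <= 0)) {
    stop("all thresholds must be strictly positive")
  }
  if (cfg$glucose_low >= cfg$glucose_high) {
    stop("glucose band lower bound must be below upper bound")
  }
  if (cfg$calc_risk_low >= cfg$calc_risk_high) {
    stop("calc_risk_low must be below calc_risk_high")
  }
  if (cfg$hba1c_target_strict > cfg$hba1c_target_lenient) {
    stop("strict HbA1c target must not exceed the lenient target")
  }
  cfg$bmi_waist_rescue <- isTRUE(cfg$bmi_waist_rescue)
  cfg$cvd_diabetes_includes_detected <- isTRUE(cfg$cvd_diabetes_includes_detected)
  structure(cfg, class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  nm <- names(x)
  for (i in seq_along(x)) {
    cat(sprintf("  %-32s %s\n", nm[i], format(x[[i]])))
  }
  invisible(x)
}
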