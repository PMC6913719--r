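#' Round half away from zero
#'
#' Decimal rounding with halves rounded up (away from zero), the convention
#' used throughout the engine's reports. Base [round()] rounds half to even,
#' which disagrees with hand-tallied report arithmetic at exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @examples
#' round_half_up(2.5, 0)   # 3, where round(2.5) gives 2
#' round_half_up(61.185, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a relative epsilon so values that are exact halves in decimal but
  # stored fractionally below them in binary still round up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncated normal via inverse-CDF; vectorised over n
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# location mu such that a N(mu, sd) truncated to [a, b] has mean `target`
truncnorm_location <- function(target, sd, a, b) {
  tmean <- function(mu) {
    al <- (a - mu) / sd; be <- (b - mu) / sd
    mu + sd * (stats::dnorm(al) - stats::dnorm(be)) /
      (stats::pnorm(be) - stats::pnorm(al))
  }
  stats::uniroot(function(mu) tmean(mu) - target, c(a, b), tol = 1e-8)$root
}

# TRUE where x is a non-missing TRUE (missing never fires a rule)
is_true <- function(x) !is.na(x) & x

# logical -> "yes"/"no"/"" for delimited output
format_yesno <- function(x) {
  out <- character(length(x))
  out[is_true(x)] <- "yes"
  out[!is.na(x) & !x] <- "no"
  out
}

# "yes"/"no"/""/NA -> logical (anything else left NA; caller validates)
parse_yesno <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("yes", "true", "1")] <- TRUE
  out[x %in% c("no", "false", "0")] <- FALSE
  out
}
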