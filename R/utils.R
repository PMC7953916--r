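# Classed conditions shared by all modules. Every user-facing failure goes
# through one of these so callers (and the batch driver) can branch on class.

abort_validation <- function(message, ...) {
  rlang::abort(message, class = c("regenscore_validation_error", "regenscore_error"), ...)
}

abort_measurement <- function(message, ...) {
  rlang::abort(message, class = c("regenscore_measurement_error", "regenscore_error"), ...)
}

abort_insufficient <- function(message, ...) {
  rlang::abort(message, class = c("regenscore_insufficient_data_error", "regenscore_error"), ...)
}

abort_config <- function(message, ...) {
  rlang::abort(message, class = c("regenscore_config_error", "regenscore_error"), ...)
}

abort_schema <- function(message, ...) {
  rlang::abort(message, class = c("regenscore_schema_error", "regenscore_error"), ...)
}

#' Parse questionnaire booleans
#'
#' Accepts `yes`/`no`, `true`/`false`, `t`/`f`, `y`/`n` and `1`/`0`
#' (case-insensitive, whitespace-trimmed). `NA` and empty strings stay `NA`;
#' anything else is an error naming the offending values.
#'
#' @param x character, logical or numeric vector of answers.
#' @return logical vector of the same length.
#' @export
#' @examples
#' parse_answer(c("Yes", "no", "1", "FALSE", NA))
parse_answer <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !x %in% c(0, 1)
    if (any(bad)) abort_schema(paste0("Numeric answers must be 0/1; got: ",
                                      paste(unique(x[bad]), collapse = ", ")))
    return(x == 1)
  }
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("yes", "y", "true", "t", "1")] <- TRUE
  out[s %in% c("no", "n", "false", "f", "0")] <- FALSE
  bad <- !is.na(s) & s != "" & is.na(out)
  if (any(bad)) {
    abort_schema(paste0("Unparseable boolean answer(s): ",
                        paste(unique(s[bad]), collapse = ", ")))
  }
  out
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

# Derive a deterministic 32-bit sub-seed for a named substream, so adding a
# generator never perturbs the draws of another under the same master seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(substream_seed(seed, name))
  force(code)
}
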