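#' Questionnaire schemas
#'
#' Column names and types expected by [read_survey()]. The cropland survey
#' has one boolean column per practice item; the rangeland survey records
#' answers in natural units (applications per year, AU/ha, days). Booleans
#' are accepted as yes/no, true/false, t/f, y/n or 1/0, case-insensitive.
#'
#' @param system `"cropland"` or `"rangeland"`.
#' @return character vector of required column names.
#' @export
#' @examples
#' cropland_schema()
cropland_schema <- function() {
  c("operation_id", "system", unname(cropland_answer_fields()))
}

#' @rdname cropland_schema
#' @export
rangeland_schema <- function() {
  c("operation_id", rangeland_answer_fields())
}

#' @rdname cropland_schema
#' @export
survey_schema <- function(system = c("cropland", "rangeland")) {
  system <- match.arg(system)
  if (system == "cropland") cropland_schema() else rangeland_schema()
}

#' Read a producer survey table
#'
#' Reads a comma-separated survey (one row per operation), validates it
#' against the questionnaire schema, and returns a typed answer tibble ready
#' for [score_cropland()] or [score_rangeland()]. Malformed rows are rejected
#' with the row number and offending column; unknown columns beyond the
#' schema are allowed and carried through untouched (metadata such as
#' location or years in system never enters the score).
#'
#' @param path file path to a CSV survey.
#' @param system `"cropland"` or `"rangeland"`.
#' @return tibble of answers.
#' @export
read_survey <- function(path, system = c("cropland", "rangeland")) {
  system <- match.arg(system)
  if (!file.exists(path)) abort_validation(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) abort_validation(paste0("Empty survey file: ", path))
  need <- survey_schema(system)
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort_schema(paste0("Survey is missing column(s): ", paste(miss, collapse = ", ")))
  }
  validate_ids(raw$operation_id)

  parse_num <- function(col, check, what) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    x[trimws(raw[[col]] %||% "") %in% c("Inf", "inf")] <- Inf
    bad <- which(!is.na(raw[[col]]) & is.na(x) | (!is.na(x) & !check(x)))
    if (length(bad)) {
      abort_schema(paste0("Row ", bad[1], ", column '", col, "': ", what,
                          " (got '", raw[[col]][bad[1]], "')"))
    }
    x
  }
  parse_col_bool <- function(col) {
    tryCatch(parse_answer(raw[[col]]),
             regenscore_schema_error = function(e) {
               bad <- which(!is.na(raw[[col]]) &
                              is.na(suppressWarnings(parse_answer_quiet(raw[[col]]))))
               abort_schema(paste0("Row ", bad[1], ", column '", col, "': ",
                                   conditionMessage(e)))
             })
  }

  if (system == "cropland") {
    out <- raw
    bad_sys <- which(!raw$system %in% c("cropland_full", "cropland_corn"))
    if (length(bad_sys)) {
      abort_schema(paste0("Row ", bad_sys[1],
                          ", column 'system': must be cropland_full or cropland_corn"))
    }
    for (col in unname(cropland_answer_fields())) out[[col]] <- parse_col_bool(col)
    out
  } else {
    out <- raw
    out$ivermectin_applications_per_year <- parse_num(
      "ivermectin_applications_per_year",
      function(x) x >= 0 & x == round(x), "must be a nonnegative integer")
    out$ivermectin_applied_during_grazing <-
      parse_col_bool("ivermectin_applied_during_grazing")
    out$stocking_density_au_per_ha <- parse_num(
      "stocking_density_au_per_ha", function(x) x >= 0, "must be nonnegative")
    out$rotation_frequency_days <- parse_num(
      "rotation_frequency_days", function(x) x > 0, "must be positive (Inf = never)")
    out$rest_period_days <- parse_num(
      "rest_period_days", function(x) x >= 0, "must be nonnegative")
    out
  }
}

# parse_answer that returns NA instead of aborting, for error localization
parse_answer_quiet <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("yes", "y", "true", "t", "1")] <- TRUE
  out[s %in% c("no", "n", "false", "f", "0")] <- FALSE
  out
}

#' Write a score-record table
#'
#' Writes score records as CSV with a stable column order and numeric
#' formatting at six significant digits, so output files are deterministic
#' given the same input.
#'
#' @param records score-record tibble from [score_cropland()] /
#'   [score_rangeland()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(records, path) {
  records <- as_tibble(records)
  lead <- intersect(c("operation_id", "system"), names(records))
  rest <- setdiff(names(records), lead)
  records <- records[, c(lead, rest)]
  records[] <- lapply(records, function(x) if (is.double(x)) signif(x, 6) else x)
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Direct-cost net profit per hectare
#'
#' Sums revenue entries and subtracts cost entries for each operation; only
#' direct costs and revenues enter (no overhead allocation, inflation or
#' discounting). Both kinds must be recorded as positive magnitudes.
#'
#' @param entries data frame with `operation_id`, `kind` (`"revenue"` or
#'   `"cost"`), `category` (free text) and `amount_per_ha`.
#' @param operation_id optional single id to compute; default all.
#' @return tibble with `operation_id` and `net_profit_per_ha` (or a single
#'   numeric when `operation_id` is given).
#' @export
#' @examples
#' led <- tibble::tibble(
#'   operation_id = "farm-1", kind = c("revenue", "cost"),
#'   category = c("grain sale", "seed"), amount_per_ha = c(1000, 400)
#' )
#' net_profit(led, "farm-1")  # 600
net_profit <- function(entries, operation_id = NULL) {
  entries <- as_tibble(entries)
  need <- c("operation_id", "kind", "category", "amount_per_ha")
  miss <- setdiff(need, names(entries))
  if (length(miss)) abort_schema(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  if (!is.null(operation_id)) {
    entries <- entries[entries$operation_id %in% operation_id, , drop = FALSE]
  }
  if (nrow(entries) == 0) abort_validation("No ledger entries for the operation")
  bad_kind <- setdiff(unique(entries$kind), c("revenue", "cost"))
  if (length(bad_kind)) {
    abort_validation(paste0("kind must be revenue/cost; got: ",
                            paste(bad_kind, collapse = ", ")))
  }
  if (anyNA(entries$amount_per_ha) || any(entries$amount_per_ha < 0)) {
    abort_validation("Amounts must be nonnegative magnitudes (kind carries the sign)")
  }
  out <- dplyr::summarise(
    entries,
    net_profit_per_ha = sum(.data$amount_per_ha[.data$kind == "revenue"]) -
      sum(.data$amount_per_ha[.data$kind == "cost"]),
    .by = "operation_id"
  )
  if (!is.null(operation_id) && length(operation_id) == 1) {
    return(out$net_profit_per_ha)
  }
  out
}

#' Assemble a classification and validation report
#'
#' Bundles the gap threshold, per-operation labels and the validation table
#' into one serializable report; [write_report()] emits it as JSON.
#'
#' @param threshold a [find_threshold()] result.
#' @param labels labelled score table from [classify_scores()] (with
#'   `operation_id` attached) or `NULL`.
#' @param validation a [run_validation()] table or `NULL`.
#' @return list of class `regen_report`.
#' @export
build_report <- function(threshold, labels = NULL, validation = NULL) {
  if (!inherits(threshold, "gap_threshold")) {
    abort_validation("threshold must be a gap_threshold")
  }
  structure(
    list(
      threshold = threshold[c("gap_low", "gap_high", "midpoint",
                              "dividing_score", "gap_width")],
      labels = if (!is.null(labels)) as.data.frame(labels),
      validation = if (!is.null(validation)) as.data.frame(validation),
      n_models = if (!is.null(validation)) attr(validation, "n_models")
    ),
    class = "regen_report"
  )
}

#' @rdname build_report
#' @param report a `regen_report`.
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "regen_report")) abort_validation("Not a regen_report")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = 6,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Packaged practice-matrix tables
#'
#' The cropland (36 operations: 16 almond orchards, 20 cornfields) and
#' rangeland (52 ranches) practice matrices ship as CSV fixtures with the
#' questionnaire answers, the printed per-item codes, the printed composite
#' score, and an `erratum` flag. Two source rows print a composite that
#' disagrees by one with the sum of their own printed item codes (a
#' regenerative Gary, SD cornfield: codes sum 5, composite 4; a Castlewood,
#' SD ranch: codes sum 3, composite 2). The composite column is corroborated
#' by the published score clusters, so in those two rows the single aberrant
#' item code is corrected (grazers 1 to 0; rotation 1 to 0) and the row is
#' flagged `erratum = TRUE`.
#'
#' @param system `"cropland"` or `"rangeland"`.
#' @return tibble of the packaged table.
#' @export
#' @examples
#' practice_table("rangeland")
practice_table <- function(system = c("cropland", "rangeland")) {
  system <- match.arg(system)
  path <- system.file("extdata", paste0(system, "_practices.csv"),
                      package = "regenscore", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
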