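#' @title Cropland and rangeland practice rubrics
#' @description
#' The cropland matrix codes nine binary practice items: a practice earns 1
#' when it is the regenerative state and 0 when conventional. Eliminating
#' synthetic fertilizers, herbicides, fungicides, insecticides and tillage is
#' regenerative (so *use* codes 0); including cover crops or fostered resident
#' vegetation, diversified field margins/hedgerows, organic amendments and
#' grazing livestock is regenerative (so *use* codes 1). Cornfield surveys
#' asked only six of the nine items (no fungicide, field-margin or
#' organic-amendment question), so the corn composite is out of 6, never
#' imputed. The rangeland matrix codes four ordinal 0-2 items: ivermectin use,
#' stocking density, rotation frequency and post-grazing rest period.
#' @name rubric
NULL

# Item vocabulary ------------------------------------------------------------

cropland_items <- function() {
  c("fertilizers", "herbicides", "fungicides", "insecticides", "tillage",
    "cover_crops", "field_margins", "organic_amendments", "grazers")
}

# items where *eliminating* the practice is regenerative (use => 0)
elimination_items <- function() {
  c("fertilizers", "herbicides", "fungicides", "insecticides", "tillage")
}

corn_items <- function() {
  setdiff(cropland_items(), c("fungicides", "field_margins", "organic_amendments"))
}

rangeland_items <- function() {
  c("ivermectin", "stocking_density", "rotation_frequency", "rest_period")
}

# map item name -> questionnaire column
cropland_answer_fields <- function() {
  c(fertilizers = "synthetic_fertilizer_used",
    herbicides = "herbicide_used",
    fungicides = "fungicide_used",
    insecticides = "insecticide_used",
    tillage = "tillage_used",
    cover_crops = "cover_crop_or_resident_vegetation",
    field_margins = "field_margins_hedgerows",
    organic_amendments = "organic_amendments_used",
    grazers = "livestock_integrated")
}

rangeland_answer_fields <- function() {
  c("ivermectin_applications_per_year", "ivermectin_applied_during_grazing",
    "stocking_density_au_per_ha", "rotation_frequency_days", "rest_period_days")
}

# Item coders ----------------------------------------------------------------

#' Code one binary cropland practice item
#'
#' For the five elimination items (fertilizers, herbicides, fungicides,
#' insecticides, tillage) use codes 0 and non-use codes 1; for the four
#' inclusion items (cover_crops, field_margins, organic_amendments, grazers)
#' use codes 1 and non-use codes 0.
#'
#' @param item one of `"fertilizers"`, `"herbicides"`, `"fungicides"`,
#'   `"insecticides"`, `"tillage"`, `"cover_crops"`, `"field_margins"`,
#'   `"organic_amendments"`, `"grazers"`.
#' @param used logical vector: was the practice used on the operation?
#' @return integer vector of 0/1 codes.
#' @export
#' @examples
#' code_cropland_item("tillage", TRUE)      # tilling is conventional -> 0
#' code_cropland_item("cover_crops", TRUE)  # cover cropping is regenerative -> 1
code_cropland_item <- function(item, used) {
  item <- as.character(item)
  if (length(item) != 1 || !item %in% cropland_items()) {
    abort_validation(paste0("Unknown cropland item: ", paste(item, collapse = ", ")))
  }
  if (length(used) == 0 || anyNA(used)) {
    abort_validation(paste0("Missing answer for cropland item '", item, "'"))
  }
  used <- as.logical(used)
  if (item %in% elimination_items()) as.integer(!used) else as.integer(used)
}

#' Code ivermectin use on a ranch (0-2)
#'
#' No ivermectin codes 2; a single annual application outside the grazing
#' period codes 1 ("low"); multiple applications per year, or any application
#' during the grazing period, codes 0 ("high"). The during-grazing flag
#' dominates: even a single dose applied while cattle graze forfeits the
#' "low" category.
#'
#' @param applications_per_year nonnegative integer vector of annual doses.
#' @param during_grazing logical vector: was any dose applied during the
#'   grazing period?
#' @return integer vector of 0/1/2 codes.
#' @export
#' @examples
#' code_ivermectin(0, FALSE)  # 2
#' code_ivermectin(1, FALSE)  # 1
#' code_ivermectin(3, FALSE)  # 0
code_ivermectin <- function(applications_per_year, during_grazing = FALSE) {
  n <- applications_per_year
  if (anyNA(n) || anyNA(during_grazing)) {
    abort_validation("Missing ivermectin answer")
  }
  if (any(n < 0) || any(n != round(n))) {
    abort_validation("ivermectin applications per year must be a nonnegative integer")
  }
  if (any(during_grazing & n < 1)) {
    abort_validation("ivermectin_applied_during_grazing requires at least one application")
  }
  ifelse(n == 0, 2L, ifelse(n == 1 & !during_grazing, 1L, 0L))
}

#' Code stocking density in animal units per hectare (0-2)
#'
#' Fewer than 5 AU/ha codes 0, 5-10 AU/ha codes 1 (closed bin: both
#' boundaries code 1), more than 10 AU/ha codes 2. Higher densities are the
#' regenerative (adaptive multi-paddock) end of the axis.
#'
#' @param au_per_ha nonnegative numeric vector of stocking densities.
#' @return integer vector of 0/1/2 codes.
#' @export
#' @examples
#' code_stocking_density(c(3, 10, 12))  # 0 1 2
code_stocking_density <- function(au_per_ha) {
  if (anyNA(au_per_ha)) abort_validation("Missing stocking density")
  if (any(au_per_ha < 0)) abort_validation("Stocking density must be nonnegative")
  ifelse(au_per_ha < 5, 0L, ifelse(au_per_ha <= 10, 1L, 2L))
}

#' Code rotation frequency in days (0-2)
#'
#' Rotating every 30 days or more (including never: `Inf`) codes 0; every
#' 10 to <30 days codes 1; more often than every 10 days codes 2.
#'
#' @param days positive numeric vector; `Inf` means never rotated.
#' @return integer vector of 0/1/2 codes.
#' @export
#' @examples
#' code_rotation_frequency(c(45, 14, 3, Inf))  # 0 1 2 0
code_rotation_frequency <- function(days) {
  if (anyNA(days)) abort_validation("Missing rotation frequency")
  if (any(days <= 0)) abort_validation("Rotation frequency must be positive (Inf = never rotated)")
  ifelse(days >= 30, 0L, ifelse(days >= 10, 1L, 2L))
}

#' Code post-grazing rest period in days (0-2)
#'
#' Continuous grazing (0 days of rest) codes 0; a rest of 1-30 days codes 1;
#' more than 30 days codes 2. The 30-day boundary is assigned to code 1
#' (the printed upper bound is strict only for code 2). A fractional rest
#' below one day is coded 1 with a warning, since it is rested but under the
#' stated lower bound.
#'
#' @param days nonnegative numeric vector of rest days over a growing season.
#' @return integer vector of 0/1/2 codes.
#' @export
#' @examples
#' code_rest_period(c(0, 20, 60))  # 0 1 2
code_rest_period <- function(days) {
  if (anyNA(days)) abort_validation("Missing rest period")
  if (any(days < 0)) abort_validation("Rest period must be nonnegative")
  frac <- days > 0 & days < 1
  if (any(frac)) {
    rlang::warn("Rest period between 0 and 1 day coded as 1 (rested, below stated bin)",
                class = "regenscore_boundary_warning")
  }
  ifelse(days == 0, 0L, ifelse(days <= 30, 1L, 2L))
}

# Composite scoring ----------------------------------------------------------

validate_ids <- function(operation_id) {
  if (anyNA(operation_id) || any(trimws(operation_id) == "")) {
    abort_validation("operation_id must be non-missing and non-empty")
  }
  dup <- unique(operation_id[duplicated(operation_id)])
  if (length(dup)) {
    abort_validation(paste0("Duplicate operation_id: ", paste(dup, collapse = ", ")))
  }
  invisible(operation_id)
}

#' Score cropland operations on the nine-item practice matrix
#'
#' Takes one row per operation with boolean practice answers in questionnaire
#' columns (see [cropland_schema()]) and returns per-item 0/1 codes, the
#' composite score (sum over the items asked), and the maximum possible
#' (9 for the full matrix, 6 for the corn subset where fungicides, field
#' margins and organic amendments were not asked). A normalized score
#' (composite / max) is included for cross-system display only; it never
#' drives classification.
#'
#' @param answers data frame with columns `operation_id`, `system`
#'   (`"cropland_full"` or `"cropland_corn"`), and the nine answer columns;
#'   the three unasked columns must be `NA` (or absent) on corn rows and
#'   answered on full rows.
#' @return tibble with `operation_id`, `system`, `code_*` columns (NA where
#'   the item was not asked), `n_items_asked`, `composite_score`,
#'   `max_possible`, `score_normalized`.
#' @seealso [score_rangeland()], [code_cropland_item()]
#' @export
#' @examples
#' answers <- tibble::tibble(
#'   operation_id = "orchard-1", system = "cropland_full",
#'   synthetic_fertilizer_used = FALSE, herbicide_used = FALSE,
#'   fungicide_used = FALSE, insecticide_used = FALSE, tillage_used = TRUE,
#'   cover_crop_or_resident_vegetation = TRUE, field_margins_hedgerows = TRUE,
#'   organic_amendments_used = TRUE, livestock_integrated = FALSE
#' )
#' score_cropland(answers)
score_cropland <- function(answers) {
  answers <- as_tibble(answers)
  need <- c("operation_id", "system")
  miss <- setdiff(need, names(answers))
  if (length(miss)) abort_schema(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(answers) == 0) abort_validation("Empty input: no operations to score")
  validate_ids(answers$operation_id)
  bad_sys <- setdiff(unique(answers$system), c("cropland_full", "cropland_corn"))
  if (length(bad_sys)) {
    abort_validation(paste0("Unknown cropland system: ", paste(bad_sys, collapse = ", ")))
  }

  fields <- cropland_answer_fields()
  # absent answer columns are treated as all-NA (legal only if never asked)
  for (f in fields) if (!f %in% names(answers)) answers[[f]] <- NA

  items <- cropland_items()
  codes <- matrix(NA_integer_, nrow(answers), length(items),
                  dimnames = list(NULL, items))
  for (i in seq_len(nrow(answers))) {
    asked <- if (answers$system[i] == "cropland_corn") corn_items() else items
    for (it in items) {
      ans <- parse_answer(answers[[fields[[it]]]][i])
      if (it %in% asked) {
        if (is.na(ans)) {
          abort_validation(paste0("Operation '", answers$operation_id[i],
                                  "': missing answer for asked item '", it, "'"))
        }
        codes[i, it] <- code_cropland_item(it, ans)
      } else if (!is.na(ans)) {
        abort_validation(paste0("Operation '", answers$operation_id[i],
                                "': item '", it, "' is not asked for system '",
                                answers$system[i], "' but has an answer"))
      }
    }
  }

  out <- tibble(operation_id = answers$operation_id, system = answers$system)
  for (it in items) out[[paste0("code_", it)]] <- codes[, it]
  out$n_items_asked <- as.integer(rowSums(!is.na(codes)))
  out$composite_score <- as.integer(rowSums(codes, na.rm = TRUE))
  out$max_possible <- ifelse(out$system == "cropland_corn", 6L, 9L)
  out$score_normalized <- out$composite_score / out$max_possible
  out
}

#' Score rangeland operations on the four-item ordinal matrix
#'
#' Codes ivermectin use, stocking density, rotation frequency and rest period
#' on 0-2 scales from natural-unit answers and sums them into a composite out
#' of 8.
#'
#' @param answers data frame with columns `operation_id`,
#'   `ivermectin_applications_per_year`, `ivermectin_applied_during_grazing`,
#'   `stocking_density_au_per_ha`, `rotation_frequency_days`,
#'   `rest_period_days`.
#' @return tibble with per-item `code_*` columns, `n_items_asked`,
#'   `composite_score`, `max_possible` (8) and `score_normalized`.
#' @seealso [score_cropland()]
#' @export
#' @examples
#' score_rangeland(tibble::tibble(
#'   operation_id = "ranch-1",
#'   ivermectin_applications_per_year = 0,
#'   ivermectin_applied_during_grazing = FALSE,
#'   stocking_density_au_per_ha = 12,
#'   rotation_frequency_days = 7,
#'   rest_period_days = 60
#' ))
score_rangeland <- function(answers) {
  answers <- as_tibble(answers)
  need <- c("operation_id", rangeland_answer_fields())
  miss <- setdiff(need, names(answers))
  if (length(miss)) abort_schema(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(answers) == 0) abort_validation("Empty input: no operations to score")
  validate_ids(answers$operation_id)

  out <- tibble(
    operation_id = answers$operation_id,
    system = "rangeland",
    code_ivermectin = code_ivermectin(
      answers$ivermectin_applications_per_year,
      parse_answer(answers$ivermectin_applied_during_grazing)
    ),
    code_stocking_density = code_stocking_density(answers$stocking_density_au_per_ha),
    code_rotation_frequency = code_rotation_frequency(answers$rotation_frequency_days),
    code_rest_period = code_rest_period(answers$rest_period_days)
  )
  code_cols <- paste0("code_", rangeland_items())
  out$n_items_asked <- 4L
  out$composite_score <- as.integer(rowSums(out[code_cols]))
  out$max_possible <- 8L
  out$score_normalized <- out$composite_score / out$max_possible
  out
}

#' Composite regenerative score for a profile table
#'
#' Dispatches on the columns present: rangeland questionnaire columns go to
#' [score_rangeland()], otherwise [score_cropland()].
#'
#' @param answers data frame of questionnaire answers, one row per operation.
#' @return score record tibble (see [score_cropland()]).
#' @export
composite_score <- function(answers) {
  if (all(rangeland_answer_fields() %in% names(answers))) {
    score_rangeland(answers)
  } else {
    score_cropland(answers)
  }
}
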