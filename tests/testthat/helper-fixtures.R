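# shared helpers: tiny hand-built tables used across test files

cropland_code_cols <- paste0(
  "code_", c("fertilizers", "herbicides", "fungicides", "insecticides",
             "tillage", "cover_crops", "field_margins", "organic_amendments",
             "grazers"))

rangeland_code_cols <- paste0(
  "code_", c("ivermectin", "stocking_density", "rotation_frequency",
             "rest_period"))

# a fully regenerative full-matrix answer row
regen_cropland_row <- function(operation_id = "op1") {
  tibble::tibble(
    operation_id = operation_id, system = "cropland_full",
    synthetic_fertilizer_used = FALSE, herbicide_used = FALSE,
    fungicide_used = FALSE, insecticide_used = FALSE, tillage_used = FALSE,
    cover_crop_or_resident_vegetation = TRUE, field_margins_hedgerows = TRUE,
    organic_amendments_used = TRUE, livestock_integrated = TRUE
  )
}

# outcome table for hand-checked regression cases: one row per operation
hand_outcomes <- function(score, value, outcome = "y", clay = NULL) {
  tibble::tibble(
    operation_id = sprintf("op%02d", seq_along(score)),
    field_or_plot_id = "f1", month = NA_character_,
    score = score, outcome_name = outcome, outcome_value = value,
    clay_pct = if (is.null(clay)) NA_real_ else clay
  )
}

# outcome table with exactly zero within-sample farm variance: residuals are
# centred within farm so the REML farm-variance estimate is 0 by construction
zero_farm_variance_outcomes <- function(n_farms = 30, n_fields = 4,
                                        slope = 1.5, sigma = 3) {
  score <- sample(0:9, n_farms, replace = TRUE)
  e <- matrix(rnorm(n_farms * n_fields, 0, sigma), n_farms)
  e <- e - rowMeans(e)
  score_row <- rep(score, each = n_fields)
  value_row <- rep(10 + slope * score, each = n_fields) + as.vector(t(e))
  tibble::tibble(
    operation_id = rep(sprintf("op%02d", 1:n_farms), each = n_fields),
    field_or_plot_id = rep(sprintf("f%d", 1:n_fields), n_farms),
    month = NA_character_,
    score = score_row,
    outcome_name = "y",
    outcome_value = value_row,
    clay_pct = NA_real_
  )
}
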