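test_that("binary cropland items code use/non-use by item direction", {
  # elimination items: use is conventional (0)
  for (it in c("fertilizers", "herbicides", "fungicides", "insecticides", "tillage")) {
    expect_identical(code_cropland_item(it, TRUE), 0L)
    expect_identical(code_cropland_item(it, FALSE), 1L)
  }
  # inclusion items: use is regenerative (1)
  for (it in c("cover_crops", "field_margins", "organic_amendments", "grazers")) {
    expect_identical(code_cropland_item(it, TRUE), 1L)
    expect_identical(code_cropland_item(it, FALSE), 0L)
  }
  expect_error(code_cropland_item("mulching", TRUE), class = "regenscore_validation_error")
  expect_error(code_cropland_item("tillage", NA), class = "regenscore_validation_error")
})

test_that("ordinal rangeland coders reproduce every stated mapping and boundary", {
  cases <- list(
    # fn, input list, expected
    list(code_ivermectin, list(0, FALSE), 2L),
    list(code_ivermectin, list(1, FALSE), 1L),
    list(code_ivermectin, list(2, FALSE), 0L),
    list(code_ivermectin, list(3, FALSE), 0L),
    list(code_ivermectin, list(1, TRUE), 0L),   # during-grazing dominates
    list(code_stocking_density, list(3), 0L),
    list(code_stocking_density, list(4.99), 0L),
    list(code_stocking_density, list(5), 1L),   # closed middle bin
    list(code_stocking_density, list(10), 1L),
    list(code_stocking_density, list(10.01), 2L),
    list(code_stocking_density, list(12), 2L),
    list(code_rotation_frequency, list(45), 0L),
    list(code_rotation_frequency, list(Inf), 0L),
    list(code_rotation_frequency, list(30), 0L),  # "30 d or more"
    list(code_rotation_frequency, list(29.9), 1L),
    list(code_rotation_frequency, list(14), 1L),
    list(code_rotation_frequency, list(10), 1L),
    list(code_rotation_frequency, list(9.9), 2L),
    list(code_rotation_frequency, list(3), 2L),
    list(code_rest_period, list(0), 0L),
    list(code_rest_period, list(1), 1L),
    list(code_rest_period, list(20), 1L),
    list(code_rest_period, list(30), 1L),  # boundary assigned to the middle bin
    list(code_rest_period, list(31), 2L),
    list(code_rest_period, list(60), 2L)
  )
  for (cs in cases) {
    expect_identical(do.call(cs[[1]], cs[[2]]), cs[[3]])
  }
  expect_error(code_ivermectin(-1, FALSE), class = "regenscore_validation_error")
  expect_error(code_ivermectin(0, TRUE), class = "regenscore_validation_error")
  expect_error(code_stocking_density(-2), class = "regenscore_validation_error")
  expect_error(code_rotation_frequency(0), class = "regenscore_validation_error")
  expect_error(code_rest_period(-1), class = "regenscore_validation_error")
  expect_warning(expect_identical(code_rest_period(0.5), 1L),
                 class = "regenscore_boundary_warning")
})

test_that("scoring the packaged tables reproduces every printed code and composite", {
  crop <- practice_table("cropland")
  sc <- score_cropland(crop)
  expect_identical(sc$composite_score, as.integer(crop$composite_printed))
  for (cn in cropland_code_cols) {
    expect_identical(is.na(sc[[cn]]), is.na(crop[[cn]]))
    expect_equal(sc[[cn]][!is.na(sc[[cn]])], crop[[cn]][!is.na(crop[[cn]])],
                 ignore_attr = TRUE)
  }
  expect_identical(unique(sc$max_possible[sc$system == "cropland_full"]), 9L)
  expect_identical(unique(sc$max_possible[sc$system == "cropland_corn"]), 6L)
  expect_identical(unique(sc$n_items_asked[sc$system == "cropland_corn"]), 6L)

  rng <- practice_table("rangeland")
  sr <- score_rangeland(rng)
  expect_identical(sr$composite_score, as.integer(rng$composite_printed))
  for (cn in rangeland_code_cols) {
    expect_equal(sr[[cn]], rng[[cn]], ignore_attr = TRUE)
  }
  expect_identical(unique(sr$max_possible), 8L)
})

test_that("composite equals the sum of asked item codes and respects bounds", {
  crop <- practice_table("cropland")
  sc <- score_cropland(crop)
  resummed <- rowSums(as.matrix(sc[cropland_code_cols]), na.rm = TRUE)
  expect_equal(sc$composite_score, as.integer(resummed), ignore_attr = TRUE)
  expect_true(all(sc$composite_score >= 0 & sc$composite_score <= sc$max_possible))

  # all-regenerative profile attains the maximum; all-conventional scores 0
  full <- regen_cropland_row()
  expect_identical(score_cropland(full)$composite_score, 9L)
  conv <- full
  conv[unname(regenscore:::cropland_answer_fields())] <-
    as.list(!unlist(conv[unname(regenscore:::cropland_answer_fields())]))
  expect_identical(score_cropland(conv)$composite_score, 0L)
})

test_that("flipping one item to its regenerative state raises the composite by exactly 1", {
  set.seed(301)
  fields <- regenscore:::cropland_answer_fields()
  elim <- regenscore:::elimination_items()
  for (rep in 1:20) {
    row <- regen_cropland_row()
    row[unname(fields)] <- as.list(runif(9) < 0.5)
    base <- score_cropland(row)$composite_score
    for (it in names(fields)) {
      regen_answer <- !(it %in% elim)  # answer that earns the point
      if (identical(row[[fields[[it]]]], regen_answer)) next
      flipped <- row
      flipped[[fields[[it]]]] <- regen_answer
      expect_identical(score_cropland(flipped)$composite_score, base + 1L)
    }
  }
  # rangeland: raising any item one level adds exactly 1
  units <- list(
    ivermectin_applications_per_year = c(3, 1, 0),
    stocking_density_au_per_ha = c(3, 7.5, 12),
    rotation_frequency_days = c(45, 20, 7),
    rest_period_days = c(0, 20, 60)
  )
  base_row <- tibble::tibble(
    operation_id = "r1", ivermectin_applications_per_year = 3,
    ivermectin_applied_during_grazing = FALSE,
    stocking_density_au_per_ha = 3, rotation_frequency_days = 45,
    rest_period_days = 0
  )
  for (col in names(units)) {
    for (lev in 1:2) {
      row <- base_row
      row[[col]] <- units[[col]][lev + 1]
      expect_identical(score_rangeland(row)$composite_score, as.integer(lev))
    }
  }
})

test_that("composite is invariant to row and column order", {
  crop <- practice_table("cropland")
  shuffled <- crop[sample(nrow(crop)), sample(ncol(crop))]
  sc <- score_cropland(shuffled)
  sc <- sc[match(crop$operation_id, sc$operation_id), ]
  expect_equal(sc$composite_score, as.integer(crop$composite_printed),
               ignore_attr = TRUE)
})

test_that("corn rows never answer the three unasked items and are scored out of 6", {
  row <- tibble::tibble(
    operation_id = "corn1", system = "cropland_corn",
    synthetic_fertilizer_used = FALSE, herbicide_used = TRUE,
    fungicide_used = NA, insecticide_used = FALSE, tillage_used = FALSE,
    cover_crop_or_resident_vegetation = TRUE, field_margins_hedgerows = NA,
    organic_amendments_used = NA, livestock_integrated = TRUE
  )
  sc <- score_cropland(row)
  expect_identical(sc$composite_score, 5L)
  expect_identical(sc$max_possible, 6L)
  expect_true(is.na(sc$code_fungicides))
  expect_equal(sc$score_normalized, 5 / 6)

  # an answer on an unasked item is a contract violation, never silently used
  bad <- row
  bad$fungicide_used <- TRUE
  expect_error(score_cropland(bad), class = "regenscore_validation_error")
  # a missing answer on an asked item fails validation
  bad2 <- row
  bad2$tillage_used <- NA
  expect_error(score_cropland(bad2), class = "regenscore_validation_error")
})
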