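test_that("least-squares fits recover hand-computed slopes", {
  # perfect line: slope 2, zero residual
  perfect <- hand_outcomes(0:4, 2 * (0:4) + 1)
  fit <- suppressWarnings(fit_score_regression(perfect, "y"))  # zero-residual fit
  sl <- fit$terms[fit$terms$term == "score", ]
  expect_equal(sl$estimate, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # normal-equations value Sxy/Sxx = 8/10 on the 5-point set
  hand <- hand_outcomes(0:4, c(1, 3, 2, 5, 4))
  fit2 <- fit_score_regression(hand, "y")
  sl2 <- fit2$terms[fit2$terms$term == "score", ]
  expect_equal(sl2$estimate, 0.8, tolerance = 1e-12)
  expect_identical(fit2$df_num, 1L)
  expect_identical(fit2$df_den, 3L)  # n - k - 1 = 5 - 2

  # closed form Sxy/Sxx matches the matrix solution on random inputs
  set.seed(55)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    s <- sample(0:9, n, replace = TRUE)
    if (length(unique(s)) < 2) s[1] <- s[1] + 1
    y <- rnorm(n)
    f <- fit_score_regression(hand_outcomes(s, y), "y")
    est <- f$terms$estimate[f$terms$term == "score"]
    expect_equal(est, sum((s - mean(s)) * (y - mean(y))) / sum((s - mean(s))^2),
                 tolerance = 1e-9)
  }

  expect_error(fit_score_regression(hand_outcomes(rep(3, 5), rnorm(5)), "y"),
               class = "regenscore_singular_design_error")
  expect_error(fit_score_regression(hand_outcomes(0:1, c(1, 2)), "y"),
               class = "regenscore_insufficient_data_error")
  expect_error(fit_score_regression(hand, "nope"),
               class = "regenscore_insufficient_data_error")
})

test_that("ols results are invariant to row permutation and score centering", {
  set.seed(66)
  s <- sample(0:9, 24, replace = TRUE)
  y <- 1.2 * s + rnorm(24)
  tab <- hand_outcomes(s, y)
  f1 <- fit_score_regression(tab, "y")
  f2 <- fit_score_regression(tab[sample(nrow(tab)), ], "y")
  expect_equal(f1$terms$estimate, f2$terms$estimate, tolerance = 1e-12)
  centered <- tab
  centered$score <- centered$score - 5
  f3 <- fit_score_regression(centered, "y")
  expect_equal(f3$terms$estimate[f3$terms$term == "score"],
               f1$terms$estimate[f1$terms$term == "score"], tolerance = 1e-12)
})

test_that("replicates are composited per operation before ols", {
  tab <- tibble::tibble(
    operation_id = rep(c("a", "b", "c"), each = 2),
    field_or_plot_id = rep(c("f1", "f2"), 3), month = NA_character_,
    score = rep(c(0, 1, 2), each = 2), outcome_name = "y",
    outcome_value = c(1, 3, 4, 6, 7, 9), clay_pct = NA_real_
  )
  f <- suppressWarnings(fit_score_regression(tab, "y"))
  expect_identical(f$n, 3L)  # three operations, not six rows
  sl <- f$terms$estimate[f$terms$term == "score"]
  expect_equal(sl, 3, tolerance = 1e-12)  # means 2, 5, 8 on scores 0,1,2
})

test_that("the clay covariate enters additively and is demanded when requested", {
  set.seed(10)
  s <- rep(0:9, each = 2)
  clay <- runif(20, 10, 40)
  y <- 5 + 2 * s + 0.5 * clay  # exact plane
  tab <- hand_outcomes(s, y, clay = clay)
  f <- suppressWarnings(fit_score_regression(tab, "y", include_clay = TRUE))
  expect_equal(f$terms$estimate[f$terms$term == "score"], 2, tolerance = 1e-8)
  expect_equal(f$terms$estimate[f$terms$term == "clay_pct"], 0.5, tolerance = 1e-8)
  tab$clay_pct[3] <- NA
  expect_error(fit_score_regression(tab, "y", include_clay = TRUE),
               class = "regenscore_validation_error")
})

test_that("mixed model collapses to ols when the farm variance is zero", {
  set.seed(99)
  tab <- zero_farm_variance_outcomes()
  lmm <- fit_mixed_model(tab, "y", random = "farm")
  ols <- fit_score_regression(tab, "y", composite_replicates = FALSE)
  expect_equal(lmm$terms$estimate[lmm$terms$term == "score"],
               ols$terms$estimate[ols$terms$term == "score"], tolerance = 1e-6)
  expect_match(lmm$note, "ols")
})

test_that("mixed model recovers a known farm-level slope", {
  cfg <- sim_config(
    n_operations = 40, seed = 7,
    effects = list(y = list(intercept = 10, slope = 1.5, clay_slope = 0,
                            farm_sd = 2, residual_sd = 3, sd_inflation = 0))
  )
  tab <- generate_outcomes(generate_profiles(cfg), cfg)
  lmm <- fit_mixed_model(tab, "y", random = "farm")
  sl <- lmm$terms[lmm$terms$term == "score", ]
  expect_lt(abs(sl$estimate - 1.5), 2 * sl$std_error)
  expect_identical(lmm$model_kind, "lmm")
  expect_lt(sl$p_value, 0.05)

  # grouping column absent -> schema error
  expect_error(
    fit_mixed_model(tab[setdiff(names(tab), "field_or_plot_id")], "y",
                    random = "farm_field"),
    class = "regenscore_schema_error"
  )
  # one observation per farm: variance inestimable, falls back to ols
  single <- tab[!duplicated(tab$operation_id) & tab$outcome_name == "y", ]
  expect_warning(
    f <- fit_mixed_model(single, "y", random = "farm"),
    class = "regenscore_inestimable_variance_warning"
  )
  expect_identical(f$model_kind, "ols")
})

test_that("variability trend recovers hand CVs and degenerate cases", {
  # three levels, two operations each, CVs 0.1, 0.2, 0.3 exactly
  mk_level <- function(score, mean, cv, ids) {
    # two points mean +/- d have sd = d*sqrt(2); pick d for the target cv
    d <- cv * mean / sqrt(2)
    hand_outcomes(rep(score, 2), c(mean - d, mean + d))[1:2, ] |>
      dplyr::mutate(operation_id = ids)
  }
  tab <- dplyr::bind_rows(
    mk_level(0, 10, 0.1, c("a1", "a2")),
    mk_level(1, 10, 0.2, c("b1", "b2")),
    mk_level(2, 10, 0.3, c("c1", "c2"))
  )
  f <- suppressWarnings(variability_trend(tab, "y"))
  sl <- f$terms[f$terms$term == "score", ]
  expect_equal(sl$estimate, 0.1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_identical(f$df_num, 1L)
  expect_identical(f$df_den, 1L)  # levels - 2

  # a flat CV profile has slope 0
  flat <- dplyr::bind_rows(
    mk_level(0, 10, 0.2, c("a1", "a2")),
    mk_level(1, 20, 0.2, c("b1", "b2")),
    mk_level(2, 40, 0.2, c("c1", "c2"))
  )
  ffl <- suppressWarnings(variability_trend(flat, "y"))
  expect_equal(ffl$terms$estimate[ffl$terms$term == "score"], 0, tolerance = 1e-10)

  two <- dplyr::bind_rows(mk_level(0, 10, 0.1, c("a1", "a2")),
                          mk_level(1, 10, 0.2, c("b1", "b2")))
  expect_error(variability_trend(two, "y"),
               class = "regenscore_insufficient_data_error")
  zero <- dplyr::bind_rows(
    mk_level(0, 10, 0.1, c("a1", "a2")),
    hand_outcomes(c(1, 1), c(-1, 1)) |> dplyr::mutate(operation_id = c("b1", "b2")),
    mk_level(2, 10, 0.3, c("c1", "c2"))
  )
  expect_error(variability_trend(zero, "y"), class = "regenscore_undefined_cv_error")
})

test_that("run_validation drives the batch and captures per-entry failures", {
  expect_identical(nrow(run_validation(hand_outcomes(0:4, 1:5), list())), 0L)

  tab <- dplyr::bind_rows(
    hand_outcomes(0:9, 2 * (0:9) + rnorm(10, 0, 1e-8), outcome = "up"),
    hand_outcomes(0:9, rep(5, 10), outcome = "flat")
  )
  res <- suppressWarnings(run_validation(tab, list(
    list(outcome_name = "up", model_kind = "ols"),
    list(outcome_name = "flat", model_kind = "ols"),
    list(outcome_name = "absent", model_kind = "ols")
  )))
  expect_identical(res$sign, c("positive", "ns", NA_character_))
  expect_false(is.na(res$error[3]))
  expect_lt(res$p_value[1], 1e-6)
  expect_identical(attr(res, "n_models"), 3L)

  # scores can be joined from a score-record table
  scores <- tibble::tibble(operation_id = sprintf("op%02d", 1:10),
                           composite_score = 0:9)
  noscore <- hand_outcomes(0:9, 3 * (0:9), outcome = "up")
  noscore$score <- NULL
  res2 <- suppressWarnings(
    run_validation(noscore, list(list(outcome_name = "up")), scores = scores))
  expect_equal(res2$estimate, 3, tolerance = 1e-10)
})
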