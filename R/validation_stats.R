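#' @title Score-versus-outcome validation models
#' @description
#' The validation surface regresses each response variable on the composite
#' regenerative score: ordinary least squares on per-operation values (with
#' soil clay percent as a covariate for carbon-related outcomes), linear
#' mixed models with farm (and field-within-farm) random intercepts where an
#' operation was resampled, and a coefficient-of-variation trend that asks
#' whether the standard deviation becomes a greater proportion of the mean as
#' scores rise. Mixed models use restricted maximum likelihood; p-values use
#' the containment degrees-of-freedom convention (operation-level terms are
#' tested against the number of operations, within-operation terms against
#' the residual observations), a choice that can shift small p-values
#' relative to other software.
#' @name validation_stats
NULL

new_regen_fit <- function(outcome_name, model_kind, terms, f_stat, df_num,
                          df_den, model_p, r_squared, n, note = NA_character_) {
  structure(
    list(outcome_name = outcome_name, model_kind = model_kind, terms = terms,
         f_stat = f_stat, df_num = df_num, df_den = df_den, model_p = model_p,
         r_squared = r_squared, n = n, note = note),
    class = "regen_fit"
  )
}

#' @export
print.regen_fit <- function(x, ...) {
  cat(x$model_kind, " fit of '", x$outcome_name, "' on score (n = ", x$n, ")\n",
      sep = "")
  print(as.data.frame(x$terms), digits = 4, row.names = FALSE)
  cat(sprintf("F(%d, %d) = %.4g, P = %.4g, R^2 = %.4g\n",
              x$df_num, x$df_den, x$f_stat, x$model_p, x$r_squared))
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

validate_outcomes <- function(outcomes, outcome_name, need_clay = FALSE,
                              need_month = FALSE, need_field = FALSE) {
  outcomes <- as_tibble(outcomes)
  need <- c("operation_id", "score", "outcome_name", "outcome_value")
  if (need_clay) need <- c(need, "clay_pct")
  if (need_month) need <- c(need, "month")
  if (need_field) need <- c(need, "field_or_plot_id")
  miss <- setdiff(need, names(outcomes))
  if (length(miss)) abort_schema(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  out <- outcomes[outcomes$outcome_name == outcome_name, , drop = FALSE]
  if (nrow(out) == 0) {
    abort_insufficient(paste0("No rows for outcome '", outcome_name, "'"))
  }
  if (anyNA(out$outcome_value)) {
    abort_validation(paste0("Missing outcome_value rows for '", outcome_name, "'"))
  }
  score_per_op <- tapply(out$score, out$operation_id, function(s) length(unique(s)))
  if (any(score_per_op > 1)) {
    abort_validation("score must be constant within operation_id")
  }
  if (need_clay && anyNA(out$clay_pct)) {
    abort_validation("clay_pct required on every row when include_clay = TRUE")
  }
  out
}

# Collapse replicate rows to one value per operation (scores and clay are
# operation-level, so their first value is kept).
composite_per_operation <- function(out, has_clay) {
  grp <- dplyr::summarise(
    out,
    score = .data$score[1],
    outcome_value = mean(.data$outcome_value),
    clay_pct = if (has_clay) mean(.data$clay_pct) else NA_real_,
    .by = "operation_id"
  )
  grp
}

terms_from_lm <- function(fit) {
  cf <- summary(fit)$coefficients
  tibble(
    term = rownames(cf),
    estimate = unname(cf[, 1]), std_error = unname(cf[, 2]),
    statistic = unname(cf[, 3]), df = fit$df.residual,
    p_value = unname(cf[, 4])
  )
}

#' Ordinary least squares of an outcome on the regenerative score
#'
#' Fits `outcome ~ score` (optionally `+ clay_pct`) by least squares.
#' Replicate rows are averaged to one value per operation first (the default,
#' matching how replicate plots are composited into single farm values);
#' `composite_replicates = FALSE` fits the raw rows.
#'
#' @param outcomes long-format outcome table with columns `operation_id`,
#'   `score`, `outcome_name`, `outcome_value` and, when `include_clay`,
#'   `clay_pct`.
#' @param outcome_name which outcome to fit.
#' @param include_clay add soil clay percent as a covariate (used for
#'   carbon-related outcomes).
#' @param composite_replicates average replicates per operation before
#'   fitting (default `TRUE`).
#' @return a `regen_fit`: term table (estimate, SE, t, p), overall F with
#'   (k, n-k-1) degrees of freedom, model p, R-squared, n.
#' @export
fit_score_regression <- function(outcomes, outcome_name, include_clay = FALSE,
                                 composite_replicates = TRUE) {
  out <- validate_outcomes(outcomes, outcome_name, need_clay = include_clay)
  dat <- if (composite_replicates) {
    composite_per_operation(out, include_clay)
  } else {
    out
  }
  if (nrow(dat) < 3) {
    abort_insufficient(paste0("Need at least 3 observations to fit '",
                              outcome_name, "'; got ", nrow(dat)))
  }
  if (length(unique(dat$score)) < 2) {
    rlang::abort("score is constant: singular design",
                 class = c("regenscore_singular_design_error", "regenscore_error"))
  }
  form <- if (include_clay) outcome_value ~ score + clay_pct else outcome_value ~ score
  fit <- lm(form, data = dat)
  sm <- summary(fit)
  fst <- sm$fstatistic
  new_regen_fit(
    outcome_name, "ols", terms_from_lm(fit),
    f_stat = unname(fst[1]), df_num = as.integer(fst[2]),
    df_den = as.integer(fst[3]),
    model_p = unname(pf(fst[1], fst[2], fst[3], lower.tail = FALSE)),
    r_squared = sm$r.squared, n = nrow(dat)
  )
}

#' Linear mixed model of an outcome on the regenerative score
#'
#' Fits a random-intercept model for resampled designs: farm (operation) as a
#' random factor, optionally field nested within farm (the corn design) and
#' month as a fixed factor (the rangeland design). Estimation is restricted
#' maximum likelihood via [lme4::lmer()]. When a random variance is estimated
#' at zero the fixed-effect estimates coincide with ordinary least squares;
#' when the grouping is inestimable (one observation per group) the model
#' falls back to least squares with a warning.
#'
#' The reported p-values use containment degrees of freedom: the score (an
#' operation-level covariate) is tested on `n_operations - p_between` df,
#' month contrasts on residual within-operation df.
#'
#' @inheritParams fit_score_regression
#' @param include_month add month as a fixed factor (requires a `month`
#'   column).
#' @param random `"farm"` for a farm random intercept or `"farm_field"` to
#'   add field nested within farm (requires `field_or_plot_id`).
#' @return a `regen_fit` with `model_kind = "lmm"` (or `"ols"` after
#'   fallback). `r_squared` is the squared correlation between fitted and
#'   observed values.
#' @export
fit_mixed_model <- function(outcomes, outcome_name, include_month = FALSE,
                            random = c("farm", "farm_field"),
                            include_clay = FALSE) {
  random <- match.arg(random)
  out <- validate_outcomes(outcomes, outcome_name, need_clay = include_clay,
                           need_month = include_month,
                           need_field = random == "farm_field")
  n_ops <- length(unique(out$operation_id))
  if (n_ops < 2) abort_insufficient("Need at least 2 operations for a mixed model")
  if (length(unique(out$score)) < 2) {
    rlang::abort("score is constant: singular design",
                 class = c("regenscore_singular_design_error", "regenscore_error"))
  }
  if (include_month) out$month <- factor(out$month)

  fixed <- "outcome_value ~ score"
  if (include_clay) fixed <- paste(fixed, "+ clay_pct")
  if (include_month) fixed <- paste(fixed, "+ month")
  rand <- "(1 | operation_id)"
  if (random == "farm_field") {
    rand <- paste(rand, "+ (1 | operation_id:field_or_plot_id)")
  }
  form <- stats::as.formula(paste(fixed, "+", rand))

  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = out, REML = TRUE,
                                control = lme4::lmerControl(check.conv.singular = "ignore"))),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    rlang::warn(paste0("Mixed model inestimable (", conditionMessage(fit),
                       "); falling back to least squares"),
                class = "regenscore_inestimable_variance_warning")
    res <- fit_score_regression(outcomes, outcome_name,
                                include_clay = include_clay,
                                composite_replicates = FALSE)
    res$note <- "lmm fallback to ols"
    return(res)
  }

  cf <- coef(summary(fit))
  n_obs <- nrow(out)
  # containment df: operation-level terms vs operations, within terms vs residual
  between_terms <- intersect(rownames(cf), c("(Intercept)", "score", "clay_pct"))
  p_between <- length(between_terms)
  df_between <- max(n_ops - p_between, 1)
  df_within <- max(n_obs - n_ops - (nrow(cf) - p_between), 1)
  dfs <- ifelse(rownames(cf) %in% between_terms, df_between, df_within)
  terms <- tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]), std_error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "t value"]), df = unname(dfs),
    p_value = unname(2 * pt(abs(cf[, "t value"]), dfs, lower.tail = FALSE))
  )
  t_score <- terms$statistic[terms$term == "score"]
  df_score <- terms$df[terms$term == "score"]
  fitted_r2 <- stats::cor(stats::fitted(fit), out$outcome_value)^2
  new_regen_fit(
    outcome_name, "lmm", terms,
    f_stat = t_score^2, df_num = 1L, df_den = as.integer(df_score),
    model_p = unname(pf(t_score^2, 1, df_score, lower.tail = FALSE)),
    r_squared = fitted_r2, n = n_obs,
    note = if (lme4::isSingular(fit)) "a random variance estimated at 0 (fixed effects = ols)" else NA_character_
  )
}

#' Trend in outcome variability across score levels
#'
#' Computes the coefficient of variation (standard deviation over mean) of an
#' outcome across operations within each integer score level, then regresses
#' that ratio on score. A positive slope means outcomes grow relatively more
#' variable as operations become more regenerative. Levels represented by a
#' single operation carry no dispersion information and are dropped; at least
#' three usable levels are required.
#'
#' @inheritParams fit_score_regression
#' @return a `regen_fit` with `model_kind = "cv_trend"`; the slope term is the
#'   change in CV per score point, with `df_num = 1`,
#'   `df_den = usable levels - 2`.
#' @export
variability_trend <- function(outcomes, outcome_name) {
  out <- validate_outcomes(outcomes, outcome_name)
  per_op <- composite_per_operation(out, has_clay = FALSE)
  lev <- dplyr::summarise(
    per_op,
    n_ops = dplyr::n(),
    mean_value = mean(.data$outcome_value),
    sd_value = sd(.data$outcome_value),
    .by = "score"
  )
  lev <- lev[lev$n_ops >= 2, , drop = FALSE]
  if (nrow(lev) < 3) {
    abort_insufficient(paste0("Need >= 3 score levels with >= 2 operations; got ",
                              nrow(lev)))
  }
  if (any(lev$mean_value == 0)) {
    rlang::abort("A score level has mean 0: coefficient of variation undefined",
                 class = c("regenscore_undefined_cv_error", "regenscore_error"))
  }
  lev$cv <- lev$sd_value / lev$mean_value
  fit <- lm(cv ~ score, data = lev)
  sm <- summary(fit)
  fst <- sm$fstatistic
  new_regen_fit(
    outcome_name, "cv_trend", terms_from_lm(fit),
    f_stat = unname(fst[1]), df_num = as.integer(fst[2]),
    df_den = as.integer(fst[3]),
    model_p = unname(pf(fst[1], fst[2], fst[3], lower.tail = FALSE)),
    r_squared = sm$r.squared, n = nrow(lev)
  )
}

slope_of <- function(fit) {
  i <- match("score", fit$terms$term)
  fit$terms[i, , drop = FALSE]
}

#' Run a batch of score-versus-outcome validation models
#'
#' Applies a list of model specifications to an outcome table and collects
#' the score slope, test statistics and a sign call (positive / negative at
#' two-sided alpha = 0.05, else `ns`) per outcome. Failures are captured per
#' entry and never abort the batch. No multiple-testing correction is
#' applied; the number of models fitted is attached so readers can apply
#' their own.
#'
#' @param outcomes long-format outcome table (see [fit_score_regression()]);
#'   if it lacks a `score` column, supply `scores`.
#' @param models list of specs, each a list with `outcome_name`, `model_kind`
#'   (`"ols"`, `"lmm"` or `"cv_trend"`), and optional `include_clay`,
#'   `include_month`, `random`.
#' @param scores optional score-record table (from [score_cropland()] /
#'   [score_rangeland()]) joined onto `outcomes` by `operation_id`.
#' @param alpha two-sided significance level for the sign call (default 0.05).
#' @return tibble with one row per spec: slope estimate, SE, statistic,
#'   p-value, F, dfs, R-squared, n, `sign`, and `error` (NA when the fit
#'   succeeded). Attribute `n_models` holds the number of entries fitted.
#' @export
run_validation <- function(outcomes, models, scores = NULL, alpha = 0.05) {
  outcomes <- as_tibble(outcomes)
  if (!is.null(scores)) {
    sc <- as_tibble(scores)[, c("operation_id", "composite_score")]
    names(sc)[2] <- "score"
    outcomes$score <- NULL
    outcomes <- dplyr::left_join(outcomes, sc, by = "operation_id")
  }
  rows <- purrr::map(models, function(m) {
    kind <- m$model_kind %||% "ols"
    res <- tryCatch({
      fit <- switch(
        kind,
        ols = fit_score_regression(outcomes, m$outcome_name,
                                   include_clay = isTRUE(m$include_clay)),
        lmm = fit_mixed_model(outcomes, m$outcome_name,
                              include_month = isTRUE(m$include_month),
                              random = m$random %||% "farm",
                              include_clay = isTRUE(m$include_clay)),
        cv_trend = variability_trend(outcomes, m$outcome_name),
        abort_config(paste0("Unknown model_kind: ", kind))
      )
      sl <- slope_of(fit)
      tibble(
        outcome_name = m$outcome_name, model_kind = fit$model_kind,
        estimate = sl$estimate, std_error = sl$std_error,
        statistic = sl$statistic, p_value = sl$p_value,
        f_stat = fit$f_stat, df_num = fit$df_num, df_den = fit$df_den,
        r_squared = fit$r_squared, n = fit$n,
        sign = if (!is.na(sl$p_value) && sl$p_value < alpha) {
          if (sl$estimate > 0) "positive" else "negative"
        } else "ns",
        error = NA_character_
      )
    }, regenscore_error = function(e) {
      tibble(outcome_name = m$outcome_name, model_kind = kind,
             estimate = NA_real_, std_error = NA_real_, statistic = NA_real_,
             p_value = NA_real_, f_stat = NA_real_, df_num = NA_integer_,
             df_den = NA_integer_, r_squared = NA_real_, n = NA_integer_,
             sign = NA_character_, error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_models") <- length(models)
  out
}
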