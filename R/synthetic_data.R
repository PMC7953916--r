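#' @title Synthetic farm-data generator
#' @description
#' The generator emulates the statistical structure the validation pipeline
#' assumes, so every stage can be exercised offline: practice adoption is
#' bimodal (a latent regenerative/conventional class whose members bundle
#' practices), outcomes are linear in the composite score with an optional
#' clay covariate, farms carry random intercepts, yield- and profit-like
#' outcomes grow relatively more variable with score, and community richness
#' rises with score over heavy-tailed (log-normal) abundances. It does not
#' emulate spatial structure, weather, prices, or real taxonomic composition;
#' a green test on generated data establishes that the estimators recover a
#' stated linear world, not that any real farm behaves this way.
#' @name synthetic_data
NULL

default_effects <- function() {
  list(
    soil_carbon = list(intercept = 40, slope = 2, clay_slope = 0.5,
                       farm_sd = 3, residual_sd = 4, sd_inflation = 0),
    yield = list(intercept = 100, slope = -1.5, clay_slope = 0,
                 farm_sd = 5, residual_sd = 8, sd_inflation = 0.03),
    pest_abundance = list(intercept = 20, slope = 0, clay_slope = 0,
                          farm_sd = 3, residual_sd = 6, sd_inflation = 0),
    # profit: positive score effect with SD growing faster than the mean, so
    # the coefficient of variation rises from ~0.18 (score 0) to ~0.34 (score 9)
    profit = list(intercept = 300, slope = 15, clay_slope = 0,
                  farm_sd = 30, residual_sd = 45, sd_inflation = 0.25)
  )
}

#' Simulation configuration
#'
#' Collects and validates the knobs of the synthetic world. Defaults state
#' the emulated conditions once: a balanced mixture of regenerative and
#' conventional operations, strong practice bundling (adoption probability
#' 0.9 for the regenerative class and 0.1 for the conventional, sharpened by
#' `adoption_coupling = 1`), four replicate fields per operation, clay drawn
#' once per operation in 10-40%, and effects whose signs mirror the validated
#' pattern (soil carbon +, yield -, pests null, profit + with
#' score-inflated spread).
#'
#' @param n_operations number of operations to simulate.
#' @param system `"cropland_full"`, `"cropland_corn"` or `"rangeland"`.
#' @param p_regenerative probability an operation belongs to the latent
#'   regenerative class.
#' @param adoption_coupling nonnegative; how strongly practices bundle within
#'   an operation. The per-item adoption probability is
#'   `plogis((1 + coupling) * qlogis(p_class))`, so large values drive whole
#'   operations to the extremes of the score range.
#' @param p_adopt_regen,p_adopt_conv baseline per-item regenerative-state
#'   probabilities for the two latent classes.
#' @param effects named list of outcome effect settings, each with
#'   `intercept`, `slope` (per score unit), `clay_slope`, `farm_sd`,
#'   `residual_sd`, `sd_inflation` (relative SD growth per score unit).
#' @param community list with `base_richness`, `richness_slope_per_score`,
#'   `abundance_meanlog`, `abundance_sdlog`, `guild_probs` (named
#'   probabilities over trophic guilds).
#' @param n_fields replicate fields/plots per operation.
#' @param months optional character vector of month labels; when given, every
#'   field is observed each month and `month_effects` (named numeric,
#'   default 0) shift the outcome.
#' @param month_effects optional named numeric of month fixed effects.
#' @param clay_range range of the per-operation clay percent draw.
#' @param seed master seed; sub-generators draw from named substreams so
#'   adding one outcome never perturbs another.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_operations = 20,
                       system = c("cropland_full", "cropland_corn", "rangeland"),
                       p_regenerative = 0.5,
                       adoption_coupling = 1,
                       p_adopt_regen = 0.9,
                       p_adopt_conv = 0.1,
                       effects = default_effects(),
                       community = list(base_richness = 8,
                                        richness_slope_per_score = 1.5,
                                        abundance_meanlog = 2,
                                        abundance_sdlog = 1,
                                        guild_probs = c(coprophage = 0.2,
                                                        predator = 0.3,
                                                        parasitoid = 0.1,
                                                        herbivore = 0.3,
                                                        pest = 0.1)),
                       n_fields = 4,
                       months = NULL,
                       month_effects = NULL,
                       clay_range = c(10, 40),
                       seed = 1L) {
  system <- match.arg(system)
  if (n_operations < 1 || n_operations != round(n_operations)) {
    abort_config("n_operations must be a positive integer")
  }
  if (p_regenerative < 0 || p_regenerative > 1) {
    abort_config("p_regenerative must lie in [0, 1]")
  }
  if (adoption_coupling < 0) abort_config("adoption_coupling must be nonnegative")
  if (p_adopt_regen <= 0 || p_adopt_regen >= 1 || p_adopt_conv <= 0 || p_adopt_conv >= 1) {
    abort_config("class adoption probabilities must lie in (0, 1)")
  }
  for (nm in names(effects)) {
    e <- effects[[nm]]
    need <- c("intercept", "slope", "farm_sd", "residual_sd")
    miss <- setdiff(need, names(e))
    if (length(miss)) abort_config(paste0("Effect '", nm, "' missing: ",
                                          paste(miss, collapse = ", ")))
    if (e$farm_sd < 0 || e$residual_sd < 0 || (e$sd_inflation %||% 0) < 0) {
      abort_config(paste0("Effect '", nm, "': SDs and sd_inflation must be nonnegative"))
    }
  }
  max_score <- c(cropland_full = 9, cropland_corn = 6, rangeland = 8)[[system]]
  if (community$base_richness < 1 ||
      community$base_richness + community$richness_slope_per_score * max_score < 1) {
    abort_config("Expected richness must stay >= 1 across the score range")
  }
  if (abs(sum(community$guild_probs) - 1) > 1e-8) {
    abort_config("guild_probs must sum to 1")
  }
  if (length(clay_range) != 2 || clay_range[1] > clay_range[2]) {
    abort_config("clay_range must be an increasing pair")
  }
  if (!is.null(month_effects) && !is.null(months) &&
      !all(names(month_effects) %in% months)) {
    abort_config("month_effects names must match months")
  }
  structure(
    list(n_operations = as.integer(n_operations), system = system,
         p_regenerative = p_regenerative, adoption_coupling = adoption_coupling,
         p_adopt_regen = p_adopt_regen, p_adopt_conv = p_adopt_conv,
         effects = effects, community = community,
         n_fields = as.integer(n_fields), months = months,
         month_effects = month_effects, clay_range = clay_range,
         max_score = max_score, seed = seed),
    class = "sim_config"
  )
}

# representative natural-unit answers for each ordinal rangeland code
rangeland_units_from_codes <- function(iverm, stock, rot, rest) {
  tibble(
    ivermectin_applications_per_year = c(3L, 1L, 0L)[iverm + 1],
    ivermectin_applied_during_grazing = FALSE,
    stocking_density_au_per_ha = c(3, 7.5, 12)[stock + 1],
    rotation_frequency_days = c(45, 20, 7)[rot + 1],
    rest_period_days = c(0, 20, 60)[rest + 1]
  )
}

#' Generate practice profiles with bimodal adoption
#'
#' Each operation is drawn into a latent regenerative class with probability
#' `p_regenerative`; its per-item probability of the regenerative state is
#' the class baseline sharpened by the coupling (see [sim_config()]).
#' Cropland items are Bernoulli in the regenerative state; rangeland ordinal
#' items are Binomial(2, p) over the two steps of each 0-2 scale. Answers are
#' returned in natural units (representative mid-bin values for rangeland) so
#' the scoring rubric is exercised end to end. The latent class is kept in
#' `latent_class` as generator truth; scoring never reads it.
#'
#' @param config a [sim_config()].
#' @return tibble of questionnaire answers, one row per operation, with
#'   `latent_class` (`"regenerative"`/`"conventional"`).
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "profiles", {
    n <- config$n_operations
    regen <- runif(n) < config$p_regenerative
    base_p <- ifelse(regen, config$p_adopt_regen, config$p_adopt_conv)
    p_item <- plogis((1 + config$adoption_coupling) * qlogis(base_p))
    ids <- sprintf("op%03d", seq_len(n))

    if (config$system == "rangeland") {
      draw2 <- function() rbinom(n, 2, p_item)
      ans <- rangeland_units_from_codes(draw2(), draw2(), draw2(), draw2())
      out <- dplyr::bind_cols(tibble(operation_id = ids), ans)
    } else {
      items <- if (config$system == "cropland_corn") corn_items() else cropland_items()
      fields <- cropland_answer_fields()
      out <- tibble(operation_id = ids, system = config$system)
      for (it in cropland_items()) {
        if (it %in% items) {
          regen_state <- runif(n) < p_item
          # elimination items: regenerative state means NOT used
          out[[fields[[it]]]] <- if (it %in% elimination_items()) !regen_state else regen_state
        } else {
          out[[fields[[it]]]] <- NA
        }
      }
    }
    out$latent_class <- ifelse(regen, "regenerative", "conventional")
    out
  })
}

score_of_profiles <- function(profiles, config) {
  ans <- profiles[, setdiff(names(profiles), "latent_class"), drop = FALSE]
  if (config$system == "rangeland") score_rangeland(ans) else score_cropland(ans)
}

#' Generate a long-format outcome table from scored profiles
#'
#' For every configured effect and operation:
#' `outcome = intercept + slope * score + clay_slope * clay + farm_effect +
#' month_effect + noise`, with the farm effect Normal(0, farm_sd^2) drawn
#' once per operation and outcome, clay Uniform over `clay_range` drawn once
#' per operation (a soil property), and residual noise
#' Normal(0, (residual_sd * (1 + sd_inflation * score))^2) per row - the
#' score-proportional variance inflation seen in yield and profit. Replicates
#' are `n_fields` fields per operation, observed once per month when months
#' are configured.
#'
#' @param profiles output of [generate_profiles()] (or any score-record /
#'   answer table the rubric can score).
#' @param config a [sim_config()].
#' @return long tibble: `operation_id`, `field_or_plot_id`, `month`, `score`,
#'   `outcome_name`, `outcome_value`, `clay_pct`.
#' @export
generate_outcomes <- function(profiles, config) {
  stopifnot(inherits(config, "sim_config"))
  scores <- if ("composite_score" %in% names(profiles)) {
    tibble(operation_id = profiles$operation_id, score = profiles$composite_score)
  } else {
    rec <- score_of_profiles(profiles, config)
    tibble(operation_id = rec$operation_id, score = rec$composite_score)
  }
  n <- nrow(scores)
  months <- config$months %||% NA_character_
  grid <- tidyr::expand_grid(
    operation_id = scores$operation_id,
    field_or_plot_id = sprintf("field%02d", seq_len(config$n_fields)),
    month = months
  )
  grid <- dplyr::left_join(grid, scores, by = "operation_id")

  clay <- with_substream(config$seed, "clay", {
    setNames(runif(n, config$clay_range[1], config$clay_range[2]),
             scores$operation_id)
  })
  grid$clay_pct <- unname(clay[grid$operation_id])

  rows <- purrr::imap(config$effects, function(e, nm) {
    with_substream(config$seed, paste0("outcome:", nm), {
      farm_eff <- setNames(rnorm(n, 0, e$farm_sd), scores$operation_id)
      g <- grid
      mu <- e$intercept + e$slope * g$score +
        (e$clay_slope %||% 0) * g$clay_pct +
        unname(farm_eff[g$operation_id])
      if (!is.null(config$month_effects)) {
        me <- config$month_effects[g$month]
        mu <- mu + ifelse(is.na(me), 0, me)
      }
      sdv <- e$residual_sd * (1 + (e$sd_inflation %||% 0) * g$score)
      g$outcome_name <- nm
      g$outcome_value <- mu + rnorm(nrow(g), 0, sdv)
      g
    })
  })
  out <- dplyr::bind_rows(rows)
  out[, c("operation_id", "field_or_plot_id", "month", "score",
          "outcome_name", "outcome_value", "clay_pct")]
}

#' Generate community samples with score-dependent richness
#'
#' Per operation, the number of morphospecies is Poisson with mean
#' `base_richness + richness_slope_per_score * score` (floored at one
#' species), abundances are log-normal rounded up to whole specimens (heavy
#' right tail, every drawn species observed at least once), and trophic
#' guilds are assigned by the configured proportions.
#'
#' @inheritParams generate_outcomes
#' @return long tibble: `operation_id`, `sample_id`, `morphospecies`,
#'   `guild`, `count`.
#' @export
generate_communities <- function(profiles, config) {
  stopifnot(inherits(config, "sim_config"))
  scores <- if ("composite_score" %in% names(profiles)) {
    tibble(operation_id = profiles$operation_id, score = profiles$composite_score)
  } else {
    rec <- score_of_profiles(profiles, config)
    tibble(operation_id = rec$operation_id, score = rec$composite_score)
  }
  cm <- config$community
  with_substream(config$seed, "communities", {
    rows <- purrr::map(seq_len(nrow(scores)), function(i) {
      lambda <- cm$base_richness + cm$richness_slope_per_score * scores$score[i]
      s <- max(1L, rpois(1, lambda))
      tibble(
        operation_id = scores$operation_id[i],
        sample_id = paste0(scores$operation_id[i], "-s1"),
        morphospecies = sprintf("msp%03d", seq_len(s)),
        guild = sample(names(cm$guild_probs), s, replace = TRUE,
                       prob = cm$guild_probs),
        count = as.integer(ceiling(rlnorm(s, cm$abundance_meanlog,
                                          cm$abundance_sdlog)))
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a contiguous synthetic soil profile
#'
#' Builds `n_layers` contiguous layers summing to `depth_cm`, with bulk
#' density drawn uniformly in `bd_range` and carbon percent in `c_range`
#' sorted to decline with depth (as real profiles do); nitrogen is set at a
#' tenth of carbon, a typical soil C:N of 10.
#'
#' @param n_layers number of layers (>= 1).
#' @param depth_cm total profile depth.
#' @param bd_range,c_range ranges for bulk density (g/cm^3) and carbon %.
#' @param seed optional seed for reproducible draws.
#' @return tibble of layers suitable for [esm_stock()].
#' @export
generate_soil_profile <- function(n_layers = 4, depth_cm = 60,
                                  bd_range = c(1, 1.6), c_range = c(0.5, 3),
                                  seed = NULL) {
  if (n_layers < 1 || depth_cm <= 0) abort_config("Need >= 1 layer and positive depth")
  if (bd_range[1] > bd_range[2] || c_range[1] > c_range[2]) {
    abort_config("Ranges must be increasing")
  }
  draw <- function() {
    cuts <- sort(runif(n_layers - 1, 0.2, 0.8)) * depth_cm
    bounds <- unique(c(0, cuts, depth_cm))
    # degenerate duplicate cuts collapse; pad with even splits if needed
    if (length(bounds) < n_layers + 1) {
      bounds <- seq(0, depth_cm, length.out = n_layers + 1)
    }
    tibble(
      top_cm = bounds[-length(bounds)],
      bottom_cm = bounds[-1],
      bulk_density_g_cm3 = runif(n_layers, bd_range[1], bd_range[2]),
      carbon_pct = sort(runif(n_layers, c_range[1], c_range[2]),
                        decreasing = TRUE)
    )
  }
  prof <- if (is.null(seed)) draw() else with_substream(seed, "soil_profile", draw())
  prof$nitrogen_pct <- prof$carbon_pct / 10
  prof
}

#' Simulate a full synthetic bundle
#'
#' Runs [generate_profiles()], scores them, and attaches outcomes and
#' community samples: everything the scoring, classification and validation
#' stages consume, plus the generator's latent class for truth checks.
#'
#' @param config a [sim_config()].
#' @return list with `profiles`, `scores`, `outcomes`, `communities`,
#'   `config`.
#' @export
simulate_bundle <- function(config) {
  profiles <- generate_profiles(config)
  scores <- score_of_profiles(profiles, config)
  list(
    profiles = profiles,
    scores = scores,
    outcomes = generate_outcomes(scores, config),
    communities = generate_communities(scores, config),
    config = config
  )
}
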