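#' Shannon diversity (H)
#'
#' `H = -sum(p_i * log(p_i))` over morphospecies with positive counts, natural
#' log. Bounded by `log(richness)`, attained at even abundances.
#'
#' @param counts nonnegative integer vector of specimen counts (zeros allowed
#'   and ignored).
#' @return Shannon H (natural log).
#' @export
#' @examples
#' shannon_h(c(1, 2, 3))
shannon_h <- function(counts) {
  counts <- validate_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Simpson diversity (DS)
#'
#' The Gini-Simpson index `1 - sum(p_i^2)` by default; `inverse = TRUE` gives
#' the inverse Simpson form `1 / sum(p_i^2)`.
#'
#' @param counts nonnegative integer vector of specimen counts.
#' @param inverse return the inverse Simpson index instead.
#' @return diversity index; Gini-Simpson lies in \[0, 1 - 1/richness\].
#' @export
#' @examples
#' simpson_ds(c(1, 1, 2))  # 0.625
simpson_ds <- function(counts, inverse = FALSE) {
  counts <- validate_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  if (inverse) 1 / sum(p^2) else 1 - sum(p^2)
}

validate_counts <- function(counts) {
  if (length(counts) == 0 || anyNA(counts)) abort_validation("Counts must be non-missing")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_validation("Counts must be nonnegative integers")
  }
  if (sum(counts) == 0) {
    rlang::abort("All counts are zero: diversity undefined",
                 class = c("regenscore_undefined_diversity_error", "regenscore_error"))
  }
  counts
}

#' Species richness and total abundance
#'
#' Richness counts morphospecies with positive counts; abundance sums all
#' specimens. Both accept an empty sample (returning 0).
#'
#' @param counts nonnegative integer vector of specimen counts.
#' @return integer.
#' @export
#' @examples
#' richness(c(0, 0, 5))  # 1
richness <- function(counts) {
  if (anyNA(counts)) abort_validation("Counts must be non-missing")
  if (any(counts < 0)) abort_validation("Counts must be nonnegative")
  sum(counts > 0)
}

#' @rdname richness
#' @export
abundance <- function(counts) {
  if (anyNA(counts)) abort_validation("Counts must be non-missing")
  if (any(counts < 0)) abort_validation("Counts must be nonnegative")
  as.integer(sum(counts))
}

#' Abundance of one trophic guild
#'
#' Sums counts over morphospecies assigned to a guild (coprophage, predator,
#' parasitoid, herbivore, pest, other). Every morphospecies with a positive
#' count must carry a guild label; guild sums partition total abundance.
#'
#' @param counts nonnegative integer vector of specimen counts.
#' @param guilds character vector of guild labels, same length as `counts`.
#' @param guild the guild to total.
#' @return integer abundance of that guild.
#' @export
#' @examples
#' guild_abundance(c(3, 2, 4), c("predator", "predator", "herbivore"), "predator")
guild_abundance <- function(counts, guilds, guild) {
  if (length(counts) != length(guilds)) {
    abort_validation("counts and guilds must have the same length")
  }
  if (anyNA(counts) || any(counts < 0)) abort_validation("Counts must be nonnegative")
  if (any(counts > 0 & (is.na(guilds) | guilds == ""))) {
    abort_validation("Every morphospecies with a positive count needs a guild label")
  }
  as.integer(sum(counts[!is.na(guilds) & guilds == guild]))
}

#' Disc pasture meter biomass index
#'
#' The mean compression height (cm) of the drop plate across placements: an
#' index of standing vegetation biomass, not a calibrated mass.
#'
#' @param compression_heights_cm nonnegative numeric vector of settling
#'   heights.
#' @return mean height in cm.
#' @export
#' @examples
#' biomass_index(c(5, 15))  # 10
biomass_index <- function(compression_heights_cm) {
  if (length(compression_heights_cm) == 0) {
    abort_validation("At least one compression height required")
  }
  if (anyNA(compression_heights_cm) || any(compression_heights_cm < 0)) {
    abort_validation("Compression heights must be nonnegative")
  }
  mean(compression_heights_cm)
}

#' Ground-cover class
#'
#' Bins a percent ground cover into the survey's four classes. Bins are
#' half-open at the low edge and closed at 100, resolving the overlapping
#' printed labels: \[0,25), \[25,50), \[50,75), \[75,100\].
#'
#' @param percent numeric in \[0, 100\].
#' @return factor with levels `0-25`, `25-50`, `50-75`, `75-100`.
#' @export
#' @examples
#' cover_class(c(0, 25, 100))
cover_class <- function(percent) {
  if (anyNA(percent)) abort_validation("Missing cover percent")
  if (any(percent < 0 | percent > 100)) {
    abort_validation("Cover percent must lie in [0, 100]")
  }
  # right = FALSE gives half-open low edges; include.lowest closes the top at 100
  cut(percent, breaks = c(0, 25, 50, 75, 100),
      labels = c("0-25", "25-50", "50-75", "75-100"),
      right = FALSE, include.lowest = TRUE)
}

#' Per-operation community summary
#'
#' Summarizes long-format specimen counts into richness, abundance, Shannon H
#' and Gini-Simpson per operation. By default replicate samples are pooled
#' (counts summed over samples) before indices are computed, matching how
#' replicate plots are composited into single farm values; with
#' `pool = FALSE` indices are computed per sample and then averaged, for
#' sensitivity analysis.
#'
#' @param specimens data frame with columns `operation_id`, `sample_id`,
#'   `morphospecies`, `guild`, `count`.
#' @param pool pool counts across samples within an operation before
#'   computing indices (default `TRUE`).
#' @return tibble with one row per operation: `richness`, `abundance`,
#'   `shannon_h`, `simpson_ds`, and per-guild abundance columns
#'   (`n_<guild>`, pooled counts regardless of `pool`).
#' @export
community_summary <- function(specimens, pool = TRUE) {
  specimens <- as_tibble(specimens)
  need <- c("operation_id", "sample_id", "morphospecies", "guild", "count")
  miss <- setdiff(need, names(specimens))
  if (length(miss)) abort_schema(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  if (any(specimens$count > 0 & (is.na(specimens$guild) | specimens$guild == ""))) {
    abort_validation("Every morphospecies with a positive count needs a guild label")
  }

  index_one <- function(counts) {
    tibble(richness = richness(counts), abundance = abundance(counts),
           shannon_h = shannon_h(counts), simpson_ds = simpson_ds(counts))
  }

  per_op <- if (pool) {
    specimens |>
      dplyr::summarise(count = sum(.data$count),
                       .by = c("operation_id", "morphospecies")) |>
      dplyr::reframe(index_one(.data$count), .by = "operation_id")
  } else {
    specimens |>
      dplyr::reframe(index_one(.data$count),
                     .by = c("operation_id", "sample_id")) |>
      dplyr::summarise(dplyr::across(c("richness", "abundance",
                                       "shannon_h", "simpson_ds"), mean),
                       .by = "operation_id")
  }

  guild_tot <- specimens |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("operation_id", "guild")) |>
    tidyr::pivot_wider(names_from = "guild", values_from = "count",
                       names_prefix = "n_", values_fill = 0L)

  dplyr::left_join(per_op, guild_tot, by = "operation_id")
}
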