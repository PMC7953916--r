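#' Locate the natural break in a set of composite scores
#'
#' Observed composite scores fall into two clusters (conventional near 0,
#' regenerative near the maximum). The threshold is the widest gap between
#' consecutive distinct sorted scores; the dividing score is the gap midpoint
#' rounded half up. When two gaps tie in width the one at higher scores wins,
#' keeping the conventional cluster anchored at the bottom. Scores are never
#' pooled across systems with different maxima: call once per system.
#'
#' @param scores integer-valued numeric vector of composite scores (with
#'   duplicates; at least two distinct values).
#' @return object of class `gap_threshold`: a list with `gap_low` (highest
#'   score below the gap), `gap_high` (lowest score above it), `midpoint`,
#'   `dividing_score` (midpoint rounded half up), `gap_width`, and
#'   `distinct_scores`.
#' @export
#' @examples
#' thr <- find_threshold(c(0, 1, 2, 4, 5, 6, 7, 8))
#' thr$dividing_score  # 3
find_threshold <- function(scores) {
  if (length(scores) == 0) abort_validation("Empty score vector")
  if (anyNA(scores)) abort_validation("Scores must not be missing")
  if (any(scores != round(scores))) abort_validation("Scores must be integers")
  distinct <- sort(unique(as.integer(scores)))
  if (length(distinct) < 2) {
    rlang::abort("All scores identical: no gap to divide at",
                 class = c("regenscore_no_gap_error", "regenscore_error"))
  }
  widths <- diff(distinct)
  # widest gap; on ties prefer the gap at higher scores
  k <- max(which(widths == max(widths)))
  gap_low <- distinct[k]
  gap_high <- distinct[k + 1]
  midpoint <- (gap_low + gap_high) / 2
  structure(
    list(
      gap_low = gap_low,
      gap_high = gap_high,
      midpoint = midpoint,
      dividing_score = as.integer(round_half_up(midpoint)),
      gap_width = as.integer(gap_high - gap_low),
      distinct_scores = distinct
    ),
    class = "gap_threshold"
  )
}

#' @export
print.gap_threshold <- function(x, ...) {
  cat("Gap threshold: widest gap (", x$gap_low, ", ", x$gap_high,
      "), width ", x$gap_width, "\n", sep = "")
  cat("  midpoint ", x$midpoint, " -> dividing score ", x$dividing_score,
      " (half-up)\n", sep = "")
  cat("  distinct scores:", paste(x$distinct_scores, collapse = " "), "\n")
  invisible(x)
}

#' Label scores regenerative or conventional against a gap threshold
#'
#' Scores at or above `gap_high` are regenerative; at or below `gap_low`,
#' conventional. A score strictly inside the gap (possible only for new
#' operations scored after the threshold was fixed) is labelled by the
#' dividing score and flagged `in_gap`.
#'
#' @param scores integer-valued numeric vector.
#' @param threshold a [find_threshold()] result.
#' @return tibble with `score`, `label` (factor conventional/regenerative) and
#'   `in_gap` (logical).
#' @export
#' @examples
#' thr <- find_threshold(c(0, 1, 2, 4, 5, 6, 7, 8))
#' classify_scores(c(0, 3, 8), thr)
classify_scores <- function(scores, threshold) {
  if (!inherits(threshold, "gap_threshold")) {
    abort_validation("threshold must be a gap_threshold from find_threshold()")
  }
  if (anyNA(scores)) abort_validation("Scores must not be missing")
  regen <- scores >= threshold$gap_high |
    (scores > threshold$gap_low & scores >= threshold$dividing_score)
  tibble(
    score = as.integer(scores),
    label = factor(ifelse(regen, "regenerative", "conventional"),
                   levels = c("conventional", "regenerative")),
    in_gap = scores > threshold$gap_low & scores < threshold$gap_high
  )
}
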