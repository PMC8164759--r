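#' Semi-quantitative tumor-cell coverage score
#'
#' Maps the fraction of chromogen-positive tumor cells to the 5-level
#' coverage score: below 1 percent scores 0; 1-5 percent scores 1; then
#' 6-10, 11-20 and over 20 percent score 2, 3 and 4. Continuous fractions
#' are binned half-open so the five categories partition `[0, 1]`:
#' `[0, 0.01)` -> 0, `[0.01, 0.05]` -> 1, `(0.05, 0.10]` -> 2,
#' `(0.10, 0.20]` -> 3, `(0.20, 1]` -> 4.
#'
#' @param fraction Positive-cell fraction(s) in `[0, 1]` (vectorised).
#' @return Integer score(s) 0-4.
#' @examples
#' score_ido_coverage(c(0.005, 0.03, 0.08, 0.15, 0.25)) # 0 1 2 3 4
#' @export
score_ido_coverage <- function(fraction) {
  if (any(is.na(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    stop("fraction must lie in [0, 1]")
  }
  ifelse(fraction < 0.01, 0L,
    ifelse(fraction <= 0.05, 1L,
      ifelse(fraction <= 0.10, 2L,
        ifelse(fraction <= 0.20, 3L, 4L)
      )
    )
  )
}

#' Predominant staining-intensity score
#'
#' The tumor-level intensity score (1 weak, 2 moderate, 3 strong) is the
#' modal per-cell intensity category — the predominant intensity deposit.
#' Ties break toward the lower (weaker) category.
#'
#' @param per_cell_intensity Non-empty vector of values in `{1, 2, 3}`.
#' @return Integer 1, 2 or 3.
#' @examples
#' score_ido_intensity(c(1, 1, 2)) # 1
#' @export
score_ido_intensity <- function(per_cell_intensity) {
  if (length(per_cell_intensity) == 0L) {
    stop("intensity scoring requires at least one cell")
  }
  if (!all(per_cell_intensity %in% 1:3)) {
    stop("per-cell intensity categories must be 1, 2 or 3")
  }
  counts <- tabulate(per_cell_intensity, nbins = 3L)
  which.max(counts) # first maximum = lower category on ties
}

#' Dichotomize the coverage score into IDO status
#'
#' Tumors with coverage category 0 (below 1 percent positive tumor cells) are
#' negative; categories 1-4 are positive.
#'
#' @param coverage_category Integer(s) in 0-4 (vectorised; NA passes through).
#' @return Factor with levels `negative`, `positive`.
#' @export
dichotomize_ido_status <- function(coverage_category) {
  if (!all(coverage_category %in% c(0:4, NA))) {
    stop("coverage_category must be in 0-4")
  }
  factor(
    ifelse(is.na(coverage_category), NA_character_,
      ifelse(coverage_category >= 1, "positive", "negative")
    ),
    levels = c("negative", "positive")
  )
}

#' Group the intensity score into weak vs moderate-or-strong
#'
#' Intensity categories 2 and 3 are fused (small strata at the strong end),
#' giving the two-level factor used in association tests.
#'
#' @param intensity_category Integer(s) in 1-3 (vectorised; NA passes through).
#' @return Factor with levels `weak`, `moderate_or_strong`.
#' @export
group_intensity <- function(intensity_category) {
  if (!all(intensity_category %in% c(1:3, NA))) {
    stop("intensity_category must be in 1-3")
  }
  factor(
    ifelse(is.na(intensity_category), NA_character_,
      ifelse(intensity_category >= 2, "moderate_or_strong", "weak")
    ),
    levels = c("weak", "moderate_or_strong")
  )
}

#' Median dichotomization of a marker
#'
#' Splits per-sample marker values into low/high at the cohort median: values
#' at or below the median are low, values above are high (ties go to low —
#' the published rule defines only strict less/greater, so the tie side is a
#' documented convention and configurable).
#'
#' @param values Numeric vector (NAs allowed; at least 2 non-missing values).
#' @param ties One of `"low"` (default) or `"high"`: which side values equal
#'   to the median fall on.
#' @return An object of class `dichotomized_marker`: list with `threshold`
#'   (the median) and `labels` (factor `low`/`high`, NA preserved).
#' @examples
#' dichotomize_by_median(c(50, 56, 57, 63))$labels # low low high high
#' @export
dichotomize_by_median <- function(values, ties = c("low", "high")) {
  ties <- match.arg(ties)
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("median dichotomization needs >= 2 non-missing values")
  med <- stats::median(values[ok])
  high <- if (ties == "low") values > med else values >= med
  structure(
    list(
      threshold = med,
      labels = factor(
        ifelse(is.na(values), NA_character_, ifelse(high, "high", "low")),
        levels = c("low", "high")
      )
    ),
    class = "dichotomized_marker"
  )
}

#' @export
print.dichotomized_marker <- function(x, ...) {
  cat(sprintf(
    "<dichotomized_marker> threshold (median) = %.4g; %d low / %d high\n",
    x$threshold, sum(x$labels == "low", na.rm = TRUE),
    sum(x$labels == "high", na.rm = TRUE)
  ))
  invisible(x)
}
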