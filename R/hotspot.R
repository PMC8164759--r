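#' Number of hotspot fields for a lesion
#'
#' Hotspot quantification images either three or five representative
#' high-density areas depending on lesion size: lesions at least
#' `threshold_mm2` large contribute five fields, smaller ones three.
#'
#' @param lesion_area_mm2 Lesion area in mm^2 (> 0).
#' @param threshold_mm2 Size cutoff; the default 2 mm^2 separates small
#'   excisions from larger lesions.
#' @return 3 or 5 (integer).
#' @examples
#' choose_field_number(0.8) # 3
#' choose_field_number(4.5) # 5
#' @export
choose_field_number <- function(lesion_area_mm2, threshold_mm2 = 2) {
  if (!is.numeric(lesion_area_mm2) || length(lesion_area_mm2) != 1L ||
      is.na(lesion_area_mm2) || lesion_area_mm2 <= 0) {
    stop("lesion_area_mm2 must be a single positive number")
  }
  if (lesion_area_mm2 >= threshold_mm2) 5L else 3L
}

#' Select hotspot fields for one lesion
#'
#' Picks the `k` tumor-containing fields with the highest accepted positive
#' cell counts (the areas of highest marker density), breaking count ties by
#' field index ascending, and aggregates them into the per-sample value with
#' [aggregate_sample_count()]. When fewer than `k` eligible fields exist, all
#' eligible fields are used and the result is flagged.
#'
#' @param counts Numeric vector of accepted counts per candidate field.
#' @param tumor_present Logical vector: does the field contain tumor cells
#'   (fields without tumor are ineligible — hotspots must lie close to the
#'   lesion)? Default: all eligible.
#' @param k Number of fields to select (3 or 5, see [choose_field_number()]).
#' @param sample_id Optional sample identifier.
#' @return An object of class `hotspot_result`: list with `sample_id`,
#'   `selected` (field indices), `field_counts`, `aggregate_count`,
#'   `short_of_fields` flag.
#' @examples
#' select_hotspots(c(5, 9, 2, 7, 1), k = 3)$selected # fields 2, 4, 1
#' @export
select_hotspots <- function(counts, tumor_present = rep(TRUE, length(counts)),
                            k, sample_id = NA_character_) {
  if (length(counts) == 0L) stop("at least one candidate field is required")
  if (length(tumor_present) != length(counts)) {
    stop("tumor_present must match the number of fields")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("field counts must be non-negative and non-missing")
  }
  if (k < 1) stop("k must be >= 1")
  eligible <- which(tumor_present)
  if (length(eligible) == 0L) {
    stop("no tumor-containing field available for hotspot selection")
  }
  # order by count descending, ties by field index ascending
  ord <- eligible[order(-counts[eligible], eligible)]
  sel <- ord[seq_len(min(k, length(ord)))]
  structure(
    list(
      sample_id = sample_id,
      selected = sel,
      field_counts = counts[sel],
      aggregate_count = aggregate_sample_count(counts[sel]),
      short_of_fields = length(sel) < k
    ),
    class = "hotspot_result"
  )
}

#' @export
print.hotspot_result <- function(x, ...) {
  cat(sprintf(
    "<hotspot_result> %s: fields [%s] -> aggregate %.2f%s\n",
    ifelse(is.na(x$sample_id), "(unnamed)", x$sample_id),
    paste(x$selected, collapse = ", "), x$aggregate_count,
    if (x$short_of_fields) " (fewer fields than requested)" else ""
  ))
  invisible(x)
}

#' Aggregate hotspot field counts into one per-sample value
#'
#' The per-sample marker value is the arithmetic mean of the selected fields'
#' accepted counts; means of integer counts naturally produce half-integer
#' sample values.
#'
#' @param per_field_counts Non-empty numeric vector of non-negative counts.
#' @return The mean count (real).
#' @examples
#' aggregate_sample_count(c(56, 57)) # 56.5
#' @export
aggregate_sample_count <- function(per_field_counts) {
  if (length(per_field_counts) == 0L) {
    stop("cannot aggregate an empty list of field counts")
  }
  if (any(is.na(per_field_counts)) || any(per_field_counts < 0)) {
    stop("field counts must be non-negative and non-missing")
  }
  mean(per_field_counts)
}
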