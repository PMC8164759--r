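#' Detection criteria for positive-cell counting
#'
#' Bundles the exclusion rules used by the automated counter: a size window in
#' square micrometres ("too large" / too small), the aspect-ratio cutoff
#' (objects with major/minor axis ratio strictly greater than
#' `max_aspect_ratio` are excluded; a ratio of exactly 2.0 is kept), an
#' image-edge rule, an intensity rule ("stained intensely enough to clearly
#' stand out from the background"), and the melanin colour band used by the
#' pigment rejection filter.
#'
#' @param stain_model Stain model, see [separate_stain_channels()].
#' @param max_aspect_ratio Exclude objects with aspect ratio > this (default 2).
#' @param min_area_um2,max_area_um2 Acceptance window for object area, in um^2.
#'   Defaults 10-120 um^2 cover the lymphocyte-nucleus scale.
#' @param intensity_rule `"otsu_on_stain_channel"` (Otsu threshold on the
#'   primary stain OD map, never below `od_floor`) or
#'   `"background_mean_plus_k_sd"` (background OD mean + `k` SD).
#' @param k SD multiplier for the background intensity rule.
#' @param od_floor Absolute OD floor for the intensity threshold; keeps blank
#'   fields detection-free.
#' @param od_segment Permissive OD threshold used to segment candidate
#'   objects before the intensity rule is applied.
#' @param edge_margin_px Widens the edge-contact band beyond the outermost
#'   pixel row/column (0 = outermost row/column only).
#' @param melanin_hue_band,melanin_saturation_range,melanin_value_range HSV
#'   bands (all components in `[0, 1]`) classifying a pixel as melanin
#'   pigment: brown hue, moderate saturation, dark-to-mid value. DAB brown is
#'   more saturated and brighter; DAB-Ni is nearly achromatic, so both escape
#'   the band.
#' @param qc_candidate_factor,qc_solidity_min QC rule: a field is flagged
#'   `needs_manual_review` when candidates outnumber accepted cells by more
#'   than `qc_candidate_factor`, or mean candidate solidity falls below
#'   `qc_solidity_min` (merged blobs).
#' @return An object of class `detection_criteria`.
#' @export
detection_criteria <- function(stain_model = "dab_ni_no_counterstain",
                               max_aspect_ratio = 2.0,
                               min_area_um2 = 10,
                               max_area_um2 = 120,
                               intensity_rule = c(
                                 "otsu_on_stain_channel",
                                 "background_mean_plus_k_sd"
                               ),
                               k = 3,
                               od_floor = 0.35,
                               od_segment = 0.12,
                               edge_margin_px = 0L,
                               melanin_hue_band = c(0.03, 0.15),
                               melanin_saturation_range = c(0.25, 0.65),
                               melanin_value_range = c(0.15, 0.62),
                               qc_candidate_factor = 3,
                               qc_solidity_min = 0.8) {
  stain_model <- match.arg(stain_model, STAIN_MODELS)
  intensity_rule <- match.arg(intensity_rule)
  if (max_aspect_ratio < 1) stop("max_aspect_ratio must be >= 1")
  if (min_area_um2 >= max_area_um2) stop("min_area_um2 must be < max_area_um2")
  if (edge_margin_px < 0) stop("edge_margin_px must be >= 0")
  structure(
    list(
      stain_model = stain_model,
      max_aspect_ratio = max_aspect_ratio,
      min_area_um2 = min_area_um2,
      max_area_um2 = max_area_um2,
      intensity_rule = intensity_rule,
      k = k,
      od_floor = od_floor,
      od_segment = od_segment,
      edge_margin_px = as.integer(edge_margin_px),
      melanin_hue_band = melanin_hue_band,
      melanin_saturation_range = melanin_saturation_range,
      melanin_value_range = melanin_value_range,
      qc_candidate_factor = qc_candidate_factor,
      qc_solidity_min = qc_solidity_min
    ),
    class = "detection_criteria"
  )
}

#' Melanin rejection filter
#'
#' Classifies pixels as endogenous melanin pigment by their HSV colour
#' (desaturated dark brown) and returns the retained (non-melanin) mask.
#' Pigment confounds chromogen detection in melanocytic lesions, so flagged
#' pixels are removed from further analysis.
#'
#' @param image A [field_image()].
#' @param criteria A [detection_criteria()].
#' @return Logical matrix, `TRUE` where the pixel is retained.
#' @export
melanin_rejection_filter <- function(image, criteria = detection_criteria()) {
  stopifnot(inherits(image, "field_image"))
  px <- image$pixels
  hsv <- grDevices::rgb2hsv(
    r = as.vector(px[, , 1]), g = as.vector(px[, , 2]), b = as.vector(px[, , 3]),
    maxColorValue = 1
  )
  mel <- hsv[1, ] >= criteria$melanin_hue_band[1] &
    hsv[1, ] <= criteria$melanin_hue_band[2] &
    hsv[2, ] >= criteria$melanin_saturation_range[1] &
    hsv[2, ] <= criteria$melanin_saturation_range[2] &
    hsv[3, ] >= criteria$melanin_value_range[1] &
    hsv[3, ] <= criteria$melanin_value_range[2]
  matrix(!mel, nrow = dim(px)[1], ncol = dim(px)[2])
}

.intensity_threshold <- function(od, criteria) {
  if (criteria$intensity_rule == "otsu_on_stain_channel") {
    rng <- c(0, max(max(od), 1e-6))
    t_otsu <- EBImage::otsu(EBImage::Image(od), range = rng, levels = 256L)
    max(t_otsu, criteria$od_floor)
  } else {
    bg <- od[od < criteria$od_segment]
    if (length(bg) < 2L) bg <- as.vector(od)
    max(mean(bg) + criteria$k * stats::sd(bg), criteria$od_floor)
  }
}

# Moment/shape measurements for every labelled object.
# x/y in pixel coordinates (x = column, y = row, 1-based).
.measure_labels <- function(lab, od, pixel_size_um, edge_margin_px = 0L) {
  n <- max(lab)
  empty <- data.frame(
    label = integer(0), x = numeric(0), y = numeric(0), n_px = integer(0),
    area_um2 = numeric(0), major_axis_um = numeric(0), minor_axis_um = numeric(0),
    aspect_ratio = numeric(0), mean_stain_od = numeric(0),
    touches_edge = logical(0), solidity = numeric(0)
  )
  if (n == 0L) return(empty)
  fm <- EBImage::computeFeatures.moment(lab)
  fm <- matrix(fm, ncol = ncol(fm), dimnames = list(NULL, colnames(fm)))
  npx <- tabulate(lab[lab > 0L], nbins = n)
  mean_od <- as.numeric(tapply(od[lab > 0L], lab[lab > 0L], mean)[as.character(1:n)])

  # edge contact: any pixel within the margin band at the image border
  nr <- nrow(lab); nc <- ncol(lab)
  b <- edge_margin_px + 1L
  band <- c(
    lab[seq_len(min(b, nr)), ], lab[seq(max(nr - b + 1L, 1L), nr), ],
    lab[, seq_len(min(b, nc))], lab[, seq(max(nc - b + 1L, 1L), nc)]
  )
  on_edge <- sort(unique(band[band > 0L]))

  # solidity: pixel count over convex-hull area of pixel centres
  idx <- which(lab > 0L)
  ord <- order(lab[idx])
  idx <- idx[ord]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  grp <- lab[idx]
  starts <- c(1L, which(diff(grp) > 0L) + 1L)
  ends <- c(starts[-1L] - 1L, length(grp))
  solidity <- numeric(n)
  for (i in seq_len(n)) {
    xs <- cols[starts[i]:ends[i]]; ys <- rows[starts[i]:ends[i]]
    if (length(xs) < 4L) { solidity[i] <- 1; next }
    h <- grDevices::chull(xs, ys)
    hx <- xs[h]; hy <- ys[h]
    hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    solidity[i] <- min(1, length(xs) / max(hull_area, 1))
  }

  major_px <- fm[, "m.majoraxis"]
  minor_px <- major_px * sqrt(pmax(0, 1 - fm[, "m.eccentricity"]^2))
  minor_px <- pmax(minor_px, 1) # a 1-px-thin object is one pixel wide
  data.frame(
    label = 1:n,
    x = fm[, "m.cy"], # EBImage first dim = row = y
    y = fm[, "m.cx"],
    n_px = npx,
    area_um2 = npx * pixel_size_um^2,
    major_axis_um = major_px * pixel_size_um,
    minor_axis_um = minor_px * pixel_size_um,
    aspect_ratio = pmax(1, major_px / minor_px),
    mean_stain_od = mean_od,
    touches_edge = (1:n) %in% on_edge,
    solidity = solidity
  )
}

#' Detect candidate cells on a stain OD map
#'
#' Candidates are connected components (8-connectivity) of pixels whose stain
#' OD reaches the permissive segmentation threshold inside the retained
#' (non-melanin) mask. Each candidate is measured: centroid, area, major and
#' minor axis via second moments (in physical units), aspect ratio, mean
#' stain OD, edge contact, solidity. No accept/reject verdicts are assigned
#' yet — see [apply_exclusion_rules()].
#'
#' @param channels A `stain_od` object from [separate_stain_channels()], or a
#'   plain OD matrix.
#' @param retained_mask Logical matrix from [melanin_rejection_filter()]
#'   (`NULL` = retain everything).
#' @param criteria A [detection_criteria()].
#' @param pixel_size_um Physical pixel size in micrometres.
#' @return A `detected_cells` data frame; attributes `intensity_threshold`
#'   (the OD cutoff the intensity rule will use) and `image_dim`.
#' @export
detect_candidates <- function(channels, retained_mask, criteria, pixel_size_um) {
  od <- if (inherits(channels, "stain_od")) primary_od(channels) else channels
  if (!is.null(retained_mask) && !all(dim(retained_mask) == dim(od))) {
    stop("retained_mask and OD map must have identical dimensions")
  }
  bw <- od >= criteria$od_segment
  if (!is.null(retained_mask)) bw <- bw & retained_mask
  lab <- EBImage::bwlabel(bw)
  cells <- .measure_labels(lab, od, pixel_size_um, criteria$edge_margin_px)
  class(cells) <- c("detected_cells", class(cells))
  attr(cells, "intensity_threshold") <- .intensity_threshold(od, criteria)
  attr(cells, "image_dim") <- dim(od)
  attr(cells, "label_matrix") <- lab
  cells
}

#' Apply the exclusion rules and assign verdicts
#'
#' Each candidate receives exactly one verdict, determined by the first
#' failing rule in the fixed order size, aspect ratio, edge contact, staining
#' intensity; candidates passing all four are `accepted`. The aspect-ratio
#' rule is a strict inequality: a ratio of exactly `max_aspect_ratio` passes.
#'
#' @param cells A `detected_cells` data frame from [detect_candidates()].
#' @param criteria A [detection_criteria()].
#' @param intensity_threshold OD cutoff for the intensity rule; defaults to
#'   the threshold computed by [detect_candidates()] (falling back to
#'   `criteria$od_floor`).
#' @return `cells` with a `verdict` factor column added.
#' @export
apply_exclusion_rules <- function(cells, criteria,
                                  intensity_threshold = attr(cells, "intensity_threshold")) {
  if (is.null(intensity_threshold)) intensity_threshold <- criteria$od_floor
  verdict <- rep("accepted", nrow(cells))
  too_small_or_large <- cells$area_um2 < criteria$min_area_um2 |
    cells$area_um2 > criteria$max_area_um2
  bad_aspect <- cells$aspect_ratio > criteria$max_aspect_ratio
  faint <- cells$mean_stain_od < intensity_threshold
  verdict[faint] <- "rejected_intensity"
  verdict[cells$touches_edge] <- "rejected_edge"
  verdict[bad_aspect] <- "rejected_aspect"
  verdict[too_small_or_large] <- "rejected_size"
  cells$verdict <- factor(verdict, levels = VERDICT_LEVELS)
  cells
}

VERDICT_LEVELS <- c(
  "accepted", "rejected_size", "rejected_aspect", "rejected_edge",
  "rejected_intensity", "rejected_melanin"
)

#' Count positive cells in one field image
#'
#' Runs the full per-field pipeline: stain separation, melanin rejection,
#' candidate detection, exclusion rules. Stained connected components lying
#' in the melanin-masked area are tallied as `rejected_melanin`, so accepted
#' plus per-reason rejected counts always reconcile with the total number of
#' stained objects found. A QC flag marks fields whose counts look unreliable
#' (many more candidates than accepted cells, or low-solidity merged blobs)
#' for manual review.
#'
#' @param image A [field_image()].
#' @param criteria A [detection_criteria()].
#' @return An object of class `field_count`: list with `id`, `n_accepted`,
#'   `n_rejected_by_reason`, `n_candidates`, `qc_flag`
#'   (`"auto_ok"`/`"needs_manual_review"`) and the measured `cells`.
#' @export
count_field <- function(image, criteria = detection_criteria(image$stain_model)) {
  stopifnot(inherits(image, "field_image"))
  channels <- separate_stain_channels(image, criteria$stain_model)
  od <- primary_od(channels)
  retained <- melanin_rejection_filter(image, criteria)
  cells <- detect_candidates(channels, retained, criteria, image$pixel_size_um)
  cells <- apply_exclusion_rules(cells, criteria)

  # stained objects inside the melanin mask: rejected by the pigment filter
  bw_mel <- (od >= criteria$od_segment) & !retained
  n_melanin <- max(EBImage::bwlabel(bw_mel))

  reasons <- table(cells$verdict)[setdiff(VERDICT_LEVELS, "accepted")]
  reasons[is.na(reasons)] <- 0L
  reasons["rejected_melanin"] <- n_melanin
  n_accepted <- sum(cells$verdict == "accepted")
  n_candidates <- nrow(cells) + n_melanin

  qc <- "auto_ok"
  if (nrow(cells) > 0L) {
    if (nrow(cells) / max(n_accepted, 1L) > criteria$qc_candidate_factor ||
        mean(cells$solidity) < criteria$qc_solidity_min) {
      qc <- "needs_manual_review"
    }
  }
  structure(
    list(
      id = image$id,
      n_accepted = n_accepted,
      n_rejected_by_reason = as.integer(reasons) |> stats::setNames(names(reasons)),
      n_candidates = n_candidates,
      qc_flag = qc,
      cells = cells
    ),
    class = "field_count"
  )
}

#' @export
print.field_count <- function(x, ...) {
  cat(sprintf(
    "<field_count> %s: %d accepted / %d candidates [%s]\n",
    ifelse(is.na(x$id), "(unnamed)", x$id), x$n_accepted, x$n_candidates, x$qc_flag
  ))
  rej <- x$n_rejected_by_reason[x$n_rejected_by_reason > 0]
  if (length(rej)) {
    cat("  rejected:", paste(names(rej), rej, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
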