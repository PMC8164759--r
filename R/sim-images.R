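#' Parameters for synthetic field-image generation
#'
#' Defines one simulated brightfield microscope field. The default geometry
#' matches the reference acquisition: 2560 x 1920 px at 0.11 um/px (a
#' 282 x 211 um field at x200 magnification). Planted object classes map onto
#' the detector's exclusion rules: `positive` cells satisfy every acceptance
#' criterion by construction, while each distractor class violates exactly
#' one — `too_large` (area at least twice the acceptance window maximum),
#' `elongated` (aspect ratio sampled in 2.5-4), `faint` (stained above the
#' segmentation threshold but below the intensity rule), `edge` (protrudes
#' past the image border), `melanin` (pigment-coloured granules). Positive
#' nuclei are ellipses with major axis 6-10 um and aspect ratio below 1.8
#' (lymphocyte-nucleus scale).
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Physical pixel size (default 0.11 um/px).
#' @param n_positive Number of genuine positive cells.
#' @param n_large_distractors,n_elongated_distractors,n_faint_distractors,n_edge_cells
#'   Distractor counts per class.
#' @param n_melanin_granules Number of melanin pigment granules.
#' @param n_hematoxylin_nuclei Counterstained (chromogen-negative) nuclei;
#'   only meaningful under `dab_with_hematoxylin`.
#' @param stain_model Stain model, see [separate_stain_channels()].
#' @param background_noise_sd SD of Gaussian pixel noise added per channel.
#' @param overlap_fraction Fraction of positive cells planted as touching
#'   pairs that merge into one connected component (0 = none; emulates
#'   under-segmented nuclei for QC testing).
#' @param seed Integer RNG seed; identical parameters and seed reproduce
#'   identical pixels and annotations.
#' @return An object of class `image_sim_params`.
#' @export
image_sim_params <- function(width_px = 2560L, height_px = 1920L,
                             pixel_size_um = 0.11,
                             n_positive = 25L,
                             n_large_distractors = 3L,
                             n_elongated_distractors = 3L,
                             n_faint_distractors = 3L,
                             n_edge_cells = 2L,
                             n_melanin_granules = 30L,
                             n_hematoxylin_nuclei = 0L,
                             stain_model = "dab_ni_no_counterstain",
                             background_noise_sd = 0.01,
                             overlap_fraction = 0,
                             seed = 1L) {
  counts <- c(
    n_positive, n_large_distractors, n_elongated_distractors,
    n_faint_distractors, n_edge_cells, n_melanin_granules, n_hematoxylin_nuclei
  )
  if (any(counts < 0)) stop("object counts must be non-negative")
  if (width_px < 16 || height_px < 16) stop("image must be at least 16 x 16 px")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (background_noise_sd < 0) stop("background_noise_sd must be non-negative")
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in [0, 1]")
  }
  stain_model <- match.arg(stain_model, STAIN_MODELS)
  structure(
    list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      pixel_size_um = pixel_size_um,
      n_positive = as.integer(n_positive),
      n_large_distractors = as.integer(n_large_distractors),
      n_elongated_distractors = as.integer(n_elongated_distractors),
      n_faint_distractors = as.integer(n_faint_distractors),
      n_edge_cells = as.integer(n_edge_cells),
      n_melanin_granules = as.integer(n_melanin_granules),
      n_hematoxylin_nuclei = as.integer(n_hematoxylin_nuclei),
      stain_model = stain_model,
      background_noise_sd = background_noise_sd,
      overlap_fraction = overlap_fraction,
      seed = as.integer(seed)
    ),
    class = "image_sim_params"
  )
}

# flat rendering colours (RGB in [0,1]) per stain model
.sim_colors <- function(stain_model) {
  if (stain_model == "dab_ni_no_counterstain") {
    list(
      background = c(0.95, 0.94, 0.92),
      strong = c(0.18, 0.17, 0.19),   # DAB-Ni: near-black, near-achromatic
      faint = c(0.61, 0.60, 0.62),
      melanin = c(0.45, 0.35, 0.25),  # desaturated dark brown
      hematoxylin = c(0.40, 0.45, 0.72)
    )
  } else {
    list(
      background = c(0.95, 0.94, 0.92),
      strong = c(0.65, 0.39, 0.16),   # DAB brown: saturated, brighter than pigment
      faint = c(0.85, 0.76, 0.68),
      melanin = c(0.45, 0.35, 0.25),
      hematoxylin = c(0.40, 0.45, 0.72)
    )
  }
}

# stain OD of a flat colour under the model (what the detector will measure)
.color_stain_od <- function(color, stain_model) {
  od <- .rgb_to_od(color)
  if (stain_model == "dab_ni_no_counterstain") {
    mean(od)
  } else {
    max(0, as.numeric(od %*% solve(.stain_matrix_h_dab()))[2])
  }
}

# geometry samplers: major axis (um) and aspect ratio per class
.sample_geometry <- function(class) {
  switch(class,
    positive = c(stats::runif(1, 6, 10), stats::runif(1, 1.0, 1.8)),
    too_large = c(stats::runif(1, 20, 26), stats::runif(1, 1.0, 1.15)),
    elongated = c(stats::runif(1, 12, 16), stats::runif(1, 2.5, 4.0)),
    faint = c(stats::runif(1, 6, 10), stats::runif(1, 1.0, 1.8)),
    edge_touching = c(stats::runif(1, 7, 10), stats::runif(1, 1.0, 1.2)),
    melanin = c(stats::runif(1, 4.5, 6.5), stats::runif(1, 1.0, 1.2)),
    hematoxylin = c(stats::runif(1, 6, 10), stats::runif(1, 1.0, 1.6)),
    overlap_pair = c(stats::runif(1, 9.5, 10), 1.0)
  )
}

.rasterize_ellipse <- function(cx, cy, a_px, b_px, phi, nrow_img, ncol_img) {
  r0 <- max(1L, floor(cy - a_px - 1)); r1 <- min(nrow_img, ceiling(cy + a_px + 1))
  c0 <- max(1L, floor(cx - a_px - 1)); c1 <- min(ncol_img, ceiling(cx + a_px + 1))
  if (r0 > r1 || c0 > c1) return(NULL)
  xs <- c0:c1; ys <- r0:r1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(phi) + dy * sin(phi)) / a_px
  v <- (-dx * sin(phi) + dy * cos(phi)) / b_px
  inside <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  if (nrow(inside) == 0L) return(NULL)
  cbind(row = ys[inside[, 1]], col = xs[inside[, 2]])
}

#' Generate one synthetic field image with ground truth
#'
#' Plants non-overlapping elliptical objects of the classes configured in
#' `params` on a light background, renders them with the stain-model colour
#' palette, and adds Gaussian pixel noise. The paired ground truth records
#' every object (centroid, class, axes in px, mean stain OD) and a label
#' mask with one distinct integer label per object.
#'
#' @param params An [image_sim_params()].
#' @return A list with elements `image` (a [field_image()]) and `truth`
#'   (class `ground_truth`: data frame `objects` + integer `label_mask`).
#' @export
generate_field_image <- function(params = image_sim_params()) {
  stopifnot(inherits(params, "image_sim_params"))
  set.seed(params$seed)
  w <- params$width_px; h <- params$height_px
  ps <- params$pixel_size_um
  cols <- .sim_colors(params$stain_model)

  n_overlap_pairs <- floor(params$n_positive * params$overlap_fraction / 2)
  n_plain_positive <- params$n_positive - 2L * n_overlap_pairs
  spec <- c(
    rep("positive", n_plain_positive),
    rep("overlap_pair", n_overlap_pairs),
    rep("too_large", params$n_large_distractors),
    rep("elongated", params$n_elongated_distractors),
    rep("faint", params$n_faint_distractors),
    rep("edge_touching", params$n_edge_cells),
    rep("melanin", params$n_melanin_granules),
    rep("hematoxylin", params$n_hematoxylin_nuclei)
  )

  placed <- list() # each: cx, cy, r (clearance radius, px)
  objects <- list()
  max_attempts <- 300L

  .clearance_ok <- function(cx, cy, r) {
    for (p in placed) {
      if ((cx - p$cx)^2 + (cy - p$cy)^2 < (r + p$r + 3)^2) return(FALSE)
    }
    TRUE
  }

  for (cls in spec) {
    geom <- .sample_geometry(cls)
    a <- (geom[1] / ps) / 2 # semi-major, px
    b <- a / geom[2]        # semi-minor, px
    phi <- stats::runif(1, 0, pi)
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      if (cls == "edge_touching") {
        side <- sample(4L, 1L)
        depth <- 0.7 * b # centre this far inside: object protrudes past border
        along <- stats::runif(1, a + 2, (if (side <= 2) w else h) - a - 2)
        if (side == 1L) { cx <- along; cy <- depth }
        else if (side == 2L) { cx <- along; cy <- h - depth }
        else if (side == 3L) { cx <- depth; cy <- along }
        else { cx <- w - depth; cy <- along }
        phi <- if (side <= 2) 0 else pi / 2 # major axis along the border
      } else {
        if (w - a - 3 <= a + 3 || h - a - 3 <= a + 3) break
        cx <- stats::runif(1, a + 3, w - a - 3)
        cy <- stats::runif(1, a + 3, h - a - 3)
      }
      if (.clearance_ok(cx, cy, a)) { ok <- TRUE; break }
    }
    if (!ok) {
      stop(
        "generate_field_image(): could not place all requested objects ",
        "without overlap (field overcrowded); reduce counts or enlarge the field"
      )
    }
    placed[[length(placed) + 1L]] <- list(cx = cx, cy = cy, r = a)
    objects[[length(objects) + 1L]] <- list(
      class = if (cls == "overlap_pair") "positive" else cls,
      cx = cx, cy = cy, a = a, b = b, phi = phi
    )
    if (cls == "overlap_pair") { # partner cell touching the first
      geom2 <- .sample_geometry("overlap_pair")
      a2 <- (geom2[1] / ps) / 2; b2 <- a2
      th <- stats::runif(1, 0, 2 * pi)
      d <- 0.95 * (b + b2)
      cx2 <- min(max(cx + d * cos(th), a2 + 3), w - a2 - 3)
      cy2 <- min(max(cy + d * sin(th), a2 + 3), h - a2 - 3)
      placed[[length(placed) + 1L]] <- list(cx = cx2, cy = cy2, r = a2)
      objects[[length(objects) + 1L]] <- list(
        class = "positive", cx = cx2, cy = cy2, a = a2, b = b2,
        phi = stats::runif(1, 0, pi)
      )
    }
  }

  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- cols$background[1]
  img[, , 2] <- cols$background[2]
  img[, , 3] <- cols$background[3]
  label_mask <- matrix(0L, h, w)

  class_color <- function(cls) {
    switch(cls,
      positive = , too_large = , elongated = , edge_touching = cols$strong,
      faint = cols$faint, melanin = cols$melanin, hematoxylin = cols$hematoxylin
    )
  }

  rows <- vector("list", length(objects))
  for (i in seq_along(objects)) {
    o <- objects[[i]]
    pix <- .rasterize_ellipse(o$cx, o$cy, o$a, o$b, o$phi, h, w)
    color <- class_color(o$class)
    if (!is.null(pix)) {
      label_mask[pix] <- i
      for (ch in 1:3) {
        idx <- pix[, 1] + (pix[, 2] - 1L) * h + (ch - 1L) * h * w
        img[idx] <- color[ch]
      }
    }
    rows[[i]] <- data.frame(
      label = i, x = o$cx, y = o$cy, class = o$class,
      major_axis_px = 2 * o$a, minor_axis_px = 2 * o$b,
      mean_stain_od = .color_stain_od(color, params$stain_model)
    )
  }

  if (params$background_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, params$background_noise_sd)
    img[img < 0] <- 0
    img[img > 1] <- 1
  }

  truth <- structure(
    list(
      objects = if (length(rows)) do.call(rbind, rows) else
        data.frame(
          label = integer(0), x = numeric(0), y = numeric(0),
          class = character(0), major_axis_px = numeric(0),
          minor_axis_px = numeric(0), mean_stain_od = numeric(0)
        ),
      label_mask = label_mask
    ),
    class = "ground_truth"
  )
  list(
    image = field_image(img, ps, params$stain_model,
                        id = sprintf("sim_seed%d", params$seed)),
    truth = truth
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", nrow(x$objects), "objects:\n")
  if (nrow(x$objects)) print(table(x$objects$class))
  invisible(x)
}

#' Write ground truth to a JSON sidecar
#'
#' @param truth A `ground_truth` object.
#' @param path Output JSON path (the label mask is not embedded; write it
#'   with [write_field_image()]).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(truth$objects, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
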