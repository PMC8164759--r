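#' Construct a field image
#'
#' One microscope field: RGB pixels in `[0, 1]` plus the physical pixel size.
#' Arrays are indexed `[row (y), column (x), channel]`, matching what
#' [tiff::readTIFF()] returns.
#'
#' @param pixels Numeric array `height x width x 3` with values in `[0, 1]`.
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @param stain_model Stain model the field was acquired under (see
#'   [separate_stain_channels()]).
#' @param id Optional image identifier.
#' @return An object of class `field_image`.
#' @export
field_image <- function(pixels, pixel_size_um, stain_model = "dab_ni_no_counterstain",
                        id = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("pixels must be a height x width x 3 RGB array")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  stain_model <- match.arg(stain_model, STAIN_MODELS)
  structure(
    list(
      pixels = pixels,
      pixel_size_um = pixel_size_um,
      stain_model = stain_model,
      id = id
    ),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<field_image> %s: %d x %d px @ %.3f um/px (%s)\n",
    ifelse(is.na(x$id), "(unnamed)", x$id), d[2], d[1], x$pixel_size_um,
    x$stain_model
  ))
  invisible(x)
}

#' Write a field image (and optional label mask) to disk
#'
#' The RGB image is written as an 8-bit TIFF (or PNG when the path ends in
#' `.png` and the png package is available); a ground-truth label mask, when
#' given, goes to a 16-bit single-channel TIFF next to it.
#'
#' @param image A [field_image()].
#' @param path Output path (`.tif`/`.tiff`/`.png`).
#' @param label_mask Optional integer matrix of object labels.
#' @return `path`, invisibly.
#' @export
write_field_image <- function(image, path, label_mask = NULL) {
  stopifnot(inherits(image, "field_image"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG requires the png package")
    }
    png::writePNG(image$pixels, target = path)
  } else {
    tiff::writeTIFF(image$pixels, path, bits.per.sample = 8L)
  }
  if (!is.null(label_mask)) {
    mask_path <- sub("\\.(tif|tiff|png)$", "_labels.tif", path, ignore.case = TRUE)
    if (max(label_mask) > 65535L) stop("label mask exceeds 16-bit range")
    tiff::writeTIFF(label_mask / 65535, mask_path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a field image from disk
#'
#' @param path TIFF or PNG path.
#' @inheritParams field_image
#' @return A [field_image()].
#' @export
read_field_image <- function(path, pixel_size_um,
                             stain_model = "dab_ni_no_counterstain",
                             id = basename(path)) {
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the png package")
    }
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3] # drop alpha
  field_image(px, pixel_size_um, stain_model, id = id)
}
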