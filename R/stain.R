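#' Stain colour constants and optical-density helpers
#'
#' Brightfield chromogens absorb light, so per-channel optical density
#' OD = -log10(I / I0) is linear in stain amount (Beer-Lambert). Two stain
#' models are supported: nickel-enhanced DAB without counterstain (near-black
#' reaction product, e.g. nuclear FoxP3) and plain DAB over a hematoxylin
#' counterstain (brown cytoplasmic signal over blue nuclei, e.g. IDO).
#'
#' @name stain-models
#' @keywords internal
NULL

STAIN_MODELS <- c("dab_ni_no_counterstain", "dab_with_hematoxylin")

# Ruifrok-Johnston reference absorption vectors (RGB OD space), unit length.
.stain_matrix_h_dab <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  h <- h / sqrt(sum(h^2))
  d <- d / sqrt(sum(d^2))
  r <- c(
    h[2] * d[3] - h[3] * d[2],
    h[3] * d[1] - h[1] * d[3],
    h[1] * d[2] - h[2] * d[1]
  )
  r <- r / sqrt(sum(r^2))
  rbind(hematoxylin = h, dab = d, residual = r)
}

.rgb_to_od <- function(x) -log10(pmax(x, 1 / 255))

#' Separate stain channels of a brightfield RGB field image
#'
#' Converts the image to optical density and returns one OD map per modelled
#' stain. Under `dab_ni_no_counterstain` the DAB-Ni product is a broadband
#' absorber, so the stain map is the mean OD over the three channels. Under
#' `dab_with_hematoxylin` the OD vectors are unmixed by colour deconvolution
#' with the standard hematoxylin/DAB absorption matrix; negative
#' concentrations are clipped to zero.
#'
#' @param image A [field_image()] (RGB array in `[0, 1]`).
#' @param stain_model One of `"dab_ni_no_counterstain"`,
#'   `"dab_with_hematoxylin"`.
#' @return A named list of OD matrices (same height x width as the image)
#'   with attribute `"primary"` naming the channel carrying the chromogen of
#'   interest (`"stain"` or `"dab"`).
#' @examples
#' img <- field_image(array(1, dim = c(20, 30, 3)), pixel_size_um = 0.44)
#' ch <- separate_stain_channels(img, "dab_ni_no_counterstain")
#' max(ch$stain) # ~0: a blank white field carries no stain
#' @export
separate_stain_channels <- function(image, stain_model = image$stain_model) {
  stopifnot(inherits(image, "field_image"))
  stain_model <- match.arg(stain_model, STAIN_MODELS)
  px <- image$pixels
  if (length(dim(px)) != 3L || dim(px)[3] != 3L) {
    stop("separate_stain_channels() requires an RGB image (h x w x 3 array)")
  }
  od <- .rgb_to_od(px)
  if (stain_model == "dab_ni_no_counterstain") {
    out <- list(stain = (od[, , 1] + od[, , 2] + od[, , 3]) / 3)
    attr(out, "primary") <- "stain"
  } else {
    m <- .stain_matrix_h_dab()
    odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
    conc <- odm %*% solve(m) # rows: pixels; cols: hematoxylin, dab, residual
    conc[conc < 0] <- 0
    dims <- dim(px)[1:2]
    out <- list(
      hematoxylin = matrix(conc[, 1], dims[1], dims[2]),
      dab = matrix(conc[, 2], dims[1], dims[2])
    )
    attr(out, "primary") <- "dab"
  }
  class(out) <- "stain_od"
  out
}

#' @export
print.stain_od <- function(x, ...) {
  cat("<stain_od> channels:", paste(names(x), collapse = ", "),
      "| primary:", attr(x, "primary"), "\n")
  invisible(x)
}

primary_od <- function(channels) channels[[attr(channels, "primary")]]
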