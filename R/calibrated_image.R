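#' Construct a calibrated grayscale image
#'
#' Wraps a matrix of non-negative pixel intensities with its spatial
#' calibration and section metadata. The pixel grid is indexed
#' \code{[row, col]} with the origin at the top-left corner and y increasing
#' downwards; the centre of pixel \code{[r, c]} sits at
#' \code{((c - 0.5), (r - 0.5)) * pixel_size_um} in micrometres.
#'
#' @param pixels numeric matrix of non-negative intensities (arbitrary stain
#'   units).
#' @param pixel_size_um micrometres per pixel (isotropic), > 0.
#' @param stain one of \code{"GFAP"}, \code{"NeuN"}, \code{"other"}.
#' @param section_id,animal_id,group free-text metadata carried through to
#'   profiles.
#' @return An object of class \code{calibrated_image}.
#' @export
calibrated_image <- function(pixels, pixel_size_um, stain = "other",
                             section_id = NA_character_,
                             animal_id = NA_character_,
                             group = NA_character_) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixel intensities must be finite and non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  stain <- match.arg(stain, c("GFAP", "NeuN", "other"))
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um, stain = stain,
         section_id = section_id, animal_id = animal_id, group = group),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px @ %g um/px, stain=%s, section=%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$stain,
              x$section_id))
  invisible(x)
}

#' Apply a stain-polarity transform
#'
#' Bright-field DAB chemistry renders signal dark on a light background, so
#' "more stain" means lower grey values; fluorescence-like images are the
#' opposite. All measurements in this package are taken on signal-bright
#' images; \code{polarity = "invert"} maps an image to
#' \code{max(pixels) - pixels} beforehand.
#'
#' @param image a \code{\link{calibrated_image}}.
#' @param polarity \code{"as-is"} (signal already bright) or \code{"invert"}.
#' @return A \code{calibrated_image} with transformed pixels.
#' @export
apply_polarity <- function(image, polarity = c("as-is", "invert")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(image, "calibrated_image"))
  if (polarity == "invert")
    image$pixels <- max(image$pixels) - image$pixels
  image
}

# x/y coordinates (um) of pixel centres for an nr x nc grid
pixel_centers <- function(nr, nc, pixel_size_um) {
  list(x = (seq_len(nc) - 0.5) * pixel_size_um,
       y = (seq_len(nr) - 0.5) * pixel_size_um)
}
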