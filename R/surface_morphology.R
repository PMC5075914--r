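#' Area-ratio surface roughness of a height map
#'
#' Computes the ratio of the measured (3-D) surface area to the projected
#' (planar) area, the standard AFM roughness factor: 1.0 for a flat
#' horizontal surface, larger for any relief. Each grid quad is split into
#' two triangles along the same diagonal (top-left to bottom-right) and the
#' triangle areas are summed; the projected area is
#' \code{(rows - 1) * (cols - 1) * step^2}.
#'
#' @param hm a \code{\link{generate_height_map}} object, or a numeric
#'   matrix of heights in nm (then \code{lateral_step_nm} is required).
#' @param lateral_step_nm lateral grid step in nm (ignored when \code{hm}
#'   is a \code{height_map}).
#' @return Dimensionless ratio >= 1.
#' @export
roughness_ratio <- function(hm, lateral_step_nm = NULL) {
  if (inherits(hm, "height_map")) {
    z <- hm$heights; step <- hm$lateral_step_nm
  } else {
    z <- hm; step <- lateral_step_nm
    if (is.null(step)) stop("`lateral_step_nm` is required for a bare matrix")
  }
  if (!is.matrix(z) || nrow(z) < 2L || ncol(z) < 2L)
    stop("height map must be at least 2 x 2")
  if (any(!is.finite(z))) stop("height map contains non-finite values")

  nr <- nrow(z); nc <- ncol(z)
  z00 <- z[-nr, -nc]; z01 <- z[-nr, -1]
  z10 <- z[-1, -nc];  z11 <- z[-1, -1]
  # triangle (00, 01, 11): cross product of (step, 0, z01-z00), (step, step, z11-z00)
  a1 <- 0.5 * sqrt((-step * (z01 - z00))^2 +
                   (step * (z01 - z00) - step * (z11 - z00))^2 +
                   (step * step)^2)
  # triangle (00, 11, 10): edges (step, step, z11-z00), (0, step, z10-z00)
  a2 <- 0.5 * sqrt((step * (z11 - z00) - step * (z10 - z00))^2 +
                   (-step * (z10 - z00))^2 +
                   (step * step)^2)
  measured <- sum(a1) + sum(a2)
  projected <- (nr - 1) * (nc - 1) * step^2
  measured / projected
}

#' Pillar density of a nanostructured surface
#'
#' Counts spot-like local maxima (pillar apexes) in a height map or
#' top-view image and normalizes to the analyzed area in um^2, mirroring
#' the SEM spot-counting procedure for black-Si surfaces.
#'
#' @param x a \code{height_map}, a \code{\link{calibrated_image}}, or a
#'   numeric matrix (then \code{lateral_step_nm} is required).
#' @param lateral_step_nm grid step in nm for bare matrices.
#' @param threshold_frac candidate maxima must rise above
#'   \code{min + threshold_frac * (max - min)} of the map (default 0.2).
#' @param min_separation_nm non-maximum-suppression radius; defaults to
#'   3 grid steps.
#' @return An object of class \code{pillar_measurements}: list with
#'   \code{count}, \code{density_per_um2}, \code{counting_area_um2},
#'   \code{centers_nm}.
#' @export
pillar_density <- function(x, lateral_step_nm = NULL, threshold_frac = 0.2,
                           min_separation_nm = NULL) {
  if (inherits(x, "height_map")) {
    z <- x$heights; step <- x$lateral_step_nm
  } else if (inherits(x, "calibrated_image")) {
    z <- x$pixels; step <- x$pixel_size_um * 1000
  } else {
    z <- x; step <- lateral_step_nm
    if (is.null(step)) stop("`lateral_step_nm` is required for a bare matrix")
  }
  area_um2 <- nrow(z) * ncol(z) * (step / 1000)^2
  if (area_um2 < 0.25)
    stop("field of view below 0.25 um^2 is too small for density estimation")
  if (area_um2 <= 0) stop("zero analyzable area")
  sep <- min_separation_nm %||% (3 * step)
  pk <- find_peaks_2d(z, threshold = min(z) + threshold_frac * (max(z) - min(z)),
                      min_sep_px = sep / step)
  centers <- cbind(x_nm = (pk$col - 0.5) * step, y_nm = (pk$row - 0.5) * step)
  structure(list(count = nrow(centers),
                 density_per_um2 = nrow(centers) / area_um2,
                 counting_area_um2 = area_um2, centers_nm = centers),
            class = "pillar_measurements")
}

# Local maxima of a matrix: strict-or-equal max of the 3x3 neighbourhood,
# above `threshold`, then greedy non-maximum suppression by descending
# height within `min_sep_px`.
find_peaks_2d <- function(z, threshold, min_sep_px) {
  nr <- nrow(z); nc <- ncol(z)
  if (max(z) == min(z))
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- z
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    is_max <- is_max & (z >= nb)
  }
  cand <- which(is_max & z > threshold)
  if (!length(cand))
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  rows <- (cand - 1L) %% nr + 1L
  cols <- (cand - 1L) %/% nr + 1L
  vals <- z[cand]
  o <- order(-vals, rows, cols)
  rows <- rows[o]; cols <- cols[o]; vals <- vals[o]
  keep <- logical(length(rows))
  for (i in seq_along(rows)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    ki <- which(keep[seq_len(i - 1L)])
    d2 <- (rows[ki] - rows[i])^2 + (cols[ki] - cols[i])^2
    keep[i] <- all(d2 > min_sep_px^2)
  }
  data.frame(row = rows[keep], col = cols[keep], value = vals[keep])
}

#' Tilt-corrected pillar heights from annotated cross-section segments
#'
#' Converts annotated base-to-tip segments measured on a tilted
#' cross-sectional micrograph into true pillar heights. Because the exact
#' geometric conversion depends on the imaging convention, the correction
#' factor is supplied explicitly (default 1, i.e. a pure side view at 90
#' degrees) and recorded in the output.
#'
#' @param segment_endpoints data.frame/matrix with columns \code{x0, y0,
#'   x1, y1} in pixels (base and tip).
#' @param pixel_size_nm nm per pixel.
#' @param tilt_deg stage tilt in (0, 90].
#' @param correction_factor multiplicative apparent-to-true factor (> 0).
#' @return An object of class \code{pillar_heights}: list with
#'   \code{heights_nm}, \code{apparent_nm}, \code{tilt_deg},
#'   \code{correction_factor}.
#' @export
pillar_height <- function(segment_endpoints, pixel_size_nm, tilt_deg = 10,
                          correction_factor = 1) {
  seg <- as.data.frame(segment_endpoints)
  stopifnot(all(c("x0", "y0", "x1", "y1") %in% names(seg)),
            pixel_size_nm > 0, correction_factor > 0)
  if (tilt_deg <= 0 || tilt_deg > 90)
    stop("`tilt_deg` must lie in (0, 90]")
  len_px <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2)
  if (any(len_px == 0)) stop("zero-length segment in annotations")
  apparent <- len_px * pixel_size_nm
  structure(list(heights_nm = apparent * correction_factor,
                 apparent_nm = apparent, tilt_deg = tilt_deg,
                 correction_factor = correction_factor,
                 convention = "true = apparent * correction_factor"),
            class = "pillar_heights")
}
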