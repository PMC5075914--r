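#' Per-band, per-face mean stain intensity
#'
#' Averages pixel intensity over every (band, face) region of the band map
#' and normalizes each face's profile to its background zone — the
#' outermost 100 um (400-500 um with the default banding), treated as
#' unaffected tissue. Band/face combinations with no analyzable pixels are
#' flagged \code{missing} rather than reported as zero.
#'
#' @param image a \code{\link{calibrated_image}} (GFAP-like stain).
#' @param band_map a face-assigned \code{\link{compute_band_map}} result.
#' @param polarity \code{"as-is"} or \code{"invert"}; bright-field DAB
#'   images must be inverted so that more stain means larger values.
#' @param background_zone_um numeric length-2; must align to band
#'   boundaries. Default: the outermost two bands.
#' @param normalize \code{"per-face"} (default: each face normalized by its
#'   own background, removing face-level illumination bias) or
#'   \code{"global"} (one pooled background per section).
#' @return A data.frame of class \code{gb_profile} with one row per
#'   (band, face): columns \code{kind, section_id, group, face, band,
#'   band_lo_um, band_hi_um, raw, n_pixels, area_mm2, count, normalized,
#'   missing}. Attributes record the background zone, normalization mode
#'   and per-face background values.
#' @export
intensity_profile <- function(image, band_map,
                              polarity = c("as-is", "invert"),
                              background_zone_um = NULL,
                              normalize = c("per-face", "global")) {
  stopifnot(inherits(image, "calibrated_image"), inherits(band_map, "band_map"))
  if (!all(dim(image$pixels) == dim(band_map$band_index)))
    stop("image and band map dimensions differ")
  normalize <- match.arg(normalize)
  image <- apply_polarity(image, match.arg(polarity))
  measure_profile(values = image$pixels, band_map = band_map,
                  kind = "intensity",
                  background_zone_um = background_zone_um,
                  normalize = normalize, section_id = image$section_id,
                  group = image$group,
                  pixel_size_um = band_map$pixel_size_um)
}

#' Per-band, per-face neuron density
#'
#' Counts annotated nuclei per (band, face) region and divides by the
#' region's analyzable area to obtain neurons/mm^2, then normalizes each
#' face to its background zone. Each point is assigned the band and face of
#' the pixel containing it, so counts and areas share one discretization.
#' Points falling inside the track, on excluded pixels, or outside the
#' image are tallied as \code{unassigned} (attribute), never silently
#' dropped.
#'
#' @param detections a \code{\link{cell_detections}} object or data.frame
#'   with columns \code{x_um}, \code{y_um}.
#' @inheritParams intensity_profile
#' @return A \code{gb_profile} data.frame (kind \code{"density"}); the
#'   \code{count} column holds per-region nucleus counts and
#'   \code{attr(, "unassigned")} the out-of-region tally.
#' @export
density_profile <- function(detections, band_map,
                            background_zone_um = NULL,
                            normalize = c("per-face", "global")) {
  stopifnot(inherits(band_map, "band_map"))
  normalize <- match.arg(normalize)
  pts <- as.data.frame(detections)
  stopifnot(all(c("x_um", "y_um") %in% names(pts)))
  px <- band_map$pixel_size_um
  nr <- nrow(band_map$band_index); nc <- ncol(band_map$band_index)

  col <- floor(pts$x_um / px) + 1L
  row <- floor(pts$y_um / px) + 1L
  in_img <- row >= 1L & row <= nr & col >= 1L & col <= nc
  band <- rep(NA_integer_, nrow(pts))
  face <- rep(NA_character_, nrow(pts))
  ii <- which(in_img)
  lin <- (col[ii] - 1L) * nr + row[ii]
  band[ii] <- band_map$band_index[lin]
  face[ii] <- band_map$face[lin]
  assigned <- !is.na(band) & band >= 0L & !is.na(face)

  prof <- measure_profile(values = NULL, band_map = band_map,
                          kind = "density",
                          background_zone_um = background_zone_um,
                          normalize = normalize,
                          section_id = attr(detections, "section_id") %||%
                            NA_character_,
                          group = NA_character_, pixel_size_um = px,
                          point_band = band[assigned],
                          point_face = face[assigned])
  attr(prof, "unassigned") <- sum(!assigned)
  attr(prof, "n_points") <- nrow(pts)
  attr(prof, "provenance") <- attr(detections, "provenance") %||% "manual"
  prof
}

# Shared engine: region bookkeeping, raw measurement, background
# normalization, missing flags.
measure_profile <- function(values, band_map, kind, background_zone_um,
                            normalize, section_id, group, pixel_size_um,
                            point_band = NULL, point_face = NULL) {
  bw <- band_map$band_width_um
  if (is.null(background_zone_um))
    background_zone_um <- c(band_map$max_distance_um - 2 * bw,
                            band_map$max_distance_um)
  bz <- background_zone_um
  if (bz[1] %% bw != 0 || bz[2] %% bw != 0 || bz[2] <= bz[1] ||
      bz[2] > band_map$max_distance_um)
    stop("background zone must align to whole band intervals within range")
  bg_bands <- seq(bz[1] / bw, bz[2] / bw - 1)

  sel <- which(!is.na(band_map$band_index) & band_map$band_index >= 0L &
                 !is.na(band_map$face))
  band_px <- band_map$band_index[sel]
  face_px <- band_map$face[sel]
  faces <- sort(unique(face_px))
  ivals <- band_intervals(band_map)

  grid <- expand.grid(band = ivals$band, face = faces,
                      stringsAsFactors = FALSE)
  key_px <- paste(band_px, face_px)
  key_grid <- paste(grid$band, grid$face)
  npx <- table(key_px)
  grid$n_pixels <- as.integer(npx[key_grid])
  grid$n_pixels[is.na(grid$n_pixels)] <- 0L
  grid$area_mm2 <- grid$n_pixels * pixel_size_um^2 * 1e-6

  if (kind == "intensity") {
    mval <- tapply(values[sel], key_px, mean)
    grid$raw <- as.numeric(mval[key_grid])
    grid$count <- NA_integer_
    bg_raw_for <- function(face_filter) {
      s <- band_px %in% bg_bands & face_filter
      if (!any(s)) return(NA_real_)
      mean(values[sel][s])
    }
  } else {
    key_pt <- paste(point_band, point_face)
    cnt <- table(key_pt)
    grid$count <- as.integer(cnt[key_grid])
    grid$count[is.na(grid$count)] <- 0L
    grid$raw <- ifelse(grid$area_mm2 > 0, grid$count / grid$area_mm2,
                       NA_real_)
    bg_raw_for <- function(face_filter) {
      s_px <- band_px %in% bg_bands & face_filter
      area <- sum(s_px) * pixel_size_um^2 * 1e-6
      if (area <= 0) return(NA_real_)
      if (identical(face_filter, TRUE) || all(face_filter)) {
        n <- sum(point_band %in% bg_bands)
      } else {
        fl <- unique(face_px[face_filter])
        n <- sum(point_band %in% bg_bands & point_face %in% fl)
      }
      n / area
    }
  }
  grid$missing <- grid$n_pixels == 0L | !is.finite(grid$raw)
  grid$raw[grid$missing] <- NA_real_

  if (normalize == "per-face") {
    bg <- vapply(faces, function(f) bg_raw_for(face_px == f), numeric(1))
    names(bg) <- faces
    grid$background <- as.numeric(bg[grid$face])
  } else {
    bgv <- bg_raw_for(rep(TRUE, length(face_px)))
    bg <- setNames(rep(bgv, length(faces)), faces)
    grid$background <- bgv
  }
  grid$normalized <- ifelse(!grid$missing & is.finite(grid$background) &
                              grid$background > 0,
                            grid$raw / grid$background, NA_real_)

  out <- data.frame(kind = kind, section_id = section_id, group = group,
                    face = grid$face, band = grid$band,
                    band_lo_um = ivals$lo_um[grid$band + 1L],
                    band_hi_um = ivals$hi_um[grid$band + 1L],
                    raw = grid$raw, n_pixels = grid$n_pixels,
                    area_mm2 = grid$area_mm2, count = grid$count,
                    normalized = grid$normalized, missing = grid$missing,
                    stringsAsFactors = FALSE)
  out <- out[order(out$face, out$band), ]
  rownames(out) <- NULL
  class(out) <- c("gb_profile", "data.frame")
  attr(out, "kind") <- kind
  attr(out, "background_zone_um") <- bz
  attr(out, "normalize") <- normalize
  attr(out, "background_values") <- bg
  attr(out, "non_normalizable") <- all(!is.finite(grid$background) |
                                         grid$background <= 0)
  out
}

#' Container for nucleus point annotations
#'
#' @param points data.frame with columns \code{x_um}, \code{y_um}.
#' @param provenance \code{"manual"} (expert counts, the primary input) or
#'   \code{"auto"} (from \code{\link{detect_nuclei}}).
#' @param section_id section identifier.
#' @export
cell_detections <- function(points, provenance = c("manual", "auto"),
                            section_id = NA_character_) {
  provenance <- match.arg(provenance)
  pts <- as.data.frame(points)
  if (!all(c("x_um", "y_um") %in% names(pts)))
    stop("`points` needs columns x_um, y_um")
  if (nrow(pts) && any(!is.finite(pts$x_um) | !is.finite(pts$y_um)))
    stop("non-finite coordinates in detections")
  pts <- pts[order(pts$y_um, pts$x_um), c("x_um", "y_um"), drop = FALSE]
  rownames(pts) <- NULL
  structure(pts, provenance = provenance, section_id = section_id,
            class = c("cell_detections", "data.frame"))
}

#' Automated nucleus detection by scale-space blob search
#'
#' Multi-scale difference-of-Gaussian blob detection for NeuN-like images
#' where nuclei appear as bright, roughly Gaussian spots. Candidate maxima
#' above a response threshold are kept greedily from strongest to weakest
#' with a minimum mutual separation. Manual annotations remain the
#' recommended primary input on real bright-field material, where staining
#' artefacts defeat automated counting; this detector is reliable on clean,
#' well-separated spots.
#'
#' @param image a \code{\link{calibrated_image}} with signal-bright nuclei
#'   (apply \code{\link{apply_polarity}} first for DAB material).
#' @param min_sigma_um,max_sigma_um blob scale range in um
#'   (\code{min < max}).
#' @param n_scales number of scales spanning the range geometrically.
#' @param threshold minimum normalized DoG response in units of the image
#'   maximum (default 0.02).
#' @return A \code{\link{cell_detections}} object (provenance
#'   \code{"auto"}), sorted by y then x.
#' @export
detect_nuclei <- function(image, min_sigma_um = 1.2, max_sigma_um = 4,
                          n_scales = 4, threshold = 0.02) {
  stopifnot(inherits(image, "calibrated_image"))
  if (min_sigma_um >= max_sigma_um)
    stop("`min_sigma_um` must be smaller than `max_sigma_um`")
  px <- image$pixel_size_um
  img <- image$pixels
  mx <- max(img)
  empty <- cell_detections(data.frame(x_um = numeric(), y_um = numeric()),
                           provenance = "auto",
                           section_id = image$section_id)
  if (mx <= 0 || mx == min(img)) return(empty)
  img <- img / mx

  sig_px <- exp(seq(log(min_sigma_um / px), log(max_sigma_um / px),
                    length.out = n_scales + 1L))
  blurred <- lapply(sig_px, function(s)
    as.matrix(EBImage::gblur(img, sigma = s)))
  cands <- list()
  for (i in seq_len(n_scales)) {
    dog <- blurred[[i]] - blurred[[i + 1L]]
    pk <- find_peaks_2d(dog, threshold = threshold,
                        min_sep_px = max(1, sig_px[i]))
    if (nrow(pk)) {
      pk$sigma_px <- sig_px[i]
      cands[[length(cands) + 1L]] <- pk
    }
  }
  if (!length(cands)) return(empty)
  cand <- do.call(rbind, cands)
  o <- order(-cand$value, cand$row, cand$col)
  cand <- cand[o, ]
  keep <- logical(nrow(cand))
  min_sep <- max(1.5, min(sig_px))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    ki <- which(keep)
    d2 <- (cand$row[ki] - cand$row[i])^2 + (cand$col[ki] - cand$col[i])^2
    keep[i] <- all(d2 > (2 * min_sep)^2)
  }
  cand <- cand[keep, ]
  cell_detections(data.frame(x_um = (cand$col - 0.5) * px,
                             y_um = (cand$row - 0.5) * px),
                  provenance = "auto", section_id = image$section_id)
}

#' Pool profiles across sections into per-(band, group) samples
#'
#' Collects the per-section normalized values into the long-format samples
#' the statistical module consumes, plus a summary table (mean, SD, n) per
#' band and group. The grouping unit follows the study design: one value
#' per (section, face) per band, with the face label as the group.
#'
#' @param profiles list of \code{gb_profile} objects of one kind.
#' @param value which column to pool (default \code{"normalized"}).
#' @return An object of class \code{gb_aggregate}: list with
#'   \code{samples} (section_id, group, band, band_lo_um, band_hi_um,
#'   value) and \code{summary} (band, group, mean, sd, n, n1_flag).
#' @export
aggregate_profiles <- function(profiles, value = "normalized") {
  if (inherits(profiles, "gb_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L)
  kinds <- vapply(profiles, function(p) attr(p, "kind"), character(1))
  if (length(unique(kinds)) != 1L)
    stop("cannot aggregate profiles of mixed kinds (",
         paste(unique(kinds), collapse = ", "), ")")
  usable <- !vapply(profiles, function(p)
    isTRUE(attr(p, "non_normalizable")), logical(1))
  if (!all(usable))
    warning(sum(!usable), " profile(s) non-normalizable (no measurable ",
            "background zone); excluded from aggregation")
  profiles <- profiles[usable]
  if (!length(profiles)) stop("no normalizable profiles to aggregate")

  samples <- do.call(rbind, lapply(profiles, function(p) {
    d <- as.data.frame(p)[, c("section_id", "face", "band", "band_lo_um",
                              "band_hi_um", value, "missing")]
    names(d)[6] <- "value"
    d <- d[!d$missing & is.finite(d$value), ]
    d$group <- d$face
    d[, c("section_id", "group", "band", "band_lo_um", "band_hi_um",
          "value")]
  }))
  rownames(samples) <- NULL

  agg <- aggregate(value ~ band + group, data = samples,
                   FUN = function(v) c(mean = mean(v),
                                       sd = if (length(v) > 1) sd(v) else 0,
                                       n = length(v)))
  summary <- data.frame(band = agg$band, group = agg$group,
                        mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                        n = as.integer(agg$value[, "n"]))
  summary$n1_flag <- summary$n == 1L
  summary <- summary[order(summary$group, summary$band), ]
  rownames(summary) <- NULL
  structure(list(samples = samples, summary = summary,
                 kind = kinds[1], value = value),
            class = "gb_aggregate")
}

#' @export
print.gb_aggregate <- function(x, ...) {
  cat(sprintf("<gb_aggregate> kind=%s, %d samples, %d (band, group) cells\n",
              x$kind, nrow(x$samples), nrow(x$summary)))
  invisible(x)
}

#' Fit the scar decay model to per-band profile means
#'
#' Fits \code{normalized(d) = 1 + A * exp(-d / tau)} to per-band mean
#' normalized values at the band-centre distances, by Levenberg-Marquardt
#' least squares. Used to check that the analysis recovers the generator's
#' amplitude and decay length.
#'
#' @param band_centers_um numeric, band-centre distances in um.
#' @param values mean normalized values per band.
#' @param start optional list with \code{A}, \code{tau_um}.
#' @return list with \code{A}, \code{tau_um}, and the \code{nls} fit.
#' @export
fit_decay_profile <- function(band_centers_um, values, start = NULL) {
  stopifnot(length(band_centers_um) == length(values),
            length(values) >= 3L)
  st <- start %||% list(A = max(values) - 1, tau_um = 100)
  fit <- minpack.lm::nlsLM(
    values ~ 1 + A * exp(-band_centers_um / tau_um),
    start = st,
    lower = c(A = 0, tau_um = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  list(A = unname(cf["A"]), tau_um = unname(cf["tau_um"]), fit = fit)
}
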