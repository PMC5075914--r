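#' Gliosis intensity model for synthetic sections
#'
#' Expected stain intensity at distance \code{d} from the track on face
#' \code{f} is \code{background * (1 + A_f * exp(-d / decay_length))}: a
#' strong glial scar at the track falling off smoothly to the background by
#' 400-500 um. Face-specific amplitudes emulate small (few percent)
#' side-to-side differences in scar severity; the default gives the
#' nanostructured face a slightly weaker scar than the other three surfaces.
#' The exponential form is a modelling choice for validation, not a claim
#' about real tissue.
#'
#' @param background_intensity background stain level (grayscale units), > 0.
#' @param scar_amplitude_per_face named non-negative multipliers, one per
#'   face label (\code{A_f}).
#' @param decay_length_um scar decay length in um, > 0.
#' @param noise_sd additive Gaussian pixel noise (stain units).
#' @param polarity \code{"stain-bright"} (signal = intensity, default) or
#'   \code{"stain-dark"} (bright-field DAB-like; the image is flipped about
#'   a recorded white level).
#' @return An object of class \code{gliosis_model}.
#' @export
gliosis_model <- function(background_intensity = 100,
                          scar_amplitude_per_face = c(
                            nanoSi = 0.85, flatSi = 1.0, microSi = 1.0,
                            "micro-polymer" = 1.0),
                          decay_length_um = 100,
                          noise_sd = 5,
                          polarity = c("stain-bright", "stain-dark")) {
  polarity <- match.arg(polarity)
  stopifnot(background_intensity > 0, decay_length_um > 0, noise_sd >= 0)
  if (any(scar_amplitude_per_face < 0)) stop("amplitudes must be >= 0")
  if (!all(FACE_LABELS %in% names(scar_amplitude_per_face)))
    stop("`scar_amplitude_per_face` must name all four face labels")
  structure(list(background_intensity = background_intensity,
                 scar_amplitude_per_face = scar_amplitude_per_face,
                 decay_length_um = decay_length_um, noise_sd = noise_sd,
                 polarity = polarity),
            class = "gliosis_model")
}

#' Neuron point-field model for synthetic sections
#'
#' Nuclei form an inhomogeneous Poisson process with intensity
#' \code{baseline * (1 - B_f * g(d))} outside the track (zero inside), where
#' \code{g} is either \code{exp(-d / depletion_length)}
#' (\code{depletion_shape = "exponential"}) or a step that is 1 for
#' \code{d < depletion_length} and 0 beyond (\code{"step"}, used for
#' band-limited effects). This emulates the marked neuronal loss confined to
#' roughly the first 50-100 um around an implant. Accepted nuclei are
#' rendered as Gaussian bright spots.
#'
#' @param baseline_density neurons per mm^2 far from the track, > 0.
#' @param depletion_fraction_per_face named fractions in [0, 1]
#'   (\code{B_f}); the default makes loss worst at the micro-polymer face
#'   and mildest at the nanostructured face.
#' @param depletion_length_um depletion length scale in um.
#' @param nucleus_radius_um nominal nucleus radius (um), used for rendering.
#' @param render_sd_um Gaussian sd of the rendered spot (um).
#' @param depletion_shape \code{"exponential"} or \code{"step"}.
#' @return An object of class \code{neuron_field_model}.
#' @export
neuron_field_model <- function(baseline_density = 1000,
                               depletion_fraction_per_face = c(
                                 nanoSi = 0.5, flatSi = 0.7, microSi = 0.75,
                                 "micro-polymer" = 0.85),
                               depletion_length_um = 75,
                               nucleus_radius_um = 4,
                               render_sd_um = 2,
                               depletion_shape = c("exponential", "step")) {
  depletion_shape <- match.arg(depletion_shape)
  stopifnot(baseline_density > 0, depletion_length_um > 0,
            nucleus_radius_um > 0, render_sd_um > 0)
  if (any(depletion_fraction_per_face < 0 | depletion_fraction_per_face > 1))
    stop("depletion fractions must lie in [0, 1]")
  if (!all(FACE_LABELS %in% names(depletion_fraction_per_face)))
    stop("`depletion_fraction_per_face` must name all four face labels")
  structure(list(baseline_density = baseline_density,
                 depletion_fraction_per_face = depletion_fraction_per_face,
                 depletion_length_um = depletion_length_um,
                 nucleus_radius_um = nucleus_radius_um,
                 render_sd_um = render_sd_um,
                 depletion_shape = depletion_shape),
            class = "neuron_field_model")
}

depletion_g <- function(d, model) {
  switch(model$depletion_shape,
         exponential = exp(-d / model$depletion_length_um),
         step = as.numeric(d < model$depletion_length_um))
}

#' Generate one synthetic calibrated section with ground truth
#'
#' Renders a GFAP-like intensity image and a NeuN-like nucleus image around
#' a rectangular track with labelled faces, together with the analytic
#' expectations ("truth profiles") that the analysis pipeline should
#' recover. The analytic distance used for both models is the Euclidean
#' distance from each pixel centre (or nucleus position) to the track
#' polygon boundary, with faces taken from the nearest edge.
#'
#' @param gliosis a \code{\link{gliosis_model}}.
#' @param neurons a \code{\link{neuron_field_model}}.
#' @param track_spec list: \code{width_um}, \code{height_um} (default
#'   180 x 380), and \code{face_labels} as in \code{\link{rect_track}}.
#' @param image_spec list: \code{pixel_size_um} (default 2) and
#'   \code{margin_um} — tissue margin around the track, scalar or named
#'   (top/right/bottom/left), each at least 500 um so the full band range
#'   fits (default 520).
#' @param seed integer; the whole section is a deterministic function of it.
#' @param band_width_um,max_distance_um banding used for the truth profiles.
#' @param layer_rows_um optional numeric length-2 (y-range in um): restrict
#'   the exported layer mask to this horizontal stripe; default full image.
#' @param render_images if FALSE, skip pixel rendering and return NULL
#'   images; the point field, geometry and truth profiles are still
#'   produced (useful for large point-process simulation studies).
#' @return An object of class \code{synthetic_section}: list with
#'   \code{gfap_image}, \code{neun_image} (\code{\link{calibrated_image}}),
#'   \code{truth_track} (\code{\link{track_geometry}}), \code{truth_points}
#'   (data.frame \code{x_um}, \code{y_um}), \code{truth_profiles}
#'   (data.frame of analytic per-band, per-face expectations),
#'   \code{layer_mask}, \code{band_map}, \code{seed}, and the two models.
#' @export
generate_section <- function(gliosis = gliosis_model(),
                             neurons = neuron_field_model(),
                             track_spec = list(),
                             image_spec = list(),
                             seed = 1L,
                             band_width_um = 50, max_distance_um = 500,
                             layer_rows_um = NULL, render_images = TRUE) {
  stopifnot(inherits(gliosis, "gliosis_model"),
            inherits(neurons, "neuron_field_model"))
  ts <- modifyList(list(width_um = 180, height_um = 380,
                        face_labels = c(top = "micro-polymer",
                                        right = "nanoSi",
                                        bottom = "microSi",
                                        left = "flatSi")),
                   track_spec)
  is_ <- modifyList(list(pixel_size_um = 2, margin_um = 520), image_spec)
  margins <- is_$margin_um
  if (length(margins) == 1L)
    margins <- c(top = margins, right = margins, bottom = margins,
                 left = margins)
  short <- names(margins)[margins < max_distance_um]
  if (length(short))
    stop(sprintf("margin on the %s side (%g um) is smaller than the %g um analysis range (face %s)",
                 short[1], margins[[short[1]]], max_distance_um,
                 ts$face_labels[[short[1]]]))

  px <- is_$pixel_size_um
  width_um <- ts$width_um + margins[["left"]] + margins[["right"]]
  height_um <- ts$height_um + margins[["top"]] + margins[["bottom"]]
  nc <- as.integer(ceiling(width_um / px))
  nr <- as.integer(ceiling(height_um / px))
  center <- c(margins[["left"]] + ts$width_um / 2,
              margins[["top"]] + ts$height_um / 2)
  track <- rect_track(ts$width_um, ts$height_um, center_um = center,
                      face_labels = ts$face_labels)

  mask <- rasterize_track(track, list(dim = c(nr, nc), pixel_size_um = px))
  layer_mask <- matrix(TRUE, nr, nc)
  if (!is.null(layer_rows_um)) {
    yc <- (seq_len(nr) - 0.5) * px
    layer_mask[yc < layer_rows_um[1] | yc >= layer_rows_um[2], ] <- FALSE
  }
  bm <- compute_band_map(mask, px, band_width_um, max_distance_um,
                         analysis_mask = layer_mask)
  bm <- assign_faces(bm, track)

  # analytic distance/face for every exterior pixel centre (also beyond the
  # banded range, so the whole image gets a sensible expectation)
  ext <- which(!mask)
  rows <- (ext - 1L) %% nr + 1L
  cols <- (ext - 1L) %/% nr + 1L
  pxc <- (cols - 0.5) * px
  pyc <- (rows - 0.5) * px
  ne <- nearest_edge(pxc, pyc, track$polygon)
  face_all <- track$edge_faces[ne$edge]

  A <- gliosis$scar_amplitude_per_face[face_all]
  # the explant void carries no tissue; it is rendered at the unstained
  # background level so measurements on track pixels (never taken) are inert
  expect_gfap <- matrix(gliosis$background_intensity, nr, nc)
  expect_gfap[ext] <- gliosis$background_intensity *
    (1 + A * exp(-ne$distance_um / gliosis$decay_length_um))

  sec <- with_local_seed(seed, {
    pts <- sample_neuron_field(neurons, track,
                               width_um = nc * px, height_um = nr * px,
                               seed = NULL)
    if (!render_images) {
      list(gfap = NULL, neun = NULL, pts = pts)
    } else {
      gfap <- expect_gfap +
        matrix(rnorm(nr * nc, 0, gliosis$noise_sd), nr, nc)
      if (gliosis$polarity == "stain-dark") {
        white <- gliosis$background_intensity *
          (1 + max(gliosis$scar_amplitude_per_face)) * 1.05
        gfap <- white - gfap
      }
      gfap <- pmax(gfap, 0)
      neun <- render_points_image(pts, nr, nc, px,
                                  sd_um = neurons$render_sd_um,
                                  amplitude = 100, background = 10,
                                  noise_sd = 2)
      list(gfap = gfap, neun = neun, pts = pts)
    }
  })

  truth <- analytic_truth_profiles(bm, gliosis, neurons, expect_gfap,
                                   ne, ext, face_all)

  sid <- sprintf("synth-%d", seed)
  structure(list(
    gfap_image = if (render_images)
      calibrated_image(sec$gfap, px, stain = "GFAP", section_id = sid),
    neun_image = if (render_images)
      calibrated_image(sec$neun, px, stain = "NeuN", section_id = sid),
    truth_track = track, truth_points = sec$pts,
    truth_profiles = truth, layer_mask = layer_mask, band_map = bm,
    seed = as.integer(seed), gliosis = gliosis, neurons = neurons),
    class = "synthetic_section")
}

#' Sample a peri-implant neuron point field
#'
#' Draws one realization of the inhomogeneous Poisson nucleus process of a
#' \code{\link{neuron_field_model}} over a \code{width_um} x
#' \code{height_um} tissue rectangle containing a labelled track: a
#' homogeneous Poisson field at the baseline density is thinned by the
#' face- and distance-dependent depletion, and points falling inside the
#' track polygon are rejected. Distances and faces use the exact polygon
#' geometry (not a pixel grid).
#'
#' @param neurons a \code{\link{neuron_field_model}}.
#' @param track a \code{\link{track_geometry}} inside the rectangle.
#' @param width_um,height_um extent of the tissue rectangle (um).
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return data.frame with columns \code{x_um}, \code{y_um}.
#' @export
sample_neuron_field <- function(neurons, track, width_um, height_um,
                                seed = NULL) {
  stopifnot(inherits(neurons, "neuron_field_model"),
            inherits(track, "track_geometry"))
  draw <- function() {
    lam_um2 <- neurons$baseline_density / 1e6
    n0 <- rpois(1L, lam_um2 * width_um * height_um)
    qx <- runif(n0, 0, width_um)
    qy <- runif(n0, 0, height_um)
    outside <- !points_in_polygon(qx, qy, track$polygon)
    qx <- qx[outside]; qy <- qy[outside]
    nep <- nearest_edge(qx, qy, track$polygon)
    B <- neurons$depletion_fraction_per_face[track$edge_faces[nep$edge]]
    keep <- runif(length(qx)) >= B * depletion_g(nep$distance_um, neurons)
    data.frame(x_um = qx[keep], y_um = qy[keep])
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# Gaussian-spot rendering of a point set onto the pixel grid
render_points_image <- function(pts, nr, nc, px, sd_um, amplitude,
                                background, noise_sd) {
  img <- matrix(background, nr, nc)
  if (nrow(pts)) {
    sd_px <- sd_um / px
    rad <- max(1L, ceiling(3 * sd_px))
    off <- seq(-rad, rad)
    kern <- amplitude * exp(-(outer(off^2, off^2, "+")) / (2 * sd_px^2))
    for (i in seq_len(nrow(pts))) {
      r0 <- round(pts$y_um[i] / px + 0.5)
      c0 <- round(pts$x_um[i] / px + 0.5)
      rr <- (r0 - rad):(r0 + rad); cc <- (c0 - rad):(c0 + rad)
      ok_r <- rr >= 1 & rr <= nr; ok_c <- cc >= 1 & cc <= nc
      img[rr[ok_r], cc[ok_c]] <- img[rr[ok_r], cc[ok_c]] +
        kern[ok_r, ok_c, drop = FALSE]
    }
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  pmax(img, 0)
}

# Expected per-(band, face) intensity and density from the analytic models,
# averaged over the pixel centres of each region of the supplied band map —
# independent of rendered noise and of any particular point draw.
analytic_truth_profiles <- function(bm, gliosis, neurons, expect_gfap,
                                    ne, ext_idx, face_all) {
  sel <- !is.na(bm$band_index) & bm$band_index >= 0L
  idx <- which(sel)
  band <- bm$band_index[idx]
  face <- bm$face[idx]

  gi <- expect_gfap[idx]
  key <- interaction(band, face, drop = TRUE)
  int_raw <- tapply(gi, key, mean)

  g <- numeric(length(bm$band_index))
  g[ext_idx] <- depletion_g(ne$distance_um, neurons) *
    neurons$depletion_fraction_per_face[face_all]
  dens_raw <- neurons$baseline_density * (1 - tapply(g[idx], key, mean))

  parts <- do.call(rbind, strsplit(names(int_raw), "\\."))
  out <- data.frame(band = as.integer(parts[, 1]), face = parts[, 2],
                    intensity = as.numeric(int_raw),
                    density = as.numeric(dens_raw))
  out <- out[order(out$face, out$band), ]
  rownames(out) <- NULL

  # normalize to the pooled background zone (the outermost 100 um)
  bg_lo <- bm$max_distance_um - 2 * bm$band_width_um
  bgsel <- idx[bm$distance_um[idx] >= bg_lo]
  bg_int <- tapply(expect_gfap[bgsel], bm$face[bgsel], mean)
  bg_dens <- neurons$baseline_density *
    (1 - tapply(g[bgsel], bm$face[bgsel], mean))
  out$intensity_normalized <- out$intensity / as.numeric(bg_int[out$face])
  out$density_normalized <- out$density / as.numeric(bg_dens[out$face])
  out
}

#' @export
print.synthetic_section <- function(x, ...) {
  cat(sprintf(
    "<synthetic_section> seed=%d, %d x %d px @ %g um/px, %d nuclei%s\n",
    x$seed, nrow(x$band_map$band_index), ncol(x$band_map$band_index),
    x$band_map$pixel_size_um, nrow(x$truth_points),
    if (is.null(x$gfap_image)) " (images not rendered)" else ""))
  invisible(x)
}
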