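#' Write a calibrated image as 16-bit TIFF with a JSON sidecar
#'
#' Intensities are scaled by the recorded \code{scale} (the image maximum,
#' or 1 for an empty image) into [0, 1] and stored as 16-bit grayscale;
#' the sidecar carries the scale, the um/px calibration and the section
#' metadata so the image round-trips to within 16-bit quantization.
#'
#' @param image a \code{\link{calibrated_image}}.
#' @param path output path ending in \code{.tif}/\code{.tiff}; the sidecar
#'   is written next to it with extension \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_calibrated_tiff <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  scale <- max(image$pixels, 1e-12)
  tiff::writeTIFF(image$pixels / scale, path, bits.per.sample = 16L)
  sidecar <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size_um, stain = image$stain,
         section_id = image$section_id, animal_id = image$animal_id,
         group = image$group, scale = scale),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated image written by \code{\link{write_calibrated_tiff}}
#'
#' @param path TIFF path; the sidecar JSON must sit next to it.
#' @return A \code{\link{calibrated_image}}.
#' @export
read_calibrated_tiff <- function(path) {
  sidecar <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(sidecar))
    stop("missing calibration sidecar for ", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_um))
    stop("sidecar for ", path, " lacks pixel_size_um calibration")
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  calibrated_image(px * meta$scale, meta$pixel_size_um,
                   stain = meta$stain %||% "other",
                   section_id = meta$section_id %||% NA_character_,
                   animal_id = meta$animal_id %||% NA_character_,
                   group = meta$group %||% NA_character_)
}

#' Write / read a labelled track outline as JSON
#'
#' @param track a \code{\link{track_geometry}}.
#' @param path JSON path.
#' @return the path / the track.
#' @export
write_track_json <- function(track, path) {
  stopifnot(inherits(track, "track_geometry"))
  jsonlite::write_json(
    list(polygon = unname(apply(track$polygon, 1, as.list)),
         edge_faces = track$edge_faces, damaged = track$damaged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_track_json
#' @export
read_track_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  poly <- j$polygon
  poly <- if (is.data.frame(poly)) as.matrix(poly[, c("x_um", "y_um")])
          else if (is.list(poly)) do.call(rbind, lapply(poly, unlist))
          else as.matrix(poly)
  track_geometry(poly, j$edge_faces, damaged = isTRUE(j$damaged))
}

#' Write / read nucleus detections as CSV (x_um, y_um)
#'
#' @param detections a \code{\link{cell_detections}}.
#' @param path CSV path.
#' @export
write_detections_csv <- function(detections, path) {
  write.csv(as.data.frame(detections)[, c("x_um", "y_um")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @param provenance,section_id metadata attached on read.
#' @export
read_detections_csv <- function(path, provenance = "manual",
                                section_id = NA_character_) {
  cell_detections(read.csv(path), provenance = provenance,
                  section_id = section_id)
}

#' Export one synthetic section to a directory
#'
#' Writes the full bundle for a section: GFAP and NeuN TIFFs with sidecars,
#' the track JSON, the truth points CSV, the truth profiles CSV, and the
#' layer mask as PNG.
#'
#' @param section a \code{\link{generate_section}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_section <- function(section, dir) {
  stopifnot(inherits(section, "synthetic_section"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_calibrated_tiff(section$gfap_image, file.path(dir, "gfap.tif"))
  write_calibrated_tiff(section$neun_image, file.path(dir, "neun.tif"))
  write_track_json(section$truth_track, file.path(dir, "track.json"))
  write_detections_csv(
    cell_detections(section$truth_points, section_id =
                      section$gfap_image$section_id),
    file.path(dir, "truth_points.csv"))
  write.csv(section$truth_profiles, file.path(dir, "truth_profiles.csv"),
            row.names = FALSE)
  png::writePNG(section$layer_mask * 1, file.path(dir, "layer_mask.png"))
  invisible(dir)
}

#' Read a section directory back into analysis inputs
#'
#' @param dir a directory written by \code{\link{write_section}} (or laid
#'   out the same way by hand). \code{neun.tif}, \code{layer_mask.png} and
#'   the detection CSV are optional.
#' @return list with \code{gfap_image}, \code{neun_image} (or NULL),
#'   \code{track}, \code{detections} (or NULL), \code{layer_mask} (or
#'   NULL).
#' @export
read_section <- function(dir) {
  gf <- file.path(dir, "gfap.tif")
  if (!file.exists(gf)) stop("no gfap.tif in ", dir)
  gfap <- read_calibrated_tiff(gf)
  nf <- file.path(dir, "neun.tif")
  neun <- if (file.exists(nf)) read_calibrated_tiff(nf) else NULL
  track <- read_track_json(file.path(dir, "track.json"))
  dcsv <- file.path(dir, "truth_points.csv")
  if (!file.exists(dcsv)) dcsv <- file.path(dir, "detections.csv")
  det <- if (file.exists(dcsv))
    read_detections_csv(dcsv, section_id = gfap$section_id) else NULL
  lmf <- file.path(dir, "layer_mask.png")
  lm <- if (file.exists(lmf)) {
    m <- png::readPNG(lmf)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m > 0.5
  } else NULL
  list(gfap_image = gfap, neun_image = neun, track = track,
       detections = det, layer_mask = lm)
}

#' Load all sections listed in a manifest
#'
#' The manifest (YAML or JSON, or an equivalent R list) lists one entry per
#' section: \code{dir} (a \code{\link{read_section}} layout) plus optional
#' metadata \code{animal}, \code{damaged}. Damaged sections are loaded and
#' reported but excluded from analysis by the pipeline.
#'
#' @param manifest path to a YAML/JSON manifest, or a list with element
#'   \code{sections}.
#' @return list with \code{sections} (loaded inputs + metadata) and
#'   \code{excluded} (data.frame of excluded section ids and reasons).
#' @export
read_inputs <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- if (grepl("\\.json$", manifest))
      jsonlite::read_json(manifest, simplifyVector = FALSE)
    else yaml::read_yaml(manifest)
  }
  entries <- manifest$sections
  if (is.null(entries) || !length(entries))
    stop("manifest lists no sections")
  sections <- list()
  excluded <- data.frame(section_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (e in entries) {
    sec <- read_section(e$dir)
    sec$animal_id <- e$animal %||% NA_character_
    sec$section_id <- sec$gfap_image$section_id %||% basename(e$dir)
    if (is.na(sec$section_id)) sec$section_id <- basename(e$dir)
    damaged <- isTRUE(e$damaged) || sec$track$damaged
    sec$damaged <- damaged
    if (damaged) {
      excluded <- rbind(excluded, data.frame(
        section_id = sec$section_id,
        reason = "massive tissue damage / fissure (damaged flag)",
        stringsAsFactors = FALSE))
    }
    sections[[length(sections) + 1L]] <- sec
  }
  list(sections = sections, excluded = excluded)
}

#' Read a height map from a plain-text matrix file or float TIFF
#'
#' @param path whitespace-delimited text matrix (nm) or single-channel
#'   TIFF.
#' @param lateral_step_nm grid step in nm.
#' @return A \code{height_map} object.
#' @export
read_height_map <- function(path, lateral_step_nm) {
  z <- if (grepl("\\.tiff?$", path)) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m
  } else {
    as.matrix(read.table(path))
  }
  dimnames(z) <- NULL
  structure(list(heights = z, lateral_step_nm = lateral_step_nm,
                 true_ratio = NA_real_, form = "measured", seed = NA_integer_),
            class = "height_map")
}
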