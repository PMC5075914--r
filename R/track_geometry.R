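#' Construct a labelled track outline
#'
#' The electrode track — the void left in the section after explantation —
#' is described by a simple closed polygon in micrometre coordinates. Edge
#' \code{i} joins vertex \code{i} to vertex \code{i + 1} (the last edge
#' closes the ring) and carries the surface label of the implant face that
#' produced it.
#'
#' @param polygon numeric matrix (n >= 3 rows) of vertices, columns
#'   \code{x_um}, \code{y_um}. Do not repeat the first vertex at the end.
#' @param edge_faces character vector, one label per edge, each from
#'   \code{\link{FACE_LABELS}}.
#' @param damaged logical; sections flagged by the histologist as having
#'   massive tissue damage or fissures are carried through loading but
#'   excluded from all analysis.
#' @return An object of class \code{track_geometry}.
#' @export
track_geometry <- function(polygon, edge_faces, damaged = FALSE) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("`polygon` must be an n x 2 matrix with n >= 3 vertices")
  storage.mode(polygon) <- "double"
  if (any(!is.finite(polygon))) stop("polygon vertices must be finite")
  n <- nrow(polygon)
  if (length(edge_faces) != n)
    stop(sprintf("need one face label per edge: %d edges, %d labels",
                 n, length(edge_faces)))
  bad <- setdiff(unique(edge_faces), FACE_LABELS)
  if (length(bad))
    stop("unknown face label(s): ", paste(bad, collapse = ", "))
  if (polygon_area(polygon) <= 0)
    stop("polygon has zero area (degenerate outline)")
  if (!polygon_is_simple(polygon))
    stop("polygon is self-intersecting; the track outline must be simple")
  dimnames(polygon) <- list(NULL, c("x_um", "y_um"))
  structure(list(polygon = polygon, edge_faces = as.character(edge_faces),
                 damaged = isTRUE(damaged)),
            class = "track_geometry")
}

#' Axis-aligned rectangular track
#'
#' Convenience constructor for the common rectangular device cross-section
#' (default 180 um x 380 um). Edges are ordered top, right, bottom, left.
#'
#' @param width_um,height_um rectangle dimensions in um.
#' @param center_um numeric length-2, centre (x, y) in um.
#' @param face_labels named character vector with entries \code{top},
#'   \code{right}, \code{bottom}, \code{left}.
#' @inheritParams track_geometry
#' @export
rect_track <- function(width_um = 180, height_um = 380,
                       center_um = c(0, 0),
                       face_labels = c(top = "micro-polymer",
                                       right = "nanoSi",
                                       bottom = "microSi",
                                       left = "flatSi"),
                       damaged = FALSE) {
  stopifnot(width_um > 0, height_um > 0)
  need <- c("top", "right", "bottom", "left")
  if (!all(need %in% names(face_labels)))
    stop("`face_labels` must name top, right, bottom, left")
  hw <- width_um / 2; hh <- height_um / 2
  poly <- cbind(x_um = center_um[1] + c(-hw, hw, hw, -hw),
                y_um = center_um[2] + c(-hh, -hh, hh, hh))
  track_geometry(poly, unname(face_labels[need]), damaged = damaged)
}

# Shoelace area (absolute), um^2
polygon_area <- function(p) {
  n <- nrow(p); j <- c(n, seq_len(n - 1L))
  abs(sum(p[j, 1] * p[, 2] - p[, 1] * p[j, 2])) / 2
}

# Simplicity check: no two non-adjacent edges intersect (O(n^2), n is tiny)
polygon_is_simple <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1L), , drop = FALSE])
  inter <- function(a, b) {
    d <- function(p1, p2, p3)
      (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    a1 <- a[1:2]; a2 <- a[3:4]; b1 <- b[1:2]; b2 <- b[3:4]
    d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
    d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  if (n <= 3L) return(TRUE)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent through the closing edge
      if (inter(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over a pixel
# grid. Pixel centres exactly on an edge follow the crossing parity of the
# half-open ray convention; for the band analysis this affects only a
# measure-zero set of centres.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

# Squared distance from points to each polygon edge segment.
# Returns list(d2 = n_pts x n_edges matrix).
points_segment_dist2 <- function(px, py, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  d2 <- matrix(NA_real_, length(px), n)
  for (e in seq_len(n)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    x2 <- poly[nxt[e], 1]; y2 <- poly[nxt[e], 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2[, e] <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
      d2[, e] <- (px - x1 - t * dx)^2 + (py - y1 - t * dy)^2
    }
  }
  d2
}

# Distance (um) to polygon boundary + nearest edge index (ties -> lowest
# index, within a small relative tolerance so exactly-equidistant corner
# points are deterministic).
nearest_edge <- function(px, py, poly) {
  d2 <- points_segment_dist2(px, py, poly)
  dmin <- sqrt(do.call(pmin, as.data.frame(d2)))
  # tie criterion in distance units: |d - dmin| <= 1e-9 * (1 + dmin)
  cutoff2 <- (dmin + 1e-9 * (1 + dmin))^2
  # first edge attaining the minimum (within tolerance) = lowest index
  edge <- max.col(-(d2 > cutoff2), ties.method = "first")
  list(distance_um = dmin, edge = as.integer(edge))
}

#' Rasterize a track outline onto an image grid
#'
#' Marks every pixel whose centre falls inside the track polygon
#' (even-odd rule).
#'
#' @param track a \code{\link{track_geometry}}.
#' @param image a \code{\link{calibrated_image}}, or a list with elements
#'   \code{dim} (rows, cols) and \code{pixel_size_um}.
#' @return Logical matrix of the image's dimensions; \code{TRUE} inside the
#'   track.
#' @export
rasterize_track <- function(track, image) {
  stopifnot(inherits(track, "track_geometry"))
  if (inherits(image, "calibrated_image")) {
    nr <- nrow(image$pixels); nc <- ncol(image$pixels)
    px_um <- image$pixel_size_um
  } else {
    nr <- image$dim[1]; nc <- image$dim[2]; px_um <- image$pixel_size_um
  }
  poly <- track$polygon
  if (min(poly[, 1]) < 0 || min(poly[, 2]) < 0 ||
      max(poly[, 1]) > nc * px_um || max(poly[, 2]) > nr * px_um)
    stop("track polygon extends outside the image bounds")
  ctr <- pixel_centers(nr, nc, px_um)
  grid_x <- rep(ctr$x, each = nr)
  grid_y <- rep(ctr$y, times = nc)
  matrix(points_in_polygon(grid_x, grid_y, poly), nr, nc)
}
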