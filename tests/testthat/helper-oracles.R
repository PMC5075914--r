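# Independent brute-force oracles and small fixture builders, written
# deliberately as plain per-element loops so they share no code path with
# the implementation.

# Scalar ray-casting point-in-polygon (even-odd), one point at a time.
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > y) != (poly[j, 2] > y)) {
      xint <- (poly[j, 1] - poly[i, 1]) * (y - poly[i, 2]) /
        (poly[j, 2] - poly[i, 2]) + poly[i, 1]
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Exhaustive distance-to-nearest-track-pixel and band index per pixel.
oracle_band_map <- function(track_mask, pixel_size_um, band_width_um,
                            max_distance_um) {
  nr <- nrow(track_mask); nc <- ncol(track_mask)
  tr <- which(track_mask, arr.ind = TRUE)
  band <- matrix(NA_integer_, nr, nc)
  dist <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c_ in seq_len(nc)) {
      if (track_mask[r, c_]) { band[r, c_] <- -1L; next }
      d2 <- (tr[, 1] - r)^2 + (tr[, 2] - c_)^2
      d <- sqrt(min(d2)) * pixel_size_um
      dist[r, c_] <- d
      if (d < max_distance_um)
        band[r, c_] <- as.integer(floor(d / band_width_um))
    }
  }
  list(band_index = band, distance_um = dist)
}

# Scalar point-to-segment distance
oracle_seg_dist <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx^2 + dy^2
  if (l2 == 0) return(sqrt((x - x1)^2 + (y - y1)^2))
  t <- ((x - x1) * dx + (y - y1) * dy) / l2
  t <- min(1, max(0, t))
  sqrt((x - x1 - t * dx)^2 + (y - y1 - t * dy)^2)
}

# Brute-force nearest-edge label per pixel (ties -> lowest edge index)
oracle_faces <- function(band_map, track) {
  nr <- nrow(band_map$band_index); nc <- ncol(band_map$band_index)
  poly <- track$polygon
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  face <- matrix(NA_character_, nr, nc)
  for (r in seq_len(nr)) {
    for (c_ in seq_len(nc)) {
      b <- band_map$band_index[r, c_]
      if (is.na(b) || b < 0L) next
      x <- (c_ - 0.5) * band_map$pixel_size_um
      y <- (r - 0.5) * band_map$pixel_size_um
      ds <- vapply(seq_len(n), function(e)
        oracle_seg_dist(x, y, poly[e, 1], poly[e, 2],
                        poly[nxt[e], 1], poly[nxt[e], 2]), numeric(1))
      best <- which(ds <= min(ds) + 1e-9 * (1 + min(ds)))[1]
      face[r, c_] <- track$edge_faces[best]
    }
  }
  face
}

# Random star-shaped (hence simple) polygon inside [0, w] x [0, h] um:
# jittered regular angles keep every angular gap below pi, so the radial
# construction cannot self-intersect.
random_simple_polygon <- function(w, h, n_vertices = 6) {
  cx <- runif(1, 0.35 * w, 0.65 * w)
  cy <- runif(1, 0.35 * h, 0.65 * h)
  base <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  ang <- base + runif(n_vertices, -0.4, 0.4) * 2 * pi / n_vertices
  rad <- runif(n_vertices, 0.1, 0.32) * min(w, h)
  cbind(x_um = pmin(w, pmax(0, cx + rad * cos(ang))),
        y_um = pmin(h, pmax(0, cy + rad * sin(ang))))
}

# Greedy bipartite matching of detections to truth points at a radius;
# returns recall and precision.
match_points <- function(det, truth, radius_um) {
  if (!nrow(det) || !nrow(truth))
    return(list(recall = 0, precision = 0, matches = 0))
  d2 <- outer(det$x_um, truth$x_um, "-")^2 +
    outer(det$y_um, truth$y_um, "-")^2
  pairs <- which(d2 <= radius_um^2, arr.ind = TRUE)
  if (!nrow(pairs)) return(list(recall = 0, precision = 0, matches = 0))
  o <- order(d2[pairs])
  pairs <- pairs[o, , drop = FALSE]
  used_d <- logical(nrow(det)); used_t <- logical(nrow(truth))
  m <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (!used_d[a] && !used_t[b]) {
      used_d[a] <- TRUE; used_t[b] <- TRUE; m <- m + 1L
    }
  }
  list(recall = m / nrow(truth), precision = m / nrow(det), matches = m)
}

# Small labelled square track for profile unit tests: 40 x 40 px grid at
# 25 um/px with a 4 x 4 px track in the middle -> full 10-band range fits.
small_square_fixture <- function(pixel_size_um = 25) {
  trk <- rect_track(width_um = 4 * pixel_size_um,
                    height_um = 4 * pixel_size_um,
                    center_um = c(20, 20) * pixel_size_um)
  img <- calibrated_image(matrix(100, 40, 40), pixel_size_um,
                          stain = "GFAP", section_id = "fix")
  mask <- rasterize_track(trk, img)
  bm <- assign_faces(compute_band_map(mask, pixel_size_um), trk)
  list(track = trk, image = img, band_map = bm)
}
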