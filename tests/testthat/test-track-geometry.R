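test_that("rasterization of an axis-aligned rectangle covers exactly its pixels", {
  trk <- rect_track(width_um = 10, height_um = 20, center_um = c(16, 16))
  mask <- rasterize_track(trk, list(dim = c(32, 32), pixel_size_um = 1))
  expect_equal(sum(mask), 10 * 20)
  # mask is a contiguous axis-aligned block
  rows <- range(which(apply(mask, 1, any)))
  cols <- range(which(apply(mask, 2, any)))
  expect_equal(diff(rows) + 1, 20)
  expect_equal(diff(cols) + 1, 10)
})

test_that("degenerate and out-of-bounds outlines are rejected", {
  expect_error(track_geometry(cbind(c(0, 5, 10), c(0, 0, 0)),
                              rep("flatSi", 3)),
               "zero area")
  expect_error(track_geometry(cbind(c(0, 1), c(0, 1)), rep("flatSi", 2)),
               ">= 3 vertices")
  trk <- rect_track(width_um = 10, height_um = 10, center_um = c(100, 100))
  expect_error(rasterize_track(trk, list(dim = c(20, 20), pixel_size_um = 1)),
               "outside the image")
  expect_error(track_geometry(cbind(c(0, 8, 8, 4, 0), c(0, 0, 8, -4, 8)),
                              rep("flatSi", 5)),
               "self-intersecting")
  expect_error(rect_track(face_labels = c(top = "bad", right = "nanoSi",
                                          bottom = "microSi",
                                          left = "flatSi")),
               "unknown face label")
})

test_that("rasterization matches scalar ray-casting on random simple polygons", {
  set.seed(41)
  for (rep_i in 1:20) {
    nr <- sample(12:32, 1); nc <- sample(12:32, 1)
    poly <- random_simple_polygon(nc, nr, n_vertices = sample(4:8, 1))
    trk <- track_geometry(poly, rep("nanoSi", nrow(poly)))
    mask <- rasterize_track(trk, list(dim = c(nr, nc), pixel_size_um = 1))
    for (r in seq_len(nr)) for (c_ in seq_len(nc)) {
      expect_identical(mask[r, c_],
                       oracle_point_in_polygon(c_ - 0.5, r - 0.5, poly))
    }
  }
})

test_that("rasterization agrees with mgcv's in/out classification", {
  skip_if_not_installed("mgcv")
  set.seed(42)
  poly <- random_simple_polygon(30, 30, 7)
  trk <- track_geometry(poly, rep("microSi", 7))
  mask <- rasterize_track(trk, list(dim = c(30, 30), pixel_size_um = 1))
  ctr <- expand.grid(y = seq_len(30) - 0.5, x = seq_len(30) - 0.5)
  bnd <- rbind(poly, poly[1, ])
  io <- mgcv::in.out(bnd, cbind(ctr$x, ctr$y))
  expect_equal(as.vector(mask), io)
})

test_that("band boundaries follow the half-open convention", {
  # single-pixel track; 4-neighbours sit at exactly one pixel size away
  mask <- matrix(FALSE, 21, 21); mask[11, 11] <- TRUE

  bm <- compute_band_map(mask, pixel_size_um = 49.9)
  expect_equal(bm$band_index[11, 12], 0L)   # 49.9 um -> band 0

  bm <- compute_band_map(mask, pixel_size_um = 50)
  expect_equal(bm$band_index[11, 12], 1L)   # 50.0 um -> band 1
  expect_equal(bm$band_index[12, 12], 1L)   # ~70.7 um -> band 1
  expect_true(is.na(bm$band_index[11, 21])) # 500.0 um -> excluded
  expect_equal(bm$band_index[11, 11], -1L)  # the track itself

  expect_equal(bm$n_bands, 10L)
  # no exterior pixel centre lies closer than 50 um to a single-pixel
  # track at 50 um/px, so band 0 is empty but bands 1..9 are occupied
  expect_equal(sort(unique(bm$band_index[!is.na(bm$band_index)])),
               c(-1L, 1L:9L))
})

test_that("band map input validation", {
  expect_error(compute_band_map(matrix(FALSE, 4, 4), 1), "empty")
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE
  expect_error(compute_band_map(m, 1, band_width_um = 0), "band_width")
  expect_error(compute_band_map(m, 0), "pixel_size")
})

test_that("band indices match the exhaustive distance oracle on random masks", {
  set.seed(7)
  for (rep_i in 1:15) {
    nr <- sample(16:48, 1); nc <- sample(16:48, 1)
    mask <- matrix(FALSE, nr, nc)
    # random blob track: a few filled rectangles
    for (k in 1:sample(1:3, 1)) {
      r0 <- sample(seq_len(nr - 3), 1); c0 <- sample(seq_len(nc - 3), 1)
      mask[r0:(r0 + sample(1:3, 1)), c0:(c0 + sample(1:3, 1))] <- TRUE
    }
    px <- sample(c(5, 10, 25, 50), 1)
    bw <- sample(c(25, 50), 1)
    bm <- compute_band_map(mask, px, band_width_um = bw)
    or <- oracle_band_map(mask, px, bw, 500)
    expect_identical(bm$band_index, or$band_index)
    expect_equal(bm$distance_um[!mask], or$distance_um[!mask],
                 tolerance = 1e-9)
  }
})

test_that("face assignment follows the nearest labelled edge with tie rule", {
  trk <- rect_track(width_um = 2, height_um = 2, center_um = c(5, 5),
                    face_labels = c(top = "nanoSi", right = "flatSi",
                                    bottom = "microSi",
                                    left = "micro-polymer"))
  mask <- rasterize_track(trk, list(dim = c(10, 10), pixel_size_um = 1))
  bm <- assign_faces(compute_band_map(mask, 1, band_width_um = 5,
                                      max_distance_um = 5), trk)
  expect_equal(bm$face[2, 5], "nanoSi")    # directly above edge midpoint
  expect_equal(bm$face[5, 9], "flatSi")    # directly right
  expect_equal(bm$face[9, 5], "microSi")   # below
  expect_equal(bm$face[5, 2], "micro-polymer")
  # pixel centre on the NE corner diagonal is equidistant from edges
  # 1 (top) and 2 (right): the lower-indexed edge wins
  expect_equal(bm$face[3, 8], "nanoSi")
})

test_that("face assignment matches the brute-force nearest-segment oracle", {
  set.seed(11)
  for (rep_i in 1:10) {
    nr <- sample(20:48, 1); nc <- sample(20:48, 1)
    w <- sample(3:8, 1); h <- sample(3:8, 1)
    trk <- rect_track(width_um = w, height_um = h,
                      center_um = c(nc / 2, nr / 2),
                      face_labels = c(top = sample(FACE_LABELS, 1),
                                      right = sample(FACE_LABELS, 1),
                                      bottom = sample(FACE_LABELS, 1),
                                      left = sample(FACE_LABELS, 1)))
    mask <- rasterize_track(trk, list(dim = c(nr, nc), pixel_size_um = 1))
    bm <- assign_faces(compute_band_map(mask, 1, band_width_um = 10,
                                        max_distance_um = 20), trk)
    expect_identical(bm$face, oracle_faces(bm, trk))
  }
})

test_that("layer mask restriction excludes pixels without relabelling the rest", {
  fix <- small_square_fixture()
  bm <- fix$band_map
  all_true <- matrix(TRUE, 40, 40)
  expect_identical(apply_layer_mask(bm, all_true)$band_index, bm$band_index)

  none <- matrix(FALSE, 40, 40)
  expect_true(all(is.na(apply_layer_mask(bm, none)$band_index)))

  half <- matrix(FALSE, 40, 40); half[1:20, ] <- TRUE
  bm2 <- apply_layer_mask(bm, half)
  # retained pixels keep their labels
  kept <- !is.na(bm2$band_index)
  expect_identical(bm2$band_index[kept], bm$band_index[kept])
  expect_identical(bm2$face[kept], bm$face[kept])
  # per-band recount: only rows 1:20 contribute
  for (b in 0:9) {
    expect_equal(sum(bm2$band_index == b, na.rm = TRUE),
                 sum(bm$band_index[1:20, ] == b, na.rm = TRUE))
  }
  expect_error(apply_layer_mask(bm, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("track, bands and exclusions partition every pixel", {
  set.seed(13)
  for (rep_i in 1:8) {
    nr <- sample(16:40, 1); nc <- sample(16:40, 1)
    mask <- matrix(FALSE, nr, nc)
    mask[sample(nr, 1), sample(nc, 1)] <- TRUE
    bm <- compute_band_map(mask, sample(c(10, 50), 1))
    counts <- gliaband:::band_partition_counts(bm)
    expect_equal(counts[["track"]] + counts[["banded"]] +
                   counts[["excluded"]], counts[["total"]])
  }
})

test_that("band index never decreases along rays leaving the track", {
  fix <- small_square_fixture()
  bm <- fix$band_map
  for (ang in seq(0, 2 * pi, length.out = 17)[-17]) {
    r <- 20.5; c_ <- 20.5
    prev <- -1L
    repeat {
      r <- r + 0.7 * sin(ang); c_ <- c_ + 0.7 * cos(ang)
      ri <- round(r); ci <- round(c_)
      if (ri < 1 || ri > 40 || ci < 1 || ci > 40) break
      b <- bm$band_index[ri, ci]
      if (is.na(b)) break
      expect_gte(b, prev)
      prev <- b
    }
  }
})

test_that("permuting face labels permutes per-face outputs identically", {
  fix <- small_square_fixture()
  perm <- c(top = "flatSi", right = "micro-polymer", bottom = "nanoSi",
            left = "microSi")
  trk2 <- rect_track(width_um = 100, height_um = 100,
                     center_um = c(500, 500), face_labels = perm)
  bm1 <- fix$band_map
  bm2 <- assign_faces(compute_band_map(
    rasterize_track(trk2, fix$image), 25), trk2)
  # original default labels: top micro-polymer, right nanoSi,
  # bottom microSi, left flatSi
  map <- c("micro-polymer" = "flatSi", "nanoSi" = "micro-polymer",
           "microSi" = "nanoSi", "flatSi" = "microSi")
  idx <- !is.na(bm1$face)
  expect_identical(unname(map[bm1$face[idx]]), bm2$face[idx])
})
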