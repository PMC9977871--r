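test_that("a planar split yields the two flanking voxel layers", {
  x <- half_volumes(c(6, 8, 8))                     # split at x = 4|5
  g <- build_adjacency_graph(x)
  w <- wall_segment(x, g, 1, 2)
  expect_setequal(unique(w[, "x"]), 4:5)
  expect_equal(nrow(w), 6 * 8 * 2)
  # symmetry
  expect_setequal(point_key(w), point_key(wall_segment(x, g, 2, 1)))
  # two cells, no third: junction set empty
  expect_equal(nrow(junctions(x, g, 1, 2)), 0)
  # non-neighbour pairs are rejected with the distance in the message
  x3 <- collinear_cells()
  g3 <- build_adjacency_graph(x3, r_max = 4)
  expect_error(wall_segment(x3, g3, 1, 3), "distance 3")
})

test_that("three extruded sectors meet along the central axis", {
  x <- sector_volume()
  g <- build_adjacency_graph(x)
  j12 <- junctions(x, g, 1, 2)
  expect_gt(nrow(j12), 0)
  expect_true(all(j12[, "k"] == 3))
  # junction voxels hug the axis column (centre at y = x = 9)
  expect_true(all(abs(j12[, "y"] - 9) <= 2 & abs(j12[, "x"] - 9) <= 2))
  # junction voxels lie within one dilation of the pair's wall
  w <- wall_segment(x, g, 1, 2)
  dmin <- vapply(seq_len(nrow(j12)), function(r)
    min(sqrt(colSums((t(w) - as.numeric(j12[r, 1:3]))^2))), numeric(1))
  expect_true(all(dmin <= sqrt(3)))
})

test_that("order_segment chains points without jumps", {
  pts <- cbind(z = rep(1, 6), y = rep(1, 6), x = c(4, 1, 6, 2, 5, 3))
  pl <- order_segment(pts)
  expect_s3_class(pl, "polyline3d")
  # chaining starts from one extreme end; both orientations are valid
  expect_true(identical(as.numeric(pl[, "x"]), as.numeric(6:1)) ||
              identical(as.numeric(pl[, "x"]), as.numeric(1:6)))
  # an L-shaped set is followed without jumps > sqrt(2)
  L <- cbind(1, c(1, 2, 3, 4, 4, 4), c(1, 1, 1, 1, 2, 3))
  plL <- order_segment(L)
  steps <- sqrt(rowSums((plL[-1, ] - plL[-nrow(plL), ])^2))
  expect_true(all(steps <= sqrt(2)))
  expect_equal(nrow(order_segment(cbind(2, 3, 4))), 1)
  expect_error(order_segment(pts[0, , drop = FALSE]), "empty")
})

test_that("wall and junction sets equal the brute-force oracle exactly", {
  for (sd in c(3, 5)) {
    ph <- small_phantom(sd)
    g <- build_adjacency_graph(ph$labels)
    gt <- ground_truth_features(ph$labels)
    feats <- suppressMessages(extract_all_features(ph$labels, g))
    # every oracle wall pair is a distance-1 pair with the same voxel set
    for (key in names(gt$walls)) {
      ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      w <- wall_segment(ph$labels, g, ij[1], ij[2])
      expect_setequal(point_key(gt$walls[[key]]), point_key(w))
    }
    # and every distance-1 pair has an oracle wall
    e1 <- g$edges[g$edges$weight == 1L, ]
    expect_setequal(paste(e1$i, e1$j, sep = "|"), names(gt$walls))
    # junction voxel sets agree exactly (F1 = 1 at zero tolerance)
    gt_j <- unique(do.call(rbind, gt$junctions))
    expect_setequal(point_key(gt_j), point_key(feats$junctions))
    pr <- junction_prf(feats$junctions, gt_j, tol = 0)
    expect_equal(pr$f1, 1)
  }
})

test_that("extracted segments are valid polylines bounded by junctions", {
  ph <- small_phantom(3)
  g <- build_adjacency_graph(ph$labels)
  feats <- suppressMessages(extract_all_features(ph$labels, g))
  expect_gt(length(feats$segments), 0)
  jk <- point_key(feats$junctions)
  for (pl in feats$segments) {
    expect_gte(nrow(pl), 3)
    expect_equal(anyDuplicated(point_key(pl)), 0L)  # each point visited once
    steps <- sqrt(rowSums((pl[-1, , drop = FALSE] -
                           pl[-nrow(pl), , drop = FALSE])^2))
    # 3D wall runs are 2-voxel-thick patches, so the chain may take a few
    # return jumps; the bulk of the traversal must still be local
    expect_lte(stats::median(steps), sqrt(3))
    expect_false(any(point_key(pl) %in% jk))        # cut at junction voxels
    expect_length(attr(pl, "cells"), 2)
  }
  # a two-cell volume yields one wall and no junctions
  x2 <- half_volumes(c(4, 6, 6))
  g2 <- build_adjacency_graph(x2)
  f2 <- suppressMessages(extract_all_features(x2, g2))
  expect_length(f2$walls, 1)
  expect_equal(nrow(f2$junctions), 0)
})
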