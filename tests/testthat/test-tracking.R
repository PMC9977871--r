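toy_graph <- function(weights) {
  # star around label 1 with given edge weights to labels 2, 3, ...
  structure(list(
    vertices = data.frame(label = seq_len(length(weights) + 1L),
                          size = c(50L, rep(10L, length(weights)))),
    edges = data.frame(i = 1L, j = seq_along(weights) + 1L,
                       weight = as.integer(weights)),
    r_max = 3L), class = "adjacency_graph")
}

test_that("track features implement size, degree and weighted degree", {
  g0 <- structure(list(vertices = data.frame(label = 1L, size = 50L),
                       edges = data.frame(i = integer(0), j = integer(0),
                                          weight = integer(0)),
                       r_max = 3L), class = "adjacency_graph")
  f0 <- track_features(g0)
  expect_equal(unlist(f0[1, c("S", "deg", "wdeg")]),
               c(S = 50, deg = 0, wdeg = 0))       # sentinel D = 0
  f <- track_features(toy_graph(c(1, 1, 2)))
  v1 <- f[f$label == 1, ]
  expect_equal(v1$deg, 2)                          # two distance-1 edges
  expect_equal(v1$wdeg, 4 / 3)                     # (1 + 1 + 2) / 3
  f1 <- track_features(toy_graph(c(1, 1, 1)))
  expect_equal(f1$wdeg[f1$label == 1], 1)          # all weight-1: mean 1
})

test_that("similarity follows the asymmetric three-term formula", {
  f <- function(S, deg, wdeg) data.frame(S = S, deg = deg, wdeg = wdeg)
  expect_equal(track_similarity(f(100, 4, 2), f(100, 4, 2)), 0)
  expect_equal(track_similarity(f(100, 4, 2.0), f(110, 4, 2.5)), 0.35)
  expect_equal(track_similarity(f(100, 4, 2), f(200, 8, 4)), 3)
  # zero denominators substitute 1 and stay finite
  expect_true(is.finite(track_similarity(f(10, 0, 0), f(12, 2, 1.5))))
})

test_that("greedy linking is one-to-one and evaluates M^2 candidates", {
  g <- build_adjacency_graph(small_phantom(3)$labels)
  f <- track_features(g)
  lk <- link_frames(f, f, threshold = 0.3)
  expect_equal(nrow(lk$links), nrow(f))
  expect_true(all(lk$links$label_T == lk$links$label_T1))
  expect_true(all(lk$links$sim == 0))
  expect_equal(lk$n_evaluations, nrow(f)^2)        # O(M^2) contract
  # an extra detection stays unmatched
  f2 <- rbind(f, data.frame(label = 99L, S = 123, deg = 1, wdeg = 1))
  lk2 <- link_frames(f, f2, threshold = 0.3)
  expect_false(99L %in% lk2$links$label_T1)
  expect_equal(lk2$n_evaluations, nrow(f) * nrow(f2))
  expect_error(link_frames(f, f, threshold = 0), "threshold")
})

test_that("track_sequence seeds ids from frame 0 and handles gaps", {
  v <- small_phantom(3)$labels
  single <- suppressMessages(track_sequence(list(v)))
  expect_identical(single$relabelled[[1]], v)      # ids = labels
  # an empty middle frame terminates all tracks and reopens new ones
  empty <- array(0L, dim(v))
  tr <- suppressMessages(track_sequence(list(v, empty, v)))
  expect_true(all(tr$track_table$end[tr$track_table$begin == 0] == 0))
  expect_true(all(tr$track_table$begin[tr$track_table$end == 2] == 2))
})

test_that("zero-motion sequences track perfectly with TRA 1", {
  sq <- generate_timelapse(phantom_spec(c(12, 20, 20), n_cells = 5, seed = 5),
                           n_frames = 3, max_shift = 0)
  vols <- lapply(sq$frames, `[[`, "labels")
  tr <- suppressMessages(track_sequence(vols, threshold = 0.3))
  for (t in 1:3) expect_identical(tr$relabelled[[t]], vols[[t]])
  ref <- reference_track_graph(sq)
  m <- match_track_nodes(ref, tr$track_graph, vols, tr$relabelled)
  expect_equal(tra(ref, tr$track_graph, matching = m), 1)
})

test_that("moving phantom sequences are recovered at the permissive threshold", {
  sq <- generate_timelapse(phantom_spec(c(24, 48, 48), n_cells = 8, seed = 3),
                           n_frames = 4, max_shift = 2)
  vols <- lapply(sq$frames, `[[`, "labels")
  tr <- suppressMessages(track_sequence(vols, threshold = 0.5))
  for (t in 1:4) expect_identical(tr$relabelled[[t]], vols[[t]])
})

test_that("track graphs reject malformed edge sets", {
  nodes <- data.frame(id = 1:3, frame = c(0, 1, 1), label = c(1, 1, 2),
                      track = c(1, 1, 2))
  expect_error(track_graph(nodes, data.frame(from = 2, to = 3)), "frame")
  expect_error(track_graph(nodes, data.frame(from = c(1, 1), to = c(2, 3))),
               "incoming")
  expect_s3_class(track_graph(nodes, data.frame(from = 1, to = 2)),
                  "track_graph")
})
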