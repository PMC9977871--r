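test_that("boundary scores at range R behave at the extremes", {
  ph <- small_phantom(3)
  b <- boundary_mask(ph$labels)
  perfect <- boundary_prf(b, b, R = 5)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f_score),
               c(1, 1, 1))
  # a sheet displaced by 3 voxels stays within R = 5
  g3 <- array(FALSE, c(4, 4, 20)); g3[, , 8] <- TRUE
  p3 <- array(FALSE, c(4, 4, 20)); p3[, , 11] <- TRUE
  expect_equal(boundary_prf(g3, p3, R = 5)$f_score, 1)
  # a thin sheet displaced by 9 voxels scores zero at R = 5
  g <- array(FALSE, c(4, 4, 20)); g[, , 3] <- TRUE
  p <- array(FALSE, c(4, 4, 20)); p[, , 12] <- TRUE
  sc <- boundary_prf(g, p, R = 5)
  expect_equal(sc$f_score, 0)
  expect_equal(sc$FN, sum(g)); expect_equal(sc$FP, sum(p))
  expect_error(boundary_prf(array(FALSE, c(2, 2, 2)), p = g[1:2, 1:2, 1:2]),
               "empty ground-truth")
})

test_that("count statistics use the population standard deviation", {
  mk <- function(n) { x <- array(0L, c(2, 2, 30)); if (n > 0) for (l in 1:n) x[, , l] <- l; x }
  expect_equal(count_stats(list(mk(23), mk(23), mk(23)))[c("mean", "sd")],
               list(mean = 23, sd = 0))
  expect_equal(count_stats(list(mk(23), mk(24)))[c("mean", "sd")],
               list(mean = 23.5, sd = 0.5))
  expect_equal(count_stats(list(mk(5)))$sd, 0)
})

test_that("junction matching is greedy, one-to-one and tolerance-bounded", {
  truth <- cbind(z = c(1, 1), y = c(1, 10), x = c(1, 1))
  same <- junction_prf(truth, truth, tol = 5)
  expect_equal(same$f1, 1)
  none <- junction_prf(NULL, truth, tol = 5)
  expect_equal(none$recall, 0)
  # one detection equidistant (< tol) from two truths matches only one
  det <- cbind(z = 1, y = 5.5, x = 1)
  amb <- junction_prf(det, truth, tol = 5)
  expect_equal(amb$precision, 1)
  expect_equal(amb$recall, 0.5)
})

test_that("EDE modes expose the printed formula's anomaly", {
  P <- cbind(0:3, 0, 0)
  expect_equal(ede(P, P, "corrected"), 0)
  expect_equal(ede(P, P, "as_printed"), 3)        # mean of within-curve chords
  Q <- cbind(0:3, 4, 0)
  expect_equal(ede(P, Q, "corrected"), 4)         # both endpoints displaced by 4
  # corrected mode is orientation-invariant
  expect_equal(ede(P, Q[4:1, ], "corrected"), 4)
})

test_that("discrete Frechet distance matches the enumeration oracle", {
  P <- cbind(c(0, 1), c(0, 0), c(0, 0))
  Q <- cbind(c(0, 1), c(1, 1), c(0, 0))
  expect_equal(frechet_distance(P, P), 0)
  expect_equal(frechet_distance(P, Q), 1)
  set.seed(99)
  for (trial in 1:100) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    p <- matrix(runif(3 * m, 0, 5), m, 3)
    q <- matrix(runif(3 * n, 0, 5), n, 3)
    oracle <- min(frechet_oracle(p, q),
                  frechet_oracle(p, q[rev(seq_len(n)), , drop = FALSE]))
    expect_equal(frechet_distance(p, q), oracle, tolerance = 1e-12)
    expect_equal(frechet_distance(q, p), oracle, tolerance = 1e-12)
  }
})

test_that("length metrics normalize by the ground-truth curve", {
  P <- cbind(c(0, 10), 0, 0)
  Q <- cbind(c(0, 8), 0, 0)
  lm <- length_metrics(P, Q)
  expect_equal(lm$LD, 2)
  expect_equal(lm$DP, 25)
  expect_equal(length_metrics(Q, Q), list(LD = 0, DP = 0))
  # rigid motion leaves both unchanged
  R <- cbind(Q[, 2] + 3, Q[, 1] - 7, Q[, 3])
  expect_equal(length_metrics(P, R)$DP, 25)
  expect_error(length_metrics(P, cbind(1, 1, 1)), "zero-length")
})

two_track_reference <- function() {
  nodes <- data.frame(id = 1:4, frame = c(0, 0, 1, 1), label = c(1, 2, 1, 2),
                      track = c(1, 2, 1, 2))
  edges <- data.frame(from = c(1, 2), to = c(3, 4))
  track_graph(nodes, edges)
}

test_that("AOGM counts edit operations against a node correspondence", {
  ref <- two_track_reference()
  expect_equal(aogm(ref, ref), 0)
  # deleting one link edge costs the edge-addition weight
  res <- track_graph(ref$nodes, ref$edges[1, , drop = FALSE])
  expect_equal(aogm(ref, res), 1.5)
  # the empty result costs the build-from-scratch total
  res0 <- track_graph(ref$nodes[0, ], ref$edges[0, ])
  expect_equal(aogm(ref, res0), aogm_empty(ref))
  expect_equal(aogm_empty(ref), 4 * 10 + 2 * 1.5)
})

test_that("TRA follows the AOGM ratio with its hand-derived values", {
  ref <- two_track_reference()
  expect_equal(tra(ref, ref), 1)
  res <- track_graph(ref$nodes, ref$edges[2, , drop = FALSE])
  expect_equal(tra(ref, res), 1 - 1.5 / 43)
  res0 <- track_graph(ref$nodes[0, ], ref$edges[0, ])
  expect_equal(tra(ref, res0), 0)
  expect_error(tra(res0, ref), "empty reference")
  # monotone non-increasing as edits accumulate
  res_less <- track_graph(ref$nodes[-4, ], ref$edges[1, , drop = FALSE])
  expect_lt(tra(ref, res_less), tra(ref, res))
  # configurable weights feed straight through
  expect_equal(tra(ref, res, aogm_weights(ea = 3)), 1 - 3 / 46)
})

test_that("node splits and spurious nodes are penalized through matching", {
  ref <- two_track_reference()
  # a result in which one node covers both reference cells of frame 0
  res_nodes <- data.frame(id = 1:3, frame = c(0, 1, 1), label = c(7, 1, 2),
                          track = c(7, 1, 2))
  res <- track_graph(res_nodes, data.frame(from = integer(0), to = integer(0)))
  matching <- data.frame(ref_id = c(1, 2, 3, 4), res_id = c(1, 1, 2, 3))
  # one split (5) + two missing edges (2 * 1.5)
  expect_equal(aogm(ref, res, matching = matching), 5 + 3)
})
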