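test_that("auto_seeds handles degenerate probability maps", {
  q <- array(1, c(6, 6, 6))
  expect_equal(max(auto_seeds(q, 2)), 0)            # all membrane: no seeds
  expect_error(auto_seeds(q, 0.5), "minimum_distance")
  expect_error(auto_seeds(array(2, c(4, 4, 4)), 2), "\\[0, 1\\]")
  # a single cubic interior region yields exactly one seed at its centre
  q <- array(1, c(11, 11, 11))
  q[4:8, 4:8, 4:8] <- 0
  s <- auto_seeds(q, 3)
  expect_equal(sum(s > 0), 1)
  expect_equal(which(s == 1L), 666L)   # (z,y,x) = (6,6,6) linear index
})

test_that("auto_seeds places one seed inside each phantom cell", {
  ph <- mid_phantom(7)
  q <- fallback_probability(ph$intensity, 1)
  s <- auto_seeds(q, 10, 0.02, intensity = ph$intensity, spacing = c(2, 1, 1))
  expect_equal(max(s), 8)
  expect_identical(sort(ph$labels[which(s > 0)]), 1:8)
})

test_that("watershed floods every voxel from the seeds", {
  ph <- mid_phantom(7)
  q <- fallback_probability(ph$intensity, 1)
  s <- array(0L, dim(q)); s[12, 24, 24] <- 1L
  x <- watershed_partition(q, s)
  expect_true(all(x == 1L))                        # one seed takes all
  s8 <- auto_seeds(q, 10, 0.02, intensity = ph$intensity, spacing = c(2, 1, 1))
  x8 <- watershed_partition(q, s8)
  expect_identical(sort(unique(as.vector(x8))), 1:8)
  expect_equal(sum(tabulate(x8)), length(x8))      # labels partition the volume
  expect_error(watershed_partition(q, array(0L, dim(q))), "seeds")
})

test_that("unary potentials follow -log(1 - q) with an epsilon floor", {
  q <- array(c(0, 0.5, 1, 0.25), c(1, 2, 2))
  x0 <- array(c(1L, 1L, 2L, 2L), c(1, 2, 2))
  U <- unary_potentials(q, x0, crf_params())
  expect_equal(U[1, 2], 0)                         # q = 0, own label
  expect_equal(U[2, 2], log(2))                    # q = 0.5, own label
  expect_equal(U[3, 3], -log(1e-6))                # q = 1: floored
  expect_equal(U[1, 3], -log(1e-6))                # foreign label: floor
  expect_true(all(is.finite(U)))
})

test_that("pairwise kernel matches a direct evaluation and its bounds", {
  p <- crf_params()
  f <- c(1, 2, 3, 0.4)
  expect_equal(pairwise_kernel(f, f, p), 2)        # gamma_1 + gamma_2
  # independent high-precision scalar evaluation
  f_i <- c(0, 0, 0, 0.1); f_j <- c(0, 0.06, 0.08, 0.3)  # |dp| = 0.1, |dq| = 0.2
  manual <- 1 * exp(-0.1^2 / (2 * 3^2) - 0.2^2 / (2 * 5^2)) +
    1 * exp(-0.1^2 / (2 * 10^2))
  expect_equal(pairwise_kernel(f_i, f_j, p), manual, tolerance = 1e-12)
  expect_equal(pairwise_kernel(f_j, f_i, p), manual, tolerance = 1e-12)
  far <- c(1e4, 0, 0, 0)
  expect_lt(pairwise_kernel(f_i, far, p), 1e-10)
})

test_that("CRF with zero pairwise weights reproduces the watershed exactly", {
  ph <- mid_phantom(7)
  q <- fallback_probability(ph$intensity, 1)
  s <- auto_seeds(q, 10, 0.02, intensity = ph$intensity, spacing = c(2, 1, 1))
  x0 <- watershed_partition(q, s)
  x <- crf_refine(q, x0, crf_params(gamma_1 = 0, gamma_2 = 0))
  expect_identical(as.vector(x), as.vector(x0))
})

test_that("CRF refinement is deterministic and label-conservative", {
  ph <- mid_phantom(7)
  q <- fallback_probability(ph$intensity, 1)
  s <- auto_seeds(q, 10, 0.02, intensity = ph$intensity, spacing = c(2, 1, 1))
  x0 <- watershed_partition(q, s)
  a <- crf_refine(q, x0)
  b <- crf_refine(q, x0)
  expect_identical(a, b)
  expect_true(all(unique(as.vector(a)) %in% c(0L, unique(as.vector(x0)))))
  expect_error(crf_refine(q[1:10, , ], x0), "shapes")
})

test_that("the discretized-q appearance kernel path runs and refines", {
  # q_scale = 255 makes sigma_beta = 5 narrow on the q axis, exercising
  # the binned message passing
  ph <- small_phantom(3)
  q <- fallback_probability(ph$intensity, 1)
  s <- auto_seeds(q, 5, 0.02, intensity = ph$intensity, spacing = c(2, 1, 1))
  x0 <- watershed_partition(q, s)
  x <- crf_refine(q, x0, crf_params(q_scale = 255, n_bins = 16,
                                    n_iterations = 2))
  expect_true(all(unique(as.vector(x)) %in% c(0L, unique(as.vector(x0)))))
})

test_that("small regions merge into their longest-interface neighbour", {
  x <- array(2L, c(4, 6, 6))
  x[, 1:2, 1:2] <- 1L                               # 16-voxel label
  expect_identical(small_region_filter(x, 0), x)    # threshold 0: identity
  m <- small_region_filter(x, 20)
  expect_true(all(m == 1L))                         # merged + renumbered densely
  # the merge target is the neighbour with the longest shared interface
  y <- array(0L, c(2, 4, 9))
  y[, , 1:4] <- 1L; y[, , 6:9] <- 3L; y[, 1, 5] <- 2L; y[, 2:4, 5] <- 1L
  out <- small_region_filter(y, 3)                  # label 2 (2 voxels) merges
  expect_false(any(out == 0L & y == 2L))
  expect_identical(sort(unique(as.vector(out))), c(1L, 2L))  # renumbered
})

test_that("segment_stack composes the stages deterministically", {
  ph <- mid_phantom(7)
  r1 <- segment_stack(stack = ph$intensity, minimum_distance = 10,
                      threshold = 0.02, label_threshold = 500)
  r2 <- segment_stack(stack = ph$intensity, minimum_distance = 10,
                      threshold = 0.02, label_threshold = 500)
  expect_identical(r1$labels, r2$labels)
  expect_equal(r1$n_cells, 8)
  expect_s3_class(r1, "segmentation_result")
  expect_error(segment_stack(), "intensity stack or a probability")
})
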