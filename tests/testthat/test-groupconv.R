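G <- cube_rotation_group()

test_that("lift layer: delta kernel copies the input into every slot", {
  set.seed(1)
  x <- array(rnorm(6^3), c(6, 6, 6))
  k <- array(0, c(1, 1, 3, 3, 3)); k[1, 1, 2, 2, 2] <- 1
  f <- lift_convolution(x, k, G)
  for (g in 1:24)
    expect_equal(array(f[g, 1, , , ], dim(x)), x, tolerance = 1e-12)
})

test_that("lift layer: constant input and zero-mean kernel give ~0", {
  set.seed(2)
  k <- array(rnorm(27), c(1, 1, 3, 3, 3))
  k <- k - mean(k)
  x <- array(1, c(8, 8, 8))
  f <- lift_convolution(x, k, G)
  expect_lt(max(abs(f[, , 3:6, 3:6, 3:6])), 1e-10)  # away from zero padding
  expect_error(lift_convolution(x, array(0, c(1, 1, 2, 2, 2)), G), "odd")
})

test_that("lift equivariance holds for every group element", {
  set.seed(3)
  x <- array(rnorm(8^3), c(8, 8, 8))
  k <- array(rnorm(27), c(1, 1, 3, 3, 3))
  f <- lift_convolution(x, k, G)
  for (r in 1:24) {
    fr <- lift_convolution(rotate_volume(r, x, G), k, G)
    perm <- celltrack3d:::slot_permutation(G, r)
    dev <- 0
    for (g in 1:24)
      dev <- max(dev, max(abs(array(fr[g, 1, , , ], dim(x)) -
                              rotate_volume(r, array(f[perm[g], 1, , , ],
                                                     dim(x)), G))))
    expect_lt(dev, 1e-5)
  }
})

test_that("group convolution obeys the same equivariance contract", {
  set.seed(4)
  x <- array(rnorm(8^3), c(8, 8, 8))
  lk <- array(rnorm(27), c(1, 1, 3, 3, 3))
  gk <- array(rnorm(24 * 27), c(1, 1, 24, 3, 3, 3))
  f <- lift_convolution(x, lk, G)
  y <- group_convolution(f, gk, G)
  for (r in c(2L, 7L, 13L, 19L, 24L)) {
    yr <- group_convolution(lift_convolution(rotate_volume(r, x, G), lk, G),
                            gk, G)
    perm <- celltrack3d:::slot_permutation(G, r)
    dev <- 0
    for (g in 1:24)
      dev <- max(dev, max(abs(array(yr[g, 1, , , ], dim(x)) -
                              rotate_volume(r, array(y[perm[g], 1, , , ],
                                                     dim(x)), G))))
    expect_lt(dev, 1e-5)
  }
  # zero kernels produce zero output
  expect_equal(max(abs(group_convolution(f, array(0, c(1, 1, 24, 3, 3, 3)), G))), 0)
  # delta kernel in the identity slot only reproduces the input map
  dk <- array(0, c(1, 1, 24, 3, 3, 3)); dk[1, 1, 1, 2, 2, 2] <- 1
  expect_equal(group_convolution(f, dk, G), f, tolerance = 1e-12)
  expect_error(group_convolution(x, gk, G), "dim")
})

test_that("orientation pooling collapses slots as specified", {
  set.seed(5)
  f <- array(rnorm(24 * 2 * 4^3), c(24, 2, 4, 4, 4))
  # all slots equal -> output equals any slot
  fe <- f
  for (g in 1:24) fe[g, , , , ] <- f[1, , , , ]
  expect_equal(orientation_pool(fe), array(f[1, , , , ], c(2, 4, 4, 4)))
  # single nonzero slot -> output equals that slot
  fs <- array(0, dim(f))
  fs[7, , , , ] <- abs(f[7, , , , ])
  expect_equal(orientation_pool(fs), array(abs(f[7, , , , ]), c(2, 4, 4, 4)))
})

test_that("the assembled U-Net maps to [0,1] and is shape-preserving", {
  net <- fixture("unet22", function() equivariant_unet(depth = 2, base_channels = 2,
                                                       seed = 9))
  set.seed(6)
  x <- array(runif(8 * 8 * 8), c(8, 8, 8))
  p <- unet_forward(net, x)
  expect_identical(dim(p), dim(x))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(unet_forward(net, array(0, c(7, 8, 8))), "divisible")
})

test_that("prediction tiles 16-slice windows and blends exactly", {
  net <- fixture("unet22", function() equivariant_unet(depth = 2, base_channels = 2,
                                                       seed = 9))
  set.seed(7)
  x <- array(runif(16 * 8 * 8), c(16, 8, 8))
  expect_equal(predict_probability(net, x), unet_forward(net, x),
               tolerance = 1e-12)
  # fewer than 16 slices: reflection-padded (logged), shape preserved
  xs <- x[1:10, , ]
  expect_message(ps <- predict_probability(net, xs), "reflection-padding")
  expect_identical(dim(ps), dim(xs))
})

test_that("head training on phantom pairs beats the untrained head", {
  ph <- small_phantom(4)
  mask <- boundary_mask(ph$labels)
  net <- equivariant_unet(depth = 2, base_channels = 2, seed = 1)
  trained <- train_probability_head(net, list(ph$intensity), list(mask),
                                    epochs = 5)
  bce <- function(p) {
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    -mean(mask * log(p) + (1 - mask) * log(1 - p))
  }
  expect_lt(bce(unet_forward(trained, ph$intensity)),
            bce(unet_forward(net, ph$intensity)))
  # trained probabilities separate membrane from interior
  q <- unet_forward(trained, ph$intensity)
  expect_gt(mean(q[mask]), mean(q[!mask]) + 0.2)
})

test_that("checkpoints round-trip through save/load", {
  net <- fixture("unet22", function() equivariant_unet(depth = 2, base_channels = 2,
                                                       seed = 9))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_unet(net, path)
  net2 <- load_unet(path)
  set.seed(8)
  x <- array(runif(8^3), c(8, 8, 8))
  expect_identical(unet_forward(net2, x), unet_forward(net, x))
})

test_that("fallback probability is bounded, monotone and warns on constants", {
  ph <- small_phantom(3)
  q <- fallback_probability(ph$intensity, 1)
  expect_true(all(q >= 0 & q <= 1))
  mem <- boundary_mask(ph$labels)
  expect_gt(mean(q[mem]), mean(q[!mem]) + 0.3)   # membranes bright
  expect_warning(z <- fallback_probability(array(0, c(4, 4, 4))), "constant")
  expect_true(all(z == 0))
})
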