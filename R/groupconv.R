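#' @title Rotation-equivariant group convolution layers
#' @description
#' Layers operating on group feature maps: 5D arrays with dimensions
#' (orientation slot = 24, channel, z, y, x). A lift layer turns an
#' intensity grid into a group feature map by convolving with all 24
#' rotated copies of each base kernel; group convolution layers mix
#' orientation slots through the group's composition structure so that the
#' whole stack stays equivariant: rotating the input rotates the output
#' spatially and permutes its orientation slots, nothing else.
#' @name groupconv
NULL

relu <- function(x) { x[x < 0] <- 0; x }

check_group_map <- function(f) {
  d <- dim(f)
  if (length(d) != 5L || d[1] != 24L)
    stop("group feature map must have dim (24, channel, z, y, x)")
  d
}

rotate_kernel_bank_lift <- function(w, group) {
  # w: (C_out, C_in, k, k, k) -> list over g of same-shaped arrays
  dk <- dim(w)
  lapply(1:24, function(g) {
    out <- w
    for (o in seq_len(dk[1])) for (ci in seq_len(dk[2]))
      out[o, ci, , , ] <- rotate_volume(g, array(w[o, ci, , , ], dk[3:5]), group)
    out
  })
}

rotate_kernel_bank_group <- function(w, group) {
  # w: (C_out, C_in, 24, k, k, k) -> list over g
  dk <- dim(w)
  lapply(1:24, function(g) {
    out <- w
    for (o in seq_len(dk[1])) for (ci in seq_len(dk[2])) for (m in 1:24)
      out[o, ci, m, , , ] <- rotate_volume(g, array(w[o, ci, m, , , ], dk[4:6]), group)
    out
  })
}

#' Lifting convolution: intensity grid to group feature map
#'
#' Orientation slot `g` of the output is the plain 3D convolution of the
#' input with the `g`-rotated base kernel. Equivariance: rotating the
#' input by `r` rotates each slot spatially and permutes slots by
#' `g -> r^-1 o g`.
#'
#' @param x input grid, 3D `(z,y,x)` or 4D `(channel,z,y,x)`
#' @param kernels base kernels, array `(C_out, C_in, k, k, k)`, `k` odd
#' @param group a [cube_rotation_group()]; default cached
#' @param bank optional precomputed rotated-kernel bank
#' @return group feature map `(24, C_out, z, y, x)`
#' @export
lift_convolution <- function(x, kernels, group = cached_group(), bank = NULL) {
  if (length(dim(x)) == 3L) x <- array(x, c(1L, dim(x)))
  dk <- dim(kernels)
  if (length(dk) != 5L) stop("lift kernels must be (C_out, C_in, k, k, k)")
  if (any(dk[3:5] %% 2L == 0L))
    stop("kernel extents must be odd (rotation about the centre)")
  if (dim(x)[1] != dk[2]) stop("input channels do not match kernels")
  if (is.null(bank)) bank <- rotate_kernel_bank_lift(kernels, group)
  sp <- dim(x)[2:4]
  out <- array(0, c(24L, dk[1], sp))
  for (g in 1:24) {
    kb <- bank[[g]]
    for (o in seq_len(dk[1])) {
      acc <- array(0, sp)
      for (ci in seq_len(dk[2]))
        acc <- acc + conv3d_same(array(x[ci, , , ], sp),
                                 array(kb[o, ci, , , ], dk[3:5]))
      out[g, o, , , ] <- acc
    }
  }
  out
}

#' Group convolution on group feature maps
#'
#' Output slot `g` sums, over input slots `h`, the convolution of slot `h`
#' with the base kernel indexed by `g^-1 o h`, spatially rotated by `g`.
#' Shares the lift layer's equivariance contract (joint spatial rotation
#' plus slot permutation).
#'
#' @param f group feature map `(24, C_in, z, y, x)`
#' @param kernels array `(C_out, C_in, 24, k, k, k)`
#' @param group a [cube_rotation_group()]
#' @param bank optional precomputed rotated bank
#' @return group feature map `(24, C_out, z, y, x)`
#' @export
group_convolution <- function(f, kernels, group = cached_group(), bank = NULL) {
  d <- check_group_map(f)
  dk <- dim(kernels)
  if (length(dk) != 6L || dk[3] != 24L)
    stop("group kernels must be (C_out, C_in, 24, k, k, k)")
  if (d[2] != dk[2]) stop("input channels do not match kernels")
  if (is.null(bank)) bank <- rotate_kernel_bank_group(kernels, group)
  sp <- d[3:5]
  out <- array(0, c(24L, dk[1], sp))
  inv <- group$inverse
  cay <- group$cayley
  for (g in 1:24) {
    kb <- bank[[g]]
    gi <- inv[g]
    for (o in seq_len(dk[1])) {
      acc <- array(0, sp)
      for (h in 1:24) {
        m <- cay[gi, h]
        for (ci in seq_len(dk[2]))
          acc <- acc + conv3d_same(array(f[h, ci, , , ], sp),
                                   array(kb[o, ci, m, , , ], dk[4:6]))
      }
      out[g, o, , , ] <- acc
    }
  }
  out
}

#' Maximum over orientation slots
#'
#' Per-voxel, per-channel max over the 24 orientation slots. Applied to
#' the output of an equivariant stack this yields a map that is invariant
#' to input rotation up to the spatial rotation itself.
#'
#' @param f group feature map `(24, C, z, y, x)`
#' @return intensity grid `(C, z, y, x)`
#' @export
orientation_pool <- function(f) {
  d <- check_group_map(f)
  out <- array(f[1, , , , ], d[2:5])
  for (g in 2:24) out <- pmax(out, array(f[g, , , , ], d[2:5]))
  out
}

maxpool_spatial <- function(f) {
  d <- dim(f)
  if (any(d[3:5] %% 2L != 0L)) stop("spatial extents must be even for pooling")
  zi <- seq(1L, d[3], 2L); yi <- seq(1L, d[4], 2L); xi <- seq(1L, d[5], 2L)
  out <- f[, , zi, yi, xi, drop = FALSE]
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    if (dz + dy + dx == 0) next
    out <- pmax(out, f[, , zi + dz, yi + dy, xi + dx, drop = FALSE])
  }
  out
}

upsample_spatial <- function(f) {
  d <- dim(f)
  f[, , rep(seq_len(d[3]), each = 2L), rep(seq_len(d[4]), each = 2L),
    rep(seq_len(d[5]), each = 2L), drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(24L, da[2] + db[2], da[3:5]))
  out[, seq_len(da[2]), , , ] <- a
  out[, da[2] + seq_len(db[2]), , , ] <- b
  out
}

#' Build a small rotation-equivariant 3D U-Net
#'
#' Lift layer at entry, group convolutions with ReLU elsewhere, spatial
#' max-pooling and nearest-neighbour upsampling (the orientation axis is
#' never pooled), skip connections by concatenation, and an
#' orientation-pool plus logistic 1x1 head producing a per-voxel membrane
#' probability in `[0, 1]`. Weights are random (seeded); see
#' [train_probability_head()] for the optional smoke-scale training.
#'
#' @param depth number of resolution levels (>= 1)
#' @param base_channels group channels per layer (each holding 24 slots)
#' @param kernel_size odd spatial kernel extent
#' @param seed RNG seed for weight initialization
#' @return object of class `equivariant_unet`
#' @export
equivariant_unet <- function(depth = 3L, base_channels = 4L,
                             kernel_size = 3L, seed = 1L) {
  if (depth < 1L) stop("depth must be >= 1")
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd")
  group <- cached_group()
  set.seed(seed)
  k <- kernel_size
  rand_w <- function(dims, fan_in) array(rnorm(prod(dims), 0, 1 / sqrt(fan_in)), dims)
  lift_w <- rand_w(c(base_channels, 1L, k, k, k), k^3)
  down_w <- lapply(seq_len(max(depth - 1L, 0L)), function(l)
    rand_w(c(base_channels, base_channels, 24L, k, k, k), 24 * base_channels * k^3))
  up_w <- lapply(seq_len(max(depth - 1L, 0L)), function(l)
    rand_w(c(base_channels, 2L * base_channels, 24L, k, k, k),
           24 * 2 * base_channels * k^3))
  head_w <- rnorm(base_channels, 0, 1 / sqrt(base_channels))
  head_b <- 0
  net <- list(depth = as.integer(depth), base_channels = as.integer(base_channels),
              kernel_size = as.integer(k), seed = as.integer(seed),
              lift_w = lift_w, down_w = down_w, up_w = up_w,
              head_w = head_w, head_b = head_b,
              version = "celltrack3d-unet-1")
  net$lift_bank <- rotate_kernel_bank_lift(lift_w, group)
  net$down_bank <- lapply(down_w, rotate_kernel_bank_group, group = group)
  net$up_bank <- lapply(up_w, rotate_kernel_bank_group, group = group)
  class(net) <- "equivariant_unet"
  net
}

# Forward pass up to the orientation-pooled feature map (C, z, y, x).
unet_features <- function(net, vol) {
  assert_volume(vol)
  group <- cached_group()
  m <- 2L^(net$depth - 1L)
  if (any(dim(vol) %% m != 0L))
    stop(sprintf("spatial extents must be divisible by %d (depth %d)",
                 m, net$depth))
  f <- relu(lift_convolution(vol, net$lift_w, group, bank = net$lift_bank))
  skips <- list()
  if (net$depth > 1L) {
    for (l in seq_len(net$depth - 1L)) {
      skips[[l]] <- f
      f <- maxpool_spatial(f)
      f <- relu(group_convolution(f, net$down_w[[l]], group,
                                  bank = net$down_bank[[l]]))
    }
    for (l in rev(seq_len(net$depth - 1L))) {
      f <- upsample_spatial(f)
      f <- concat_channels(f, skips[[l]])
      f <- relu(group_convolution(f, net$up_w[[l]], group,
                                  bank = net$up_bank[[l]]))
    }
  }
  orientation_pool(f)
}

unet_head <- function(net, feats) {
  d <- dim(feats)
  acc <- array(net$head_b, d[2:4])
  for (c_i in seq_len(d[1]))
    acc <- acc + net$head_w[c_i] * array(feats[c_i, , , ], d[2:4])
  stats::plogis(acc)
}

#' Forward pass of the equivariant U-Net on one (sub)volume
#' @param net an [equivariant_unet()]
#' @param vol 3D intensity array with extents divisible by `2^(depth-1)`
#' @return probability volume in `[0, 1]`, same shape
#' @export
unet_forward <- function(net, vol) {
  unet_head(net, unet_features(net, vol))
}

pad_reflect <- function(v, axis, after) {
  if (after <= 0) return(v)
  n <- dim(v)[axis]
  ix <- lapply(dim(v), seq_len)
  ix[[axis]] <- c(seq_len(n), rev(seq_len(n))[seq_len(after)])
  v[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

#' Predict a membrane probability volume for a full stack
#'
#' Tiles the stack into 16-slice z-windows with 4-slice overlap, blends
#' overlaps by averaging, and reflection-pads stacks with fewer than 16
#' slices (logged). Lateral extents are reflection-padded to the U-Net's
#' divisibility constraint and cropped back.
#'
#' @param net an [equivariant_unet()]
#' @param stack normalized 3D intensity volume
#' @param tile_z window depth (16 by default)
#' @param overlap overlap between consecutive windows (4 by default)
#' @return probability volume, same shape as `stack`
#' @export
predict_probability <- function(net, stack, tile_z = 16L, overlap = 4L) {
  assert_volume(stack)
  d0 <- dim(stack)
  m <- 2L^(net$depth - 1L)
  pad_y <- (m - d0[2] %% m) %% m
  pad_x <- (m - d0[3] %% m) %% m
  v <- pad_reflect(pad_reflect(stack, 2L, pad_y), 3L, pad_x)
  nz <- dim(v)[1]
  if (nz < tile_z) {
    log_msg("predict", sprintf("reflection-padding %d z-slices to %d", nz, tile_z))
    v <- pad_reflect(v, 1L, tile_z - nz)
    nz <- tile_z
  }
  stride <- tile_z - overlap
  starts <- unique(c(seq(1L, nz - tile_z + 1L, by = stride), nz - tile_z + 1L))
  acc <- array(0, dim(v)); cnt <- array(0, dim(v))
  for (s in starts) {
    sl <- s:(s + tile_z - 1L)
    acc[sl, , ] <- acc[sl, , ] + unet_forward(net, v[sl, , , drop = FALSE])
    cnt[sl, , ] <- cnt[sl, , ] + 1
  }
  out <- acc / cnt
  out[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
}

#' Train the logistic readout of the U-Net (smoke scale)
#'
#' The equivariant convolution stack is kept fixed (seeded random
#' features, so the rotated kernel copies are never trained
#' independently); the final 1x1 logistic head is fit by iteratively
#' reweighted least squares on voxel-wise binary cross-entropy against
#' membrane masks. One epoch = one IRLS pass.
#'
#' @param net an [equivariant_unet()]
#' @param volumes list of intensity volumes
#' @param masks list of logical membrane masks (same shapes)
#' @param epochs IRLS passes (<= 5 for smoke runs)
#' @param max_voxels subsample cap for the fit, for determinism use of all
#'   voxels below the cap
#' @return the net with updated `head_w`, `head_b`
#' @export
train_probability_head <- function(net, volumes, masks, epochs = 5L,
                                   max_voxels = 200000L) {
  stopifnot(length(volumes) == length(masks), length(volumes) >= 1)
  Xs <- list(); ys <- list()
  for (i in seq_along(volumes)) {
    feats <- unet_features(net, volumes[[i]])
    dC <- dim(feats)[1]
    Xs[[i]] <- t(matrix(feats, nrow = dC))
    ys[[i]] <- as.numeric(masks[[i]])
  }
  X <- do.call(rbind, Xs); y <- unlist(ys)
  if (nrow(X) > max_voxels) {
    keep <- seq(1L, nrow(X), length.out = max_voxels)
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial(),
                   control = list(maxit = epochs)))
  net$head_b <- fit$coefficients[1]
  net$head_w <- fit$coefficients[-1]
  net$head_w[is.na(net$head_w)] <- 0
  if (is.na(net$head_b)) net$head_b <- 0
  net
}

#' Classical fallback membrane probability (no trained model needed)
#'
#' Gaussian-smoothed intensity normalized to `[0, 1]` (membrane-bright
#' convention). Normalization is robust: values are scaled by the
#' `norm_quantile` (99th percentile by default) of the smoothed stack and
#' clipped, so that a handful of very bright wall-junction voxels do not
#' drag ordinary membrane faces below the 0.5 interior cut used for
#' seeding. A monotone (non-decreasing) transform of intensity.
#'
#' @param stack 3D intensity volume
#' @param smooth_sigma per-axis Gaussian sd (scalar recycled)
#' @param norm_quantile upper quantile mapped to 1
#' @return probability volume in `[0, 1]`; all zeros with a warning for
#'   constant input
#' @export
fallback_probability <- function(stack, smooth_sigma = 1,
                                 norm_quantile = 0.99) {
  assert_volume(stack)
  s <- rep(as.numeric(smooth_sigma), length.out = 3)
  v <- if (any(s > 0)) gauss3d(stack, s, normalize = TRUE) else stack
  if (diff(range(v)) <= 0) {
    warning("constant input stack: returning an all-zero probability volume")
    return(array(0, dim(stack)))
  }
  lo <- min(v)
  hi <- as.numeric(stats::quantile(v, norm_quantile))
  if (hi <= lo) hi <- max(v)
  out <- (v - lo) / (hi - lo)
  out[out > 1] <- 1
  out
}

#' Save / load a U-Net checkpoint (single file, version-tagged)
#' @param net an [equivariant_unet()]
#' @param path checkpoint file
#' @export
save_unet <- function(net, path) {
  slim <- net[c("depth", "base_channels", "kernel_size", "seed",
                "lift_w", "down_w", "up_w", "head_w", "head_b", "version")]
  saveRDS(slim, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  slim <- readRDS(path)
  if (!identical(slim$version, "celltrack3d-unet-1"))
    stop("unsupported checkpoint version: ", slim$version)
  group <- cached_group()
  slim$lift_bank <- rotate_kernel_bank_lift(slim$lift_w, group)
  slim$down_bank <- lapply(slim$down_w, rotate_kernel_bank_group, group = group)
  slim$up_bank <- lapply(slim$up_w, rotate_kernel_bank_group, group = group)
  class(slim) <- "equivariant_unet"
  slim
}
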