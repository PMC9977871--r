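#' Dense-CRF refinement parameters
#'
#' Hyperparameters of the pairwise kernel
#' `k(f_i,f_j) = gamma_1 exp(-|p_i-p_j|^2/2 sigma_alpha^2
#'                           - |q_i-q_j|^2/2 sigma_beta^2)
#'             + gamma_2 exp(-|p_i-p_j|^2/2 sigma_gamma^2)`
#' with features `f = <p, q>`: voxel position `p` and membrane probability
#' `q`. Positions are measured in voxels (`sigma_gamma` doubles as the
#' "Minimum Distance" seed spacing, a voxel quantity); `q` is used raw in
#' `[0, 1]` with `sigma_beta = 5` — `q_scale = 255` rescales it to an
#' 8-bit-like range where `sigma_beta` is actually sensitive.
#'
#' @param sigma_alpha appearance-kernel spatial bandwidth, voxels (3)
#' @param sigma_beta appearance-kernel probability bandwidth (5)
#' @param sigma_gamma smoothness-kernel spatial bandwidth, voxels (10);
#'   set by the smallest allowed cell size
#' @param gamma_1,gamma_2 kernel weights (1, 1)
#' @param label_weights per-label weights `w^(m)`; default all 1
#' @param n_iterations mean-field rounds (5, no convergence criterion)
#' @param unary_epsilon probability floor keeping unary costs finite
#' @param q_scale multiplier applied to `q` inside the appearance kernel
#' @param n_bins discretization of the q axis for message passing
#' @return object of class `crf_params`
#' @export
crf_params <- function(sigma_alpha = 3, sigma_beta = 5, sigma_gamma = 10,
                       gamma_1 = 1, gamma_2 = 1, label_weights = NULL,
                       n_iterations = 5L, unary_epsilon = 1e-6,
                       q_scale = 1, n_bins = 16L) {
  if (sigma_alpha <= 0 || sigma_beta <= 0 || sigma_gamma <= 0)
    stop("all sigmas must be > 0")
  if (gamma_1 < 0 || gamma_2 < 0) stop("weights must be >= 0")
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  structure(list(sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
                 sigma_gamma = sigma_gamma, gamma_1 = gamma_1,
                 gamma_2 = gamma_2, label_weights = label_weights,
                 n_iterations = as.integer(n_iterations),
                 unary_epsilon = unary_epsilon, q_scale = q_scale,
                 n_bins = as.integer(n_bins)),
            class = "crf_params")
}

local_maxima26 <- function(v, mask) {
  is_max <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- shift_array(shift_array(shift_array(v, 1L, dz, -Inf), 2L, dy, -Inf),
                      3L, dx, -Inf)
    is_max <- is_max & (v >= nb)
  }
  is_max
}

gray_dilate6 <- function(v) {
  out <- v
  for (axis in 1:3)
    out <- pmax(out, shift_array(v, axis, 1L, -Inf),
                shift_array(v, axis, -1L, -Inf))
  out
}

# Morphological reconstruction of `marker` under `mask` by iterated
# grayscale dilation; used for h-maxima suppression of the EDT.
reconstruct_under <- function(marker, mask) {
  cur <- pmin(marker, mask)
  repeat {
    nxt <- pmin(gray_dilate6(cur), mask)
    if (max(abs(nxt - cur)) < 1e-9) return(nxt)
    cur <- nxt
  }
}

#' Automatic watershed seeds from a probability volume
#'
#' Membrane evidence weaker than `threshold` raw intensity is suppressed
#' (the "Threshold" hyperparameter, typically 0 to 0.1 on a normalized
#' image: intensity below it is ignored, i.e. cannot be cell wall).
#' Interior voxels are those whose remaining membrane probability is
#' below 0.5. Seeds are the regional maxima of the Euclidean distance
#' transform of the interior mask after h-maxima suppression (maxima of
#' prominence below `seed_prominence` voxels are merged into their
#' parent, removing discrete-EDT plateau duplicates along a cell's medial
#' axis), then kept at least `minimum_distance` voxels apart, deepest
#' first ("Minimum Distance", set from the smallest allowed cell size).
#'
#' @param q probability volume, values in `[0, 1]`
#' @param minimum_distance minimum seed separation in voxels (>= 1)
#' @param threshold membrane-evidence intensity threshold
#' @param intensity optional raw intensity stack backing the threshold
#' @param seed_prominence h-maxima depth in voxels
#' @param spacing per-axis voxel spacing (z, y, x); anisotropic stacks
#'   should pass their physical spacing so plate-shaped voxel-space cells
#'   still have a single deepest point
#' @return integer seed volume, 0 everywhere except seed voxels labelled
#'   `1..L`
#' @export
auto_seeds <- function(q, minimum_distance = 10, threshold = 0.02,
                       intensity = NULL, seed_prominence = 2,
                       spacing = c(1, 1, 1)) {
  assert_volume(q, "q")
  if (minimum_distance < 1) stop("minimum_distance must be >= 1")
  if (min(q) < 0 || max(q) > 1) stop("q values must lie in [0, 1]")
  q_eff <- q
  if (!is.null(intensity)) q_eff[intensity < threshold] <- 0
  interior <- q_eff < 0.5
  seeds <- array(0L, dim(q))
  if (!any(interior)) return(seeds)
  # the volume border counts as boundary, so clipped cells keep their
  # deepest point at the cell centre: pad the complement with a shell
  d0 <- dim(q)
  comp_pad <- array(TRUE, d0 + 2L)
  comp_pad[2:(d0[1] + 1L), 2:(d0[2] + 1L), 2:(d0[3] + 1L)] <- !interior
  edt <- distance_to_set(comp_pad, spacing)[2:(d0[1] + 1L), 2:(d0[2] + 1L),
                                            2:(d0[3] + 1L)]
  rec <- reconstruct_under(edt - seed_prominence, edt)
  # a maximum of prominence p carries a dome of height min(h, p); keeping
  # only full-height domes suppresses maxima shallower than h
  domes <- label_components(array(as.integer(edt - rec >= seed_prominence - 1e-6),
                                  dim(q)), 26L)
  nd <- max(domes)
  if (nd == 0L) return(seeds)
  # one representative voxel per dome: its deepest point
  rep_idx <- vapply(seq_len(nd), function(k) {
    ii <- which(domes == k)
    ii[which.max(edt[ii])]
  }, integer(1))
  depth <- edt[rep_idx]
  ord <- order(-depth, rep_idx)
  rep_idx <- rep_idx[ord]
  d <- dim(q)
  coords <- cbind((rep_idx - 1L) %% d[1] * spacing[1],
                  ((rep_idx - 1L) %/% d[1]) %% d[2] * spacing[2],
                  (rep_idx - 1L) %/% (d[1] * d[2]) * spacing[3])
  acc <- matrix(numeric(0), ncol = 3)
  acc_idx <- integer(0)
  for (i in seq_along(rep_idx)) {
    p <- coords[i, ]
    if (nrow(acc) == 0 ||
        all(sqrt(rowSums((acc - matrix(p, nrow(acc), 3, byrow = TRUE))^2)) >=
            minimum_distance)) {
      acc <- rbind(acc, p)
      acc_idx <- c(acc_idx, rep_idx[i])
    }
  }
  seeds[acc_idx] <- seq_along(acc_idx)
  seeds
}

#' Seeded 3D watershed on a probability volume
#'
#' Priority flooding of the elevation `q` from the seed voxels
#' (6-connectivity, deterministic FIFO tie-break). Every voxel receives
#' the label of exactly one seed: the output is a closed partition, with
#' background 0 only where a background seed region was supplied.
#'
#' @param q probability volume (elevation; membranes high)
#' @param seeds integer seed volume from [auto_seeds()] (or any volume
#'   with positive seed labels)
#' @return integer label volume, same shape
#' @export
watershed_partition <- function(q, seeds) {
  assert_volume(q, "q"); assert_volume(seeds, "seeds")
  if (!any(seeds > 0))
    stop_stage("watershed", "no seeds found; lower the intensity threshold ",
               "or the minimum distance")
  lab <- watershed3d(q, array(as.integer(seeds), dim(seeds)))
  bg <- attr(seeds, "background")
  if (!is.null(bg)) lab[lab == bg] <- 0L
  lab
}

#' Unary potentials of the refinement CRF
#'
#' `psi_u(x_i) = -log P(x_i)` with `P = 1 - q_i` for the voxel's watershed
#' label (and for background where the watershed label is 0), and
#' `P = unary_epsilon` for every other label. `P` is floored at
#' `unary_epsilon` so costs stay finite even where `q = 1`.
#'
#' @param q probability volume in `[0, 1]`
#' @param x0 initial (watershed) label volume, labels `0..L`
#' @param params a [crf_params()]
#' @return numeric matrix, voxels x (L+1) label costs; column `l+1` is
#'   label `l`
#' @export
unary_potentials <- function(q, x0, params = crf_params()) {
  assert_volume(q, "q"); assert_volume(x0, "x0")
  if (min(q) < 0 || max(q) > 1) stop("q values must lie in [0, 1]")
  eps <- params$unary_epsilon
  L <- max(x0)
  n <- length(q)
  U <- matrix(-log(eps), n, L + 1L)
  own <- as.integer(x0) + 1L
  U[cbind(seq_len(n), own)] <- -log(pmax(1 - as.numeric(q), eps))
  U
}

#' Pairwise kernel of the dense CRF (scalar form)
#'
#' @param f_i,f_j feature vectors `c(p_z, p_y, p_x, q)` with positions in
#'   voxels and `q` in `[0, 1]`
#' @param params a [crf_params()]
#' @return kernel value in `(0, gamma_1 + gamma_2]`
#' @export
pairwise_kernel <- function(f_i, f_j, params = crf_params()) {
  dp2 <- sum((f_i[1:3] - f_j[1:3])^2)
  dq2 <- ((f_i[4] - f_j[4]) * params$q_scale)^2
  params$gamma_1 * exp(-dp2 / (2 * params$sigma_alpha^2) -
                       dq2 / (2 * params$sigma_beta^2)) +
    params$gamma_2 * exp(-dp2 / (2 * params$sigma_gamma^2))
}

# Raw (unnormalized-tap) Gaussian transport of a field through the
# appearance kernel; the q factor is handled by discretizing q (n_bins),
# or collapsed entirely when sigma_beta covers the q range (with
# sigma_beta = 5 and q in [0,1] the factor is >= 0.98).
appearance_transport <- function(v, params, bins) {
  p <- params
  if (p$sigma_beta >= 2 * p$q_scale)
    return(gauss3d(v, rep(p$sigma_alpha, 3), normalize = FALSE))
  nb <- p$n_bins
  binw <- p$q_scale / nb
  W <- outer(1:nb, 1:nb, function(a, b) exp(-((a - b) * binw)^2 /
                                            (2 * p$sigma_beta^2)))
  filt <- vector("list", nb)
  for (b in seq_len(nb)) {
    vb <- array(0, dim(v))
    vb[bins == b] <- v[bins == b]
    filt[[b]] <- gauss3d(vb, rep(p$sigma_alpha, 3), normalize = FALSE)
  }
  app <- array(0, dim(v))
  for (b in seq_len(nb)) {
    acc <- array(0, dim(v))
    for (b2 in seq_len(nb)) if (W[b, b2] > 1e-8) acc <- acc + W[b, b2] * filt[[b2]]
    sel <- bins == b
    app[sel] <- acc[sel]
  }
  app
}

# Mean-field message sum_j k~(f_i, f_j) v_j for one label's marginal
# field v, excluding j = i. As in standard dense-CRF implementations the
# kernel is normalized per voxel by its response to an all-ones field
# (excluding self), keeping the pairwise energy on the same scale as the
# unary term regardless of the Gaussian bandwidths; `norms` carries the
# precomputed ones-responses from crf_message_norms().
crf_message <- function(v, params, bins = NULL, norms = NULL) {
  p <- params
  msg <- array(0, dim(v))
  if (p$gamma_2 > 0) {
    raw <- gauss3d(v, rep(p$sigma_gamma, 3), normalize = FALSE) - v
    msg <- msg + p$gamma_2 * raw / norms$smooth
  }
  if (p$gamma_1 > 0) {
    raw <- appearance_transport(v, params, bins) - v
    msg <- msg + p$gamma_1 * raw / norms$app
  }
  msg
}

crf_message_norms <- function(dims, params, bins = NULL) {
  ones <- array(1, dims)
  norms <- list()
  if (params$gamma_2 > 0)
    norms$smooth <- pmax(gauss3d(ones, rep(params$sigma_gamma, 3),
                                 normalize = FALSE) - 1, 1e-8)
  if (params$gamma_1 > 0)
    norms$app <- pmax(appearance_transport(ones, params, bins) - 1, 1e-8)
  norms
}

#' Mean-field dense-CRF refinement of a watershed segmentation
#'
#' Approximate minimization of the Gibbs energy (unary potentials from the
#' probability volume and watershed labels; Potts label compatibility
#' scaled by per-label weights over the two Gaussian pairwise kernels).
#' Runs exactly `n_iterations` mean-field rounds; fully deterministic.
#' Labels in the output are a subset of the watershed labels (the CRF
#' refines, never invents). Ties in the final argmax break in favour of
#' the watershed label, so the `gamma_1 = gamma_2 = 0` limit reproduces
#' the watershed exactly.
#'
#' @param q probability volume
#' @param x0 watershed label volume (labels `0..L`, `L >= 1`)
#' @param params a [crf_params()]
#' @return refined integer label volume
#' @export
crf_refine <- function(q, x0, params = crf_params()) {
  assert_volume(q, "q"); assert_volume(x0, "x0")
  if (!all(dim(q) == dim(x0))) stop("q and x0 shapes differ")
  L <- max(x0)
  if (L < 1) stop("need at least one cell label")
  n <- length(q)
  U <- unary_potentials(q, x0, params)
  w <- params$label_weights %||% rep(1, L + 1L)
  if (length(w) != L + 1L) stop("label_weights must have length L + 1")
  # initial marginals from the unary term
  Qm <- exp(-U)
  Qm <- Qm / rowSums(Qm)
  bins <- NULL
  if (params$gamma_1 > 0 && params$sigma_beta < 2 * params$q_scale)
    bins <- array(pmin(floor(as.numeric(q) * params$n_bins) + 1L,
                       params$n_bins), dim(q))
  norms <- crf_message_norms(dim(q), params, bins)
  for (iter in seq_len(params$n_iterations)) {
    M <- matrix(0, n, L + 1L)
    for (l in seq_len(L + 1L))
      M[, l] <- w[l] * as.numeric(crf_message(array(Qm[, l], dim(q)),
                                              params, bins, norms))
    Mtot <- rowSums(M)
    E <- U + (Mtot - M)        # Potts: pay for every differing label's mass
    E <- E - apply(E, 1, min)
    Qm <- exp(-E)
    Qm <- Qm / rowSums(Qm)
  }
  own <- as.integer(x0) + 1L
  best <- max.col(Qm, ties.method = "first")
  own_val <- Qm[cbind(seq_len(n), own)]
  max_val <- Qm[cbind(seq_len(n), best)]
  best[own_val >= max_val - 1e-12] <- own[own_val >= max_val - 1e-12]
  out <- array(as.integer(best - 1L), dim(q))
  out
}

#' Merge labels smaller than a voxel-count threshold
#'
#' Labels with fewer than `label_threshold` voxels (the "Label Threshold"
#' hyperparameter, guarding against protrusions and inter-cellular spaces
#' being labelled as cells) are merged into the neighbouring label with
#' the longest shared interface, or into background if they touch no
#' other label. Remaining labels are renumbered densely `1..L'`.
#'
#' @param x integer label volume
#' @param label_threshold minimum cell size in voxels (0 = identity)
#' @return relabelled volume
#' @export
small_region_filter <- function(x, label_threshold = 0) {
  assert_volume(x, "x")
  if (label_threshold < 0) stop("label_threshold must be >= 0")
  x <- array(as.integer(x), dim(x))
  repeat {
    counts <- tabulate(x[x > 0L], nbins = max(x, 1L))
    small <- which(counts > 0L & counts < label_threshold)
    if (length(small) == 0L) break
    lab <- small[which.min(counts[small])]
    m <- x == lab
    iface <- integer(0)
    for (axis in 1:3) for (s in c(-1L, 1L)) {
      nb <- shift_array(x, axis, s, fill = NA)
      vals <- nb[m]
      vals <- vals[!is.na(vals) & vals != lab & vals != 0L]
      iface <- c(iface, vals)
    }
    target <- if (length(iface) == 0L) 0L else
      as.integer(names(which.max(table(iface))))
    x[m] <- target
  }
  present <- sort(unique(x[x > 0L]))
  if (length(present) > 0L) {
    remap <- integer(max(present)); remap[present] <- seq_along(present)
    pos <- x > 0L
    x[pos] <- remap[x[pos]]
  }
  x
}

#' Full segmentation pipeline: probability, seeds, watershed, CRF, filter
#'
#' @param stack 3D intensity volume (omit when `q` is supplied)
#' @param q optional precomputed probability volume
#' @param net optional [equivariant_unet()]; when absent and `q` missing,
#'   [fallback_probability()] is used
#' @param params a [crf_params()]
#' @param minimum_distance,threshold,label_threshold the three pipeline
#'   hyperparameters (seed spacing, tissue intensity support, minimum
#'   cell size)
#' @param smooth_sigma fallback-probability smoothing
#' @return object of class `segmentation_result` with `labels` (final),
#'   `initial_labels` (watershed), `probability`, `n_cells`
#' @export
segment_stack <- function(stack = NULL, q = NULL, net = NULL,
                          params = crf_params(), minimum_distance = 10,
                          threshold = 0.02, label_threshold = 0,
                          smooth_sigma = 1) {
  if (is.null(stack) && is.null(q))
    stop_stage("segment", "supply an intensity stack or a probability volume")
  t0 <- proc.time()[3]
  if (is.null(q)) {
    q <- if (!is.null(net)) predict_probability(net, stack)
         else fallback_probability(stack, smooth_sigma)
    log_msg("probability", sprintf("%.1fs", proc.time()[3] - t0))
  }
  seeds <- tryCatch(auto_seeds(q, minimum_distance, threshold, intensity = stack),
                    error = function(e) stop_stage("seeds", conditionMessage(e)))
  x0 <- tryCatch(watershed_partition(q, seeds),
                 error = function(e) stop_stage("watershed", conditionMessage(e)))
  log_msg("watershed", sprintf("%d regions", max(x0)))
  xs <- tryCatch(crf_refine(q, x0, params),
                 error = function(e) stop_stage("crf", conditionMessage(e)))
  xf <- tryCatch(small_region_filter(xs, label_threshold),
                 error = function(e) stop_stage("filter", conditionMessage(e)))
  n_cells <- length(unique(xf[xf > 0L]))
  log_msg("segment", sprintf("%d cells, %.1fs total", n_cells,
                             proc.time()[3] - t0))
  structure(list(labels = xf, initial_labels = x0, probability = q,
                 n_cells = n_cells,
                 params = list(crf = params, minimum_distance = minimum_distance,
                               threshold = threshold,
                               label_threshold = label_threshold)),
            class = "segmentation_result")
}
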