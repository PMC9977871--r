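#' Specification of a synthetic cell phantom
#'
#' A phantom emulates, at desk scale, the two kinds of confocal imagery the
#' pipeline targets: space-filling convex-ish cells separated by thin bright
#' membranes (plant epidermis / meristem style) and blob-like bright nuclei
#' on a dark background (developing-embryo style). All downstream modules
#' are tested against phantoms because they come with exhaustive ground
#' truth: the label tessellation, wall/junction point sets and track ids.
#'
#' @param volume_shape integer (z, y, x) extents
#' @param n_cells number of cells (>= 1)
#' @param membrane_width membrane half-thickness in voxels (>= 1)
#' @param membrane_intensity peak membrane (or nucleus) intensity in (0, 1]
#' @param noise_sigma additive Gaussian noise sd
#' @param blur_sigma per-axis Gaussian blur sd (scalar recycled)
#' @param seed RNG seed; identical specs give bit-identical phantoms
#' @param mode `"membrane"` or `"nuclei"`
#' @param z_scale anisotropy factor applied to the z axis in the Voronoi
#'   metric; 2 mirrors the coarser optical sectioning of confocal stacks
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(volume_shape = c(24L, 48L, 48L), n_cells = 8L,
                         membrane_width = 1L, membrane_intensity = 1,
                         noise_sigma = 0, blur_sigma = 1, seed = 1L,
                         mode = c("membrane", "nuclei"), z_scale = 2) {
  mode <- match.arg(mode)
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 1L))
    stop("volume_shape must be three positive integers (z, y, x)")
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (membrane_width < 1L) stop("membrane_width must be >= 1")
  if (membrane_intensity <= 0 || membrane_intensity > 1)
    stop("membrane_intensity must be in (0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (prod(volume_shape) < 125 * n_cells)
    stop(sprintf("volume too small for %d cells: need >= ~5^3 voxels per cell",
                 n_cells))
  structure(list(volume_shape = volume_shape, n_cells = as.integer(n_cells),
                 membrane_width = as.integer(membrane_width),
                 membrane_intensity = membrane_intensity,
                 noise_sigma = noise_sigma,
                 blur_sigma = rep(as.numeric(blur_sigma), length.out = 3),
                 seed = as.integer(seed), mode = mode, z_scale = z_scale),
            class = "phantom_spec")
}

# Voronoi sites by rejection sampling with a minimum pairwise distance of
# half the expected cell diameter (in the anisotropy-scaled metric); this
# avoids degenerate sliver cells. Relaxes the bound geometrically if the
# volume cannot host n sites at that spacing (always terminates).
draw_sites <- function(spec) {
  d <- spec$volume_shape
  vol_scaled <- prod(d) * spec$z_scale
  dmin <- 0.5 * (vol_scaled / spec$n_cells)^(1 / 3)
  sites <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(sites) < spec$n_cells) {
    p <- c(runif(1, 0.5, d[1] + 0.5), runif(1, 0.5, d[2] + 0.5),
           runif(1, 0.5, d[3] + 0.5))
    ok <- TRUE
    if (nrow(sites) > 0) {
      dz <- (sites[, 1] - p[1]) * spec$z_scale
      dd <- sqrt(dz^2 + (sites[, 2] - p[2])^2 + (sites[, 3] - p[3])^2)
      ok <- all(dd >= dmin)
    }
    if (ok) sites <- rbind(sites, p)
    tries <- tries + 1L
    if (tries > 200L * spec$n_cells) { dmin <- dmin * 0.9; tries <- 0L }
  }
  sites
}

voronoi_labels <- function(sites, spec) {
  d <- spec$volume_shape
  z <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  x <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  best <- array(Inf, d)
  lab <- array(0L, d)
  for (i in seq_len(nrow(sites))) {
    dist2 <- ((z - sites[i, 1]) * spec$z_scale)^2 +
      (y - sites[i, 2])^2 + (x - sites[i, 3])^2
    take <- dist2 < best        # strict: ties keep the earlier site
    best[take] <- dist2[take]
    lab[take] <- i
  }
  lab
}

render_intensity <- function(labels, spec, noise = NULL) {
  if (spec$mode == "membrane") {
    mask <- boundary_mask(labels)
    if (spec$membrane_width > 1L)
      mask <- dilate6(mask, spec$membrane_width - 1L)
  } else {
    b <- boundary_mask(labels)
    dist <- distance_to_set(b)
    mask <- dist >= (spec$membrane_width + 2)
  }
  img <- array(0, dim(labels))
  img[mask] <- spec$membrane_intensity
  if (any(spec$blur_sigma > 0))
    img <- gauss3d(img, spec$blur_sigma, normalize = TRUE)
  if (!is.null(noise)) img <- img + noise
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a synthetic 3D cell phantom
#'
#' Draws `n_cells` Voronoi sites (rejection-sampled for a minimum spacing),
#' tessellates the volume under an anisotropic metric, then renders either
#' bright membranes on the inter-cell faces or bright eroded nuclei cores,
#' Gaussian-blurs, adds noise and clips to `[0, 1]`.
#'
#' @param spec a [phantom_spec()]
#' @return list with `intensity` (numeric array in `[0,1]`), `labels`
#'   (integer array; in membrane mode every voxel is labelled `1..n_cells`,
#'   in nuclei mode label 0 marks background), `sites`, and `spec`
#' @export
generate_cell_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  sites <- draw_sites(spec)
  vor <- voronoi_labels(sites, spec)
  noise <- NULL
  if (spec$noise_sigma > 0)
    noise <- array(rnorm(prod(spec$volume_shape), 0, spec$noise_sigma),
                   spec$volume_shape)
  intensity <- render_intensity(vor, spec, noise)
  labels <- vor
  if (spec$mode == "nuclei") {
    b <- boundary_mask(vor)
    core <- distance_to_set(b) >= (spec$membrane_width + 2)
    labels <- ifelse(core, vor, 0L)
    storage.mode(labels) <- "integer"
    dim(labels) <- spec$volume_shape
  }
  structure(list(intensity = intensity, labels = labels, sites = sites,
                 spec = spec), class = "cell_phantom")
}

# Smooth bounded displacement field for one time step: a global random
# translation plus one low-frequency sinusoidal warp per axis, scaled so
# the per-axis total never exceeds max_shift, and tapered to zero at the
# volume border. The taper keeps every cell inside the field of view, so
# cell counts stay constant over a sequence — matching slow epidermal
# growth, where each imaged sequence has a fixed set of cells. Returns a
# list of three arrays (dz, dy, dx).
displacement_field <- function(d, max_shift) {
  if (max_shift <= 0)
    return(lapply(1:3, function(a) array(0, d)))
  tr <- runif(3, -0.6, 0.6) * max_shift
  amp <- runif(3, 0, 0.4) * max_shift
  phase <- runif(3, 0, 2 * pi)
  z <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  x <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  taper_len <- 4 * max(1, max_shift)
  border <- pmin(z - 1, d[1] - z, y - 1, d[2] - y, x - 1, d[3] - x)
  taper <- pmin(border / taper_len, 1)
  lapply(1:3, function(a) {
    taper * (tr[a] + amp[a] * sin(2 * pi * x / d[3] + phase[a]) *
               sin(2 * pi * y / d[2] + phase[(a %% 3) + 1]))
  })
}

warp_labels <- function(labels, disp) {
  d <- dim(labels)
  z <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  x <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  sz <- pmin(pmax(round(z - disp[[1]]), 1L), d[1])
  sy <- pmin(pmax(round(y - disp[[2]]), 1L), d[2])
  sx <- pmin(pmax(round(x - disp[[3]]), 1L), d[3])
  out <- labels[cbind(as.vector(sz), as.vector(sy), as.vector(sx))]
  dim(out) <- d
  out
}

#' Generate a synthetic time-lapse sequence with persistent cell identity
#'
#' Each frame is the previous frame's label tessellation transported by a
#' smooth random displacement (global translation plus a low-frequency
#' sinusoidal warp) bounded by `max_shift` voxels per axis; intensities are
#' re-rendered from the warped labels. With `max_shift = 0` all frames are
#' bit-identical (the additive noise realization is drawn once per sequence
#' for exactly this invariant). Track ids persist; a cell that loses all
#' its voxels terminates its track.
#'
#' @param spec a [phantom_spec()]
#' @param n_frames number of frames (>= 1)
#' @param max_shift maximum per-axis displacement per step, voxels
#' @return class `phantom_sequence`: `frames` (list of
#'   `list(intensity, labels)`), `track_table` (data.frame with columns
#'   `track_id, begin, end, parent`), and `spec`
#' @export
generate_timelapse <- function(spec, n_frames, max_shift = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(spec$seed)
  sites <- draw_sites(spec)
  labels <- voronoi_labels(sites, spec)
  noise <- NULL
  if (spec$noise_sigma > 0)
    noise <- array(rnorm(prod(spec$volume_shape), 0, spec$noise_sigma),
                   spec$volume_shape)
  frames <- vector("list", n_frames)
  present_at <- matrix(FALSE, n_frames, spec$n_cells)
  cur <- labels
  for (t in seq_len(n_frames)) {
    if (t > 1) {
      disp <- displacement_field(spec$volume_shape, max_shift)
      cur <- warp_labels(cur, disp)
    }
    present_at[t, sort(unique(as.integer(cur[cur > 0])))] <- TRUE
    frames[[t]] <- list(intensity = render_intensity(cur, spec, noise),
                        labels = cur)
  }
  # label transport can only lose cells, so presence is contiguous from
  # frame 0; `end` is the last frame before the first gap
  end <- vapply(seq_len(spec$n_cells), function(p) {
    last <- 0L
    while (last < n_frames && present_at[last + 1L, p]) last <- last + 1L
    last - 1L
  }, integer(1))
  track_table <- data.frame(track_id = seq_len(spec$n_cells), begin = 0L,
                            end = end, parent = 0L)
  track_table <- track_table[track_table$end >= 0L, , drop = FALSE]
  structure(list(frames = frames, track_table = track_table, spec = spec),
            class = "phantom_sequence")
}

#' Brute-force ground-truth wall and junction point sets
#'
#' The independent oracle for the sub-cellular feature module: an
#' exhaustive per-voxel scan. A voxel belongs to the wall of cells
#' `(i, j)` iff its neighbourhood (self plus face neighbours, or the full
#' 26-neighbourhood with `connectivity = 26`) intersects both cells; it
#' belongs to the junction set of `(i, j, k)` iff the neighbourhood
#' intersects three distinct cells. No graph structure is used. The
#' face-neighbour default is the one consistent with the distance-1
#' neighbour rule of the adjacency graph: a pair shares wall points
#' exactly when its dilation distance is 1.
#'
#' @param labels integer 3D label array (0 = background, ignored)
#' @param connectivity 6 (face neighbours, default) or 26
#' @return list with `walls`: named list `"i|j"` of coordinate matrices
#'   (1-based, columns z,y,x), and `junctions`: named list `"i|j|k"` of
#'   coordinate matrices
#' @export
ground_truth_features <- function(labels, connectivity = 6L) {
  assert_volume(labels, "labels")
  d <- dim(labels)
  walls <- list()
  junctions <- list()
  offs <- if (connectivity == 6L)
    rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  else as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    u <- integer(0)
    for (o in seq_len(nrow(offs))) {
      zz <- z + offs[o, 1]; yy <- y + offs[o, 2]; xx <- x + offs[o, 3]
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3])
        next
      u <- c(u, labels[zz, yy, xx])
    }
    u <- sort(unique(u[u > 0]))
    if (length(u) >= 2) {
      prs <- utils::combn(u, 2)
      for (c_i in seq_len(ncol(prs))) {
        key <- paste(prs[1, c_i], prs[2, c_i], sep = "|")
        walls[[key]] <- rbind(walls[[key]], c(z, y, x))
      }
    }
    if (length(u) >= 3) {
      trs <- utils::combn(u, 3)
      for (c_i in seq_len(ncol(trs))) {
        key <- paste(trs[1, c_i], trs[2, c_i], trs[3, c_i], sep = "|")
        junctions[[key]] <- rbind(junctions[[key]], c(z, y, x))
      }
    }
  }
  walls <- lapply(walls, function(m) { colnames(m) <- c("z", "y", "x"); m })
  junctions <- lapply(junctions, function(m) { colnames(m) <- c("z", "y", "x"); m })
  list(walls = walls, junctions = junctions)
}
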