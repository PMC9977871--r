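# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

# small 5-cell phantom: cheap enough for the brute-force oracles
small_phantom <- function(seed = 3) {
  fixture(paste0("small_", seed), function()
    generate_cell_phantom(phantom_spec(c(12L, 20L, 20L), n_cells = 5L,
                                       seed = seed)))
}

# mid-size clean 8-cell phantom used by the segmentation tests
mid_phantom <- function(seed = 7, noise = 0) {
  fixture(sprintf("mid_%d_%g", seed, noise), function()
    generate_cell_phantom(phantom_spec(c(24L, 48L, 48L), n_cells = 8L,
                                       seed = seed, noise_sigma = noise)))
}

# three collinear slab cells of width 2 with 1-voxel gaps along x:
# merge distances w12 = w23 = 1 and w13 = 3 (fronts meet after
# ceil((7 - 2) / 2) = 3 rounds)
collinear_cells <- function() {
  x <- array(0L, c(3L, 3L, 8L))
  x[, , 1:2] <- 1L
  x[, , 4:5] <- 2L
  x[, , 7:8] <- 3L
  x
}

# two half-volumes split across x
half_volumes <- function(d = c(6L, 8L, 8L)) {
  x <- array(1L, d)
  x[, , (d[3] %/% 2 + 1L):d[3]] <- 2L
  x
}

# three ~120-degree sectors in-plane, extruded along z
sector_volume <- function(d = c(4L, 17L, 17L)) {
  x <- array(0L, d)
  cy <- (d[2] + 1) / 2; cx <- (d[3] + 1) / 2
  for (y in seq_len(d[2])) for (xx in seq_len(d[3])) {
    ang <- atan2(y - cy, xx - cx)
    lab <- if (ang < -pi / 3) 1L else if (ang < pi / 3) 2L else 3L
    x[, y, xx] <- lab
  }
  x
}

# independent discrete-Frechet oracle: exhaustive DFS over all monotone
# couplings (steps +1/0 on each index, endpoints pinned), min over
# couplings of the max pair distance
frechet_oracle <- function(p, q) {
  m <- nrow(p); n <- nrow(q)
  dmat <- matrix(0, m, n)
  for (a in seq_len(m))
    dmat[a, ] <- sqrt(colSums((t(q) - p[a, ])^2))
  best <- Inf
  rec <- function(a, b, cur) {
    cur <- max(cur, dmat[a, b])
    if (cur >= best) return(invisible())
    if (a == m && b == n) { best <<- cur; return(invisible()) }
    if (a < m) rec(a + 1, b, cur)
    if (b < n) rec(a, b + 1, cur)
    if (a < m && b < n) rec(a + 1, b + 1, cur)
  }
  rec(1, 1, 0)
  best
}

# ground-truth face adjacency (6-neighbour label contact) of a tessellation
face_adjacency <- function(labels) {
  prs <- NULL
  d <- dim(labels)
  shift <- celltrack3d:::shift_array
  for (axis in 1:3) {
    nb <- shift(labels, axis, 1L, fill = NA)
    sel <- !is.na(nb) & nb != labels & labels > 0L & nb > 0L
    if (any(sel))
      prs <- rbind(prs, cbind(pmin(labels[sel], nb[sel]),
                              pmax(labels[sel], nb[sel])))
  }
  unique(as.data.frame(prs))
}

point_key <- function(m) paste(m[, 1], m[, 2], m[, 3])
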