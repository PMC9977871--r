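#' Anticlinal wall point set shared by two neighbouring cells
#'
#' All voxels whose neighbourhood (self plus face neighbours by default,
#' the full 26-neighbourhood with `connectivity = 26`) intersects both
#' cell `i` and cell `j` — "shared points" read as neighbourhood
#' incidence on the voxel grid, since a CRF-refined partition is gapless
#' and has no dedicated boundary voxels. Symmetric in `(i, j)`. With the
#' face-neighbour default the wall of a pair is nonempty exactly when the
#' pair is at dilation distance 1.
#'
#' @param x integer label volume
#' @param g the cell [build_adjacency_graph()]
#' @param i,j cell labels with `j` a distance-1 neighbour of `i`
#' @param connectivity incidence neighbourhood: 6 (default) or 26
#' @return coordinate matrix (1-based, columns z, y, x), possibly 0-row
#' @export
wall_segment <- function(x, g, i, j, connectivity = 6L) {
  assert_volume(x, "x")
  w <- edge_weight(g, i, j)
  if (is.na(w) || w != 1L)
    stop(sprintf("cells %d and %d are not distance-1 neighbours (distance %s)",
                 i, j, ifelse(is.na(w), paste0("> ", g$r_max), w)))
  ti <- touch_mask(x, i, connectivity)
  tj <- touch_mask(x, j, connectivity)
  coords_of(ti & tj, dim(x))
}

touch_mask <- function(x, l, connectivity) {
  m <- x == l
  if (connectivity == 26L) dilate_box(m, 1L) else dilate6(m, 1L)
}

coords_of <- function(mask, d) {
  idx <- which(mask)
  m <- cbind(z = (idx - 1L) %% d[1] + 1L,
             y = ((idx - 1L) %/% d[1]) %% d[2] + 1L,
             x = (idx - 1L) %/% (d[1] * d[2]) + 1L)
  m
}

#' Junctions of three cell walls incident to a cell pair
#'
#' Union over `k` in the common neighbourhood `N_i` intersect `N_j` of
#' the voxels whose incidence neighbourhood intersects cells `i`, `j`
#' and `k`. Empty when the pair has no common neighbour.
#'
#' @inheritParams wall_segment
#' @return coordinate matrix (columns z, y, x, k)
#' @export
junctions <- function(x, g, i, j, connectivity = 6L) {
  assert_volume(x, "x")
  w <- edge_weight(g, i, j)
  if (is.na(w) || w != 1L)
    stop(sprintf("cells %d and %d are not distance-1 neighbours (distance %s)",
                 i, j, ifelse(is.na(w), paste0("> ", g$r_max), w)))
  common <- intersect(graph_neighbors(g, i), graph_neighbors(g, j))
  out <- matrix(integer(0), ncol = 4, dimnames = list(NULL, c("z", "y", "x", "k")))
  if (length(common) == 0L) return(out)
  ti <- touch_mask(x, i, connectivity)
  tj <- touch_mask(x, j, connectivity)
  tij <- ti & tj
  for (k in common) {
    tk <- touch_mask(x, k, connectivity)
    m <- coords_of(tij & tk, dim(x))
    if (nrow(m) > 0) out <- rbind(out, cbind(m, k = k))
  }
  out
}

#' Order an unordered wall point set into a polyline
#'
#' Nearest-neighbour chaining starting from the point farthest from the
#' set centroid. If the set has several 26-connected components, the
#' largest is used (logged). Every retained point is visited exactly once.
#'
#' @param points coordinate matrix (columns z, y, x)
#' @return object of class `polyline3d`: the ordered coordinate matrix
#' @export
order_segment <- function(points) {
  if (is.null(points) || nrow(points) == 0L) stop("empty point set")
  pts <- points[, 1:3, drop = FALSE]
  if (nrow(pts) > 1L) {
    dd <- as.matrix(stats::dist(pts, method = "maximum"))
    adj <- dd <= 1                    # Chebyshev <= 1 is 26-connectivity
    comp <- integer(nrow(pts)); cur <- 0L
    for (s in seq_len(nrow(pts))) {
      if (comp[s] != 0L) next
      cur <- cur + 1L
      stack <- s
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        if (comp[v] != 0L) next
        comp[v] <- cur
        stack <- c(stack, which(adj[v, ] & comp == 0L))
      }
    }
    if (cur > 1L) {
      keep <- comp == which.max(tabulate(comp))
      log_msg("order_segment",
              sprintf("point set has %d components; keeping largest (%d/%d points)",
                      cur, sum(keep), length(keep)))
      pts <- pts[keep, , drop = FALSE]
    }
  }
  n <- nrow(pts)
  if (n == 1L) {
    out <- pts
  } else {
    ctr <- colMeans(pts)
    d2c <- rowSums((pts - matrix(ctr, n, 3, byrow = TRUE))^2)
    ord <- integer(n)
    used <- logical(n)
    ord[1] <- which.max(d2c)
    used[ord[1]] <- TRUE
    de <- as.matrix(stats::dist(pts))
    for (s in 2:n) {
      prev <- ord[s - 1]
      cand <- which(!used)
      ord[s] <- cand[which.min(de[prev, cand])]
      used[ord[s]] <- TRUE
    }
    out <- pts[ord, , drop = FALSE]
  }
  structure(out, class = c("polyline3d", class(out)))
}

#' Extract all anticlinal wall segments and three-wall junctions
#'
#' Iterates every distance-1 cell pair once, deduplicates the volume-wide
#' junction voxel set, and cuts each raw wall point set at junction
#' voxels into maximal junction-to-junction runs, so each anticlinal
#' segment spans two junctions where available. Runs shorter than
#' `min_run` voxels are discarded as noise (logged).
#'
#' @param x integer label volume
#' @param g its [build_adjacency_graph()]
#' @param connectivity incidence neighbourhood: 6 (default) or 26
#' @param min_run minimum polyline length in voxels (default 3)
#' @return list with `segments` (list of `polyline3d` with attributes
#'   `cells`), `walls` (raw per-pair point sets, named `"i|j"`),
#'   `junctions` (deduplicated matrix z,y,x), `junction_triples`
#'   (named list `"i|j|k"` of point matrices)
#' @export
extract_all_features <- function(x, g, connectivity = 6L, min_run = 3L) {
  assert_volume(x, "x")
  e1 <- g$edges[g$edges$weight == 1L, , drop = FALSE]
  walls <- list()
  triples <- list()
  junc_all <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("z", "y", "x")))
  labs <- g$vertices$label
  touch <- lapply(labs, function(l) touch_mask(x, l, connectivity))
  names(touch) <- as.character(labs)
  nbrs <- lapply(labs, function(l) graph_neighbors(g, l))
  names(nbrs) <- as.character(labs)
  d <- dim(x)
  for (r in seq_len(nrow(e1))) {
    i <- e1$i[r]; j <- e1$j[r]
    tij <- touch[[as.character(i)]] & touch[[as.character(j)]]
    walls[[paste(i, j, sep = "|")]] <- coords_of(tij, d)
    common <- intersect(nbrs[[as.character(i)]], nbrs[[as.character(j)]])
    for (k in common[common > j]) {
      m <- coords_of(tij & touch[[as.character(k)]], d)
      if (nrow(m) > 0) {
        triples[[paste(i, j, k, sep = "|")]] <- m
        junc_all <- rbind(junc_all, m)
      }
    }
  }
  # deduplicated junction voxels also need triples where k < j; collect
  # them from every unordered triple by re-scanning pairs (i,k) too
  for (r in seq_len(nrow(e1))) {
    i <- e1$i[r]; j <- e1$j[r]
    common <- intersect(nbrs[[as.character(i)]], nbrs[[as.character(j)]])
    for (k in common) {
      tri <- sort(c(i, j, k))
      key <- paste(tri, collapse = "|")
      if (!is.null(triples[[key]])) next
      m <- coords_of(touch[[as.character(tri[1])]] &
                     touch[[as.character(tri[2])]] &
                     touch[[as.character(tri[3])]], d)
      if (nrow(m) > 0) {
        triples[[key]] <- m
        junc_all <- rbind(junc_all, m)
      }
    }
  }
  junc_all <- unique(junc_all)
  segments <- list()
  jkeys <- character(0)
  if (nrow(junc_all) > 0)
    jkeys <- paste(junc_all[, 1], junc_all[, 2], junc_all[, 3])
  n_dropped <- 0L
  for (key in names(walls)) {
    w <- walls[[key]]
    if (nrow(w) == 0L) next
    keep <- !(paste(w[, 1], w[, 2], w[, 3]) %in% jkeys)
    w2 <- w[keep, , drop = FALSE]
    if (nrow(w2) == 0L) next
    comp <- components26(w2)
    for (c_i in seq_len(max(comp))) {
      run <- w2[comp == c_i, , drop = FALSE]
      if (nrow(run) < min_run) { n_dropped <- n_dropped + 1L; next }
      pl <- order_segment(run)
      attr(pl, "cells") <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      segments[[length(segments) + 1L]] <- pl
    }
  }
  if (n_dropped > 0L)
    log_msg("features", sprintf("discarded %d runs shorter than %d voxels",
                                n_dropped, min_run))
  list(segments = segments, walls = walls, junctions = junc_all,
       junction_triples = triples)
}

components26 <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(1L)
  dd <- as.matrix(stats::dist(pts, method = "maximum"))
  adj <- dd <= 1
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}
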