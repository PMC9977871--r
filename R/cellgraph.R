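#' Dilation merge distance between two cell masks
#'
#' The smallest round count r (at least 1) such that the r-fold 6-connected dilations of
#' the two masks intersect — equivalently, the number of simultaneous
#' morphological dilation rounds until the two cells become one connected
#' component. Voxel-adjacent cells have distance 1.
#'
#' @param mask_i,mask_j disjoint, nonempty logical masks (same shape)
#' @param r_max maximum number of rounds tried
#' @return integer distance, or `NA` when not merged within `r_max`
#' @export
merge_distance <- function(mask_i, mask_j, r_max = 3L) {
  assert_volume(mask_i, "mask_i"); assert_volume(mask_j, "mask_j")
  if (!any(mask_i) || !any(mask_j)) stop("masks must be nonempty")
  if (any(mask_i & mask_j)) stop("masks must be disjoint (labels overlap)")
  a <- mask_i; b <- mask_j
  for (r in seq_len(r_max)) {
    a <- dilate6(a, 1L)
    b <- dilate6(b, 1L)
    if (any(a & b)) return(as.integer(r))
  }
  NA_integer_
}

#' Build the weighted cell adjacency graph by simultaneous dilation
#'
#' All label masks are dilated one 6-connected round at a time; the first
#' round at which the fronts of labels `i` and `j` meet sets the edge
#' weight `w_ij = r`. Equivalent to [merge_distance()] on every pair, but
#' one sweep. Background (label 0) never participates. Distance-1 pairs
#' are the neighbour relation used for sub-cellular features and the
#' degree feature; edges are tracked up to `r_max`.
#'
#' @param x integer label volume
#' @param r_max largest dilation distance recorded (default 3)
#' @return object of class `adjacency_graph`: `vertices` data.frame
#'   (`label`, `size`), `edges` data.frame (`i`, `j`, `weight`, `i < j`),
#'   `r_max`
#' @export
build_adjacency_graph <- function(x, r_max = 3L) {
  assert_volume(x, "x")
  labs <- sort(unique(x[x > 0L]))
  sizes <- vapply(labs, function(l) sum(x == l), numeric(1))
  vertices <- data.frame(label = as.integer(labs), size = as.integer(sizes))
  edges <- data.frame(i = integer(0), j = integer(0), weight = integer(0))
  if (length(labs) >= 2L) {
    masks <- lapply(labs, function(l) x == l)
    names(masks) <- labs
    pending <- utils::combn(seq_along(labs), 2)
    found_i <- integer(0); found_j <- integer(0); found_w <- integer(0)
    for (r in seq_len(r_max)) {
      masks <- lapply(masks, dilate6, rounds = 1L)
      if (ncol(pending) == 0L) break
      hit <- logical(ncol(pending))
      for (c_i in seq_len(ncol(pending))) {
        a <- pending[1, c_i]; b <- pending[2, c_i]
        if (any(masks[[a]] & masks[[b]])) {
          found_i <- c(found_i, labs[a]); found_j <- c(found_j, labs[b])
          found_w <- c(found_w, r)
          hit[c_i] <- TRUE
        }
      }
      pending <- pending[, !hit, drop = FALSE]
    }
    edges <- data.frame(i = as.integer(found_i), j = as.integer(found_j),
                        weight = as.integer(found_w))
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(vertices = vertices, edges = edges, r_max = as.integer(r_max)),
            class = "adjacency_graph")
}

#' Distance-1 neighbours of a cell
#'
#' All cells at dilation distance exactly 1 from cell `i` — the neighbour
#' set `N_i` that defines walls, junctions and the degree feature.
#'
#' @param g an [build_adjacency_graph()] result
#' @param i cell label
#' @return integer vector of neighbour labels (possibly empty)
#' @export
graph_neighbors <- function(g, i) {
  stopifnot(inherits(g, "adjacency_graph"))
  if (!(i %in% g$vertices$label)) stop("unknown label: ", i)
  e <- g$edges[g$edges$weight == 1L, , drop = FALSE]
  sort(c(e$j[e$i == i], e$i[e$j == i]))
}

edge_weight <- function(g, i, j) {
  e <- g$edges
  hit <- (e$i == min(i, j)) & (e$j == max(i, j))
  if (!any(hit)) return(NA_integer_)
  e$weight[hit][1]
}

#' Export an adjacency graph as edge-list and vertex-table CSV
#' @param g an `adjacency_graph`
#' @param edge_path,vertex_path output CSV paths
#' @export
write_adjacency_graph <- function(g, edge_path, vertex_path) {
  stopifnot(inherits(g, "adjacency_graph"))
  feats <- track_features(g)
  vt <- merge(g$vertices, feats, by = "label")
  atomic_write(function(p) write.csv(g$edges, p, row.names = FALSE), edge_path)
  atomic_write(function(p) write.csv(vt[, c("label", "size", "deg", "wdeg")],
                                     p, row.names = FALSE), vertex_path)
  invisible(c(edge_path, vertex_path))
}
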