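#' Per-cell tracking features from an adjacency graph
#'
#' For each vertex: cell size `S` (voxel count), degree `N` (number of
#' distance-1 neighbours) and weighted degree `D` = sum of stored edge
#' weights divided by the number of stored edges. `D = 0` is the sentinel
#' for vertices with no edges.
#'
#' @param g an [build_adjacency_graph()] result
#' @return data.frame with columns `label`, `S`, `deg`, `wdeg`
#' @export
track_features <- function(g) {
  stopifnot(inherits(g, "adjacency_graph"))
  labs <- g$vertices$label
  feats <- data.frame(label = labs, S = g$vertices$size,
                      deg = integer(length(labs)), wdeg = numeric(length(labs)))
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges$i[r]; j <- g$edges$j[r]; w <- g$edges$weight[r]
    for (l in c(i, j)) {
      k <- match(l, labs)
      feats$wdeg[k] <- feats$wdeg[k] + w
      if (w == 1L) feats$deg[k] <- feats$deg[k] + 1L
    }
  }
  n_edges <- vapply(labs, function(l)
    sum(g$edges$i == l | g$edges$j == l), integer(1))
  feats$wdeg <- ifelse(n_edges > 0, feats$wdeg / n_edges, 0)
  names(feats) <- c("label", "S", "deg", "wdeg")
  feats
}

#' Similarity of two cell detections across frames
#'
#' `sim = |S1-S2|/S1 + |deg1-deg2|/deg1 + |wdeg1-wdeg2|/wdeg1`,
#' normalizing by the earlier frame's features (asymmetric, as defined).
#' Zero-valued `deg`/`wdeg` denominators are substituted by 1 so isolated
#' cells keep a finite similarity.
#'
#' @param f_i feature row of the frame-T cell (fields `S`, `deg`, `wdeg`)
#' @param f_j feature row of the frame-T+1 candidate
#' @return non-negative similarity (0 = identical features)
#' @export
track_similarity <- function(f_i, f_j) {
  den <- function(v) if (v == 0) 1 else v
  abs(f_i$S - f_j$S) / f_i$S +
    abs(f_i$deg - f_j$deg) / den(f_i$deg) +
    abs(f_i$wdeg - f_j$wdeg) / den(f_i$wdeg)
}

#' Greedy frame-to-frame linking by ascending similarity
#'
#' Repeatedly links the unmatched pair `(i*, j*)` with the smallest
#' similarity, as long as it is below `threshold` (the working range is
#' 0.1–0.5; default 0.3). One-to-one: each detection links at most once.
#'
#' @param features_T,features_T1 feature tables from [track_features()]
#' @param threshold similarity acceptance threshold (> 0)
#' @return list with `links` data.frame (`label_T`, `label_T1`, `sim`) and
#'   `n_evaluations` (similarity evaluations performed — `M_T x M_T1`)
#' @export
link_frames <- function(features_T, features_T1, threshold = 0.3) {
  if (threshold <= 0) stop("threshold must be > 0")
  m1 <- nrow(features_T); m2 <- nrow(features_T1)
  links <- data.frame(label_T = integer(0), label_T1 = integer(0),
                      sim = numeric(0))
  if (m1 == 0L || m2 == 0L)
    return(list(links = links, n_evaluations = 0L))
  S <- matrix(Inf, m1, m2)
  for (a in seq_len(m1)) for (b in seq_len(m2))
    S[a, b] <- track_similarity(features_T[a, ], features_T1[b, ])
  used1 <- logical(m1); used2 <- logical(m2)
  repeat {
    S2 <- S
    S2[used1, ] <- Inf; S2[, used2] <- Inf
    best <- which.min(S2)
    if (!length(best) || !is.finite(S2[best]) || S2[best] >= threshold) break
    a <- (best - 1L) %% m1 + 1L
    b <- (best - 1L) %/% m1 + 1L
    links <- rbind(links, data.frame(label_T = features_T$label[a],
                                     label_T1 = features_T1$label[b],
                                     sim = S2[best]))
    used1[a] <- TRUE; used2[b] <- TRUE
  }
  list(links = links, n_evaluations = m1 * m2)
}

#' Track cells across a label-volume sequence
#'
#' Frame-0 labels seed the track ids; adjacency-graph features are linked
#' frame to frame; unmatched new detections open new tracks and unmatched
#' prior detections terminate. Output volumes are recoloured by track id.
#' Deterministic.
#'
#' @param label_volumes list of integer label volumes (>= 1 frame)
#' @param threshold similarity threshold, see [link_frames()]
#' @param r_max adjacency-graph dilation cap
#' @return list with `track_graph` (a `track_graph` object: `nodes`
#'   data.frame `(id, frame, label, track)`, `edges` data.frame
#'   `(from, to)`), `relabelled` (volumes recoloured by track id),
#'   `track_table` (`track_id, begin, end, parent`)
#' @export
track_sequence <- function(label_volumes, threshold = 0.3, r_max = 3L) {
  stopifnot(length(label_volumes) >= 1L)
  n_frames <- length(label_volumes)
  graphs <- lapply(label_volumes, build_adjacency_graph, r_max = r_max)
  feats <- lapply(graphs, track_features)
  nodes <- data.frame(id = integer(0), frame = integer(0), label = integer(0),
                      track = integer(0))
  edges <- data.frame(from = integer(0), to = integer(0))
  next_track <- 0L
  node_id <- 0L
  prev_rows <- NULL
  for (t in seq_len(n_frames)) {
    ft <- feats[[t]]
    if (nrow(ft) == 0L) {
      log_msg("track", sprintf("frame %d is empty; all open tracks end", t - 1L))
      prev_rows <- NULL
      next
    }
    cur <- data.frame(id = node_id + seq_len(nrow(ft)), frame = t - 1L,
                      label = ft$label, track = NA_integer_)
    node_id <- node_id + nrow(ft)
    if (is.null(prev_rows)) {
      cur$track <- next_track + seq_len(nrow(cur))
      next_track <- next_track + nrow(cur)
    } else {
      lk <- link_frames(feats[[t - 1L]], ft, threshold)$links
      for (r in seq_len(nrow(lk))) {
        p <- prev_rows[prev_rows$label == lk$label_T[r], ]
        c_ <- which(cur$label == lk$label_T1[r])
        cur$track[c_] <- p$track
        edges <- rbind(edges, data.frame(from = p$id, to = cur$id[c_]))
      }
      new <- is.na(cur$track)
      if (any(new)) {
        cur$track[new] <- next_track + seq_len(sum(new))
        next_track <- next_track + sum(new)
      }
    }
    nodes <- rbind(nodes, cur)
    prev_rows <- cur
  }
  relabelled <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    v <- label_volumes[[t]]
    out <- array(0L, dim(v))
    nt <- nodes[nodes$frame == t - 1L, , drop = FALSE]
    for (r in seq_len(nrow(nt)))
      out[v == nt$label[r]] <- nt$track[r]
    relabelled[[t]] <- out
  }
  tg <- track_graph(nodes, edges)
  list(track_graph = tg, relabelled = relabelled,
       track_table = track_table_of(tg))
}

#' Construct a track graph object
#'
#' An acyclic oriented graph of cell detections: nodes are (frame, label)
#' detections carrying a track id; edges link a detection to its
#' successor in the next frame (at most one in, one out — divisions are
#' not modelled, parents are always 0).
#'
#' @param nodes data.frame `(id, frame, label, track)`
#' @param edges data.frame `(from, to)` of node ids
#' @return object of class `track_graph`
#' @export
track_graph <- function(nodes, edges) {
  if (nrow(edges) > 0) {
    fr <- nodes$frame[match(edges$from, nodes$id)]
    to <- nodes$frame[match(edges$to, nodes$id)]
    if (any(to - fr != 1L)) stop("track edges must advance the frame by 1")
    if (anyDuplicated(edges$from) || anyDuplicated(edges$to))
      stop("each detection may have at most one incoming and one outgoing link")
  }
  structure(list(nodes = nodes, edges = edges), class = "track_graph")
}

track_table_of <- function(tg) {
  sp <- split(tg$nodes$frame, tg$nodes$track)
  data.frame(track_id = as.integer(names(sp)),
             begin = vapply(sp, min, numeric(1)),
             end = vapply(sp, max, numeric(1)),
             parent = 0L, row.names = NULL)
}

#' Build the reference track graph of a phantom sequence
#'
#' Ground-truth detections and links from a [generate_timelapse()] result:
#' one node per (frame, label present), edges between consecutive
#' presences of the same track id.
#'
#' @param seq_ a `phantom_sequence`
#' @return a [track_graph()]
#' @export
reference_track_graph <- function(seq_) {
  stopifnot(inherits(seq_, "phantom_sequence"))
  nodes <- data.frame(id = integer(0), frame = integer(0), label = integer(0),
                      track = integer(0))
  edges <- data.frame(from = integer(0), to = integer(0))
  id <- 0L
  prev <- NULL
  for (t in seq_along(seq_$frames)) {
    labs <- sort(unique(seq_$frames[[t]]$labels[seq_$frames[[t]]$labels > 0L]))
    cur <- data.frame(id = id + seq_along(labs), frame = t - 1L,
                      label = as.integer(labs), track = as.integer(labs))
    id <- id + nrow(cur)
    if (!is.null(prev)) {
      common <- intersect(prev$track, cur$track)
      if (length(common))
        edges <- rbind(edges,
                       data.frame(from = prev$id[match(common, prev$track)],
                                  to = cur$id[match(common, cur$track)]))
    }
    nodes <- rbind(nodes, cur)
    prev <- cur
  }
  track_graph(nodes, edges)
}
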