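#' Boundary precision / recall / F-score at range R
#'
#' Given a ground-truth boundary mask `G` and a computed boundary mask
#' `B`: TP = boundary voxels of `G` with a voxel of `B` within Euclidean
#' range `R`; FN = the rest of `G`; FP = voxels of `B` with no voxel of
#' `G` within `R`. Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F their
#' harmonic mean. The working tolerance in this pipeline is `R = 5`.
#'
#' @param gt_boundary,pred_boundary logical masks of equal shape
#' @param R tolerance radius, voxels
#' @return list with `TP`, `FN`, `FP`, `precision`, `recall`, `f_score`, `R`
#' @export
boundary_prf <- function(gt_boundary, pred_boundary, R = 5) {
  assert_volume(gt_boundary, "gt_boundary")
  assert_volume(pred_boundary, "pred_boundary")
  if (!any(gt_boundary)) stop("empty ground-truth boundary: recall undefined")
  d_to_pred <- distance_to_set(pred_boundary)
  d_to_gt <- distance_to_set(gt_boundary)
  TP <- sum(gt_boundary & d_to_pred <= R)
  FN <- sum(gt_boundary) - TP
  FP <- sum(pred_boundary & d_to_gt > R)
  precision <- if (TP + FP == 0) 0 else TP / (TP + FP)
  recall <- TP / (TP + FN)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(TP = TP, FN = FN, FP = FP, precision = precision, recall = recall,
       f_score = f, R = R)
}

#' Mean and standard deviation of per-frame cell counts
#'
#' Counts distinct nonzero labels per frame; the standard deviation is
#' the population form (denominator `n`), matching how per-sequence count
#' spread is usually reported.
#'
#' @param label_volumes list of label volumes (>= 1)
#' @return list with `counts`, `mean`, `sd`
#' @export
count_stats <- function(label_volumes) {
  stopifnot(length(label_volumes) >= 1L)
  counts <- vapply(label_volumes,
                   function(v) length(unique(v[v > 0L])), numeric(1))
  m <- mean(counts)
  list(counts = counts, mean = m, sd = sqrt(mean((counts - m)^2)))
}

#' Junction detection precision / recall / F1 at a voxel tolerance
#'
#' Greedy one-to-one assignment of detections to ground-truth junctions
#' by ascending Euclidean distance within `tol` (5 voxels by default).
#' Unmatched detections are false positives, unmatched truths false
#' negatives.
#'
#' @param detected,truth coordinate matrices (columns z, y, x)
#' @param tol matching tolerance, voxels
#' @return list with `TP`, `FP`, `FN`, `precision`, `recall`, `f1`
#' @export
junction_prf <- function(detected, truth, tol = 5) {
  nd <- if (is.null(detected)) 0L else nrow(detected)
  nt <- if (is.null(truth)) 0L else nrow(truth)
  matched <- 0L
  if (nd > 0L && nt > 0L) {
    dmat <- matrix(Inf, nd, nt)
    for (a in seq_len(nd))
      dmat[a, ] <- sqrt(colSums((t(truth[, 1:3, drop = FALSE]) -
                                 as.numeric(detected[a, 1:3]))^2))
    cand <- which(dmat <= tol, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      used_d <- logical(nd); used_t <- logical(nt)
      for (r in seq_len(nrow(cand))) {
        a <- cand[r, 1]; b <- cand[r, 2]
        if (!used_d[a] && !used_t[b]) {
          used_d[a] <- TRUE; used_t[b] <- TRUE
          matched <- matched + 1L
        }
      }
    }
  }
  FP <- nd - matched; FN <- nt - matched
  precision <- if (nd == 0L) NA_real_ else matched / nd
  recall <- if (nt == 0L) NA_real_ else matched / nt
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (identical(matched, 0L) && (FP + FN) > 0) 0 else NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(TP = matched, FP = FP, FN = FN, precision = precision,
       recall = recall, f1 = f1)
}

poly_points <- function(p) {
  m <- unclass(p)
  if (!is.matrix(m)) m <- matrix(m, ncol = 3)
  m[, 1:3, drop = FALSE]
}

#' End-point displacement error between two wall segments
#'
#' `corrected` (default): half the sum of the two endpoint displacements,
#' minimized over the two possible endpoint pairings (segments have no
#' canonical direction). `as_printed`: half the sum of each curve's own
#' chord `(|p_1 - p_m| + |q_1 - q_n|)/2` — kept available because that is
#' the formula as published, although it measures within-curve extent,
#' not between-curve displacement (it is nonzero for identical curves).
#'
#' @param P,Q polylines (coordinate matrices, columns z, y, x)
#' @param mode `"corrected"` or `"as_printed"`
#' @return displacement in voxels
#' @export
ede <- function(P, Q, mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  p <- poly_points(P); q <- poly_points(Q)
  if (mode == "as_printed") {
    return(0.5 * (sqrt(sum((p[1, ] - p[nrow(p), ])^2)) +
                  sqrt(sum((q[1, ] - q[nrow(q), ])^2))))
  }
  d <- function(a, b) sqrt(sum((a - b)^2))
  straight <- d(p[1, ], q[1, ]) + d(p[nrow(p), ], q[nrow(q), ])
  crossed <- d(p[1, ], q[nrow(q), ]) + d(p[nrow(p), ], q[1, ])
  0.5 * min(straight, crossed)
}

frechet_dp <- function(p, q) {
  m <- nrow(p); n <- nrow(q)
  dmat <- matrix(0, m, n)
  for (a in seq_len(m))
    dmat[a, ] <- sqrt(colSums((t(q) - p[a, ])^2))
  ca <- matrix(0, m, n)
  ca[1, 1] <- dmat[1, 1]
  for (a in 2:max(m, 2)) if (m > 1) ca[a, 1] <- max(ca[a - 1, 1], dmat[a, 1])
  for (b in 2:max(n, 2)) if (n > 1) ca[1, b] <- max(ca[1, b - 1], dmat[1, b])
  if (m > 1 && n > 1)
    for (a in 2:m) for (b in 2:n)
      ca[a, b] <- max(min(ca[a - 1, b], ca[a - 1, b - 1], ca[a, b - 1]),
                      dmat[a, b])
  ca[m, n]
}

#' Discrete Fréchet distance between two polylines
#'
#' Minimum over monotone couplings (index steps of 0 or +1 on each curve,
#' endpoints pinned) of the longest coupled-pair Euclidean distance,
#' computed by dynamic programming. Because manually traced segments have
#' no canonical direction, the minimum over the two orientations of `Q`
#' is reported; the measure is symmetric.
#'
#' @param P,Q polylines (coordinate matrices)
#' @return distance in voxels
#' @export
frechet_distance <- function(P, Q) {
  p <- poly_points(P); q <- poly_points(Q)
  min(frechet_dp(p, q), frechet_dp(p, q[rev(seq_len(nrow(q))), , drop = FALSE]))
}

polyline_length <- function(P) {
  p <- poly_points(P)
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Length difference and percentage length difference
#'
#' `LD = |len(P) - len(Q)|` in voxels; `DP = 100 * LD / len(Q)` with `Q`
#' the ground-truth segment.
#'
#' @param P computed polyline
#' @param Q ground-truth polyline (normalization side)
#' @return list with `LD` (voxels) and `DP` (percent)
#' @export
length_metrics <- function(P, Q) {
  lp <- polyline_length(P); lq <- polyline_length(Q)
  if (lq == 0) stop("zero-length ground-truth segment")
  list(LD = abs(lp - lq), DP = 100 * abs(lp - lq) / lq)
}

#' Edit-operation weights for acyclic oriented graph matching
#'
#' Node split, missing-node addition, spurious-node deletion, edge
#' deletion, edge addition, edge semantics change. The published pipeline
#' never prints its weights; these defaults are the Cell Tracking
#' Challenge convention (5, 10, 1, 1, 1.5, 1) and are fully configurable.
#'
#' @param ns,fn,fp,ed,ea,ec non-negative weights
#' @return object of class `aogm_weights`
#' @export
aogm_weights <- function(ns = 5, fn = 10, fp = 1, ed = 1, ea = 1.5, ec = 1) {
  w <- c(ns = ns, fn = fn, fp = fp, ed = ed, ea = ea, ec = ec)
  if (any(w < 0)) stop("AOGM weights must be non-negative")
  structure(as.list(w), class = "aogm_weights")
}

#' Match result detections to reference detections by voxel overlap
#'
#' A result node matches a reference node when its mask covers the
#' majority (> 1/2) of the reference node's voxels in that frame; each
#' reference node matches at most one result node, while one result node
#' may cover several reference nodes (counted as splits by [aogm()]).
#'
#' @param ref,res [track_graph()] objects
#' @param ref_volumes,res_volumes label-volume lists the graphs refer to
#' @return data.frame `(ref_id, res_id)`
#' @export
match_track_nodes <- function(ref, res, ref_volumes, res_volumes) {
  out <- data.frame(ref_id = integer(0), res_id = integer(0))
  for (t in sort(unique(ref$nodes$frame))) {
    rn <- ref$nodes[ref$nodes$frame == t, , drop = FALSE]
    sn <- res$nodes[res$nodes$frame == t, , drop = FALSE]
    if (nrow(sn) == 0L) next
    rv <- ref_volumes[[t + 1L]]; sv <- res_volumes[[t + 1L]]
    for (k in seq_len(nrow(rn))) {
      mask <- rv == rn$label[k]
      sz <- sum(mask)
      if (sz == 0L) next
      cover <- sv[mask]
      cover <- cover[cover > 0L]
      if (length(cover) == 0L) next
      tab <- table(cover)
      best <- as.integer(names(tab)[which.max(tab)])
      if (max(tab) > sz / 2) {
        sid <- sn$id[sn$label == best]
        if (length(sid) == 1L)
          out <- rbind(out, data.frame(ref_id = rn$id[k], res_id = sid))
      }
    }
  }
  out
}

#' Acyclic oriented graph matching cost
#'
#' Weighted number of edit operations (add/delete/split nodes,
#' add/delete/change edges) needed to turn the result tracking graph into
#' the reference graph, given a node correspondence. With no
#' correspondence supplied the graphs are assumed to describe the same
#' detections and nodes are matched by (frame, label).
#'
#' @param reference,result [track_graph()] objects
#' @param weights an [aogm_weights()]
#' @param matching optional data.frame `(ref_id, res_id)` from
#'   [match_track_nodes()]
#' @return non-negative cost; 0 iff the graphs agree
#' @export
aogm <- function(reference, result, weights = aogm_weights(),
                 matching = NULL) {
  if (is.null(matching)) {
    key_r <- paste(reference$nodes$frame, reference$nodes$label)
    key_s <- paste(result$nodes$frame, result$nodes$label)
    hit <- match(key_r, key_s)
    matching <- data.frame(ref_id = reference$nodes$id[!is.na(hit)],
                           res_id = result$nodes$id[hit[!is.na(hit)]])
  }
  cost <- 0
  # nodes
  n_fn <- sum(!(reference$nodes$id %in% matching$ref_id))
  n_fp <- sum(!(result$nodes$id %in% matching$res_id))
  splits <- table(matching$res_id)
  n_ns <- sum(pmax(as.integer(splits) - 1L, 0L))
  cost <- cost + n_fn * weights$fn + n_fp * weights$fp + n_ns * weights$ns
  # edges: compare through the correspondence
  ref_of <- function(res_id) matching$ref_id[matching$res_id == res_id]
  res_of <- function(ref_id) matching$res_id[matching$ref_id == ref_id]
  ref_edges <- reference$edges
  res_edges <- result$edges
  ref_keys <- character(0)
  if (nrow(ref_edges) > 0)
    ref_keys <- paste(ref_edges$from, ref_edges$to)
  matched_ref_keys <- character(0)
  n_ed <- 0L
  for (r in seq_len(nrow(res_edges))) {
    ra <- ref_of(res_edges$from[r]); rb <- ref_of(res_edges$to[r])
    keys <- as.vector(outer(ra, rb, paste))
    hit <- keys[keys %in% ref_keys & !(keys %in% matched_ref_keys)]
    if (length(hit) >= 1L) {
      matched_ref_keys <- c(matched_ref_keys, hit[1])
    } else {
      n_ed <- n_ed + 1L
    }
  }
  n_ea <- length(ref_keys) - length(matched_ref_keys)
  cost <- cost + n_ed * weights$ed + n_ea * weights$ea
  # edge semantics changes (link vs division) cannot occur without
  # divisions; parents are always 0 here, so the EC term is zero.
  cost
}

#' AOGM cost of building a reference graph from scratch
#' @param reference a [track_graph()]
#' @param weights an [aogm_weights()]
#' @export
aogm_empty <- function(reference, weights = aogm_weights()) {
  nrow(reference$nodes) * weights$fn + nrow(reference$edges) * weights$ea
}

#' Tracking accuracy (TRA)
#'
#' `TRA = 1 - min(AOGM, AOGM_0) / AOGM_0`, where `AOGM_0` is the cost of
#' creating the reference graph from scratch (all nodes as missing-node
#' additions, all edges as edge additions). Ranges over `[0, 1]`; 1 means
#' perfect tracking.
#'
#' @inheritParams aogm
#' @return TRA in `[0, 1]`
#' @export
tra <- function(reference, result, weights = aogm_weights(),
                matching = NULL) {
  if (nrow(reference$nodes) == 0L) stop("empty reference graph")
  a0 <- aogm_empty(reference, weights)
  a <- aogm(reference, result, weights, matching)
  1 - min(a, a0) / a0
}
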