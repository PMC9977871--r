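#' @useDynLib celltrack3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

assert_volume <- function(v, name = "volume") {
  if (!is.array(v) || length(dim(v)) != 3L)
    stop(sprintf("%s must be a 3D array with dim (z, y, x)", name), call. = FALSE)
  invisible(v)
}

#' Shift a 3D array along one axis, zero/constant-filling the vacated slab
#' @keywords internal
shift_array <- function(v, axis, by, fill = 0) {
  d <- dim(v)
  if (by == 0) return(v)
  out <- array(fill, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  ix_src <- list(1:d[1], 1:d[2], 1:d[3]); ix_src[[axis]] <- src
  ix_dst <- list(1:d[1], 1:d[2], 1:d[3]); ix_dst[[axis]] <- dst
  out[ix_dst[[1]], ix_dst[[2]], ix_dst[[3]]] <-
    v[ix_src[[1]], ix_src[[2]], ix_src[[3]]]
  out
}

#' Binary dilation by the 6-connected cross, `rounds` times
#' @keywords internal
dilate6 <- function(mask, rounds = 1L) {
  m <- mask
  for (r in seq_len(rounds)) {
    out <- m
    for (axis in 1:3) {
      out <- out | shift_array(m, axis, 1L, FALSE) | shift_array(m, axis, -1L, FALSE)
    }
    m <- out
  }
  m
}

#' Binary dilation by the 3^3 box (26-neighbourhood incidence)
#' @keywords internal
dilate_box <- function(mask, radius = 1L) {
  m <- mask
  for (axis in 1:3) {
    acc <- m
    for (r in seq_len(radius)) {
      acc <- acc | shift_array(m, axis, r, FALSE) | shift_array(m, axis, -r, FALSE)
    }
    m <- acc
  }
  m
}

#' Voxels whose 6-neighbourhood contains a different label
#'
#' A voxel is a boundary voxel when at least one face neighbour carries a
#' different label. The volume edge itself does not count as boundary.
#'
#' @param labels integer 3D label array
#' @return logical array of the same shape
#' @export
boundary_mask <- function(labels) {
  assert_volume(labels, "labels")
  b <- array(FALSE, dim(labels))
  for (axis in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- shift_array(labels, axis, s, fill = NA)
      b <- b | (!is.na(nb) & nb != labels)
    }
  }
  b
}

#' Exact Euclidean distance to the nearest voxel of a set
#' @param set logical/integer 3D array marking the target set
#' @param spacing per-axis voxel spacing (z, y, x)
#' @return numeric array of distances (Inf when the set is empty)
#' @export
distance_to_set <- function(set, spacing = c(1, 1, 1)) {
  assert_volume(set, "set")
  sq <- edt3d_sq(array(as.integer(set != 0), dim(set)), as.numeric(spacing))
  sqrt(sq)
}

normalize01 <- function(v) {
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) return(array(0, dim(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

volume_hash <- function(v) {
  # cheap content digest without external deps
  x <- as.numeric(v)
  paste(format(sum(x * seq_along(x) %% 7919), digits = 15),
        format(sum(x^2), digits = 15), length(x), sep = "/")
}
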