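#' The 24-element rotation group of the cube
#'
#' Enumerates all orientation-preserving symmetries of the voxel cube as
#' signed axis permutations: 3x3 matrices with entries in \{-1, 0, 1\},
#' one nonzero entry per row and column, determinant +1. A cube has 6
#' faces, any face can be put at the bottom and then rotated into 4
#' positions, giving 6 x 4 = 24 rotations. Acting on voxel indices these
#' are exact (no interpolation), which is what makes layer equivariance
#' testable to machine precision.
#'
#' Matrices act on centred voxel coordinates in (z, y, x) order.
#'
#' @return object of class `rotation_group` with `elements` (list of 24
#'   matrices, identity first), `cayley` (24x24 composition table:
#'   `cayley[i, j]` is the index of `elements[[i]] %*% elements[[j]]`) and
#'   `inverse` (index of each element's inverse)
#' @export
cube_rotation_group <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  elements <- list()
  keys <- character(0)
  for (p in perms) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      m <- matrix(0, 3, 3)
      m[cbind(1:3, p)] <- c(s1, s2, s3)
      if (round(det(m)) == 1) {
        elements[[length(elements) + 1L]] <- m
        keys <- c(keys, paste(as.vector(m), collapse = ","))
      }
    }
  }
  stopifnot(length(elements) == 24L)
  id_key <- paste(as.vector(diag(3)), collapse = ",")
  ord <- c(which(keys == id_key), setdiff(order(keys), which(keys == id_key)))
  elements <- elements[ord]
  keys <- keys[ord]
  cayley <- matrix(0L, 24, 24)
  for (i in 1:24) for (j in 1:24) {
    k <- paste(as.vector(elements[[i]] %*% elements[[j]]), collapse = ",")
    cayley[i, j] <- match(k, keys)
  }
  if (any(is.na(cayley))) stop("rotation group is not closed — internal error")
  inverse <- vapply(1:24, function(i) which(cayley[i, ] == 1L), integer(1))
  structure(list(elements = elements, cayley = cayley, inverse = inverse),
            class = "rotation_group")
}

group_element <- function(group, g) {
  if (inherits(g, "matrix")) return(g)
  group$elements[[g]]
}

#' Rotate a cubic 3D grid by a cube-group element
#'
#' Applies the signed axis permutation `g` about the grid centre:
#' `out[p] = v[g^-1 p]` in centred (z, y, x) coordinates, realized as an
#' axis permutation plus axis flips — exact, no interpolation.
#'
#' @param g group element: an index into `group$elements` or a 3x3 signed
#'   permutation matrix
#' @param v 3D array with equal extents along all three axes
#' @param group a [cube_rotation_group()] (only needed when `g` is an index)
#' @return rotated array, same shape
#' @export
rotate_volume <- function(g, v, group = NULL) {
  if (!inherits(g, "matrix")) {
    if (is.null(group)) group <- cached_group()
    g <- group_element(group, g)
  }
  d <- dim(v)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("rotate_volume needs a cubic 3D array; pad to cubic first")
  S <- t(g)                       # inverse of a rotation matrix
  pi_ <- apply(S != 0, 1, which)  # source axis feeding each target axis
  s <- S[cbind(1:3, pi_)]
  A <- v
  ix <- lapply(1:3, function(a) if (s[a] < 0) rev(seq_len(d[a])) else seq_len(d[a]))
  A <- A[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  aperm(A, order(pi_))
}

# The orientation-axis permutation induced on a lifted feature map when
# the input is rotated by r: slot g of the rotated map comes from slot
# r^-1 o g of the original.
slot_permutation <- function(group, r) {
  vapply(1:24, function(g) group$cayley[group$inverse[r], g], integer(1))
}

# memoized default group (enumeration is cheap but called often)
.ct3d_env <- new.env(parent = emptyenv())
cached_group <- function() {
  if (is.null(.ct3d_env$group)) .ct3d_env$group <- cube_rotation_group()
  .ct3d_env$group
}
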