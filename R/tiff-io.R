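# Minimal baseline TIFF support (uncompressed, grayscale, multi-page).
# Hand-rolled because the runtime environment ships no TIFF package; only
# the subset of the format the pipeline needs is implemented: 8/16-bit
# unsigned and 32-bit float samples, one strip per row group, little- or
# big-endian on read, little-endian on write.

TIFF_TYPES <- list(uint8 = list(bits = 8L, fmt = 1L),
                   uint16 = list(bits = 16L, fmt = 1L),
                   float = list(bits = 32L, fmt = 3L))

atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

#' Write a 3D volume as a multi-page TIFF (one page per z-slice)
#'
#' Pages are written z-ascending, uncompressed, little-endian. `uint8`
#' and `uint16` round values; `float` writes 32-bit IEEE samples.
#' The write is atomic (temp file + rename).
#'
#' @param vol 3D numeric/integer array, dim (z, y, x)
#' @param path output path
#' @param type `"float"`, `"uint16"` or `"uint8"`
#' @export
write_stack <- function(vol, path, type = c("float", "uint16", "uint8")) {
  assert_volume(vol)
  type <- match.arg(type)
  tt <- TIFF_TYPES[[type]]
  d <- dim(vol)
  h <- d[2]; w <- d[3]; npages <- d[1]
  bytes <- tt$bits / 8L
  page_size <- w * h * bytes
  ifd_entry_count <- 11L
  ifd_size <- 2L + 12L * ifd_entry_count + 4L
  data0 <- 8L
  ifd0 <- data0 + npages * page_size
  rat0 <- ifd0 + npages * ifd_size      # shared 1/1 resolution rational
  atomic_write(function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
    w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
    writeChar("II", con, nchars = 2, eos = NULL)
    w2(42L); w4(ifd0)
    for (p in seq_len(npages)) {
      m <- vol[p, , ]
      dim(m) <- c(h, w)
      v <- as.vector(t(m))                     # row-major: x fastest
      if (type == "float") {
        writeBin(as.numeric(v), con, size = 4, endian = "little")
      } else {
        v <- round(v)
        maxv <- 2^tt$bits - 1
        if (any(v < 0 | v > maxv))
          stop(sprintf("values outside [0, %d] cannot be written as %s",
                       maxv, type))
        half <- 2^(tt$bits - 1)
        v <- ifelse(v >= half, v - 2^tt$bits, v)  # two's complement
        writeBin(as.integer(v), con, size = bytes, endian = "little")
      }
    }
    tag <- function(id, typ, count, value) { w2(id); w2(typ); w4(count); w4(value) }
    for (p in seq_len(npages)) {
      w2(ifd_entry_count)
      tag(256L, 4L, 1L, w)                        # ImageWidth
      tag(257L, 4L, 1L, h)                        # ImageLength
      tag(258L, 3L, 1L, tt$bits)                  # BitsPerSample
      tag(259L, 3L, 1L, 1L)                       # Compression: none
      tag(262L, 3L, 1L, 1L)                       # Photometric: BlackIsZero
      tag(273L, 4L, 1L, data0 + (p - 1L) * page_size)  # StripOffsets
      tag(278L, 4L, 1L, h)                        # RowsPerStrip
      tag(279L, 4L, 1L, page_size)                # StripByteCounts
      tag(282L, 5L, 1L, rat0)                     # XResolution 1/1
      tag(283L, 5L, 1L, rat0)                     # YResolution 1/1
      tag(339L, 3L, 1L, tt$fmt)                   # SampleFormat
      w4(if (p < npages) ifd0 + p * ifd_size else 0L)
    }
    w4(1L); w4(1L)                                # the shared rational
  }, path)
}

read_u <- function(con, size, endian) {
  if (size < 4)
    readBin(con, "integer", 1, size = size, signed = FALSE, endian = endian)
  else readBin(con, "integer", 1, size = size, endian = endian)
}

#' Read a multi-page TIFF into a 3D intensity volume
#'
#' Supports the uncompressed grayscale subset written by [write_stack()]
#' (plus big-endian and multi-strip layouts). Integer samples are
#' normalized by the type maximum so a 16-bit stack with max 65535 maps
#' to 1.0; float samples are taken as-is.
#'
#' @param path TIFF file
#' @param normalize divide integer samples by their type maximum
#' @return list with `volume` (numeric array, dim (z, y, x)) and
#'   `spacing` (voxel spacing; `(1,1,1)` with a warning when the file
#'   carries no resolution metadata)
#' @export
read_stack <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2, useBytes = TRUE)
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop(path, " is not a TIFF file (bad byte-order mark)")
  if (read_u(con, 2, endian) != 42L) stop(path, " is not a TIFF file")
  ifd_off <- read_u(con, 4, endian)
  pages <- list()
  has_resolution <- FALSE
  while (ifd_off != 0L) {
    seek(con, ifd_off)
    n <- read_u(con, 2, endian)
    tags <- list()
    for (i in seq_len(n)) {
      id <- read_u(con, 2, endian)
      typ <- read_u(con, 2, endian)
      count <- read_u(con, 4, endian)
      tsize <- c(1L, 1L, 2L, 4L, 8L)[min(typ, 5L)]
      here <- seek(con)   # position of the value field
      values <- NULL
      if (typ == 5L) {
        seek(con, here + 4)        # rationals: presence only
      } else if (tsize * count <= 4L) {
        values <- vapply(seq_len(count), function(k)
          read_u(con, tsize, endian), integer(1))
        seek(con, here + 4)
      } else {
        off <- read_u(con, 4, endian)
        back <- seek(con)
        seek(con, off)
        values <- vapply(seq_len(count), function(k)
          read_u(con, tsize, endian), integer(1))
        seek(con, back)
      }
      tags[[as.character(id)]] <- values
      if (id %in% c(282L, 283L)) has_resolution <- TRUE
    }
    nxt <- read_u(con, 4, endian)
    gt <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    w <- gt(256); h <- gt(257)
    if (is.null(w) || is.null(h)) stop("TIFF page without dimensions")
    if (gt(259, 1L)[1] != 1L) stop("compressed TIFF not supported")
    if (gt(277, 1L)[1] != 1L) stop("multi-sample TIFF not supported")
    bits <- gt(258, 8L)[1]
    fmt <- gt(339, 1L)[1]
    offs <- gt(273); counts <- gt(279, w * h * bits / 8L)
    raw_vals <- numeric(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      nvals <- counts[s] / (bits / 8L)
      if (fmt == 3L) {
        raw_vals <- c(raw_vals, readBin(con, "numeric", nvals, size = 4,
                                        endian = endian))
      } else {
        raw_vals <- c(raw_vals,
                      readBin(con, "integer", nvals, size = bits / 8L,
                              signed = bits >= 32, endian = endian))
      }
    }
    if (fmt != 3L && bits < 32) raw_vals[raw_vals < 0] <- raw_vals[raw_vals < 0] + 2^bits
    m <- matrix(raw_vals, nrow = w, ncol = h)   # x fastest in the stream
    pages[[length(pages) + 1L]] <- t(m)
    ifd_off <- nxt
  }
  if (length(pages) < 2L)
    stop(path, " holds a single 2D image; a 3D multi-page stack is required")
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  vol <- array(0, c(length(pages), h, w))
  for (p in seq_along(pages)) vol[p, , ] <- pages[[p]]
  if (normalize) {
    # infer the sample type from the data range: float pages stay as-is
    if (all(vol == round(vol)) && max(vol) > 1) {
      maxv <- if (max(vol) > 255) 65535 else 255
      vol <- vol / maxv
    }
  }
  spacing <- c(1, 1, 1)
  if (!has_resolution)
    warning("no resolution metadata in ", basename(path),
            "; assuming voxel spacing (1, 1, 1)")
  list(volume = vol, spacing = spacing)
}

#' Write / read an integer label volume as 16-bit TIFF
#' @param labels integer 3D label array (max label 65535)
#' @param path file path
#' @export
write_labels <- function(labels, path) {
  assert_volume(labels)
  if (max(labels) > 65535)
    stop("more than 65535 labels cannot be stored in 16-bit TIFF; ",
         "merge or split the volume")
  write_stack(labels, path, type = "uint16")
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  v <- read_stack(path, normalize = FALSE)$volume
  storage.mode(v) <- "integer"
  v
}
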