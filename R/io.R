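#' Write and read a track table in cell-tracking text style
#'
#' One line per track: `id begin end parent` (space-separated, no
#' header). Parent is always 0 here (divisions are not modelled).
#'
#' @param track_table data.frame with columns `track_id, begin, end, parent`
#' @param path output file
#' @export
write_tracks <- function(track_table, path) {
  stopifnot(all(c("track_id", "begin", "end", "parent") %in% names(track_table)))
  atomic_write(function(tmp) {
    writeLines(sprintf("%d %d %d %d", track_table$track_id, track_table$begin,
                       track_table$end, track_table$parent), tmp)
  }, path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  m <- utils::read.table(path, col.names = c("track_id", "begin", "end", "parent"))
  m
}

#' Write junction and segment features as CSV
#'
#' Coordinates are exported 0-based in (z, y, x) order, z first — the
#' convention is stated in a comment header line in each file.
#'
#' @param features result of [extract_all_features()]
#' @param junctions_path,segments_path output CSV paths
#' @export
write_features <- function(features, junctions_path, segments_path) {
  hdr <- "# coordinates are 0-based voxel indices, order z,y,x (z-slice first)"
  jt <- features$junction_triples
  jrows <- data.frame(z = integer(0), y = integer(0), x = integer(0),
                      label_i = integer(0), label_j = integer(0),
                      label_k = integer(0))
  for (key in names(jt)) {
    tri <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    m <- jt[[key]]
    jrows <- rbind(jrows, data.frame(z = m[, 1] - 1L, y = m[, 2] - 1L,
                                     x = m[, 3] - 1L, label_i = tri[1],
                                     label_j = tri[2], label_k = tri[3]))
  }
  atomic_write(function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    writeLines(hdr, con)
    write.csv(jrows, con, row.names = FALSE)
  }, junctions_path)
  srows <- data.frame(segment_id = integer(0), label_i = integer(0),
                      label_j = integer(0), point = integer(0),
                      z = integer(0), y = integer(0), x = integer(0))
  for (s in seq_along(features$segments)) {
    pl <- features$segments[[s]]
    cells <- attr(pl, "cells")
    m <- poly_points(pl)
    srows <- rbind(srows, data.frame(segment_id = s, label_i = cells[1],
                                     label_j = cells[2],
                                     point = seq_len(nrow(m)),
                                     z = m[, 1] - 1L, y = m[, 2] - 1L,
                                     x = m[, 3] - 1L))
  }
  atomic_write(function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    writeLines(hdr, con)
    write.csv(srows, con, row.names = FALSE)
  }, segments_path)
  invisible(c(junctions_path, segments_path))
}

#' Write a run manifest echoing all parameters
#' @param params named list
#' @param path output file
#' @export
write_manifest <- function(params, path) {
  atomic_write(function(tmp) {
    lines <- c(sprintf("tool=celltrack3d %s",
                       as.character(utils::packageVersion("celltrack3d"))),
               sprintf("date=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               vapply(names(params), function(k)
                 sprintf("%s=%s", k, paste(params[[k]], collapse = ",")),
                 character(1)))
    writeLines(lines, tmp)
  }, path)
}
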