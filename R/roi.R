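# ImageJ .roi file support (polyline/polygon/freeline vertices only).
# The format is big-endian binary: "Iout" magic, version short, ROI type
# byte at offset 6, bounding box shorts at 8..15 (top, left, bottom,
# right), n_coordinates short at 16, and from offset 64 the vertex
# coordinates as n x-shorts relative to `left` followed by n y-shorts
# relative to `top`.

ROI_TYPE_POLYLINE <- 5L
ROI_TYPES_WITH_VERTICES <- c(polygon = 0L, line = 3L, freeline = 4L,
                             polyline = 5L, freehand = 7L)

#' Read vertices from an ImageJ .roi polyline file
#'
#' Supports the vertex-list ROI types (polygon, polyline, freeline,
#' freehand). Coordinates are returned 0-based, as drawn in ImageJ.
#'
#' @param path Path to a `.roi` file.
#' @return Two-column matrix of (x, y) vertices.
#' @export
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("unparseable imagej_roi file '", path, "': missing Iout magic")
  rd_short <- function(off, n = 1L)  # off is 0-based byte offset
    readBin(raw[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L,
            endian = "big", signed = TRUE)
  type <- as.integer(raw[7L])
  if (!type %in% ROI_TYPES_WITH_VERTICES)
    stop("unparseable imagej_roi file '", path, "': ROI type ", type,
         " has no vertex list")
  top <- rd_short(8L); left <- rd_short(10L)
  n <- rd_short(16L)
  if (n < 2L) stop("degenerate path: ", path)
  if (length(raw) < 64L + 4L * n)
    stop("unparseable imagej_roi file '", path, "': truncated")
  xs <- rd_short(64L, n) + left
  ys <- rd_short(64L + 2L * n, n) + top
  cbind(x = as.numeric(xs), y = as.numeric(ys))
}

#' Write vertices as an ImageJ .roi polyline file
#'
#' Coordinates are rounded to integers (the classic ROI format stores
#' 16-bit integer vertices).
#'
#' @param vertices Two-column matrix of (x, y) vertices, 0-based.
#' @param path Output `.roi` path.
#' @return `path`, invisibly.
#' @export
write_imagej_roi <- function(vertices, path) {
  vertices <- round(as.matrix(vertices))
  if (ncol(vertices) != 2L || nrow(vertices) < 2L)
    stop("degenerate path: need >= 2 vertices")
  n <- nrow(vertices)
  left <- min(vertices[, 1L]); top <- min(vertices[, 2L])
  right <- max(vertices[, 1L]); bottom <- max(vertices[, 2L])
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, eos = NULL)
  wr_short <- function(v) writeBin(as.integer(v), con, size = 2L,
                                   endian = "big")
  wr_short(227L)                              # version
  writeBin(as.raw(c(ROI_TYPE_POLYLINE, 0L)), con)
  wr_short(c(top, left, bottom, right, n))
  writeBin(raw(64L - 18L), con)               # unused header fields
  wr_short(vertices[, 1L] - left)
  wr_short(vertices[, 2L] - top)
  invisible(path)
}
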