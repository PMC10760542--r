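#' Calibrated grayscale image
#'
#' Bundles a 2D intensity matrix with its spatial calibration. Pixel
#' coordinates used throughout the package are 0-based with positions at
#' pixel centers: pixel `[row, col]` of the matrix sits at
#' `(x = col - 1, y = row - 1)`.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities
#'   (arbitrary units), at least 2 x 2.
#' @param um_per_px Positive scalar, microns per pixel.
#' @param source_id Opaque identifier carried into outputs (e.g. file name).
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, um_per_px, source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("pixels must have at least 2 rows and 2 columns")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("all intensities must be finite and >= 0")
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L ||
      !is.finite(um_per_px) || um_per_px <= 0)
    stop("um_per_px must be a positive scalar")
  structure(
    list(pixels = pixels, um_per_px = um_per_px,
         source_id = as.character(source_id)),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4f um/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$um_per_px,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Neurite path (polyline) for linescan extraction
#'
#' An ordered polyline of vertices, in 0-based pixel coordinates, tracing
#' the neurite axis, plus the width (in pixels) of the band averaged
#' perpendicular to the path when sampling intensities.
#'
#' @param vertices Two-column numeric matrix (x, y), >= 2 rows; consecutive
#'   vertices must be distinct.
#' @param line_width_px Positive integer; number of perpendicular samples
#'   averaged at each point along the path. Default 3.
#' @return An object of class `cord_path`.
#' @export
cord_path <- function(vertices, line_width_px = 3L) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L)
    stop("degenerate path: need >= 2 (x, y) vertices")
  if (!all(is.finite(vertices)))
    stop("vertices must be finite")
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  d <- sqrt(rowSums((vertices[-1L, , drop = FALSE] -
                     vertices[-nrow(vertices), , drop = FALSE])^2))
  if (any(d == 0))
    stop("consecutive vertices must be distinct")
  line_width_px <- as.integer(line_width_px)
  if (length(line_width_px) != 1L || is.na(line_width_px) || line_width_px < 1L)
    stop("line_width_px must be a positive integer")
  structure(list(vertices = vertices, line_width_px = line_width_px),
            class = "cord_path")
}

#' @export
print.cord_path <- function(x, ...) {
  cat(sprintf("<cord_path> %d vertices, length %.1f px, line width %d px\n",
              nrow(x$vertices), path_length_px(x), x$line_width_px))
  invisible(x)
}

#' Total polyline length in pixels
#' @param path A [cord_path()].
#' @return Scalar length in pixel units.
#' @export
path_length_px <- function(path) {
  v <- path$vertices
  sum(sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2)))
}

#' Calibrated 1D intensity profile (linescan)
#'
#' @param position_um Strictly increasing positions in microns, starting
#'   at 0, spaced by `um_per_px`.
#' @param intensity Intensities (arbitrary units), same length.
#' @param um_per_px Positive scalar calibration.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(position_um, intensity, um_per_px) {
  if (length(position_um) != length(intensity) || length(intensity) < 2L)
    stop("position_um and intensity must have equal length >= 2")
  if (!isTRUE(all.equal(position_um[1L], 0)))
    stop("positions must start at 0")
  dp <- diff(position_um)
  if (any(dp <= 0) || any(abs(dp - um_per_px) > 1e-6 * um_per_px))
    stop("positions must increase in steps of um_per_px")
  structure(list(position_um = as.numeric(position_um),
                 intensity = as.numeric(intensity),
                 um_per_px = as.numeric(um_per_px)),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples over %.2f um (%.4f um/px)\n",
              length(x$intensity), max(x$position_um), x$um_per_px))
  invisible(x)
}

#' @export
length.intensity_profile <- function(x) length(x$intensity)

#' @export
as.data.frame.intensity_profile <- function(x, ...) {
  data.frame(position_um = x$position_um, intensity = x$intensity)
}

#' Maximum-intensity projection of a Z stack
#'
#' Collapses a stack of equally sized slices to a single image by taking,
#' at every pixel, the maximum intensity across slices.
#'
#' @param stack List of numeric matrices with identical dimensions.
#' @return A matrix of the same dimensions as each slice.
#' @export
max_project <- function(stack) {
  if (!is.list(stack) || length(stack) == 0L)
    stop("empty stack")
  dims <- lapply(stack, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      !all(vapply(dims, function(d) identical(d, dims[[1L]]), logical(1))))
    stop("ragged stack: slices must share identical dimensions")
  out <- stack[[1L]]
  for (s in stack[-1L]) out <- pmax(out, s)
  out
}

#' Read a grayscale TIFF stack
#'
#' Reads every page of a (possibly multi-page) grayscale TIFF as a numeric
#' matrix of raw intensity values, and reports the spatial calibration from
#' the TIFF resolution tags when present (x-resolution interpreted as
#' pixels per micron, the ImageJ convention for micron-calibrated stacks).
#'
#' @param path Path to a TIFF file.
#' @return A list with `slices` (list of matrices) and `um_per_px`
#'   (scalar, or `NA_real_` when the file carries no resolution tag — the
#'   caller must then supply the calibration).
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e) stop("unreadable TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  slices <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) != 2L)
      stop("not a grayscale TIFF (page ", i, " has ",
           length(dim(p)), " dimensions): ", path)
    matrix(as.numeric(p), nrow = nrow(p), ncol = ncol(p))
  })
  xres <- attr(pages[[1L]], "x.resolution")
  um_per_px <- if (!is.null(xres) && is.finite(xres) && xres > 0)
    1 / xres else NA_real_
  list(slices = slices, um_per_px = um_per_px)
}

#' Read a cord path from file
#'
#' @param path File path: a two-column CSV with header `x,y` (0-based pixel
#'   coordinates), or an ImageJ `.roi` polyline file.
#' @param dialect `"csv"` or `"imagej_roi"`; default guessed from the file
#'   extension.
#' @param line_width_px Perpendicular averaging width, passed to
#'   [cord_path()].
#' @return A [cord_path()].
#' @export
read_cord_path <- function(path, dialect = NULL, line_width_px = 3L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.roi$", path, ignore.case = TRUE))
      "imagej_roi" else "csv"
  dialect <- match.arg(dialect, c("csv", "imagej_roi"))
  v <- switch(dialect,
    csv = {
      df <- tryCatch(utils::read.csv(path),
                     error = function(e) stop("unparseable csv path file '",
                                              path, "': ",
                                              conditionMessage(e),
                                              call. = FALSE))
      if (!all(c("x", "y") %in% names(df)))
        stop("unparseable csv path file '", path, "': need columns x,y")
      as.matrix(df[, c("x", "y")])
    },
    imagej_roi = read_imagej_roi(path)
  )
  if (nrow(v) < 2L) stop("degenerate path: ", path)
  cord_path(v, line_width_px = line_width_px)
}

# Bilinear interpolation at 0-based (x, y) pixel-center coordinates.
# Coordinates must lie inside [0, ncol-1] x [0, nrow-1].
bilinear <- function(pixels, x, y) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  x0 <- pmin(pmax(floor(x), 0), nc - 2L)
  y0 <- pmin(pmax(floor(y), 0), nr - 2L)
  fx <- x - x0; fy <- y - y0
  i00 <- pixels[cbind(y0 + 1L, x0 + 1L)]
  i01 <- pixels[cbind(y0 + 1L, x0 + 2L)]
  i10 <- pixels[cbind(y0 + 2L, x0 + 1L)]
  i11 <- pixels[cbind(y0 + 2L, x0 + 2L)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Extract the intensity profile (linescan) along a cord path
#'
#' Samples the polyline at 1-pixel arc-length steps. At each step the
#' intensity is the mean of `line_width_px` bilinear samples taken along
#' the local perpendicular (1-pixel spacing, centered on the path).
#' Positions are reported in microns from the first vertex.
#'
#' @param image A [calibrated_image()].
#' @param path A [cord_path()] whose band lies within image bounds.
#' @return An [intensity_profile()].
#' @export
extract_profile <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"), inherits(path, "cord_path"))
  v <- path$vertices
  nseg <- nrow(v) - 1L
  seg_vec <- v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE]
  seg_len <- sqrt(rowSums(seg_vec^2))
  cum0 <- c(0, cumsum(seg_len))
  total <- cum0[nseg + 1L]
  s <- seq(0, floor(total + 1e-9))          # arc-length samples, px
  # segment index for each sample
  seg <- findInterval(s, cum0, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nseg)
  frac <- (s - cum0[seg]) / seg_len[seg]
  px <- v[seg, 1L] + frac * seg_vec[seg, 1L]
  py <- v[seg, 2L] + frac * seg_vec[seg, 2L]
  tx <- seg_vec[seg, 1L] / seg_len[seg]
  ty <- seg_vec[seg, 2L] / seg_len[seg]
  w <- path$line_width_px
  offsets <- seq(-(w - 1) / 2, (w - 1) / 2, length.out = w)
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  acc <- numeric(length(s))
  for (o in offsets) {
    qx <- px - o * ty
    qy <- py + o * tx
    bad <- which(qx < 0 | qx > nc - 1 | qy < 0 | qy > nr - 1)
    if (length(bad)) {
      b <- bad[1L]
      k <- which.min((v[, 1L] - px[b])^2 + (v[, 2L] - py[b])^2)
      stop(sprintf(
        "path exits image bounds near vertex %d (x=%.1f, y=%.1f)",
        k, v[k, 1L], v[k, 2L]))
    }
    acc <- acc + bilinear(image$pixels, qx, qy)
  }
  intensity_profile(position_um = s * image$um_per_px,
                    intensity = acc / w,
                    um_per_px = image$um_per_px)
}

#' Write a profile to CSV
#' @param profile An [intensity_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Read a profile from CSV (columns position_um, intensity)
#' @param path CSV file path.
#' @param um_per_px Calibration; if `NULL`, inferred from position spacing.
#' @return An [intensity_profile()].
#' @export
read_profile_csv <- function(path, um_per_px = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("position_um", "intensity") %in% names(df)))
    stop("profile csv '", path, "' must have columns position_um,intensity")
  if (is.null(um_per_px)) um_per_px <- stats::median(diff(df$position_um))
  intensity_profile(df$position_um, df$intensity, um_per_px)
}
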