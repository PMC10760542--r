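#' Puncta detection parameters
#'
#' Defaults follow the published Fiji macro settings for GLR-1::GFP
#' linescans: Gaussian smoothing sigma 0.5 px, Phansalkar window radius
#' 2 px, minimum punctum extent 10 px. The Phansalkar constants
#' (k = 0.25, r = 0.5, p = 2, q = 10) are the method's standard published
#' defaults for min-max-rescaled intensities.
#'
#' @param sigma_px Non-negative Gaussian smoothing SD, pixels. 0 disables.
#' @param radius_px Positive integer half-width of the local threshold
#'   window (window size is `2 * radius_px + 1`).
#' @param min_size_px Positive integer minimum punctum extent, pixels.
#' @param k,r,p,q Phansalkar threshold constants; `r` in (0, 1].
#' @return A `detection_params` list.
#' @export
detection_params <- function(sigma_px = 0.5, radius_px = 2L,
                             min_size_px = 10L,
                             k = 0.25, r = 0.5, p = 2.0, q = 10.0) {
  radius_px <- as.integer(radius_px)
  min_size_px <- as.integer(min_size_px)
  vals <- c(sigma_px, radius_px, min_size_px, k, r, p, q)
  if (!all(is.finite(vals))) stop("all detection parameters must be finite")
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  if (radius_px < 1L) stop("radius_px must be a positive integer")
  if (min_size_px < 1L) stop("min_size_px must be a positive integer")
  if (r <= 0 || r > 1) stop("r must lie in (0, 1]")
  structure(list(sigma_px = sigma_px, radius_px = radius_px,
                 min_size_px = min_size_px, k = k, r = r, p = p, q = q),
            class = "detection_params")
}

# Reflect-pad a vector by `m` samples on each side (edge value repeated:
# c b a | a b c ... | z y x), then apply a centered odd-length kernel.
reflect_convolve <- function(x, kernel) {
  m <- (length(kernel) - 1L) / 2L
  n <- length(x)
  if (m == 0L) return(x * kernel)
  left <- x[pmin(m:1, n)]
  right <- x[pmax(n - seq_len(m) + 1L, 1L)]
  padded <- c(left, x, right)
  out <- stats::filter(padded, kernel, method = "convolution", sides = 2L)
  as.numeric(out[(m + 1L):(m + n)])
}

#' Gaussian-smooth an intensity profile
#'
#' Convolves the intensities with a discrete Gaussian kernel (SD
#' `sigma_px` in pixel units, truncated at 4 sigma, renormalized) using
#' reflective boundary handling. Positions are unchanged; `sigma_px = 0`
#' returns the profile untouched.
#'
#' @param profile An [intensity_profile()].
#' @param sigma_px Non-negative smoothing SD in pixels.
#' @return A smoothed [intensity_profile()].
#' @export
smooth_profile <- function(profile, sigma_px = 0.5) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  if (sigma_px == 0) return(profile)
  m <- max(1L, ceiling(4 * sigma_px))
  kern <- exp(-((-m:m)^2) / (2 * sigma_px^2))
  kern <- kern / sum(kern)
  intensity_profile(profile$position_um,
                    reflect_convolve(profile$intensity, kern),
                    profile$um_per_px)
}

#' Phansalkar local adaptive threshold on a 1D profile
#'
#' Intensities are min-max rescaled to \[0, 1\]; for each sample, the mean
#' `m` and population standard deviation `s` of the `2 * radius_px + 1`
#' window (reflected at the edges) define the local threshold
#' `t = m * (1 + p * exp(-q * m) + k * (s / r - 1))`. A sample is
#' foreground iff its rescaled intensity strictly exceeds `t`.
#'
#' A flat profile (zero dynamic range) yields an all-`FALSE` mask with a
#' warning.
#'
#' @param profile An [intensity_profile()] (typically smoothed).
#' @param params A [detection_params()].
#' @return Logical mask of the same length as the profile.
#' @export
phansalkar_threshold <- function(profile, params = detection_params()) {
  stopifnot(inherits(profile, "intensity_profile"))
  y <- profile$intensity
  R <- params$radius_px
  if (length(y) < 2L * R + 1L)
    stop("profile shorter than the threshold window (", 2L * R + 1L,
         " samples)")
  lo <- min(y); hi <- max(y)
  if (hi == lo) {
    warning("flat profile: no dynamic range, returning all-background mask")
    return(rep(FALSE, length(y)))
  }
  z <- (y - lo) / (hi - lo)
  w <- 2L * R + 1L
  box <- rep(1 / w, w)
  m <- reflect_convolve(z, box)
  m2 <- reflect_convolve(z^2, box)
  s <- sqrt(pmax(m2 - m^2, 0))
  t <- m * (1 + params$p * exp(-params$q * m) + params$k * (s / params$r - 1))
  z > t
}

#' Segment a foreground mask into puncta
#'
#' Maximal runs of consecutive `TRUE` samples become candidate segments;
#' runs shorter than `min_size_px` are discarded. Segments touching either
#' end of the profile are kept but flagged `at_edge` (their widths cannot
#' be trusted; the edge policy downstream excludes them from width and
#' intensity means while still counting them for density).
#'
#' @param mask Logical vector.
#' @param min_size_px Minimum run length to keep.
#' @return A tibble with columns `start_idx`, `end_idx` (1-based,
#'   inclusive), `length_px`, `at_edge`, ordered by `start_idx`.
#' @export
segment_puncta <- function(mask, min_size_px = 10L) {
  if (length(mask) == 0L)
    return(tibble::tibble(start_idx = integer(), end_idx = integer(),
                          length_px = integer(), at_edge = logical()))
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_size_px
  tibble::tibble(
    start_idx = starts[keep],
    end_idx = ends[keep],
    length_px = r$lengths[keep],
    at_edge = starts[keep] == 1L | ends[keep] == length(mask)
  )
}
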