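#' Locate the peak within a punctum segment
#'
#' The peak is the maximum intensity inside the segment; ties are broken
#' toward the smallest index.
#'
#' @param profile An [intensity_profile()] (the smoothed profile used for
#'   detection, for consistency).
#' @param start_idx,end_idx 1-based inclusive segment bounds.
#' @return List with `peak_idx`, `peak_pos_um`, `peak_intensity`.
#' @export
measure_peak <- function(profile, start_idx, end_idx) {
  stopifnot(inherits(profile, "intensity_profile"),
            start_idx >= 1L, end_idx >= start_idx,
            end_idx <= length(profile$intensity))
  idx <- start_idx:end_idx
  k <- idx[which.max(profile$intensity[idx])]
  list(peak_idx = k,
       peak_pos_um = profile$position_um[k],
       peak_intensity = profile$intensity[k])
}

#' Estimate the background baseline of a profile
#'
#' The reference level for "half maximal" is the median intensity of all
#' sub-threshold (background) samples of the smoothed profile — a robust
#' global estimate. A per-punctum alternative (`"local_min"`: mean of the
#' smoothed profile's values at the two samples immediately outside the
#' segment) is available through the run configuration.
#'
#' @param profile An [intensity_profile()].
#' @param mask Logical foreground mask from [phansalkar_threshold()].
#' @return Scalar baseline intensity.
#' @export
estimate_baseline <- function(profile, mask) {
  stopifnot(inherits(profile, "intensity_profile"),
            length(mask) == length(profile$intensity))
  bg <- profile$intensity[!mask]
  if (length(bg) == 0L) stop("no background available")
  stats::median(bg)
}

local_min_baseline <- function(profile, start_idx, end_idx) {
  y <- profile$intensity
  lo <- if (start_idx > 1L) y[start_idx - 1L] else NA_real_
  hi <- if (end_idx < length(y)) y[end_idx + 1L] else NA_real_
  b <- mean(c(lo, hi), na.rm = TRUE)
  if (is.nan(b)) stop("no background available")
  b
}

#' Full width at half maximum of a punctum
#'
#' The half level is `baseline + (peak - baseline) / 2`. Walking left and
#' right from the peak sample, the first sample strictly below the half
#' level bounds a crossing, whose position is linearly interpolated
#' between the straddling samples. The FWHM is the distance between the
#' two crossings, in microns. If either walk reaches a profile end before
#' crossing, the width is undefined (`NA`) and the punctum is edge-flagged.
#'
#' @param profile An [intensity_profile()].
#' @param peak_idx 1-based index of the peak sample.
#' @param peak_intensity Peak intensity (must exceed `baseline`).
#' @param baseline Background reference level.
#' @return List with `fwhm_um` (scalar or `NA`), `left_um`, `right_um`,
#'   and `at_edge` (TRUE when a walk ran off the profile).
#' @export
fwhm <- function(profile, peak_idx, peak_intensity, baseline) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (peak_intensity <= baseline) stop("non-positive prominence")
  y <- profile$intensity
  x <- profile$position_um
  h <- baseline + (peak_intensity - baseline) / 2
  cross <- function(i_out, i_in) {
    # linear interpolation of the h-crossing between samples i_out, i_in
    x[i_out] + (h - y[i_out]) / (y[i_in] - y[i_out]) * (x[i_in] - x[i_out])
  }
  left <- NA_real_
  i <- peak_idx
  while (i > 1L) {
    i <- i - 1L
    if (y[i] < h) { left <- cross(i, i + 1L); break }
  }
  right <- NA_real_
  i <- peak_idx
  n <- length(y)
  while (i < n) {
    i <- i + 1L
    if (y[i] < h) { right <- cross(i, i - 1L); break }
  }
  at_edge <- is.na(left) || is.na(right)
  list(fwhm_um = if (at_edge) NA_real_ else right - left,
       left_um = left, right_um = right, at_edge = at_edge)
}

#' Peak-to-bead intensity ratio
#'
#' Punctum peak intensity divided by the calibration-bead intensity of
#' the same imaging session, removing arc-lamp output drift. The ratio is
#' dimensionless and invariant to a global gain applied to both.
#'
#' @param peak_intensity Punctum peak intensity.
#' @param bead_intensity Positive bead intensity, same units.
#' @return Scalar ratio.
#' @export
peak_to_bead <- function(peak_intensity, bead_intensity) {
  if (!is.finite(bead_intensity) || bead_intensity <= 0)
    stop("invalid bead calibration")
  peak_intensity / bead_intensity
}

#' Puncta density per 10 microns
#'
#' @param n_puncta Number of detected puncta (all, including edge-flagged).
#' @param cord_length_um Positive analyzed cord length, microns.
#' @return Scalar density per 10 um.
#' @export
density_per_10um <- function(n_puncta, cord_length_um) {
  if (!is.finite(cord_length_um) || cord_length_um <= 0)
    stop("cord_length_um must be positive")
  10 * n_puncta / cord_length_um
}

#' Detect and measure all puncta on one profile
#'
#' Runs the full single-animal chain: Gaussian smoothing, Phansalkar
#' thresholding, minimum-size segmentation, then per-punctum peak, FWHM
#' and peak-to-bead on the smoothed profile. The raw (unsmoothed) peak is
#' reported as an extra column.
#'
#' @param profile Raw [intensity_profile()].
#' @param params [detection_params()].
#' @param bead_intensity Positive bead calibration intensity.
#' @param baseline_method `"global_median"` (default) or `"local_min"`.
#' @return List with `puncta` (tibble: one row per punctum), `smoothed`
#'   (the smoothed profile), `mask`, and `baseline` (global estimate; NA
#'   if no background sample exists).
#' @export
measure_puncta <- function(profile, params = detection_params(),
                           bead_intensity,
                           baseline_method = c("global_median", "local_min")) {
  baseline_method <- match.arg(baseline_method)
  sm <- smooth_profile(profile, params$sigma_px)
  mask <- phansalkar_threshold(sm, params)
  segs <- segment_puncta(mask, params$min_size_px)
  base_global <- if (all(mask)) NA_real_ else estimate_baseline(sm, mask)
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    pk <- measure_peak(sm, s$start_idx, s$end_idx)
    base <- if (baseline_method == "global_median") base_global
            else local_min_baseline(sm, s$start_idx, s$end_idx)
    wd <- if (is.finite(base) && pk$peak_intensity > base)
      fwhm(sm, pk$peak_idx, pk$peak_intensity, base)
    else list(fwhm_um = NA_real_, at_edge = TRUE)
    tibble::tibble(
      start_idx = s$start_idx, end_idx = s$end_idx,
      peak_pos_um = pk$peak_pos_um,
      peak_intensity = pk$peak_intensity,
      peak_intensity_raw = max(profile$intensity[s$start_idx:s$end_idx]),
      baseline = base,
      fwhm_um = wd$fwhm_um,
      peak_to_bead = peak_to_bead(pk$peak_intensity, bead_intensity),
      at_edge = s$at_edge || wd$at_edge
    )
  })
  puncta <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(start_idx = integer(), end_idx = integer(),
                   peak_pos_um = numeric(), peak_intensity = numeric(),
                   peak_intensity_raw = numeric(), baseline = numeric(),
                   fwhm_um = numeric(), peak_to_bead = numeric(),
                   at_edge = logical())
  list(puncta = puncta, smoothed = sm, mask = mask, baseline = base_global)
}

#' Aggregate puncta measurements into a per-animal record
#'
#' Width and intensity means are taken over puncta with a defined FWHM
#' and `at_edge == FALSE`; the density counts every detected punctum
#' (including edge-flagged ones) over the full analyzed span. An animal
#' with no usable puncta gets `NA` means (never zeros), and an animal with
#' no puncta at all gets density 0.
#'
#' @param puncta Tibble from [measure_puncta()].
#' @param cord_length_um Analyzed profile span, microns.
#' @param bead_intensity Bead calibration intensity.
#' @param animal_id,genotype Identifiers carried into the record.
#' @return One-row tibble (animal record).
#' @export
aggregate_animal <- function(puncta, cord_length_um, bead_intensity,
                             animal_id, genotype) {
  ok <- !puncta$at_edge & !is.na(puncta$fwhm_um)
  tibble::tibble(
    animal_id = as.character(animal_id),
    genotype = as.character(genotype),
    n_puncta = nrow(puncta),
    n_measured = sum(ok),
    cord_length_um = cord_length_um,
    mean_peak_to_bead = if (any(ok)) mean(puncta$peak_to_bead[ok]) else NA_real_,
    mean_fwhm_um = if (any(ok)) mean(puncta$fwhm_um[ok]) else NA_real_,
    density_per_10um = density_per_10um(nrow(puncta), cord_length_um),
    bead_intensity = bead_intensity
  )
}

#' Analyze one animal's profile end to end
#'
#' @inheritParams measure_puncta
#' @param animal_id,genotype Identifiers.
#' @return List with `puncta` (tibble, id columns prepended) and `animal`
#'   (one-row tibble from [aggregate_animal()]).
#' @export
analyze_profile <- function(profile, params = detection_params(),
                            bead_intensity, animal_id = "", genotype = "",
                            baseline_method = "global_median") {
  res <- measure_puncta(profile, params, bead_intensity, baseline_method)
  span <- max(profile$position_um)
  puncta <- res$puncta
  if (nrow(puncta))
    puncta <- tibble::add_column(puncta,
                                 animal_id = as.character(animal_id),
                                 genotype = as.character(genotype),
                                 .before = 1L)
  list(puncta = puncta,
       animal = aggregate_animal(res$puncta, span, bead_intensity,
                                 animal_id, genotype))
}
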