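#' Specification for a synthetic puncta study
#'
#' Defines the conditions a generated study emulates: bright Gaussian
#' puncta placed by a Poisson process along a straight nerve cord on a
#' noisy background, plus a scalar calibration-bead intensity, for two
#' genotype-like groups. Default group sizes (13 wild-type-like, 28
#' mutant-like) match the study design the protocol was validated on;
#' pixel size 0.0645 um matches a 6.45-um-pixel CCD behind a 100x
#' objective, the standard configuration for ventral-nerve-cord puncta
#' imaging; ~1 um puncta widths are typical of GLR-1::GFP accumulations.
#'
#' @param n_wt,n_mut Animals per group.
#' @param cord_length_um Analyzed cord length per animal, um.
#' @param um_per_px Pixel size, um.
#' @param punctum_fwhm_um Mean and SD of planted punctum FWHM, um.
#' @param punctum_amplitude Mean and SD of planted peak amplitude above
#'   background, arbitrary units.
#' @param density_per_10um Planted puncta rate per 10 um.
#' @param background_level Constant background intensity.
#' @param noise_sd SD of additive Gaussian (detector) noise; 0 = noiseless.
#' @param bead_intensity Calibration-bead intensity, same units.
#' @param width_effect,amplitude_effect,density_effect Multiplicative
#'   shifts applied to the mutant-like group (all 1 = null study).
#' @param line_width_px Linescan averaging width recorded with cord paths.
#' @param min_separation_um Optional minimum spacing between planted
#'   puncta, enforced by count-preserving rejection placement (the
#'   Poisson count is kept; positions are redrawn); 0 disables and
#'   allows merged puncta.
#' @param seed Base RNG seed for the study.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_wt = 13L, n_mut = 28L,
                           cord_length_um = 100,
                           um_per_px = 0.0645,
                           punctum_fwhm_um = c(mean = 1.0, sd = 0.15),
                           punctum_amplitude = c(mean = 100, sd = 20),
                           density_per_10um = 2.0,
                           background_level = 20,
                           noise_sd = 10,
                           bead_intensity = 200,
                           width_effect = 1, amplitude_effect = 1,
                           density_effect = 1,
                           line_width_px = 3L,
                           min_separation_um = 0,
                           seed = 1L) {
  spec <- list(n_wt = as.integer(n_wt), n_mut = as.integer(n_mut),
               cord_length_um = cord_length_um, um_per_px = um_per_px,
               punctum_fwhm_um = punctum_fwhm_um,
               punctum_amplitude = punctum_amplitude,
               density_per_10um = density_per_10um,
               background_level = background_level,
               noise_sd = noise_sd, bead_intensity = bead_intensity,
               width_effect = width_effect,
               amplitude_effect = amplitude_effect,
               density_effect = density_effect,
               line_width_px = as.integer(line_width_px),
               min_separation_um = min_separation_um,
               seed = as.integer(seed))
  pos <- c(spec$cord_length_um, spec$um_per_px,
           spec$punctum_fwhm_um[[1L]], spec$punctum_amplitude[[1L]],
           spec$bead_intensity, spec$width_effect, spec$amplitude_effect,
           spec$density_effect)
  if (!all(is.finite(pos)) || any(pos <= 0))
    stop("lengths, widths, amplitudes, bead and effect multipliers must be positive")
  if (spec$noise_sd < 0 || spec$density_per_10um < 0)
    stop("noise_sd and density_per_10um must be >= 0")
  structure(spec, class = "synthetic_spec")
}

FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))  # 2.3548...

# Draw planted puncta for one animal under the group's effect multipliers.
draw_truth <- function(spec, group) {
  mut <- group == "mut"
  dens <- spec$density_per_10um * if (mut) spec$density_effect else 1
  fw_mean <- spec$punctum_fwhm_um[[1L]] * if (mut) spec$width_effect else 1
  fw_sd <- spec$punctum_fwhm_um[[2L]]
  amp_mean <- spec$punctum_amplitude[[1L]] *
    if (mut) spec$amplitude_effect else 1
  amp_sd <- spec$punctum_amplitude[[2L]]
  n <- stats::rpois(1L, dens * spec$cord_length_um / 10)
  if (spec$min_separation_um > 0 && n > 1L) {
    # count-preserving hard-core placement: the Poisson draw fixes the
    # number of puncta; positions violating the separation are redrawn
    sep <- spec$min_separation_um
    if ((n - 1L) * sep >= spec$cord_length_um)
      stop("min_separation_um too large for the drawn punctum count")
    pos <- numeric(0)
    for (j in seq_len(n)) {
      repeat {
        cand <- stats::runif(1L, 0, spec$cord_length_um)
        if (!length(pos) || min(abs(pos - cand)) >= sep) break
      }
      pos <- c(pos, cand)
    }
    pos <- sort(pos)
  } else {
    pos <- sort(stats::runif(n, 0, spec$cord_length_um))
  }
  list(position_um = pos,
       fwhm_um = pmax(stats::rnorm(n, fw_mean, fw_sd), 3 * spec$um_per_px),
       amplitude = pmax(stats::rnorm(n, amp_mean, amp_sd),
                        0.1 * amp_mean),
       n = n, density_per_10um = dens)
}

render_profile_values <- function(spec, truth, x_um) {
  y <- rep(spec$background_level, length(x_um))
  if (truth$n > 0L) {
    sig <- truth$fwhm_um / FWHM_PER_SIGMA
    for (i in seq_len(truth$n))
      y <- y + truth$amplitude[i] *
        exp(-(x_um - truth$position_um[i])^2 / (2 * sig[i]^2))
  }
  if (spec$noise_sd > 0)
    y <- pmax(y + stats::rnorm(length(y), 0, spec$noise_sd), 0)
  y
}

#' Generate one synthetic animal with ground truth
#'
#' Puncta are placed by a Poisson process at the group's planted density
#' along a straight cord; each punctum is a Gaussian bump with planted
#' FWHM (sigma = FWHM / 2.3548) and amplitude over a constant background,
#' with i.i.d. additive Gaussian noise. `mode = "image"` renders a 2D
#' image with a Gaussian transverse cord section (SD 2 px) and returns a
#' matching straight cord path; `mode = "profile"` returns the 1D
#' linescan directly. Fully reproducible from `(spec, group, seed)`.
#'
#' @param spec A [synthetic_spec()].
#' @param group `"wt"` or `"mut"`.
#' @param seed RNG seed for this animal.
#' @param mode `"profile"` or `"image"`.
#' @return List with `profile` (or `image` and `path`), and `truth`
#'   (planted positions, FWHMs, amplitudes, density, bead, seed).
#' @export
generate_animal <- function(spec, group = c("wt", "mut"), seed = spec$seed,
                            mode = c("profile", "image")) {
  group <- match.arg(group)
  mode <- match.arg(mode)
  eff_fwhm <- spec$punctum_fwhm_um[[1L]] *
    if (group == "mut") spec$width_effect else 1
  if (eff_fwhm <= 2 * spec$um_per_px)
    stop("unresolvable width: planted FWHM must exceed 2 pixels")
  set.seed(as.integer(seed))
  truth <- draw_truth(spec, group)
  truth$bead_intensity <- spec$bead_intensity
  truth$seed <- as.integer(seed)
  truth$group <- group
  n_px <- floor(spec$cord_length_um / spec$um_per_px) + 1L
  x_um <- (seq_len(n_px) - 1L) * spec$um_per_px
  if (mode == "profile") {
    y <- render_profile_values(spec, truth, x_um)
    return(list(profile = intensity_profile(x_um, y, spec$um_per_px),
                truth = truth))
  }
  # 2D rendering: cord along row y0 with fixed transverse Gaussian width
  n_rows <- 21L
  y0 <- 10                       # 0-based row of the cord axis
  transverse_sd_px <- 2
  rows0 <- 0:(n_rows - 1L)
  axial <- render_profile_values(
    within_noise_off(spec), truth, x_um) - spec$background_level
  img <- outer(exp(-(rows0 - y0)^2 / (2 * transverse_sd_px^2)), axial) +
    spec$background_level
  if (spec$noise_sd > 0)
    img <- pmax(img + stats::rnorm(length(img), 0, spec$noise_sd), 0)
  path <- cord_path(rbind(c(0, y0), c(n_px - 1L, y0)),
                    line_width_px = spec$line_width_px)
  list(image = calibrated_image(img, spec$um_per_px,
                                paste0("synthetic-", group, "-", seed)),
       path = path, truth = truth)
}

within_noise_off <- function(spec) { spec$noise_sd <- 0; spec }

#' Generate a full two-group synthetic study on disk
#'
#' Writes one file per animal (profile CSV by default, or 16-bit TIFF
#' plus an ImageJ .roi cord path in image mode), a sample sheet CSV with
#' columns `file, animal_id, genotype, bead_intensity, cord_path_file,
#' um_per_px`, and a ground-truth JSON — a study that [analyze_study()]
#' and [compare_all_metrics()] consume unmodified. Per-animal seeds are
#' `spec$seed * 1000 + index`.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @param mode `"profile"` or `"image"`.
#' @return Invisible list with `sample_sheet` (tibble, also written to
#'   `sample_sheet.csv`), `truth` (per-animal list), `dir`.
#' @export
generate_study <- function(spec, out_dir, mode = c("profile", "image")) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- c(rep("wt", spec$n_wt), rep("mut", spec$n_mut))
  ids <- sprintf("%s_%02d", groups, stats::ave(seq_along(groups),
                                               groups, FUN = seq_along))
  rows <- vector("list", length(groups))
  truths <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    seed_i <- spec$seed * 1000L + i
    g <- generate_animal(spec, groups[i], seed = seed_i, mode = mode)
    truths[[i]] <- g$truth
    if (mode == "profile") {
      f <- file.path(out_dir, paste0(ids[i], ".csv"))
      write_profile_csv(g$profile, f)
      cp <- NA_character_
    } else {
      f <- file.path(out_dir, paste0(ids[i], ".tif"))
      px <- g$image$pixels
      tiff::writeTIFF(pmin(round(px) / 65535, 1), f,
                      bits.per.sample = 16L, compression = "none")
      cp <- file.path(out_dir, paste0(ids[i], ".roi"))
      write_imagej_roi(g$path$vertices, cp)
    }
    rows[[i]] <- tibble::tibble(
      file = f, animal_id = ids[i], genotype = groups[i],
      bead_intensity = spec$bead_intensity, cord_path_file = cp,
      um_per_px = spec$um_per_px)
  }
  sheet <- do.call(rbind, rows)
  utils::write.csv(sheet, file.path(out_dir, "sample_sheet.csv"),
                   row.names = FALSE)
  names(truths) <- ids
  jsonlite::write_json(
    list(spec = unclass(spec), animals = truths),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sample_sheet = sheet, truth = truths, dir = out_dir))
}
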