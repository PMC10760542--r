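# Shared fixtures and independent oracles for the test suite.

# Profile with unit (or given) pixel spacing from raw intensities.
make_profile <- function(y, um_per_px = 1) {
  intensity_profile((seq_along(y) - 1) * um_per_px, y, um_per_px)
}

# Independent brute-force Phansalkar thresholder: recomputes the window
# mean, population SD and threshold from scratch at every index, using
# explicit reflected indices. Deliberately scalar and loop-based.
phansalkar_brute <- function(y, radius = 2L, k = 0.25, r = 0.5,
                             p = 2.0, q = 10.0) {
  n <- length(y)
  lo <- min(y); hi <- max(y)
  if (hi == lo) return(rep(FALSE, n))
  z <- (y - lo) / (hi - lo)
  reflect <- function(i) {
    # edge-repeating mirror: ... 2 1 | 1 2 ... n | n n-1 ...
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- logical(n)
  for (i in seq_len(n)) {
    win <- z[reflect((i - radius):(i + radius))]
    m <- mean(win)
    s <- sqrt(sum((win - m)^2) / length(win))
    t <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
    out[i] <- z[i] > t
  }
  out
}

# Run-length segmentation oracle.
segments_brute <- function(mask, min_size) {
  res <- NULL
  i <- 1L; n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_size) res <- rbind(res, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  res
}

# Pooled-point ECDF sweep for the two-sample KS statistic.
ks_D_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

# Write a grayscale TIFF carrying a resolution tag (px per micron) using
# the Python tifffile library, which unlike tiff::writeTIFF can set
# resolution tags; used only to fixture the tag-parsing path.
write_tiff_with_resolution <- function(path, nrow, ncol, px_per_um) {
  script <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = (np.arange(%d*%d).reshape(%d, %d) %% 1000).astype('uint16')\n",
    "tifffile.imwrite(r'%s', a, resolution=(%g, %g), ",
    "resolutionunit='NONE')\n"),
    nrow, ncol, nrow, ncol, path, px_per_um, px_per_um)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  status == 0L
}

# Match detected peaks to planted positions (one-to-one, nearest first).
match_planted <- function(planted_um, detected_um, tol_um = 1) {
  matched_det <- rep(FALSE, length(detected_um))
  hits <- 0L
  for (pp in planted_um) {
    d <- abs(detected_um - pp)
    d[matched_det] <- Inf
    if (length(d) && min(d) < tol_um) {
      matched_det[which.min(d)] <- TRUE
      hits <- hits + 1L
    }
  }
  list(hits = hits, matched_det = matched_det)
}

# End-to-end recovery run: renders animals as 2D images at the given
# noise level, analyzes them through the standard pipeline, and pools
# recall / false discoveries / per-punctum width errors.
recovery_run <- function(n_animals, noise_sd, seed0,
                         fwhm_um = 1.0, amplitude = 100) {
  spec <- synthetic_spec(noise_sd = noise_sd,
                         punctum_amplitude = c(mean = amplitude, sd = 0),
                         punctum_fwhm_um = c(mean = fwhm_um, sd = 0),
                         density_per_10um = 1.0, min_separation_um = 4)
  planted <- 0L; detected <- 0L; hits <- 0L
  rel_err <- numeric(0)
  for (i in seq_len(n_animals)) {
    g <- generate_animal(spec, "wt", seed = seed0 + i, mode = "image")
    prof <- extract_profile(g$image, g$path)
    p <- analyze_profile(prof, detection_params(), 200, "a", "wt")$puncta
    planted <- planted + g$truth$n
    detected <- detected + nrow(p)
    for (j in seq_along(g$truth$position_um)) {
      d <- abs(p$peak_pos_um - g$truth$position_um[j])
      if (length(d) && min(d) < 1) {
        hits <- hits + 1L
        k <- which.min(d)
        if (!is.na(p$fwhm_um[k]))
          rel_err <- c(rel_err,
                       p$fwhm_um[k] / g$truth$fwhm_um[j] - 1)
      }
    }
  }
  list(planted = planted, detected = detected, hits = hits,
       recall = hits / planted,
       fdr = if (detected > 0) (detected - hits) / detected else 0,
       rel_err = rel_err)
}
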