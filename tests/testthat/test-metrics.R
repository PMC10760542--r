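test_that("peak location takes the max with first-index tie-breaking", {
  p <- make_profile(c(10, 20, 30, 20))
  pk <- measure_peak(p, 1, 4)
  expect_equal(pk$peak_intensity, 30)
  expect_equal(pk$peak_pos_um, 2)

  plateau <- make_profile(c(5, 9, 9, 5))
  pk2 <- measure_peak(plateau, 1, 4)
  expect_equal(pk2$peak_idx, 2)

  set.seed(12)
  y <- runif(300)
  prof <- make_profile(y)
  for (i in 1:200) {
    a <- sample(1:290, 1); b <- a + sample(1:10, 1)
    pk <- measure_peak(prof, a, b)
    # linear-scan oracle
    best_i <- a; best <- y[a]
    for (j in a:b) if (y[j] > best) { best <- y[j]; best_i <- j }
    expect_equal(pk$peak_idx, best_i)
    expect_equal(pk$peak_intensity, best)
  }
})

test_that("baseline is the median of background samples", {
  p <- make_profile(c(1, 1, 9, 1, 1))
  expect_equal(estimate_baseline(p, c(FALSE, FALSE, TRUE, FALSE, FALSE)), 1)

  p2 <- make_profile(c(1, 2, 3, 4, 99))
  expect_equal(estimate_baseline(p2, c(rep(FALSE, 4), TRUE)), 2.5)

  set.seed(13)
  for (i in 1:50) {
    y <- rnorm(40)
    m <- runif(40) > 0.5
    if (all(m)) m[1] <- FALSE
    bg <- sort(y[!m])
    n <- length(bg)
    oracle <- if (n %% 2 == 1) bg[(n + 1) / 2] else
      (bg[n / 2] + bg[n / 2 + 1]) / 2
    expect_equal(estimate_baseline(make_profile(y), m), oracle)
  }

  expect_error(estimate_baseline(p, rep(TRUE, 5)), "no background")
})

test_that("FWHM matches the Gaussian closed form and linear geometry", {
  for (sg in c(0.5, 1, 2)) {
    x <- seq(0, 30, by = 0.1)
    y <- 80 * exp(-(x - 15)^2 / (2 * sg^2))
    prof <- intensity_profile(x, y, 0.1)
    pk <- which.max(y)
    w <- fwhm(prof, pk, y[pk], 0)
    expect_equal(w$fwhm_um, 2 * sqrt(2 * log(2)) * sg,
                 tolerance = 0.01)
  }

  # triangle rising 0 -> 100 over 0..5 um, back to 0 at 10 um
  x <- seq(0, 10, by = 0.5)
  tri <- 100 - 20 * abs(x - 5)
  prof <- intensity_profile(x, tri, 0.5)
  w <- fwhm(prof, which.max(tri), 100, 0)
  expect_equal(w$fwhm_um, 5.0, tolerance = 1e-12)

  # same triangle on baseline 20: dense-resampling oracle
  prof2 <- intensity_profile(x, tri + 20, 0.5)
  w2 <- fwhm(prof2, which.max(tri), 120, 20)
  dense_x <- seq(0, 10, by = 1e-5)
  dense_y <- approx(x, tri + 20, dense_x)$y
  h <- 20 + (120 - 20) / 2
  left <- dense_x[max(which(dense_y < h & dense_x < 5))]
  right <- dense_x[min(which(dense_y < h & dense_x > 5))]
  expect_equal(w2$fwhm_um, right - left, tolerance = 1e-4)
  expect_equal(w2$fwhm_um, 5.0, tolerance = 1e-6)
})

test_that("FWHM walks that hit a profile end flag the punctum", {
  y <- c(60, 80, 100, 80, 60, 30, 10)  # left side never crosses half level
  prof <- make_profile(y)
  w <- fwhm(prof, 3, 100, 0)
  expect_true(w$at_edge)
  expect_true(is.na(w$fwhm_um))
  expect_error(fwhm(prof, 3, 50, 60), "non-positive prominence")
})

test_that("FWHM is equivariant to position scaling and invariant to gain", {
  set.seed(14)
  x <- seq(0, 20, by = 0.2)
  y <- 5 + 40 * exp(-(x - 9)^2 / 3)
  prof <- intensity_profile(x, y, 0.2)
  pk <- which.max(y)
  w0 <- fwhm(prof, pk, max(y), 5)$fwhm_um
  for (c_sp in c(0.5, 2, 7.3)) {
    pc <- intensity_profile(x * c_sp, y, 0.2 * c_sp)
    expect_equal(fwhm(pc, pk, max(y), 5)$fwhm_um, c_sp * w0,
                 tolerance = 1e-9)
  }
  for (i in 1:5) {
    a <- runif(1, 0.2, 9); b <- runif(1, -2, 20)
    pa <- intensity_profile(x, a * y + b, 0.2)
    expect_equal(fwhm(pa, pk, a * max(y) + b, a * 5 + b)$fwhm_um, w0,
                 tolerance = 1e-9)
  }
})

test_that("peak-to-bead and density obey their defining ratios", {
  expect_equal(peak_to_bead(200, 100), 2)
  expect_equal(peak_to_bead(150, 150), 1)
  expect_equal(peak_to_bead(3 * 120, 3 * 80), peak_to_bead(120, 80))
  expect_error(peak_to_bead(100, 0), "invalid bead")

  expect_equal(density_per_10um(5, 50), 1)
  expect_equal(density_per_10um(0, 80), 0)
  expect_equal(density_per_10um(12, 60), 2)
  expect_error(density_per_10um(3, 0), "positive")

  # integer count recovery
  for (n in c(0L, 3L, 17L))
    expect_identical(round(density_per_10um(n, 73.2) * 73.2 / 10), as.double(n))
})

test_that("per-animal aggregation applies the edge policy", {
  p <- tibble::tibble(
    start_idx = c(1L, 30L, 60L), end_idx = c(12L, 45L, 75L),
    peak_pos_um = c(0.5, 3.5, 7), peak_intensity = c(90, 120, 100),
    peak_intensity_raw = c(95, 125, 105), baseline = 10,
    fwhm_um = c(NA, 1.2, 0.8), peak_to_bead = c(0.45, 0.6, 0.5),
    at_edge = c(TRUE, FALSE, FALSE))
  rec <- aggregate_animal(p, cord_length_um = 50, bead_intensity = 200,
                          "a1", "wt")
  expect_equal(rec$n_puncta, 3)             # edge punctum counts for density
  expect_equal(rec$density_per_10um, 0.6)
  expect_equal(rec$mean_fwhm_um, 1.0)       # but not for the means
  expect_equal(rec$mean_peak_to_bead, 0.55)

  only_edge <- p[1, ]
  rec2 <- aggregate_animal(only_edge, 50, 200, "a2", "wt")
  expect_equal(rec2$density_per_10um, 10 * 1 / 50)
  expect_true(is.na(rec2$mean_fwhm_um))
  expect_true(is.na(rec2$mean_peak_to_bead))

  rec3 <- aggregate_animal(p[0, ], 50, 200, "a3", "wt")
  expect_equal(rec3$density_per_10um, 0)
  expect_true(is.na(rec3$mean_fwhm_um))
})
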