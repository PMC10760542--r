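test_that("max_project takes the per-pixel maximum and validates input", {
  s <- matrix(runif(16), 4, 4)
  expect_identical(max_project(list(s)), s)

  a <- rbind(c(1, 2), c(3, 4))
  b <- rbind(c(4, 3), c(2, 1))
  expect_equal(max_project(list(a, b)), rbind(c(4, 3), c(3, 4)))

  set.seed(7)
  stack <- replicate(5, matrix(runif(256), 16, 16), simplify = FALSE)
  mip <- max_project(stack)
  for (i in 1:16) for (j in 1:16)
    expect_identical(mip[i, j], max(vapply(stack, `[`, numeric(1), i, j)))

  # idempotence
  expect_identical(max_project(list(mip, mip)), mip)

  expect_error(max_project(list()), "empty stack")
  expect_error(max_project(list(a, matrix(0, 3, 2))), "ragged")
})

test_that("TIFF stacks round-trip through write/read", {
  set.seed(11)
  pages <- replicate(3, matrix(sample(0:4095, 60), 6, 10) / 65535,
                     simplify = FALSE)
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, f, bits.per.sample = 16L)
  st <- read_tiff_stack(f)
  expect_length(st$slices, 3)
  for (i in 1:3)
    expect_equal(st$slices[[i]], round(pages[[i]] * 65535),
                 ignore_attr = TRUE)
  expect_true(is.na(st$um_per_px))  # writeTIFF stores no resolution tag

  f1 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pages[[1]], f1, bits.per.sample = 16L)
  expect_length(read_tiff_stack(f1)$slices, 1)

  expect_error(read_tiff_stack(tempfile(fileext = ".tif")), "not found")
})

test_that("TIFF resolution tags yield um_per_px as the tag reciprocal", {
  f <- tempfile(fileext = ".tif")
  ok <- write_tiff_with_resolution(f, 8, 12, px_per_um = 9.2593)
  expect_true(ok)
  st <- read_tiff_stack(f)
  expect_equal(st$um_per_px, 0.108, tolerance = 1e-4)
})

test_that("RGB TIFFs are rejected with the file named", {
  f <- tempfile(fileext = ".tif")
  rgb <- array(runif(24), dim = c(2, 4, 3))
  tiff::writeTIFF(rgb, f)
  expect_error(read_tiff_stack(f), "grayscale")
})

test_that("cord paths load from CSV and ImageJ .roi files", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "0,0", "10,0"), f)
  cp <- read_cord_path(f)
  expect_equal(path_length_px(cp), 10)
  expect_equal(unname(cp$vertices[, "y"]), c(0, 0))

  v <- cbind(x = c(2, 10, 15, 30), y = c(5, 8, 3, 12))
  fr <- tempfile(fileext = ".roi")
  write_imagej_roi(v, fr)
  cp2 <- read_cord_path(fr)
  expect_equal(unname(cp2$vertices), unname(v))

  f1 <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "3,4"), f1)
  expect_error(read_cord_path(f1), "degenerate path")

  fbad <- tempfile(fileext = ".roi")
  writeLines("not an roi", fbad)
  expect_error(read_cord_path(fbad), "imagej_roi")
})

test_that("profiles along uniform and axis-aligned images are exact", {
  img <- calibrated_image(matrix(7, 20, 40), um_per_px = 0.5)
  p <- extract_profile(img, cord_path(rbind(c(2, 3), c(30, 12))))
  expect_true(all(p$intensity == 7))
  expect_equal(p$position_um[1], 0)
  expect_equal(unique(round(diff(p$position_um), 10)), 0.5)

  # row 6 (0-based y = 5) holds v(x); line width 1 samples it directly
  v <- sin(0:29) + 2
  m <- matrix(1, 12, 30)
  m[6, ] <- v
  img2 <- calibrated_image(m, 1)
  p2 <- extract_profile(img2,
                        cord_path(rbind(c(0, 5), c(29, 5)),
                                  line_width_px = 1L))
  expect_equal(p2$intensity, v)
})

test_that("diagonal sampling matches the bilinear closed form on a ramp", {
  # I(x, y) = x + y is exactly reproduced by bilinear interpolation, and
  # the symmetric perpendicular band averages to the center value
  nr <- 30; nc <- 40
  m <- outer(0:(nr - 1), 0:(nc - 1), function(y, x) x + y)
  img <- calibrated_image(m, 1)
  path <- cord_path(rbind(c(3, 4), c(33, 22)), line_width_px = 3L)
  prof <- extract_profile(img, path)
  L <- path_length_px(path)
  s <- seq(0, floor(L))
  ux <- (33 - 3) / L; uy <- (22 - 4) / L
  expect_equal(prof$intensity, (3 + s * ux) + (4 + s * uy),
               tolerance = 1e-12)
  # arc length within one pixel of path length
  expect_lt(abs(max(prof$position_um) - L), 1 + 1e-9)
})

test_that("profile extraction is gain-equivariant and reversible", {
  set.seed(3)
  m <- matrix(runif(600, 1, 5), 20, 30)
  img <- calibrated_image(m, 0.2)
  # integer segment lengths so both directions sample the same points;
  # line width 1 because at a corner sample the perpendicular direction
  # is direction-dependent
  path <- cord_path(rbind(c(2, 3), c(26, 3), c(26, 15)),
                    line_width_px = 1L)
  p1 <- extract_profile(img, path)

  img_g <- calibrated_image(3.7 * m, 0.2)
  expect_equal(extract_profile(img_g, path)$intensity, 3.7 * p1$intensity)

  rev_path <- cord_path(path$vertices[3:1, ], path$line_width_px)
  p_rev <- extract_profile(img, rev_path)
  expect_equal(p_rev$intensity, rev(p1$intensity), tolerance = 1e-12)
  expect_equal(p_rev$position_um[1], 0)
})

test_that("paths leaving the image are rejected with a vertex named", {
  img <- calibrated_image(matrix(1, 10, 10), 1)
  expect_error(
    extract_profile(img, cord_path(rbind(c(1, 1), c(20, 1)))),
    "exits image bounds near vertex")
})

test_that("constructor invariants are enforced", {
  expect_error(calibrated_image(matrix(1, 1, 5), 1), "2 rows")
  expect_error(calibrated_image(matrix(-1, 3, 3), 1), "finite")
  expect_error(calibrated_image(matrix(1, 3, 3), 0), "positive")
  expect_error(cord_path(rbind(c(0, 0))), "degenerate")
  expect_error(cord_path(rbind(c(0, 0), c(0, 0))), "distinct")
  expect_error(intensity_profile(c(0, 1, 2.5), c(1, 1, 1), 1), "steps")
})
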