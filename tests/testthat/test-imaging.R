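test_that("proportional resize follows the rounding rule and preserves aspect", {
  img <- raster_image(array(runif(200 * 100 * 3), dim = c(100, 200, 3)))
  out <- resize_to_standard_width(img, 100L)
  expect_equal(out$width_px, 100L)
  expect_equal(out$height_px, 50L)

  # non-integer ratio: height = round(1000 * 1000 / 1333) = 750
  img2 <- raster_image(matrix(runif(1333 * 200), nrow = 1000, ncol = 1333))
  out2 <- resize_to_standard_width(img2, 1000L)
  expect_equal(out2$height_px, as.integer(round(1000 * 1000 / 1333)))
  expect_equal(out2$height_px, 750L)

  # already at target: untouched
  img3 <- raster_image(matrix(0.5, nrow = 80, ncol = 100))
  expect_identical(resize_to_standard_width(img3, 100L), img3)

  expect_error(resize_to_standard_width(img3, 1L), "target_width")
})

test_that("green-channel extraction keeps exactly the green plane", {
  px <- array(0, dim = c(2, 2, 3))
  px[, , 1] <- 0.9
  px[, , 2] <- 0.2
  px[, , 3] <- 0.7
  g <- extract_green(raster_image(px))
  expect_equal(g$channels, 1L)
  expect_true(all(g$pixels == 0.2))

  gray <- raster_image(matrix(runif(16), 4, 4))
  expect_identical(extract_green(gray), gray)
})

test_that("contrast stretch is the linear min-max map", {
  img <- raster_image(matrix(c(0.2, 0.4, 0.6), 1, 3))
  expect_equal(as.numeric(maximize_contrast(img)$pixels), c(0, 0.5, 1))

  spanning <- raster_image(matrix(c(0, 0.25, 1), 1, 3))
  expect_equal(maximize_contrast(spanning)$pixels, spanning$pixels)

  expect_error(maximize_contrast(raster_image(matrix(0.3, 5, 5))),
               "degenerate contrast")
})

test_that("meridian band is vertically centred with half-open row range", {
  img <- raster_image(matrix(runif(500 * 100), nrow = 500, ncol = 100))
  band <- extract_meridian_band(img, 60L)
  expect_equal(band$row_range, c(220, 280))
  expect_equal(dim(band$pixels), c(60L, 100L))
  expect_equal(band$pixels, img$pixels[221:280, ])

  exact <- raster_image(matrix(runif(60 * 10), nrow = 60, ncol = 10))
  expect_equal(extract_meridian_band(exact, 60L)$pixels, exact$pixels)

  small <- raster_image(matrix(runif(59 * 10), nrow = 59, ncol = 10))
  expect_error(extract_meridian_band(small, 60L), "too small")
})

test_that("profile reduction is the column-wise mean of the band", {
  v <- runif(50)
  band <- extract_meridian_band(
    raster_image(matrix(rep(v, each = 10), nrow = 10)), 10L)
  expect_equal(as.numeric(compute_profile(band)), v)

  two <- extract_meridian_band(
    raster_image(matrix(c(0.2, 0.6), nrow = 2, ncol = 5)), 2L)
  expect_equal(as.numeric(compute_profile(two)), rep(0.4, 5))
  expect_equal(as.numeric(compute_profile(two, reduce = "median")),
               rep(0.4, 5))
})

test_that("absolute first derivative matches hand arithmetic", {
  expect_equal(as.numeric(abs_first_derivative(c(0, 0, 1, 1), 0)),
               c(0, 1, 0))
  expect_equal(as.numeric(abs_first_derivative(rep(0.5, 10), 2)),
               rep(0, 9))
  expect_equal(as.numeric(abs_first_derivative(c(0, 0.3, 0.1), 0)),
               c(0.3, 0.2))
  expect_error(abs_first_derivative(0.5), "at least 2")
})

test_that("gaussian smoothing preserves constants and stays centred", {
  expect_equal(gaussian_smooth(rep(0.7, 30), 2), rep(0.7, 30))
  expect_equal(gaussian_smooth(1:10, 0), as.numeric(1:10))
  x <- rep(0, 41)
  x[21] <- 1
  expect_equal(which.max(gaussian_smooth(x, 2)), 21L)
  # symmetric response around the impulse
  s <- gaussian_smooth(x, 2)
  expect_equal(s[21 + 1:8], s[21 - 1:8], tolerance = 1e-12)
})

test_that("peak detection finds steps, honours separation, survives degenerate input", {
  profile <- c(rep(0, 501), rep(1, 499))      # step between columns 500/501
  pk <- detect_peaks(abs_first_derivative(profile, 0))
  expect_equal(pk$positions, 500)

  expect_length(detect_peaks(rep(0, 100))$positions, 0)

  # two close peaks: the larger wins; tie goes to the smaller index
  d <- rep(0, 60)
  d[c(20, 25)] <- c(0.5, 0.9)
  expect_equal(detect_peaks(d, min_separation_px = 10)$positions, 24)
  d2 <- rep(0, 60)
  d2[c(20, 25)] <- 0.9
  expect_equal(detect_peaks(d2, min_separation_px = 10)$positions, 19)
  # far enough apart: both kept
  d3 <- rep(0, 60)
  d3[c(20, 35)] <- c(0.5, 0.9)
  expect_equal(detect_peaks(d3, min_separation_px = 10)$positions,
               c(19, 34))

  expect_error(detect_peaks(d, min_prominence_frac = 0), "prominence")
})

test_that("a blurred ideal step keeps its derivative maximum at the step", {
  for (sigma in c(1, 2, 3)) {
    profile <- gaussian_smooth(c(rep(0.1, 400), rep(0.9, 400)), sigma)
    pk <- detect_peaks(abs_first_derivative(profile, 0))
    expect_equal(length(pk$positions), 1L)
    expect_lte(abs(pk$positions - 399), 1)
  }
})

test_that("pipeline is deterministic and invariant to intensity scaling", {
  r <- render_pattern(std_pattern(blur_sigma = 1.5, noise_sd = 0.01, seed = 3))
  m1 <- measure_pattern(r$image, table1_lens())
  m2 <- measure_pattern(r$image, table1_lens())
  expect_identical(m1$widths$mm, m2$widths$mm)
  expect_identical(m1$peaks$positions, m2$peaks$positions)

  dim_img <- raster_image(r$image$pixels * 0.4)
  m3 <- measure_pattern(dim_img, table1_lens())
  expect_equal(m3$edges$x, m1$edges$x)
  expect_equal(as.numeric(m3$profile), as.numeric(m1$profile),
               tolerance = 1e-10)
})

test_that("mirror-symmetric patterns yield mirror-symmetric peaks", {
  r <- render_pattern(std_pattern(blur_sigma = 2, noise_sd = 0))
  m <- measure_pattern(r$image)
  pos <- m$peaks$positions
  expect_equal(length(pos), 8L)
  # profile columns mirror about x = 500, so derivative indices mirror
  # about 499.5; allow the half-pixel convention plus 1 px
  mirrored <- sort(999 - pos)
  expect_true(all(abs(pos - mirrored) <= 1))
})

test_that("noiseless four-ring patterns give exactly eight peaks at the edges", {
  r <- render_pattern(std_pattern())
  m <- measure_pattern(r$image)
  expect_equal(length(m$peaks$positions), 8L)
  expect_true(all(abs(m$peaks$positions - r$edges$x) <= 1))
})

test_that("image files round-trip through load_image", {
  r <- render_pattern(std_pattern())
  png_path <- tempfile(fileext = ".png")
  write_pattern(r, png_path)
  img <- load_image(png_path)
  expect_s3_class(img, "raster_image")
  expect_equal(img$width_px, 1000L)
  expect_equal(img$height_px, 600L)
  expect_equal(img$channels, 3L)
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))

  bad <- tempfile(fileext = ".jpg")
  writeLines("this is not an image", bad)
  expect_error(load_image(bad), "decode")
  expect_error(load_image(tempfile(fileext = ".png")), "not found")
})
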