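test_that("raster_image enforces the 8-bit grid contract", {
  img <- raster_image(matrix(0L, 10, 10))
  expect_s3_class(img, "raster_image")
  expect_equal(dim(img), c(10L, 10L, 1L))
  expect_error(raster_image(matrix(-1L, 2, 2)), "\\[0, 255\\]")
  expect_error(raster_image(matrix(256L, 2, 2)), "\\[0, 255\\]")
  expect_error(raster_image(matrix(1.5, 2, 2)), "integers")
  expect_error(raster_image(array(0L, c(2, 2, 2))), "channel count")
})

test_that("PNG round-trip preserves 8-bit intensities exactly", {
  withr::local_seed(11)
  px <- array(sample(0:255, 12 * 9 * 3, replace = TRUE), c(12, 9, 3))
  path <- withr::local_tempfile(fileext = ".png")
  write_png(raster_image(px), path)
  back <- load_image(path)
  expect_identical(back$pixels, raster_image(px)$pixels)
  expect_equal(back$channels, 3L)
})

test_that("an all-black PNG loads as all-zero intensities", {
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0, 10, 10), path)
  img <- load_image(path)
  expect_true(all(img$pixels == 0L))
  expect_equal(dim(img), c(10L, 10L, 1L))
})

test_that("alpha channels are dropped on load", {
  path <- withr::local_tempfile(fileext = ".png")
  rgba <- array(runif(6 * 5 * 4), c(6, 5, 4))
  png::writePNG(rgba, path)
  img <- load_image(path)
  expect_equal(img$channels, 3L)
})

test_that("16-bit sources rescale to 8 bits by integer division", {
  # constant 65535 must map to 255
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(1, 8, 8), path, bits.per.sample = 16L)
  img <- load_image(path)
  expect_true(all(img$pixels == 255L))
  # a mid-range 16-bit value: k %/% 256
  k <- 33000
  path2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(k / 65535, 4, 4), path2)
  expect_true(all(load_image(path2)$pixels == k %/% 256))
})

test_that("grayscale conversion uses the stated luma weights", {
  px <- array(c(100L, 200L, 50L), c(1, 1, 3))
  expect_equal(to_grayscale(raster_image(px))$pixels[1, 1, 1], 153L)
  white <- raster_image(array(255L, c(2, 2, 3)))
  expect_true(all(to_grayscale(white)$pixels == 255L))
  black <- raster_image(array(0L, c(2, 2, 3)))
  expect_true(all(to_grayscale(black)$pixels == 0L))
  # equal weighting is the plain mean
  expect_equal(to_grayscale(raster_image(px), "equal")$pixels[1, 1, 1],
               round((100 + 200 + 50) / 3))
})

test_that("grayscale output is idempotent and bounded by channel extremes", {
  withr::local_seed(21)
  px <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), c(20, 20, 3))
  img <- raster_image(px)
  g <- to_grayscale(img)
  expect_identical(to_grayscale(g), g)
  lo <- pmin(px[, , 1], px[, , 2], px[, , 3])
  hi <- pmax(px[, , 1], px[, , 2], px[, , 3])
  expect_true(all(g$pixels[, , 1] >= lo & g$pixels[, , 1] <= hi))
})

test_that("split/merge channel round-trip is the identity", {
  withr::local_seed(31)
  px <- array(sample(0:255, 15 * 10 * 3, replace = TRUE), c(15, 10, 3))
  img <- raster_image(px)
  ch <- split_channels(img)
  expect_equal(ch$red$pixels[, , 1], px[, , 1] + 0L, ignore_attr = TRUE)
  merged <- merge_channels(ch$red, ch$green, ch$blue)
  expect_identical(merged$pixels, img$pixels)
  expect_error(split_channels(ch$red), "3-channel")
  # uniform purple decomposes into its constants
  purple <- raster_image(array(rep(c(128L, 0L, 128L), each = 4), c(2, 2, 3)))
  pch <- split_channels(purple)
  expect_true(all(pch$red$pixels == 128L) && all(pch$green$pixels == 0L) &&
                all(pch$blue$pixels == 128L))
})

test_that("ROI extraction slices exact half-open ranges", {
  withr::local_seed(41)
  px <- array(sample(0:255, 100, replace = TRUE), c(10, 10, 1))
  img <- raster_image(px)
  sub <- extract_roi(img, roi(2, 5, 3, 7))
  expect_equal(dim(sub), c(3L, 4L, 1L))
  # index-by-index copy oracle (0-based spec coordinates -> 1-based R)
  for (r in 0:2) for (cc in 0:3)
    expect_equal(sub$pixels[r + 1, cc + 1, 1], px[2 + r + 1, 3 + cc + 1, 1])
  expect_identical(extract_roi(img, roi(0, 10, 0, 10))$pixels, img$pixels)
  one <- extract_roi(img, roi(0, 1, 0, 1))
  expect_equal(one$pixels[1, 1, 1], px[1, 1, 1])
  expect_error(extract_roi(img, roi(0, 11, 0, 5)), "exceeds")
  expect_error(roi(3, 3, 0, 5), "start < end")
})

test_that("histograms count every ROI pixel exactly once", {
  img <- gray_image(rep(7L, 4), 2)
  h <- compute_histogram(img)
  expect_equal(h$counts[8], 4L)
  expect_equal(sum(h$counts), 4L)
  h2 <- compute_histogram(gray_image(c(0L, 0L, 255L, 128L), 2))
  expect_equal(h2$counts[c(1, 129, 256)], c(2L, 1L, 1L))
  expect_equal(h2$total, 4L)
  withr::local_seed(51)
  big <- gray_image(sample(0:255, 2500, replace = TRUE), 50)
  hb <- compute_histogram(big)
  expect_equal(hb$total, 2500L)
  expect_equal(sum(hb$counts), 2500L)
  expect_error(compute_histogram(raster_image(array(0L, c(2, 2, 3)))),
               "1-channel")
})
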