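test_that("calibrated_image validates input", {
  expect_error(calibrated_image(matrix(numeric(0), 0, 0), 0.015), "non-empty")
  expect_error(calibrated_image(matrix(300, 2, 2), 0.015), "0, 255")
  expect_error(calibrated_image(matrix(10, 2, 2), -1), "pixel_size_mm")
  img <- calibrated_image(matrix(0:3, 2, 2), 0.015, slice_id = 3)
  expect_s3_class(img, "calibrated_image")
  expect_identical(img$slice_id, 3L)
  expect_true(is.integer(img$pixels))
})

test_that("TIFF and PNG round-trips preserve 8-bit gray pixels bit-exactly", {
  px <- matrix(sample.int(256, 300, replace = TRUE) - 1L, 15, 20)
  img <- calibrated_image(px, 0.015)
  for (ext in c("tif", "png")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_image(img, path)
    back <- read_image(path, 0.015)
    expect_identical(back$pixels, img$pixels, label = ext)
  }
})

test_that("read_image rejects unsupported formats and missing files", {
  expect_error(read_image("nope.png", 0.015), "does not exist")
  path <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", path)
  expect_error(read_image(path, 0.015), "unsupported image format")
})

test_that("multi-channel rasters are converted to gray with a warning", {
  path <- withr::local_tempfile(fileext = ".png")
  arr <- array(runif(60), dim = c(4, 5, 3))
  png::writePNG(arr, path)
  expect_warning(img <- read_image(path, 0.015), "luminance")
  expect_identical(dim(img$pixels), c(4L, 5L))
})

test_that("read_stack reads multi-page TIFFs and directories in order", {
  imgs <- lapply(1:3, function(i) calibrated_image(matrix(i * 10L, 6, 4), 0.02))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(imgs, function(im) im$pixels / 255), path,
                  bits.per.sample = 8L)
  st <- read_stack(path, 0.02)
  expect_length(st, 3)
  expect_identical(vapply(st, `[[`, integer(1), "slice_id"), 1:3)
  expect_identical(st[[2]]$pixels, imgs[[2]]$pixels)

  dir <- withr::local_tempdir()
  for (i in 1:3) write_image(imgs[[i]], file.path(dir, sprintf("s%02d.png", i)))
  st2 <- read_stack(dir, 0.02)
  expect_length(st2, 3)
  expect_identical(st2[[3]]$pixels, imgs[[3]]$pixels)
})

test_that("segment_bone uses a closed gray interval", {
  img <- calibrated_image(matrix(c(88L, 89L, 200L, 255L), 1, 4), 0.015)
  m <- segment_bone(img)
  expect_identical(as.vector(m$pixels), c(FALSE, TRUE, TRUE, TRUE))
  expect_error(gray_threshold(90, 89), "lo <= hi")
  expect_error(gray_threshold(-1, 10), "lo <= hi")
})

test_that("BMD calibration maps rod grays to rod densities exactly", {
  cal <- bmd_calibration(gray_lo = 60, gray_hi = 180)
  expect_identical(gray_to_bmd(c(60, 180), cal), c(250, 750))
  expect_identical(gray_to_bmd(120, cal), 500)
  expect_warning(out <- gray_to_bmd(200, cal), "extrapolating")
  expect_gt(out, 750)
  expect_error(bmd_calibration(100, 100), "degenerate")
})
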