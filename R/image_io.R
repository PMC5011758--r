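# Calibrated image I/O, bone segmentation and BMD calibration.

#' Calibrated 2D micro-CT image
#'
#' Wraps an 8-bit grayscale raster together with its physical pixel size.
#' Rows index depth (increasing downward, toward the subarticular
#' spongiosa), columns index horizontal position.  The physical coordinate
#' of a pixel is the position of its centre: `x = (col - 0.5) * pixel_size_mm`,
#' `y = (row - 0.5) * pixel_size_mm`.
#'
#' @param pixels Integer matrix of gray values in `[0, 255]`.
#' @param pixel_size_mm Physical side length of one (isotropic) pixel in mm.
#' @param slice_id Optional integer position of the slice within a stack.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_mm, slice_id = NULL) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stopf("`pixels` must be a non-empty matrix")
  check_pos(pixel_size_mm, "pixel_size_mm")
  px <- round(as.numeric(pixels))
  if (anyNA(px) || any(px < 0) || any(px > 255))
    stopf("`pixels` must contain gray values in [0, 255]")
  structure(
    list(
      pixels = matrix(as.integer(px), nrow = nrow(pixels)),
      pixel_size_mm = as.numeric(pixel_size_mm),
      slice_id = if (is.null(slice_id)) NULL else as.integer(slice_id)
    ),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf(
    "<calibrated_image> %d x %d px, %.4g mm/px (%.3g x %.3g mm)%s\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm,
    ncol(x$pixels) * x$pixel_size_mm, nrow(x$pixels) * x$pixel_size_mm,
    if (is.null(x$slice_id)) "" else sprintf(", slice %d", x$slice_id)
  ))
  invisible(x)
}

# Convert a decoded raster array (values in [0,1]) to an 8-bit gray matrix.
raster_to_gray <- function(arr, path) {
  if (is.matrix(arr)) return(matrix(as.integer(round(arr * 255)), nrow = nrow(arr)))
  if (length(dim(arr)) == 3L) {
    nchan <- dim(arr)[3L]
    if (nchan >= 3L) {
      warnf("multi-channel raster '%s' converted to gray by luminance", path)
      g <- 0.2126 * arr[, , 1L] + 0.7152 * arr[, , 2L] + 0.0722 * arr[, , 3L]
    } else {
      g <- arr[, , 1L]
    }
    return(matrix(as.integer(round(g * 255)), nrow = dim(arr)[1L]))
  }
  stopf("cannot interpret raster '%s' as a 2D gray image", path)
}

#' Read a calibrated grayscale image
#'
#' Reads a single-channel 8-bit TIFF or PNG raster and attaches the stated
#' physical pixel size.  Multi-channel inputs are converted to gray by
#' luminance with a warning.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_mm Physical pixel size in mm (e.g. `0.015` for 15 um).
#' @param slice_id Optional slice index stored on the result.
#' @return A [calibrated_image()].
#' @seealso [read_stack()] for multi-page TIFF stacks.
#' @export
read_image <- function(path, pixel_size_mm, slice_id = NULL) {
  if (!file.exists(path)) stopf("image file does not exist: '%s'", path)
  check_pos(pixel_size_mm, "pixel_size_mm")
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stopf("unsupported image format '.%s' for '%s' (use TIFF or PNG)", ext, path)
  )
  calibrated_image(raster_to_gray(arr, path), pixel_size_mm, slice_id)
}

#' Read a stack of calibrated images
#'
#' Accepts either a multi-page TIFF file or a directory of single images
#' (read in lexicographic filename order).
#'
#' @inheritParams read_image
#' @return A list of [calibrated_image()] objects with consecutive `slice_id`.
#' @export
read_stack <- function(path, pixel_size_mm) {
  check_pos(pixel_size_mm, "pixel_size_mm")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stopf("no TIFF/PNG images found in directory '%s'", path)
    return(lapply(seq_along(files), function(i)
      read_image(files[i], pixel_size_mm, slice_id = i)))
  }
  if (!file.exists(path)) stopf("image file does not exist: '%s'", path)
  if (tolower(tools::file_ext(path)) == "png")
    return(list(read_image(path, pixel_size_mm, slice_id = 1L)))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i)
    calibrated_image(raster_to_gray(pages[[i]], path), pixel_size_mm, slice_id = i))
}

#' Write a calibrated image to disk
#'
#' Writes the 8-bit gray raster as TIFF or PNG (by file extension).  The
#' pixel values round-trip bit-exactly through [read_image()].
#'
#' @param image A [calibrated_image()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  v <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    png = png::writePNG(v, path),
    stopf("unsupported image format '.%s' for '%s' (use TIFF or PNG)", ext, path)
  )
  invisible(path)
}

#' Gray-value segmentation threshold
#'
#' Inclusive gray-value window used to binarize bone.  The default window
#' 89--255 is the mineralized-bone setting used throughout the package.
#'
#' @param lo,hi Lower and upper gray bounds, `0 <= lo <= hi <= 255`.
#' @return An object of class `gray_threshold`.
#' @export
gray_threshold <- function(lo = 89, hi = 255) {
  if (!is_num1(lo) || !is_num1(hi) || lo < 0 || hi > 255 || lo > hi)
    stopf("need 0 <= lo <= hi <= 255 (got lo = %s, hi = %s)", lo, hi)
  structure(list(lo = lo, hi = hi), class = "gray_threshold")
}

#' Binarize bone by gray thresholding
#'
#' A pixel is bone exactly when `lo <= gray <= hi` (closed interval).
#'
#' @param image A [calibrated_image()].
#' @param thr A [gray_threshold()]; default 89--255.
#' @return An object of class `binary_mask`: logical matrix `pixels`
#'   (TRUE = bone) plus the source calibration.
#' @export
segment_bone <- function(image, thr = gray_threshold()) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!inherits(thr, "gray_threshold")) stopf("`thr` must be a gray_threshold")
  binary_mask(image$pixels >= thr$lo & image$pixels <= thr$hi,
              image$pixel_size_mm, image$slice_id)
}

#' Binary bone mask
#'
#' @param pixels Logical matrix, TRUE = bone.
#' @param pixel_size_mm Physical pixel size in mm.
#' @param slice_id Optional slice index.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size_mm, slice_id = NULL) {
  if (!is.matrix(pixels) || !is.logical(pixels) || length(pixels) == 0L)
    stopf("`pixels` must be a non-empty logical matrix")
  check_pos(pixel_size_mm, "pixel_size_mm")
  structure(
    list(pixels = pixels, pixel_size_mm = as.numeric(pixel_size_mm),
         slice_id = if (is.null(slice_id)) NULL else as.integer(slice_id)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g mm/px, %.1f%% bone\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm,
              100 * mean(x$pixels)))
  invisible(x)
}

#' Two-point bone mineral density calibration
#'
#' Calibration line through the mean gray values of two hydroxyapatite
#' phantom rods of known density (defaults 250 and 750 mg CaHA/cm^3).
#'
#' @param gray_lo,gray_hi Mean gray value of the low- and high-density rod.
#' @param bmd_lo,bmd_hi Known densities of the rods in mg CaHA/cm^3.
#' @return An object of class `bmd_calibration`.
#' @export
bmd_calibration <- function(gray_lo, gray_hi, bmd_lo = 250, bmd_hi = 750) {
  for (nm in c("gray_lo", "gray_hi", "bmd_lo", "bmd_hi"))
    if (!is_num1(get(nm))) stopf("`%s` must be a single finite number", nm)
  if (gray_lo == gray_hi)
    stopf("degenerate calibration: gray_lo == gray_hi (%s)", gray_lo)
  if (bmd_lo >= bmd_hi) stopf("need bmd_lo < bmd_hi")
  structure(list(gray_lo = gray_lo, gray_hi = gray_hi,
                 bmd_lo = bmd_lo, bmd_hi = bmd_hi),
            class = "bmd_calibration")
}

#' Convert gray values to bone mineral density
#'
#' Linear interpolation through the two rod points; values outside the rod
#' range are extrapolated on the same global line, with a warning.
#'
#' @param gray Numeric vector of gray values.
#' @param calib A [bmd_calibration()].
#' @return Densities in mg CaHA/cm^3, same length as `gray`.
#' @export
gray_to_bmd <- function(gray, calib) {
  if (!inherits(calib, "bmd_calibration")) stopf("`calib` must be a bmd_calibration")
  if (!is.numeric(gray)) stopf("`gray` must be numeric")
  slope <- (calib$bmd_hi - calib$bmd_lo) / (calib$gray_hi - calib$gray_lo)
  bmd <- calib$bmd_lo + slope * (gray - calib$gray_lo)
  if (any(bmd < min(calib$bmd_lo, calib$bmd_hi) |
          bmd > max(calib$bmd_lo, calib$bmd_hi), na.rm = TRUE))
    warnf("gray values outside the rod range: extrapolating beyond [%g, %g] mg CaHA/cm^3",
          calib$bmd_lo, calib$bmd_hi)
  bmd
}
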