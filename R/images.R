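#' Grayscale image container
#'
#' A minimal container for a single-channel fluorescence image: a numeric
#' matrix of non-negative intensities plus the physical pixel size.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param pixel_size Physical size of one pixel in micrometers
#'   (default `1/15`, i.e. 15 px per micrometer).
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, pixel_size = 1 / 15) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_param("image must have at least one row and one column")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop_param("image intensities must be finite and non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop_param("pixel_size must be a positive scalar")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "gray_image")
}

#' Binary mask container
#'
#' @param mask Logical matrix; `TRUE` marks mitochondrial signal.
#' @param pixel_size Micrometers per pixel.
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(mask, pixel_size = 1 / 15) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop_param("mask must not contain NA")
  structure(list(mask = mask, pixel_size = pixel_size),
            class = "binary_image")
}

as_pixels <- function(x) {
  if (inherits(x, "gray_image")) x$pixels else as.matrix(x)
}

as_mask_matrix <- function(x) {
  if (inherits(x, "binary_image")) return(x$mask)
  m <- as.matrix(x)
  if (is.numeric(m)) m <- m > 0
  storage.mode(m) <- "logical"
  m
}

pixel_size_of <- function(x, default = 1 / 15) {
  if (inherits(x, c("gray_image", "binary_image"))) x$pixel_size else default
}

#' Read a grayscale image from TIFF or PNG
#'
#' Reads a single-channel 8/16-bit TIFF or a PNG; multi-channel images are
#' reduced to their first channel.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param pixel_size Micrometers per pixel (default `1/15`).
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path, pixel_size = 1 / 15) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_param("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  gray_image(px, pixel_size)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask A [binary_image()] or logical matrix.
#' @param path Output path.
#' @export
write_mask_tiff <- function(mask, path) {
  m <- as_mask_matrix(mask)
  tiff::writeTIFF(m * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a grayscale image as TIFF
#'
#' Intensities are rescaled to `[0, 1]` before writing.
#'
#' @param image A [gray_image()] or numeric matrix.
#' @param path Output path.
#' @param bits Bits per sample (8 or 16).
#' @export
write_gray_tiff <- function(image, path, bits = 16L) {
  px <- as_pixels(image)
  mx <- max(px)
  if (mx > 0) px <- px / mx
  tiff::writeTIFF(px, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Fraction of foreground pixels in a mask
#'
#' @param mask A [binary_image()] or logical matrix.
#' @param region Optional bounding box `c(row_min, row_max, col_min, col_max)`
#'   (inclusive); must lie within the image.
#' @return Foreground fraction in `[0, 1]`.
#' @export
area_fraction <- function(mask, region = NULL) {
  m <- as_mask_matrix(mask)
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 4L ||
        region[1] < 1L || region[3] < 1L ||
        region[2] > nrow(m) || region[4] > ncol(m) ||
        region[1] > region[2] || region[3] > region[4])
      stop_param("region must be c(row_min, row_max, col_min, col_max) within the image")
    m <- m[region[1]:region[2], region[3]:region[4], drop = FALSE]
  }
  mean(m)
}
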