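#' Segmentation parameters
#'
#' Parameters of the confocal segmentation pipeline: median smoothing,
#' contrast enhancement with a small saturated fraction, a local median
#' threshold whose radius matches the apparent width of a mitochondrion,
#' an intersecting global threshold, and a final count-based erosion that
#' removes residual background speckle.
#'
#' @param median_radius_px Radius of the median smoothing filter (default 2).
#' @param saturation_fraction Fraction of pixels saturated during contrast
#'   enhancement (default 0.004, i.e. 0.4\%).
#' @param local_radius_px Radius of the local median threshold window
#'   (default 10, the width of a mitochondrion in pixels).
#' @param global_threshold Manual global threshold on the enhanced image in
#'   `[0, 1]`, or `NULL` for the automatic triangle method.
#' @param erode_iterations Erosion iterations (default 1).
#' @param erode_count A foreground pixel is removed when at least this many
#'   of its 8 neighbours are background (default 4).
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(median_radius_px = 2L,
                       saturation_fraction = 0.004,
                       local_radius_px = 10L,
                       global_threshold = NULL,
                       erode_iterations = 1L,
                       erode_count = 4L) {
  if (median_radius_px < 1L || local_radius_px < 1L)
    stop_param("filter radii must be >= 1")
  if (saturation_fraction < 0 || saturation_fraction >= 1)
    stop_param("saturation_fraction must be in [0, 1)")
  if (erode_iterations < 0L || erode_count < 1L || erode_count > 8L)
    stop_param("invalid erosion parameters")
  if (!is.null(global_threshold) &&
      (!is.numeric(global_threshold) || length(global_threshold) != 1L))
    stop_param("global_threshold must be a single numeric value or NULL")
  structure(list(median_radius_px = as.integer(median_radius_px),
                 saturation_fraction = saturation_fraction,
                 local_radius_px = as.integer(local_radius_px),
                 global_threshold = global_threshold,
                 erode_iterations = as.integer(erode_iterations),
                 erode_count = as.integer(erode_count)),
            class = "seg_params")
}

## reflect-pad, run f on padded image, crop back
with_reflect_pad <- function(px, pad, f) {
  nr <- nrow(px); nc <- ncol(px)
  pr <- min(pad, nr - 1L); pc <- min(pad, nc - 1L)
  rows <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  cols <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  out <- f(px[rows, cols, drop = FALSE])
  out[pr + seq_len(nr), pc + seq_len(nc), drop = FALSE]
}

median_filter <- function(px, radius) {
  with_reflect_pad(px, radius, function(p) EBImage::medianFilter(p, radius))
}

## percentile clip (saturating `saturation_fraction` of pixels split between
## both tails), rescale to [0,1], then histogram equalization anchored so the
## minimum maps to 0
enhance_contrast <- function(px, saturation_fraction = 0.004) {
  q <- quantile(px, c(saturation_fraction / 2, 1 - saturation_fraction / 2),
                names = FALSE)
  if (q[2] <= q[1]) q <- range(px)
  x <- pmin(pmax(px, q[1]), q[2])
  if (q[2] > q[1]) x <- (x - q[1]) / (q[2] - q[1])
  ## equalize: map value -> anchored empirical CDF
  r <- rank(x, ties.method = "max") / length(x)
  r0 <- min(r)
  if (r0 < 1) r <- (r - r0) / (1 - r0)
  matrix(r, nrow(px), ncol(px))
}

## triangle auto-threshold on a 256-bin histogram
triangle_threshold <- function(px, nbins = 256L) {
  h <- tabulate(pmin(nbins, floor(px * nbins) + 1L), nbins)
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  ## use the longer tail
  if ((peak - lo) >= (hi - peak)) { a <- lo; dir <- -1L } else { a <- hi; dir <- 1L }
  if (a == peak) return((peak - 0.5) / nbins)
  ## distance from histogram points to the line (peak, h[peak]) -- (a, 0)
  xs <- seq(peak, a, by = dir)
  x1 <- peak; y1 <- h[peak]; x2 <- a; y2 <- 0
  d <- abs((y2 - y1) * xs - (x2 - x1) * h[xs] + x2 * y1 - y2 * x1)
  b <- xs[which.max(d)]
  (b - 0.5) / nbins
}

#' Segment a confocal image into a binary mitochondrial mask
#'
#' The grayscale image is median-smoothed, contrast enhanced (percentile clip
#' with a saturated fraction, rescale, histogram equalization), then two
#' binary images are combined: a local median threshold (window radius equal
#' to the mitochondrial width) and a global threshold (manual or triangle
#' method). Their intersection is eroded with a count-based erosion to drop
#' residual background pixels.
#'
#' @param image A [gray_image()] or numeric matrix.
#' @param params A [seg_params()] object.
#' @return A [binary_image()] carrying the input pixel size.
#' @export
segment_confocal <- function(image, params = seg_params()) {
  if (!inherits(params, "seg_params")) stop_param("params must be seg_params()")
  px <- as_pixels(image)
  psz <- pixel_size_of(image)
  if (all(px == 0)) {
    warning("image contains no signal; returning an empty mask")
    return(binary_image(matrix(FALSE, nrow(px), ncol(px)), psz))
  }
  rng <- range(px)
  if (!is.null(params$global_threshold)) {
    ## manual thresholds are expressed on the enhanced [0,1] scale
    if (params$global_threshold < 0 || params$global_threshold > 1)
      stop_param("manual global_threshold must lie in [0, 1] (enhanced scale)")
  }
  x <- (px - rng[1]) / (rng[2] - rng[1])
  sm <- median_filter(x, params$median_radius_px)
  enh <- enhance_contrast(sm, params$saturation_fraction)
  local_bg <- median_filter(enh, params$local_radius_px)
  local_mask <- enh > local_bg
  thr <- params$global_threshold %||% triangle_threshold(enh)
  global_mask <- enh >= thr
  m <- local_mask & global_mask
  if (params$erode_iterations > 0L)
    m <- cpp_erode_count(m, params$erode_count, params$erode_iterations)
  binary_image(m, psz)
}

#' Segment a synthetic image with a global threshold
#'
#' @param image A [gray_image()] or numeric matrix.
#' @param threshold Intensity threshold; pixels with intensity `>= threshold`
#'   become foreground.
#' @return A [binary_image()].
#' @export
segment_synthetic <- function(image, threshold) {
  px <- as_pixels(image)
  if (!is.numeric(threshold) || length(threshold) != 1L)
    stop_param("threshold must be a single number")
  if (threshold < 0)
    stop_param("threshold must lie within the intensity range (>= 0)")
  binary_image(px >= threshold, pixel_size_of(image))
}
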