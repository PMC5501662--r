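#' Fit the mitochondrial network model to an image
#'
#' The main entry point of the package: takes a segmented binary mask (or a
#' grayscale image, which is segmented first), skeletonizes it, classifies
#' and merges skeleton pixels into structural elements, disconnects 4-way
#' junctions, groups elements into clusters, excludes clusters in regions
#' too dense to skeletonize reliably, and computes connectivity metrics.
#'
#' @param x A [binary_image()], logical matrix, [gray_image()] or numeric
#'   matrix. Numeric input is segmented with [segment_synthetic()] when
#'   `threshold` is given, otherwise with [segment_confocal()].
#' @param pixel_size Micrometers per pixel (taken from `x` when available).
#' @param threshold Optional global threshold for synthetic images.
#' @param params [seg_params()] for confocal segmentation.
#' @param max_area_fraction Cluster density exclusion limit (default 0.6).
#' @return An object of class `mito_network` with components `mask`,
#'   `skeleton`, `clusters` (kept), `excluded`, `excluded_fraction` and
#'   `metrics`.
#' @seealso [length_distribution()], [connectivity_metrics()]
#' @export
mito_network <- function(x, pixel_size = NULL, threshold = NULL,
                         params = seg_params(), max_area_fraction = 0.6) {
  psz <- pixel_size %||% pixel_size_of(x)
  mask <- if (inherits(x, "binary_image") || is.logical(x)) {
    binary_image(as_mask_matrix(x), psz)
  } else if (!is.null(threshold)) {
    segment_synthetic(gray_image(as_pixels(x), psz), threshold)
  } else if (inherits(x, "gray_image") || is.numeric(x)) {
    segment_confocal(gray_image(as_pixels(x), psz), params)
  } else stop_param("unsupported input type")

  skel <- skeletonize(mask)
  elems <- classify_and_merge(skel, mask = mask)
  elems <- split_four_way(elems)
  clusters <- extract_clusters(elems, mask = mask)
  filt <- filter_dense_clusters(clusters, mask, max_area_fraction)
  metrics <- if (length(filt$kept$clusters))
    connectivity_metrics(filt$kept) else NULL
  structure(list(mask = mask, skeleton = skel,
                 clusters = filt$kept, excluded = filt$excluded,
                 excluded_fraction = filt$excluded_fraction,
                 metrics = metrics, pixel_size = psz),
            class = "mito_network")
}

#' @export
print.mito_network <- function(x, ...) {
  cat("mito_network:", sum(x$mask$mask), "foreground px,",
      length(x$clusters$clusters), "clusters kept,",
      length(x$excluded$clusters), "excluded\n")
  if (!is.null(x$metrics))
    cat(sprintf("  E_C %.3g, J/E %.3g, total length %.3g um\n",
                x$metrics$E_C, x$metrics$J_over_E,
                x$metrics$total_length_um))
  invisible(x)
}

#' @export
summary.mito_network <- function(object, ...) {
  cat("Mitochondrial network fit\n")
  cat(sprintf("  image: %d x %d px at %.4g um/px\n",
              nrow(object$mask$mask), ncol(object$mask$mask),
              object$pixel_size))
  cat(sprintf("  area fraction: %.3g\n", area_fraction(object$mask)))
  cat(sprintf("  clusters: %d kept, %d excluded (%.2g%%)\n",
              length(object$clusters$clusters),
              length(object$excluded$clusters), object$excluded_fraction))
  if (!is.null(object$metrics)) print(object$metrics)
  invisible(object)
}

#' @export
coef.mito_network <- function(object, ...) {
  m <- object$metrics
  if (is.null(m)) return(setNames(numeric(0), character(0)))
  c(E_C = m$E_C, J_over_E = m$J_over_E, T_over_E = m$T_over_E,
    pct_ends = m$pct_ends, pct_tubules = m$pct_tubules,
    pct_junctions = m$pct_junctions,
    connections_per_length = m$connections_per_length,
    total_length_um = m$total_length_um,
    donut_count = m$donut_count, blob_count = m$blob_count)
}

#' @export
plot.mito_network <- function(x, ...) {
  m <- x$mask$mask
  sk <- x$skeleton$mask
  canvas <- matrix(0, nrow(m), ncol(m))
  canvas[m] <- 0.4
  canvas[sk] <- 1
  image(t(canvas[nrow(canvas):1, ]), col = gray(c(0, 0.45, 1)),
        axes = FALSE, asp = nrow(m) / ncol(m), ...)
  title(main = "mask (grey) and skeleton (white)")
  invisible(x)
}

#' Estimate the mitochondrial length distribution of a fitted network
#'
#' Resolves every kept cluster probabilistically (exact enumeration when the
#' interpretation tree is small, uniform sampling otherwise) and combines
#' the cluster distributions into the image-level distribution with a
#' 1-standard-deviation confidence band.
#'
#' @param object A [mito_network()] fit or a `mito_clusters` object.
#' @param bin_width Histogram bin width in micrometers (default 0.5).
#' @param n_samples Interpretations sampled per large cluster (default 1000).
#' @param seed RNG seed for the sampling.
#' @param table An [interpretation_table()].
#' @param max_exact_leaves Clusters whose interpretation tree has at most
#'   this many leaves are enumerated exactly (default 10000).
#' @return A `mito_length_dist` object.
#' @export
length_distribution <- function(object, bin_width = 0.5, n_samples = 1000L,
                                seed = NULL, table = interpretation_table(),
                                max_exact_leaves = 10000L) {
  clusters <- if (inherits(object, "mito_network")) object$clusters
              else object
  if (!inherits(clusters, "mito_clusters"))
    stop_param("object must be a mito_network or mito_clusters")
  n <- length(clusters$clusters)
  if (!n) stop_param("no clusters to analyse")
  psz <- clusters$pixel_size
  ## shared breaks: generous upper bound from total cluster lengths
  max_um <- max(vapply(clusters$clusters, `[[`, numeric(1),
                       "total_length_px")) * psz
  breaks <- make_breaks(max_um * 1.05 + bin_width, bin_width)
  seeds <- derive_seeds(seed %||% 1L, n)
  np <- length(table$degree3)
  cds <- lapply(seq_len(n), function(i) {
    J <- clusters$clusters[[i]]$J
    if (np^J <= max_exact_leaves) {
      brute_force_enumerate(clusters, i, table, psz, bin_width, breaks)
    } else {
      s <- sample_interpretations(clusters, i, table, n_samples, seeds[i])
      cluster_distribution(s, psz, bin_width, breaks)
    }
  })
  image_distribution(cds)
}

#' Simulate synthetic images from a fitted length distribution
#'
#' Draws new synthetic images whose mitochondrial lengths follow the fitted
#' distribution (used as a custom length table), closing the loop between
#' analysis and validation.
#'
#' @param object A [mito_network()] fit.
#' @param nsim Number of images.
#' @param seed RNG seed.
#' @param n_mitochondria Mitochondria per image; defaults to the rounded
#'   expected count of the fitted distribution.
#' @param ... Passed to [synthetic_spec()].
#' @return A list of `list(image, truth)` simulations (invisibly a list of
#'   length `nsim`).
#' @export
simulate.mito_network <- function(object, nsim = 1L, seed = NULL,
                                  n_mitochondria = NULL, ...) {
  ld <- length_distribution(object, seed = seed)
  ctr <- bin_centers(ld)
  keep <- ld$mass > 0
  tab <- data.frame(length_um = pmax(ctr[keep], 0.1),
                    density = ld$mass[keep])
  n <- n_mitochondria %||% max(1L, round(ld$expected_count))
  seeds <- derive_seeds(seed %||% 1L, nsim)
  lapply(seq_len(nsim), function(i) {
    sp <- synthetic_spec(n, length_model = tab,
                         pixels_per_um = 1 / object$pixel_size,
                         length_range = range(tab$length_um), seed = seeds[i],
                         ...)
    generate_image(sp)
  })
}

#' @importFrom stats simulate
#' @export
residuals.mito_network <- function(object, ...) {
  stop_param("residuals are not defined for a mito_network fit; ",
             "compare distributions with emd() instead")
}
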