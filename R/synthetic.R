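## Synthetic mitochondrial images with exported ground truth, emulating the
## validation setup: 500 x 500 px at 15 px/um, tortuous 1-px centerlines
## widened by a Gaussian intensity profile.

#' Specification of a synthetic mitochondrial image
#'
#' @param n_mitochondria Number of mitochondria to place.
#' @param length_model `"D1"` (Gaussian, mean 3 um), `"D2"` (equal mixture of
#'   Gaussians at 2.5 and 5 um), `"D3"` (fibroblast-like table packaged with
#'   the package), or a custom two-column table (`length_um`, `density`).
#' @param image_size Image dimensions in pixels (default `c(500, 500)`).
#' @param pixels_per_um Spatial scale (default 15).
#' @param tortuosity_sd Heading diffusion of the centerline walk, in degrees
#'   per square-root micrometer of arc length (default 15); this puts the
#'   radius of curvature on the micrometer scale, above the tube width, as
#'   in real mitochondria.
#' @param profile_sigma_px Sigma of the Gaussian cross-section added around
#'   the centerline (default 2 px).
#' @param allow_overlap Allow mitochondria to overlap (default `TRUE`, as
#'   placements are independent); `FALSE` enforces isolated mitochondria and
#'   is used for isolated-mitochondrion baselines.
#' @param length_range Admissible length range in micrometers
#'   (default `c(1, 10)`); draws outside it are resampled.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_mitochondria,
                           length_model = "D3",
                           image_size = c(500L, 500L),
                           pixels_per_um = 15,
                           tortuosity_sd = 15,
                           profile_sigma_px = 2,
                           allow_overlap = TRUE,
                           length_range = c(1, 10),
                           seed = NULL) {
  if (n_mitochondria < 1L) stop_param("n_mitochondria must be >= 1")
  if (is.character(length_model) &&
      !length_model %in% c("D1", "D2", "D3"))
    stop_param("length_model must be 'D1', 'D2', 'D3' or a length table")
  structure(list(n_mitochondria = as.integer(n_mitochondria),
                 length_model = length_model,
                 image_size = as.integer(image_size),
                 pixels_per_um = pixels_per_um,
                 tortuosity_sd = tortuosity_sd,
                 profile_sigma_px = profile_sigma_px,
                 allow_overlap = isTRUE(allow_overlap),
                 length_range = length_range,
                 seed = seed),
            class = "synthetic_spec")
}

## packaged fibroblast-like length table (truncated log-normal shape with a
## mode near 2 um, spanning 1-10 um); a configurable surrogate
d3_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "d3_length_table.csv",
                          package = "mitomorph")
      cache <<- if (nzchar(path)) {
        read.csv(path)
      } else {
        x <- seq(1, 10, by = 0.1)
        data.frame(length_um = x,
                   density = stats::dlnorm(x, meanlog = log(2) + 0.55^2,
                                           sdlog = 0.55))
      }
    }
    cache
  }
})

sigma_d1 <- 0.75
sigma_d2 <- 0.5

## inverse-CDF sampler from a tabulated density
sample_from_table <- function(tab, n) {
  cdf <- cumsum(tab$density)
  cdf <- cdf / cdf[length(cdf)]
  u <- runif(n)
  approx(c(0, cdf), c(tab$length_um[1L], tab$length_um), xout = u,
         ties = "ordered")$y
}

#' Draw mitochondrial lengths from a synthetic length model
#'
#' `D1` is Gaussian with mean 3 um; `D2` an equal mixture of Gaussians
#' centered at 2.5 and 5 um; `D3` the packaged fibroblast-like table.
#' Draws outside the admissible length range are resampled.
#'
#' @param spec A [synthetic_spec()] (its `length_model` and `length_range`
#'   are used).
#' @param n Number of lengths to draw.
#' @return Numeric vector of lengths in micrometers.
#' @export
sample_length <- function(spec, n = 1L) {
  rng <- spec$length_range
  draw <- function(k) {
    m <- spec$length_model
    if (is.character(m)) {
      switch(m,
        D1 = rnorm(k, 3, sigma_d1),
        D2 = ifelse(runif(k) < 0.5, rnorm(k, 2.5, sigma_d2),
                    rnorm(k, 5, sigma_d2)),
        D3 = sample_from_table(d3_table(), k))
    } else {
      sample_from_table(m, k)
    }
  }
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    x <- draw(n)
    out <- c(out, x[x >= rng[1L] & x <= rng[2L]])
    guard <- guard + 1L
    if (guard > 1000L) stop_param("length model incompatible with range")
  }
  out[seq_len(n)]
}

## Grow one tortuous centerline as an integer 8-connected pixel chain (so
## seed determinism holds across platforms and the chain's Euclidean length
## is the ground-truth length, measured exactly like a skeleton). The
## heading diffuses with standard deviation `tortuosity_sd` degrees per
## square-root micrometer of arc, giving a curvature radius on the
## micrometer scale -- gentle bends rather than sub-width wiggles. The walk
## stops once the accumulated chain length reaches the target, so the
## realized length matches the drawn length within one pixel step.
DIR8 <- cbind(dr = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
              dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
STEP8 <- sqrt(DIR8[, 1L]^2 + DIR8[, 2L]^2)

grow_centerline <- function(len_px, nr, nc, tortuosity_sd, pixels_per_um,
                            margin = 2L) {
  turn_sd_px <- tortuosity_sd * pi / 180 / sqrt(pixels_per_um)
  cap <- as.integer(ceiling(len_px * 1.6)) + 4L
  px <- matrix(0L, cap, 2L)
  px[1L, ] <- c(floor(runif(1, 1 + margin, nr - margin + 1)),
                floor(runif(1, 1 + margin, nc - margin + 1)))
  th <- runif(1, 0, 2 * pi)
  acc <- 0
  n <- 1L
  while (acc < len_px && n < cap) {
    k <- (round(th / (pi / 4)) %% 8) + 1
    nxt <- px[n, ] + DIR8[k, ]
    if (nxt[1L] < 1L + margin || nxt[1L] > nr - margin) th <- pi - th
    if (nxt[2L] < 1L + margin || nxt[2L] > nc - margin) th <- -th
    k <- (round(th / (pi / 4)) %% 8) + 1
    nxt <- px[n, ] + DIR8[k, ]
    nxt[1L] <- min(max(nxt[1L], 1L), nr)
    nxt[2L] <- min(max(nxt[2L], 1L), nc)
    n <- n + 1L
    px[n, ] <- nxt
    acc <- acc + STEP8[k]
    th <- th + rnorm(1, 0, turn_sd_px * sqrt(STEP8[k]))
  }
  list(px = px[seq_len(n), , drop = FALSE], length_px = acc)
}

## Does the candidate centerline come close to itself (loop back)?
## min_dist must exceed the additive-profile merge distance
## (2 * sigma * sqrt(2 * log(2 / thr)) ~ 6.7 px for sigma 2, threshold 0.5),
## otherwise the two tube flanks fuse and close a ring.
self_collides <- function(px, min_gap = 12L, min_dist = 8) {
  n <- nrow(px)
  if (n < min_gap + 2L) return(FALSE)
  for (i in seq_len(n)) {
    j <- seq.int(i + min_gap, n)
    if (!length(j) || j[1L] > n) break
    dd <- pmax(abs(px[j, 1L] - px[i, 1L]), abs(px[j, 2L] - px[i, 2L]))
    if (any(dd < min_dist)) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic mitochondrial image with ground truth
#'
#' Centerlines are grown as bounded-turn random walks from uniformly random
#' seeds, rasterized to 1-px-wide 8-connected paths, then widened by adding a
#' Gaussian intensity cross-section (unit peak for an isolated tubule;
#' overlapping mitochondria add up). With `allow_overlap = FALSE`,
#' placements whose centerline comes within a safety margin of an existing
#' mitochondrion (or of itself) are rejected and retried, guaranteeing one
#' unbranched component per mitochondrion.
#'
#' @param spec A [synthetic_spec()].
#' @param max_retries Maximum placement retries in no-overlap mode.
#' @return `list(image, truth)`: a [gray_image()] and a `ground_truth`
#'   object (per-mitochondrion centerline paths and true lengths).
#' @export
generate_image <- function(spec, max_retries = 200L) {
  nr <- spec$image_size[1L]; nc <- spec$image_size[2L]
  ppu <- spec$pixels_per_um
  with_seed(spec$seed, {
    target_um <- sample_length(spec, spec$n_mitochondria)
    lengths_um <- numeric(spec$n_mitochondria)
    pixel_paths <- vector("list", spec$n_mitochondria)
    occupied <- matrix(FALSE, nr, nc)
    clearance <- 12L
    for (i in seq_len(spec$n_mitochondria)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        gw <- grow_centerline(target_um[i] * ppu, nr, nc,
                              spec$tortuosity_sd, ppu)
        px <- gw$px
        if (!spec$allow_overlap) {
          if (self_collides(px)) next
          if (any(occupied[px])) next
          occupied <- occupied | cpp_dilate_box(
            `[<-`(matrix(FALSE, nr, nc), px, TRUE), clearance)
        }
        pixel_paths[[i]] <- px
        lengths_um[i] <- gw$length_px / ppu
        placed <- TRUE
        break
      }
      if (!placed)
        stop_param("could not place mitochondrion ", i,
                   " without overlap after ", max_retries, " retries")
    }
    img <- cpp_render_paths(nr, nc, lapply(pixel_paths, function(p) p + 0),
                            spec$profile_sigma_px)
    truth <- structure(list(paths = pixel_paths,
                            lengths_um = lengths_um,
                            target_lengths_um = target_um,
                            total_length_um = sum(lengths_um),
                            pixels_per_um = ppu,
                            image_size = c(nr, nc)),
                       class = "ground_truth")
    list(image = gray_image(img, 1 / ppu), truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$paths), "mitochondria, total",
      round(x$total_length_um, 2), "um\n")
  invisible(x)
}

ground_truth_mask <- function(truth) {
  m <- matrix(FALSE, truth$image_size[1L], truth$image_size[2L])
  for (p in truth$paths) m[p] <- TRUE
  m
}

#' Score a computed skeleton against synthetic ground truth
#'
#' Two conditions are checked: (1) the skeleton lies at the same place as
#' the original centerlines (fraction of skeleton pixels within
#' `tolerance_px` of any ground-truth pixel, Chebyshev distance), and (2)
#' lengths agree, summarized by the pre/post ratio: total true length
#' divided by total skeleton length. A ratio of 1 denotes identical length;
#' condition 1 is met when the positional match reaches 0.95.
#'
#' @param gt A `ground_truth` object.
#' @param post A [skeletonize()] result (or logical skeleton matrix).
#' @param tolerance_px Positional tolerance in pixels (default 1).
#' @return `list(length_ratio, position_match, condition1_met)`.
#' @export
skeleton_accuracy <- function(gt, post, tolerance_px = 1L) {
  sk <- if (inherits(post, "skeleton_graph")) post$mask else
    as_mask_matrix(post)
  if (!sum(sk)) {
    if (gt$total_length_um > 0)
      stop_param("empty skeleton for non-empty ground truth; ratio undefined")
    return(list(length_ratio = NA_real_, position_match = NA_real_,
                condition1_met = NA))
  }
  band <- cpp_dilate_box(ground_truth_mask(gt), as.integer(tolerance_px))
  pos <- mean(band[sk])
  post_len_um <- cpp_skeleton_length(sk) / gt$pixels_per_um
  ratio <- gt$total_length_um / post_len_um
  list(length_ratio = ratio, position_match = pos,
       condition1_met = pos >= 0.95)
}

#' Skeleton accuracy across a density sweep
#'
#' Generates replicate synthetic images over increasing mitochondrion
#' counts, segments and skeletonizes each, and scores them against ground
#' truth. Used to locate the mitochondrial area fraction beyond which
#' skeletonization degrades.
#'
#' @param spec_template A [synthetic_spec()]; its `n_mitochondria` is
#'   overridden by `n_values`.
#' @param n_values Sorted vector of mitochondrion counts.
#' @param replicates Images per count (default 10).
#' @param threshold Global segmentation threshold (default 0.5, half the
#'   isolated-tubule peak).
#' @param seed Master seed for the sweep.
#' @return Data frame with one row per count (`n`, `area_fraction`,
#'   `mean_length_ratio`, `mean_position_match`); per-image rows are in
#'   `attr(, "images")`.
#' @export
density_sweep <- function(spec_template, n_values, replicates = 10L,
                          threshold = 0.5, seed = NULL) {
  if (is.unsorted(n_values)) stop_param("n_values must be sorted increasing")
  seeds <- derive_seeds(seed %||% 1L, length(n_values) * replicates)
  rows <- list()
  k <- 0L
  for (n in n_values) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      sp <- spec_template
      sp$n_mitochondria <- as.integer(n)
      sp$seed <- seeds[k]
      g <- generate_image(sp)
      mask <- segment_synthetic(g$image, threshold)
      sk <- skeletonize(mask)
      acc <- skeleton_accuracy(g$truth, sk)
      rows[[k]] <- data.frame(n = n, replicate = r,
                              area_fraction = area_fraction(mask),
                              length_ratio = acc$length_ratio,
                              position_match = acc$position_match)
    }
  }
  img_df <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(img_df, img_df$n), function(d) {
    data.frame(n = d$n[1L], area_fraction = mean(d$area_fraction),
               mean_length_ratio = mean(d$length_ratio),
               mean_position_match = mean(d$position_match))
  }))
  rownames(agg) <- NULL
  attr(agg, "images") <- img_df
  agg
}

#' Write ground truth to CSV (mito_id, x, y per centerline pixel)
#'
#' @param truth A `ground_truth` object.
#' @param path Output CSV path.
#' @export
write_ground_truth_csv <- function(truth, path) {
  rows <- do.call(rbind, lapply(seq_along(truth$paths), function(i) {
    p <- truth$paths[[i]]
    data.frame(mito_id = i, x = p[, 2L], y = p[, 1L],
               length_um = truth$lengths_um[i])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
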