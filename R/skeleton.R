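#' Skeletonize a binary mask
#'
#' Reduces the mask to a topology-preserving 1-pixel-wide medial axis
#' (Zhang-Suen thinning with a sequential connectivity guard and removal of
#' residual 2x2 blocks). Connected components of the mask map one-to-one to
#' connected components of the skeleton.
#'
#' @param mask A [binary_image()] or logical matrix.
#' @return An object of class `skeleton_graph` with fields `mask` (logical
#'   matrix of skeleton pixels), `degree` (integer matrix of 8-connected
#'   skeleton neighbour counts) and `pixel_size`.
#' @export
skeletonize <- function(mask) {
  m <- as_mask_matrix(mask)
  thin <- cpp_thin(m)
  structure(list(mask = thin,
                 degree = neighbor_count8(thin),
                 pixel_size = pixel_size_of(mask)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  n <- sum(x$mask)
  cat("skeleton_graph:", n, "pixels,",
      sum(x$degree[x$mask] == 1L), "endpoints,",
      sum(x$degree[x$mask] >= 3L), "branch pixels\n")
  invisible(x)
}

## shift a matrix by (dr, dc), padding with FALSE/0
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_dst <- max(1L, 1L + dr):min(nr, nr + dr)
  c_dst <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(r_dst) < 1L || length(c_dst) < 1L) return(out)
  out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc]
  out
}

NB8 <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
             dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))

## per-pixel count of 8-connected foreground neighbours
neighbor_count8 <- function(m) {
  acc <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(8L))
    acc <- acc + shift_mat(m, NB8[k, 1L], NB8[k, 2L])
  acc
}

## total Euclidean length of a skeleton (exported helper used by the
## synthetic validation module)
skeleton_length_px <- function(skel) {
  m <- if (inherits(skel, "skeleton_graph")) skel$mask else as_mask_matrix(skel)
  cpp_skeleton_length(m)
}
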