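## Earth mover's distance on binned length distributions and the
## within/between-condition replicate protocol.

dist_mass <- function(d) {
  if (inherits(d, "mito_length_dist")) d$mass else as.numeric(d)
}

dist_breaks <- function(d, breaks = NULL) {
  if (inherits(d, "mito_length_dist")) d$breaks else breaks
}

#' Earth mover's distance between two length distributions
#'
#' The minimal work (mass moved times distance traveled) needed to transform
#' one distribution into the other. On shared, ordered bins this is the
#' area between the two cumulative distributions:
#' `sum(|CDF1 - CDF2|) * bin_width`, expressed in the units of the bin axis
#' (micrometers when the distributions carry a pixel size).
#'
#' @param d1,d2 `mito_length_dist` objects (or plain mass vectors).
#' @param breaks Bin edges, required when plain vectors are given.
#' @return Non-negative scalar.
#' @export
emd <- function(d1, d2, breaks = NULL) {
  b1 <- dist_breaks(d1, breaks); b2 <- dist_breaks(d2, breaks)
  if (is.null(b1) || is.null(b2))
    stop_param("bin edges missing; supply mito_length_dist objects or breaks")
  if (length(b1) != length(b2) || !isTRUE(all.equal(b1, b2)))
    stop_param("distributions must share identical bin edges")
  m1 <- dist_mass(d1); m2 <- dist_mass(d2)
  if (length(m1) != length(b1) - 1L || length(m2) != length(b1) - 1L)
    stop_param("mass vectors do not match the bin edges")
  s1 <- sum(m1); s2 <- sum(m2)
  if (abs(s1 - 1) > 1e-6 || abs(s2 - 1) > 1e-6) {
    warning("unnormalized distributions; normalizing to unit mass")
    if (s1 > 0) m1 <- m1 / s1
    if (s2 > 0) m2 <- m2 / s2
  }
  w <- diff(b1)
  sum(abs(cumsum(m1 - m2)) * w)
}

## arithmetic mean of replicate distributions per bin, renormalized
average_distribution <- function(dists) {
  breaks <- dists[[1L]]$breaks
  M <- vapply(dists, `[[`, numeric(length(breaks) - 1L), "mass")
  M <- matrix(M, nrow = length(breaks) - 1L)
  mass <- rowMeans(M)
  if (sum(mass) > 0) mass <- mass / sum(mass)
  new_length_dist(breaks, mass, rep(0, length(mass)),
                  mean(vapply(dists, `[[`, numeric(1), "expected_count")),
                  dists[[1L]]$pixel_size, "average")
}

#' Within- and between-condition EMD protocol
#'
#' For two conditions with replicate distributions, the experimental
#' variability (within) is the EMD of each replicate against its own
#' condition's average; the treatment effect (between) is the EMD of each
#' replicate against the other condition's average. Averages are per-bin
#' arithmetic means, renormalized.
#'
#' @param conditions Named list of exactly two conditions, each a list of
#'   `mito_length_dist` replicates on shared bins.
#' @return A data frame of class `emd_report` with columns `condition`,
#'   `replicate`, `comparison` (within/between), `value` and `units`.
#' @export
condition_emd_protocol <- function(conditions) {
  if (!is.list(conditions) || length(conditions) != 2L)
    stop_param("exactly two conditions are required, e.g. ",
               "list(control = ..., treated = ...)")
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    names(conditions) <- c("A", "B")
  avg <- lapply(conditions, average_distribution)
  px_known <- !is.null(conditions[[1L]][[1L]]$pixel_size)
  units <- if (px_known) "um" else "px"
  rows <- list()
  for (ci in 1:2) {
    own <- names(conditions)[ci]
    othr <- 3L - ci
    for (ri in seq_along(conditions[[ci]])) {
      d <- conditions[[ci]][[ri]]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = own, replicate = ri, comparison = "within",
        value = emd(d, avg[[ci]]), units = units)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = own, replicate = ri, comparison = "between",
        value = emd(d, avg[[othr]]), units = units)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("emd_report", "data.frame")
  out
}

#' Pool the clusters of several images into one analysis unit
#'
#' Small image sections carry few structural elements; concatenating the
#' sections of one condition before interpretation gives each sample
#' statistical weight. Elements are re-identified and clusters concatenated;
#' the pooled object behaves like a single image.
#'
#' @param cluster_sets List of `mito_clusters` objects sharing a pixel size.
#' @return A single `mito_clusters` object.
#' @export
pool_clusters <- function(cluster_sets) {
  if (!length(cluster_sets)) stop_param("nothing to pool")
  if (length(cluster_sets) == 1L) return(cluster_sets[[1L]])
  psz <- vapply(cluster_sets, `[[`, numeric(1), "pixel_size")
  if (max(abs(psz - psz[1L])) > 1e-12)
    stop_param("all pooled images must share the same pixel size")
  elements <- list()
  clusters <- list()
  for (cs in cluster_sets) {
    off <- length(elements)
    els <- lapply(cs$elements, function(e) {
      if (e$kind == "junction") e$slots$elt <- e$slots$elt + off
      else e$att <- e$att + off
      e$id <- e$id + off
      e
    })
    elements <- c(elements, els)
    clusters <- c(clusters, lapply(cs$clusters, function(cl) {
      cl$ids <- cl$ids + off
      cl
    }))
  }
  structure(list(elements = elements, clusters = clusters,
                 pixel_size = psz[1L], dim = cluster_sets[[1L]]$dim),
            class = "mito_clusters")
}

#' Ratio of connectivity metrics between two imaging channels
#'
#' Comparing the outer-membrane channel against the matrix channel of the
#' same cells: identical signals give ratios near 1, while inner-membrane
#' remodeling without outer-membrane fission shifts the ratio.
#'
#' @param metrics_outer,metrics_inner [connectivity_metrics()] of the two
#'   channels, analyzed with identical parameters.
#' @return List with `E_C_ratio` and `J_over_E_ratio` (outer/inner); `NA`
#'   with a warning when the inner value is zero or undefined.
#' @export
channel_metric_ratio <- function(metrics_outer, metrics_inner) {
  safe_ratio <- function(a, b, label) {
    if (is.na(b) || b == 0) {
      warning("inner-channel ", label, " is zero or undefined; ",
              "ratio reported as NA")
      return(NA_real_)
    }
    a / b
  }
  list(E_C_ratio = safe_ratio(metrics_outer$E_C, metrics_inner$E_C, "E_C"),
       J_over_E_ratio = safe_ratio(metrics_outer$J_over_E,
                                   metrics_inner$J_over_E, "J/E"))
}

#' Per-cell connectivity-versus-length phenotype table
#'
#' For each cell, connectivity is its `J/E` ratio and "length" is the
#' reciprocal of the mass in the 1 um bin (so the value increases with
#' mitochondrial length); both are normalized to the mean of the control
#' cells so that different experiments can be overlaid.
#'
#' @param per_cell Data frame with columns `cell`, `condition`, `j_over_e`
#'   and `mass_1um` (probability mass of the first 1 um bin).
#' @param control_label Value of `condition` marking the control cells.
#' @return Data frame with normalized `connectivity` and `length` per cell,
#'   plus attributes `control_sd` (normalized SDs of the control cloud).
#' @export
cell_phenotype_scatter <- function(per_cell, control_label = "control") {
  need <- c("cell", "condition", "j_over_e", "mass_1um")
  if (!all(need %in% names(per_cell)))
    stop_param("per_cell must have columns ", paste(need, collapse = ", "))
  ctrl <- per_cell$condition == control_label
  if (!any(ctrl)) stop_param("no control cells found")
  inv_len <- ifelse(per_cell$mass_1um > 0, 1 / per_cell$mass_1um, NA_real_)
  flagged <- is.na(inv_len)
  if (any(flagged))
    warning(sum(flagged), " cell(s) with zero 1-um-bin mass; ",
            "length value reported as NA")
  c0 <- mean(per_cell$j_over_e[ctrl])
  l0 <- mean(inv_len[ctrl], na.rm = TRUE)
  out <- data.frame(
    cell = per_cell$cell,
    condition = per_cell$condition,
    connectivity = per_cell$j_over_e / c0,
    length = inv_len / l0,
    flagged = flagged
  )
  attr(out, "control_sd") <- c(
    connectivity = sd(per_cell$j_over_e[ctrl]) / c0,
    length = sd(inv_len[ctrl], na.rm = TRUE) / l0)
  out
}
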