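## 4-way junction splitting, cluster extraction, density filtering and
## connectivity metrics.

other_slot <- function(s) if (s == 1L) 2L else 1L

## orient a tubule pixel path so that it ends (or starts) at the contact
## pixel of the given slot (slot 1 = first row, slot 2 = last row)
orient_end_at <- function(px, slot) if (slot == 1L) px[rev(seq_len(nrow(px))), , drop = FALSE] else px
orient_start_at <- function(px, slot) if (slot == 1L) px else px[rev(seq_len(nrow(px))), , drop = FALSE]

## outgoing branch direction at a junction, least squares over the first
## (up to) 5 tubule pixels from the junction side
branch_direction <- function(jel, s, els) {
  centroid <- colMeans(jel$px)
  entry <- jel$slots[s, ]
  e <- els[[entry$elt]]
  if (e$kind == "end") {
    v <- e$px[1L, ] - centroid
  } else {
    n <- nrow(e$px)
    k <- min(5L, n)
    pts <- if (entry$elt_slot == 1L) e$px[seq_len(k), , drop = FALSE]
           else e$px[n - seq_len(k) + 1L, , drop = FALSE]  # row 1 = contact
    if (k == 1L) {
      v <- pts[1L, ] - centroid
    } else {
      ctr <- colMeans(pts)
      sv <- svd(sweep(pts, 2L, ctr))
      v <- sv$v[, 1L]
      if (sum(v * (pts[k, ] - pts[1L, ])) < 0) v <- -v
    }
  }
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) c(1, 0) else v / nv
}

## all perfect matchings of an even-size index vector
all_matchings <- function(items) {
  n <- length(items)
  if (n == 0L) return(list(matrix(integer(0), 0L, 2L)))
  out <- list()
  for (b in 2:n) {
    rest <- items[-c(1L, b)]
    for (m in all_matchings(rest))
      out[[length(out) + 1L]] <- rbind(c(items[1L], items[b]), m)
  }
  out
}

#' Split junctions with four or more branches into crossing tubules
#'
#' Three-way junctions mostly represent real mitochondrial branch points,
#' whereas four-way junctions are overwhelmingly two independent mitochondria
#' crossing each other; they are therefore disconnected before the
#' probabilistic analysis. Branches are paired into pass-through tubules by
#' maximal collinearity (minimum summed angular deviation between paired
#' branch directions); junctions of odd degree >= 5 are paired greedily with
#' a warning until a degree-3 junction remains.
#'
#' @param elems A [classify_and_merge()] result.
#' @return A `mito_elements` object in which every junction has exactly
#'   three attachments.
#' @export
split_four_way <- function(elems) {
  els <- elems$elements
  deleted <- logical(length(els))
  remap <- new.env(parent = emptyenv())
  rkey <- function(id, slot) paste0(id, ".", slot)
  set_remap <- function(id, slot, nid, nslot)
    assign(rkey(id, slot), c(nid, nslot), envir = remap)
  resolve <- function(id, slot) {
    repeat {
      k <- rkey(id, slot)
      if (!exists(k, envir = remap, inherits = FALSE)) return(c(id, slot))
      v <- get(k, envir = remap)
      id <- v[1L]; slot <- v[2L]
    }
  }

  jids <- which(vapply(els, function(e) e$kind == "junction", logical(1)))
  for (j in jids) {
    jel <- els[[j]]
    deg <- nrow(jel$slots)
    if (deg < 4L) next
    ## resolve slot references (a neighbouring split may have merged tubules)
    for (s in seq_len(deg)) {
      if (!is.na(jel$slots$elt_slot[s])) {
        r <- resolve(jel$slots$elt[s], jel$slots$elt_slot[s])
        jel$slots$elt[s] <- r[1L]; jel$slots$elt_slot[s] <- r[2L]
      }
    }
    jel <- junction_geometry(jel, els)
    dirs <- t(vapply(seq_len(deg), function(s) branch_direction(jel, s, els),
                     numeric(2)))
    cost <- matrix(0, deg, deg)
    for (a in seq_len(deg - 1L)) for (b in (a + 1L):deg) {
      cost[a, b] <- cost[b, a] <-
        acos(pmin(1, pmax(-1, -sum(dirs[a, ] * dirs[b, ]))))
    }
    if (deg %% 2L == 0L) {
      ms <- all_matchings(seq_len(deg))
      tot <- vapply(ms, function(m) sum(cost[m]), numeric(1))
      pairs <- ms[[which.min(tot)]]
      leftover <- integer(0)
    } else {
      warning("junction of odd degree ", deg,
              ": pairing branches greedily, keeping a 3-way junction")
      remaining <- seq_len(deg)
      pairs <- NULL
      while (length(remaining) > 3L) {
        sub <- cost[remaining, remaining] + diag(Inf, length(remaining))
        idx <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
        p <- sort(remaining[idx])
        pairs <- rbind(pairs, p)
        remaining <- setdiff(remaining, p)
      }
      leftover <- remaining
    }

    for (pi in seq_len(NROW(pairs))) {
      a <- pairs[pi, 1L]; b <- pairs[pi, 2L]
      sa <- jel$slots[a, ]; sb <- jel$slots[b, ]
      if (!is.na(sa$elt_slot)) {
        r <- resolve(sa$elt, sa$elt_slot); sa$elt <- r[1L]; sa$elt_slot <- r[2L]
      }
      if (!is.na(sb$elt_slot)) {
        r <- resolve(sb$elt, sb$elt_slot); sb$elt <- r[1L]; sb$elt_slot <- r[2L]
      }
      L <- jel$cross[a, b]
      jpath <- jel$cross_path[[(a - 1L) * deg + b]]
      ea <- els[[sa$elt]]; eb <- els[[sb$elt]]
      nid <- length(els) + 1L
      if (ea$kind == "tubule" && eb$kind == "tubule" && sa$elt == sb$elt) {
        ## both slots of the same tubule paired: closed ring
        nt <- new_tubule(rbind(orient_start_at(ea$px, sa$elt_slot), jpath),
                         closed = TRUE, len_px = ea$len_px + L)
        deleted[sa$elt] <- TRUE
        set_remap(sa$elt, 1L, nid, 1L)
        set_remap(sa$elt, 2L, nid, 1L)
      } else if (ea$kind == "tubule" && eb$kind == "tubule") {
        pxa <- orient_end_at(ea$px, sa$elt_slot)
        pxb <- orient_start_at(eb$px, sb$elt_slot)
        outerA <- ea$att[other_slot(sa$elt_slot)]
        outerB <- eb$att[other_slot(sb$elt_slot)]
        nt <- new_tubule(rbind(pxa, jpath, pxb), att = c(outerA, outerB),
                         len_px = ea$len_px + L + eb$len_px)
        deleted[sa$elt] <- TRUE; deleted[sb$elt] <- TRUE
        set_remap(sa$elt, other_slot(sa$elt_slot), nid, 1L)
        set_remap(sa$elt, sa$elt_slot, nid, 1L)
        set_remap(sb$elt, other_slot(sb$elt_slot), nid, 2L)
        set_remap(sb$elt, sb$elt_slot, nid, 2L)
        if (!is.na(outerA) && els[[outerA]]$kind == "end")
          els[[outerA]]$att <- nid
        if (!is.na(outerB) && els[[outerB]]$kind == "end")
          els[[outerB]]$att <- nid
      } else if (ea$kind == "tubule" || eb$kind == "tubule") {
        if (ea$kind != "tubule") {  # make ea the tubule
          tmp <- sa; sa <- sb; sb <- tmp
          tmp <- ea; ea <- eb; eb <- tmp
          jpath <- jpath[rev(seq_len(NROW(jpath))), , drop = FALSE]
        }
        pxa <- orient_end_at(ea$px, sa$elt_slot)
        outerA <- ea$att[other_slot(sa$elt_slot)]
        nt <- new_tubule(rbind(pxa, jpath), att = c(outerA, sb$elt),
                         len_px = ea$len_px + L)
        deleted[sa$elt] <- TRUE
        set_remap(sa$elt, other_slot(sa$elt_slot), nid, 1L)
        set_remap(sa$elt, sa$elt_slot, nid, 1L)
        if (!is.na(outerA) && els[[outerA]]$kind == "end")
          els[[outerA]]$att <- nid
        els[[sb$elt]]$att <- nid
        els[[sb$elt]]$step_px <- 0
      } else {
        ## two ends joined across the crossing: a short tubule between them
        px <- if (NROW(jpath)) jpath else jel$px[1L, , drop = FALSE]
        nt <- new_tubule(px, att = c(sa$elt, sb$elt), len_px = L)
        els[[sa$elt]]$att <- nid; els[[sa$elt]]$step_px <- 0
        els[[sb$elt]]$att <- nid; els[[sb$elt]]$step_px <- 0
      }
      nt$id <- nid
      els[[nid]] <- nt
      deleted[nid] <- FALSE
    }

    if (length(leftover)) {
      jel$slots <- jel$slots[leftover, , drop = FALSE]
      rownames(jel$slots) <- NULL
      for (s in seq_len(nrow(jel$slots))) {
        if (!is.na(jel$slots$elt_slot[s])) {
          r <- resolve(jel$slots$elt[s], jel$slots$elt_slot[s])
          jel$slots$elt[s] <- r[1L]; jel$slots$elt_slot[s] <- r[2L]
        }
      }
      els[[j]] <- junction_geometry(jel, els)
    } else {
      deleted[j] <- TRUE
    }
  }

  ## compact: drop deleted elements, renumber, rewire references
  keep <- which(!deleted[seq_along(els)])
  newid <- rep(NA_integer_, length(els))
  newid[keep] <- seq_along(keep)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    e <- els[[keep[i]]]
    if (e$kind == "junction") {
      for (s in seq_len(nrow(e$slots))) {
        if (!is.na(e$slots$elt_slot[s])) {
          r <- resolve(e$slots$elt[s], e$slots$elt_slot[s])
          e$slots$elt[s] <- newid[r[1L]]
          e$slots$elt_slot[s] <- r[2L]
        } else {
          e$slots$elt[s] <- newid[e$slots$elt[s]]
        }
      }
    } else if (e$kind == "tubule") {
      e$att <- newid[e$att]
    } else {
      e$att <- newid[e$att]
    }
    e$id <- i
    out[[i]] <- e
  }
  elems$elements <- out
  elems
}

#' Group structural elements into clusters of connected mitochondria
#'
#' @param elems A `mito_elements` object (after [split_four_way()]).
#' @param mask Optional source mask; when given, the foreground area of each
#'   cluster's mask component is recorded (used for blob areas).
#' @return An object of class `mito_clusters` holding the elements and one
#'   record per cluster (element ids, counts per kind, total length,
#'   bounding box, area).
#' @export
extract_clusters <- function(elems, mask = NULL) {
  els <- elems$elements
  n <- length(els)
  res <- structure(list(elements = els, clusters = list(),
                        pixel_size = elems$pixel_size, dim = elems$dim),
                   class = "mito_clusters")
  if (n == 0L) return(res)
  edges <- integer(0)
  for (i in seq_len(n)) {
    e <- els[[i]]
    if (e$kind == "tubule") {
      for (a in e$att) if (!is.na(a)) edges <- c(edges, i, a)
    } else if (e$kind == "end") {
      if (!is.na(e$att)) edges <- c(edges, i, e$att)
    }
  }
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  memb <- igraph::components(g)$membership

  mlab <- NULL; mareas <- NULL
  if (!is.null(mask)) {
    mlab <- cpp_label8(as_mask_matrix(mask))
    mareas <- tabulate(mlab[mlab > 0L])
  }
  kinds <- vapply(els, `[[`, "", "kind")
  clusters <- lapply(split(seq_len(n), memb), function(ids) {
    E <- sum(kinds[ids] == "end")
    TT <- sum(kinds[ids] == "tubule")
    J <- sum(kinds[ids] == "junction")
    px <- do.call(rbind, lapply(els[ids], `[[`, "px"))
    len <- 0
    for (i in ids) {
      e <- els[[i]]
      if (e$kind == "tubule") len <- len + e$len_px
      else if (e$kind == "end") len <- len + e$cap_px + e$step_px
    }
    jdeg <- sum(vapply(els[ids], function(e)
      if (e$kind == "junction") nrow(e$slots) else 0L, numeric(1)))
    ring <- TT == 1L && E == 0L && J == 0L && isTRUE(els[[ids[1L]]]$closed)
    area <- NA_real_
    if (!is.null(mlab)) {
      lab <- mlab[px[1L, 1L], px[1L, 2L]]
      if (lab > 0L) area <- mareas[lab]
    }
    list(ids = ids, n_elements = E + TT + J, E = E, T = TT, J = J,
         junction_degree_sum = jdeg, is_ring = ring,
         total_length_px = len,
         bbox = c(range(px[, 1L]), range(px[, 2L])),
         area_px = area)
  })
  names(clusters) <- NULL
  res$clusters <- clusters
  res
}

#' Exclude clusters whose surroundings are too dense to skeletonize reliably
#'
#' Skeleton accuracy degrades abruptly when the mitochondrial area fraction
#' exceeds about 60\%; clusters whose bounding box exceeds
#' `max_area_fraction` foreground are excluded from analysis.
#'
#' @param clusters A [extract_clusters()] result.
#' @param mask The binary mask the clusters came from.
#' @param max_area_fraction Local foreground fraction above which a
#'   cluster is excluded (default 0.6).
#' @param margin_px Margin added around the cluster bounding box before
#'   measuring the foreground fraction (default 10 px, one mitochondrial
#'   width); without it an isolated straight tubule fills its own tight
#'   bounding box and would be excluded spuriously.
#' @return `list(kept, excluded, excluded_fraction)`; the fraction is the
#'   percentage of all clusters that were excluded.
#' @export
filter_dense_clusters <- function(clusters, mask, max_area_fraction = 0.6,
                                  margin_px = 10L) {
  m <- as_mask_matrix(mask)
  dens <- vapply(clusters$clusters, function(cl) {
    b <- cl$bbox
    r <- max(1L, b[1L] - margin_px):min(nrow(m), b[2L] + margin_px)
    cc <- max(1L, b[3L] - margin_px):min(ncol(m), b[4L] + margin_px)
    mean(m[r, cc, drop = FALSE])
  }, numeric(1))
  excl <- dens > max_area_fraction
  sub <- function(sel) {
    out <- clusters
    out$clusters <- clusters$clusters[sel]
    out
  }
  list(kept = sub(!excl), excluded = sub(excl),
       excluded_fraction = if (length(excl)) 100 * mean(excl) else 0)
}

#' Count donuts in each cluster
#'
#' A donut is a mitochondrion looped on itself: a junction connected twice to
#' the same tubule, with the third connection leading to a mitochondrial end
#' (directly, or through a tubule whose far side is an end).
#'
#' @param clusters A `mito_clusters` object.
#' @return Integer vector with one donut count per cluster.
#' @export
detect_donuts <- function(clusters) {
  els <- clusters$elements
  vapply(clusters$clusters, function(cl) {
    cnt <- 0L
    for (i in cl$ids) {
      e <- els[[i]]
      if (e$kind != "junction" || nrow(e$slots) != 3L) next
      tubs <- e$slots$elt[!is.na(e$slots$elt_slot)]
      dup <- unique(tubs[duplicated(tubs)])
      if (length(dup) != 1L) next
      third <- setdiff(seq_len(3L), which(e$slots$elt %in% dup))
      if (length(third) != 1L) next
      te <- e$slots$elt[third]
      leads_to_end <- if (els[[te]]$kind == "end") TRUE else {
        far <- els[[te]]$att[other_slot(e$slots$elt_slot[third])]
        !is.na(far) && els[[far]]$kind == "end"
      }
      if (leads_to_end) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
}

#' Count blobs and short isolated mitochondria
#'
#' A blob is a fully fragmented mitochondrion: an isolated cluster of three
#' structural elements (1 tubule + 2 ends) with total length below 1 um.
#' Isolated clusters with length in \[1, 2) um are counted separately.
#'
#' @param clusters A `mito_clusters` object.
#' @param pixel_size Micrometers per pixel.
#' @return `list(blob_count, blob_area_px, isolated_1_2um_count, is_blob,
#'   is_isolated_1_2um)`.
#' @export
detect_blobs <- function(clusters, pixel_size = clusters$pixel_size) {
  lens <- vapply(clusters$clusters, `[[`, numeric(1), "total_length_px") *
    pixel_size
  iso <- vapply(clusters$clusters, function(cl)
    cl$n_elements == 3L && cl$E == 2L && cl$T == 1L, logical(1))
  is_blob <- iso & lens < 1
  is_12 <- iso & lens >= 1 & lens < 2
  areas <- vapply(clusters$clusters, `[[`, numeric(1), "area_px")
  list(blob_count = sum(is_blob),
       blob_area_px = sum(areas[is_blob], na.rm = TRUE),
       isolated_1_2um_count = sum(is_12),
       is_blob = is_blob, is_isolated_1_2um = is_12)
}

#' Connectivity metrics of a clustered network
#'
#' Computes element counts and percentages, the mean number of elements per
#' cluster `E_C`, the junction/end ratio `J/E`, the tubule/end ratio `T/E`,
#' connections per unit length, and donut/blob summaries.
#'
#' @param clusters A `mito_clusters` object (normally the `kept` part of
#'   [filter_dense_clusters()]).
#' @param pixel_size Micrometers per pixel.
#' @return An object of class `connectivity_metrics`.
#' @export
connectivity_metrics <- function(clusters, pixel_size = clusters$pixel_size) {
  cls <- clusters$clusters
  if (!length(cls)) stop_param("no clusters to summarise")
  E <- sum(vapply(cls, `[[`, numeric(1), "E"))
  TT <- sum(vapply(cls, `[[`, numeric(1), "T"))
  J <- sum(vapply(cls, `[[`, numeric(1), "J"))
  tot <- E + TT + J
  ec <- mean(vapply(cls, `[[`, numeric(1), "n_elements"))
  joe <- if (E == 0L) NA_real_ else J / E
  if (E == 0L) warning("no ends in the network; J/E is undefined")
  toe <- if (E == 0L) NA_real_ else TT / E
  len_um <- sum(vapply(cls, `[[`, numeric(1), "total_length_px")) * pixel_size
  conn <- sum(vapply(cls, `[[`, numeric(1), "junction_degree_sum")) / len_um
  blobs <- detect_blobs(clusters, pixel_size)
  donuts <- detect_donuts(clusters)
  per_cluster <- data.frame(
    cluster = seq_along(cls),
    n_elements = vapply(cls, `[[`, numeric(1), "n_elements"),
    E = vapply(cls, `[[`, numeric(1), "E"),
    T = vapply(cls, `[[`, numeric(1), "T"),
    J = vapply(cls, `[[`, numeric(1), "J"),
    length_um = vapply(cls, `[[`, numeric(1), "total_length_px") * pixel_size,
    is_ring = vapply(cls, `[[`, logical(1), "is_ring"),
    donuts = donuts,
    is_blob = blobs$is_blob,
    is_isolated_1_2um = blobs$is_isolated_1_2um
  )
  structure(list(
    n_ends = E, n_tubules = TT, n_junctions = J,
    pct_ends = 100 * E / tot, pct_tubules = 100 * TT / tot,
    pct_junctions = 100 * J / tot,
    E_C = ec, J_over_E = joe, T_over_E = toe,
    connections_per_length = conn,
    total_length_um = len_um,
    n_clusters = length(cls),
    n_rings = sum(per_cluster$is_ring),
    donut_count = sum(donuts),
    blob_count = blobs$blob_count,
    blob_area_px = blobs$blob_area_px,
    isolated_1_2um_count = blobs$isolated_1_2um_count,
    per_cluster = per_cluster
  ), class = "connectivity_metrics")
}

#' @export
print.connectivity_metrics <- function(x, digits = 3L, ...) {
  cat("Mitochondrial network connectivity\n")
  cat(sprintf("  clusters: %d   elements: %d (E %d / T %d / J %d)\n",
              x$n_clusters, x$n_ends + x$n_tubules + x$n_junctions,
              x$n_ends, x$n_tubules, x$n_junctions))
  cat(sprintf("  E_C: %.*g   J/E: %.*g   T/E: %.*g\n",
              digits, x$E_C, digits, x$J_over_E, digits, x$T_over_E))
  cat(sprintf("  total length: %.*g um   connections/um: %.*g\n",
              digits, x$total_length_um, digits, x$connections_per_length))
  cat(sprintf("  donuts: %d   blobs: %d   isolated 1-2 um: %d\n",
              x$donut_count, x$blob_count, x$isolated_1_2um_count))
  invisible(x)
}
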