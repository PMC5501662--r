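## Probabilistic interpretation of cluster topology: every junction admits a
## set of equally probable local connection patterns; an interpretation picks
## one pattern per junction and resolves the cluster into individual
## mitochondrion paths whose lengths build the length distribution.

## ---- interpretation table -------------------------------------------------

generate_junction_patterns <- function(degree = 3L) {
  degree <- as.integer(degree)
  if (degree < 3L) stop_param("junction degree must be >= 3")
  pats <- list(list(pairs = list(), terminate = seq_len(degree),
                    abut = integer(0), group = FALSE))
  prs <- combn(degree, 2L)
  for (k in seq_len(ncol(prs))) {
    rest <- setdiff(seq_len(degree), prs[, k])
    pats[[length(pats) + 1L]] <- list(pairs = list(prs[, k]),
                                      terminate = rest, abut = integer(0),
                                      group = FALSE)
    pats[[length(pats) + 1L]] <- list(pairs = list(prs[, k]),
                                      terminate = integer(0), abut = rest,
                                      group = FALSE)
  }
  pats[[length(pats) + 1L]] <- list(pairs = list(), terminate = integer(0),
                                    abut = integer(0), group = TRUE)
  pats
}

#' Interpretation table for junction elements
#'
#' The admissible local connection patterns of a degree-3 junction, each
#' given the same probability: all three branches terminating; one
#' pass-through pair with the third branch terminating at the junction; one
#' pass-through pair with the third branch abutting but unconnected; and a
#' true three-way junction joining all branches into one mitochondrion. The
#' packaged table is explicit and swappable, so the pattern count is a
#' configuration property rather than a constant.
#'
#' @param path Optional path to a JSON table; `NULL` loads the packaged
#'   default.
#' @return An object of class `interpretation_table`.
#' @export
interpretation_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "interpretation_table.json",
                        package = "mitomorph")
  }
  tab <- if (nzchar(path) && file.exists(path)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(raw$patterns, function(p) list(
      pairs = lapply(p$pairs, function(x) as.integer(unlist(x))),
      terminate = as.integer(unlist(p$terminate)),
      abut = as.integer(unlist(p$abut)),
      group = isTRUE(unlist(p$group))))
  } else {
    generate_junction_patterns(3L)
  }
  ## validate: each pattern covers slots 1..3 exactly once
  for (p in tab) {
    covered <- if (p$group) 1:3 else
      sort(c(unlist(p$pairs), p$terminate, p$abut))
    if (!identical(as.integer(covered), 1:3))
      stop_param("invalid interpretation table: a pattern does not cover ",
                 "each attachment slot exactly once")
  }
  structure(list(degree3 = tab, n_patterns = length(tab)),
            class = "interpretation_table")
}

#' @export
print.interpretation_table <- function(x, ...) {
  cat("interpretation_table:", x$n_patterns,
      "equally weighted patterns for degree-3 junctions\n")
  invisible(x)
}

#' Admissible local interpretations of one structural element
#'
#' Ends always terminate; tubule interiors always pass through; junctions
#' take the table's pattern list, each pattern with equal weight.
#'
#' @param element A structural element from a `mito_elements` object.
#' @param table An [interpretation_table()].
#' @return List of patterns.
#' @export
enumerate_local_interpretations <- function(element,
                                            table = interpretation_table()) {
  switch(element$kind,
    end = list(list(action = "terminate")),
    tubule = list(list(action = "pass_through")),
    junction = {
      if (nrow(element$slots) != 3L)
        stop_param("unsupported junction degree ", nrow(element$slots),
                   ": run split_four_way() first")
      table$degree3
    },
    stop_param("unknown element kind"))
}

## ---- cluster interpretation context --------------------------------------

interp_context <- function(clusters, ci, table = interpretation_table()) {
  cl <- clusters$clusters[[ci]]
  els <- clusters$elements
  kinds <- vapply(els[cl$ids], `[[`, "", "kind")
  tub_ids <- cl$ids[kinds == "tubule"]
  jun_ids <- cl$ids[kinds == "junction"]
  tindex <- setNames(seq_along(tub_ids), tub_ids)
  Tn <- length(tub_ids)
  tub_len <- vapply(els[tub_ids], `[[`, numeric(1), "len_px")
  ring <- vapply(els[tub_ids], function(e) isTRUE(e$closed), logical(1))
  ## fixed per-tubule extra length from plain end attachments
  base_extra <- numeric(Tn)
  for (i in seq_len(Tn)) {
    e <- els[[tub_ids[i]]]
    if (ring[i]) next
    for (s in 1:2) {
      a <- e$att[s]
      if (!is.na(a) && els[[a]]$kind == "end")
        base_extra[i] <- base_extra[i] + els[[a]]$cap_px + els[[a]]$step_px
    }
  }
  junctions <- lapply(els[jun_ids], function(j) {
    ns <- nrow(j$slots)
    slot_tub <- rep(NA_integer_, ns)
    slot_cap <- numeric(ns)
    for (s in seq_len(ns)) {
      tgt <- els[[j$slots$elt[s]]]
      if (tgt$kind == "tubule") {
        slot_tub[s] <- tindex[[as.character(j$slots$elt[s])]]
      } else {
        slot_cap[s] <- tgt$cap_px
      }
    }
    list(slot_tub = slot_tub, slot_cap = slot_cap,
         slot_elt = j$slots$elt, slot_elt_slot = j$slots$elt_slot,
         dcon = j$dcon, cross = j$cross, extent = j$extent)
  })
  list(cl = cl, tub_ids = tub_ids, jun_ids = jun_ids, Tn = Tn,
       tub_len = tub_len, ring = ring,
       base_extra = base_extra, junctions = junctions,
       patterns = table$degree3, n_patterns = length(table$degree3))
}

## resolve one choice vector into mitochondrion path lengths (px)
apply_choices <- function(ctx, choices) {
  Tn <- ctx$Tn
  parent <- seq_len(Tn)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  extra <- ctx$base_extra
  standalone <- numeric(0)
  for (k in seq_along(ctx$junctions)) {
    jn <- ctx$junctions[[k]]
    pat <- ctx$patterns[[choices[k]]]
    if (pat$group) {
      tubs <- jn$slot_tub[!is.na(jn$slot_tub)]
      add <- sum(jn$dcon) + jn$extent +
        sum(jn$slot_cap[is.na(jn$slot_tub)])
      if (length(tubs)) {
        for (t in tubs[-1L]) {
          ra <- find(tubs[1L]); rb <- find(t)
          if (ra != rb) parent[rb] <- ra
        }
        extra[tubs[1L]] <- extra[tubs[1L]] + add
      } else standalone <- c(standalone, add)
      next
    }
    for (pr in pat$pairs) {
      s1 <- pr[1L]; s2 <- pr[2L]
      t1 <- jn$slot_tub[s1]; t2 <- jn$slot_tub[s2]
      L <- jn$cross[s1, s2]
      if (!is.na(t1) && !is.na(t2)) {
        ra <- find(t1); rb <- find(t2)
        if (ra != rb) parent[rb] <- ra
        extra[t1] <- extra[t1] + L
      } else if (!is.na(t1)) {
        extra[t1] <- extra[t1] + L + jn$slot_cap[s2]
      } else if (!is.na(t2)) {
        extra[t2] <- extra[t2] + L + jn$slot_cap[s1]
      } else {
        standalone <- c(standalone, L + jn$slot_cap[s1] + jn$slot_cap[s2])
      }
    }
    for (s in c(pat$terminate, pat$abut)) {
      t <- jn$slot_tub[s]
      add <- jn$dcon[s] + jn$extent / 2
      if (!is.na(t)) extra[t] <- extra[t] + add
      else standalone <- c(standalone, add + jn$slot_cap[s])
    }
  }
  if (Tn) {
    roots <- vapply(seq_len(Tn), find, integer(1))
    tot <- ctx$tub_len + extra
    lens <- vapply(split(tot, roots), sum, numeric(1))
    groups <- split(ctx$tub_ids, roots)
  } else {
    lens <- numeric(0)
    groups <- list()
  }
  list(lengths_px = c(unname(lens), standalone),
       paths = c(unname(groups), rep(list(integer(0)),
                                     length(standalone))))
}

#' Sample admissible interpretations of a cluster
#'
#' Draws `n_samples` interpretations by choosing, independently and
#' uniformly, one admissible local pattern per junction; a cluster without
#' junctions has a single interpretation, returned once. Every combination
#' of local patterns in the packaged table resolves into a valid set of
#' mitochondrion paths (each tubule belongs to exactly one path), so no
#' rejection is needed.
#'
#' @param clusters A `mito_clusters` object.
#' @param cluster Index of the cluster to interpret.
#' @param table An [interpretation_table()].
#' @param n_samples Number of interpretations to draw.
#' @param seed Optional RNG seed for reproducibility.
#' @return A list of interpretations, each with `choices` (pattern index per
#'   junction), `lengths_px`, `lengths_um` and `paths` (tubule ids per
#'   mitochondrion).
#' @export
sample_interpretations <- function(clusters, cluster = 1L,
                                   table = interpretation_table(),
                                   n_samples = 1000L, seed = NULL) {
  if (n_samples < 1L) stop_param("n_samples must be >= 1")
  ctx <- interp_context(clusters, cluster, table)
  J <- length(ctx$junctions)
  px <- clusters$pixel_size
  if (J == 0L) {
    one <- apply_choices(ctx, integer(0))
    return(list(c(one, list(choices = integer(0),
                            lengths_um = one$lengths_px * px))))
  }
  choice_mat <- with_seed(seed, matrix(
    sample.int(ctx$n_patterns, n_samples * J, replace = TRUE), n_samples, J))
  lapply(seq_len(n_samples), function(i) {
    ch <- choice_mat[i, ]
    res <- apply_choices(ctx, ch)
    c(res, list(choices = ch, lengths_um = res$lengths_px * px))
  })
}

#' Lengths of the mitochondrion paths of one interpretation
#'
#' @param interp One interpretation from [sample_interpretations()].
#' @param pixel_size Micrometers per pixel.
#' @return Numeric vector of path lengths in micrometers.
#' @export
interpretation_lengths <- function(interp, pixel_size = 1 / 15) {
  interp$lengths_px * pixel_size
}

## ---- distributions --------------------------------------------------------

make_breaks <- function(max_um, bin_width) {
  seq(0, bin_width * max(1, ceiling(max_um / bin_width + 1e-9)),
      by = bin_width)
}

hist_mass <- function(lengths_um, breaks) {
  n <- length(breaks) - 1L
  if (!length(lengths_um)) return(rep(0, n))
  b <- findInterval(lengths_um, breaks, rightmost.closed = FALSE)
  b <- pmin(pmax(b, 1L), n)  # clamp overflow into the last bin
  tabulate(b, n) / length(lengths_um)
}

new_length_dist <- function(breaks, mass, sd, expected_count, pixel_size,
                            level = "cluster") {
  structure(list(breaks = breaks, mass = mass, sd = sd,
                 expected_count = expected_count, pixel_size = pixel_size,
                 level = level),
            class = "mito_length_dist")
}

#' Probability distribution of mitochondrial length for one cluster
#'
#' Each sampled interpretation contributes a normalized length histogram;
#' the cluster distribution is their per-bin mean, with the per-bin standard
#' deviation across interpretations as the confidence band and the mean
#' number of paths as the expected mitochondrion count.
#'
#' @param samples Interpretations from [sample_interpretations()] (or the
#'   exact enumeration of [brute_force_enumerate()]).
#' @param pixel_size Micrometers per pixel.
#' @param bin_width Histogram bin width in micrometers (default 0.5).
#' @param breaks Optional shared bin edges (micrometers); computed from the
#'   samples when missing.
#' @param weights Optional per-interpretation weights (default uniform).
#' @return A `mito_length_dist` object.
#' @export
cluster_distribution <- function(samples, pixel_size = 1 / 15,
                                 bin_width = 0.5, breaks = NULL,
                                 weights = NULL) {
  if (!length(samples)) stop_param("need at least one interpretation")
  lens <- lapply(samples, function(s)
    s$lengths_um %||% (s$lengths_px * pixel_size))
  if (is.null(breaks))
    breaks <- make_breaks(max(c(0, unlist(lens))), bin_width)
  H <- vapply(lens, hist_mass, numeric(length(breaks) - 1L), breaks = breaks)
  H <- matrix(H, nrow = length(breaks) - 1L)
  w <- weights %||% rep(1 / ncol(H), ncol(H))
  w <- w / sum(w)
  mass <- as.vector(H %*% w)
  sdv <- sqrt(pmax(0, as.vector((H - mass)^2 %*% w)))
  counts <- vapply(lens, length, integer(1))
  new_length_dist(breaks, mass, sdv, sum(counts * w), pixel_size, "cluster")
}

#' Exact interpretation distribution by exhaustive enumeration
#'
#' Enumerates every combination of local junction patterns with uniform
#' weights. Used as the oracle for the sampling path and, automatically,
#' whenever the interpretation tree is small.
#'
#' @inheritParams sample_interpretations
#' @inheritParams cluster_distribution
#' @param max_leaves Guard on the enumeration size.
#' @return A `mito_length_dist` object.
#' @export
brute_force_enumerate <- function(clusters, cluster = 1L,
                                  table = interpretation_table(),
                                  pixel_size = clusters$pixel_size,
                                  bin_width = 0.5, breaks = NULL,
                                  max_leaves = 1e6) {
  ctx <- interp_context(clusters, cluster, table)
  J <- length(ctx$junctions)
  n_leaves <- ctx$n_patterns^J
  if (n_leaves > max_leaves)
    stop_param("interpretation tree too large for exact enumeration (",
               n_leaves, " leaves)")
  if (J == 0L) {
    one <- apply_choices(ctx, integer(0))
    samples <- list(c(one, list(lengths_um = one$lengths_px * pixel_size)))
  } else {
    grid <- as.matrix(do.call(expand.grid,
                              rep(list(seq_len(ctx$n_patterns)), J)))
    samples <- lapply(seq_len(nrow(grid)), function(i) {
      res <- apply_choices(ctx, grid[i, ])
      c(res, list(lengths_um = res$lengths_px * pixel_size))
    })
  }
  cluster_distribution(samples, pixel_size, bin_width, breaks)
}

#' Combine cluster distributions into the image-level distribution
#'
#' Cluster length profiles are weighted by their expected mitochondrion
#' count, summed, and renormalized to unit mass; per-bin standard deviations
#' are combined as the count-weighted root-mean-square (clusters are
#' independent).
#'
#' @param cluster_dists List of `mito_length_dist` objects on shared bins.
#' @return A `mito_length_dist` with the total expected mitochondria count.
#' @export
image_distribution <- function(cluster_dists) {
  if (!length(cluster_dists)) stop_param("no cluster distributions supplied")
  breaks <- cluster_dists[[1L]]$breaks
  for (d in cluster_dists)
    if (!isTRUE(all.equal(d$breaks, breaks)))
      stop_param("cluster distributions must share bin edges")
  w <- vapply(cluster_dists, `[[`, numeric(1), "expected_count")
  M <- vapply(cluster_dists, `[[`, numeric(length(breaks) - 1L), "mass")
  S <- vapply(cluster_dists, `[[`, numeric(length(breaks) - 1L), "sd")
  M <- matrix(M, nrow = length(breaks) - 1L)
  S <- matrix(S, nrow = length(breaks) - 1L)
  tot <- sum(w)
  mass <- as.vector(M %*% w)
  if (sum(mass) > 0) mass <- mass / sum(mass)
  sdv <- sqrt(as.vector(S^2 %*% w^2)) / tot
  new_length_dist(breaks, mass, sdv, tot,
                  cluster_dists[[1L]]$pixel_size, "image")
}

#' @export
print.mito_length_dist <- function(x, ...) {
  cat(sprintf(
    "mito_length_dist (%s): %d bins of %.3g um, %.3g expected mitochondria\n",
    x$level, length(x$mass), diff(x$breaks[1:2]), x$expected_count))
  mu <- sum(bin_centers(x) * x$mass)
  cat(sprintf("  mean length %.3g um, mass sums to %.6g\n", mu, sum(x$mass)))
  invisible(x)
}

bin_centers <- function(d) (head(d$breaks, -1L) + tail(d$breaks, -1L)) / 2

#' @export
plot.mito_length_dist <- function(x, band = TRUE, col = "steelblue", ...) {
  ctr <- bin_centers(x)
  ylim <- c(0, max(x$mass + x$sd, 1e-3))
  plot(ctr, x$mass, type = "n", xlab = "mitochondrial length (um)",
       ylab = "probability", ylim = ylim, ...)
  if (band) {
    polygon(c(ctr, rev(ctr)),
            c(pmax(0, x$mass - x$sd), rev(x$mass + x$sd)),
            col = "grey85", border = NA)
  }
  lines(ctr, x$mass, col = col, lwd = 2)
  invisible(x)
}

## ---- deterministic per-cluster length variants ---------------------------

## slot-level link map: for tubule local index i, side s (1/2), either the
## plain end attached there or the (junction local index, slot row)
tubule_link_map <- function(ctx, els) {
  links <- vector("list", ctx$Tn)
  for (i in seq_len(ctx$Tn)) {
    gid <- ctx$tub_ids[i]
    e <- els[[gid]]
    links[[i]] <- vector("list", 2L)
    if (ctx$ring[i]) next
    for (s in 1:2) {
      a <- e$att[s]
      if (is.na(a)) next
      tgt <- els[[a]]
      if (tgt$kind == "end") {
        links[[i]][[s]] <- list(type = "end", add = tgt$cap_px + tgt$step_px)
      } else {
        k <- match(a, ctx$jun_ids)
        sl <- which(ctx$junctions[[k]]$slot_elt == gid &
                      ctx$junctions[[k]]$slot_elt_slot == s)[1L]
        links[[i]][[s]] <- list(type = "junction", j = k, slot = sl)
      }
    }
  }
  links
}

## terminal length contribution of stopping a path at tubule i, side s
side_terminal_px <- function(ctx, links, i, s) {
  lk <- links[[i]][[s]]
  if (is.null(lk)) return(0)
  if (lk$type == "end") return(lk$add)
  jn <- ctx$junctions[[lk$j]]
  jn$dcon[lk$slot] + jn$extent / 2
}

#' Branch-point and longest-path length readings of a cluster
#'
#' Two deterministic extremes bracketing the probabilistic estimate: the
#' branch-point variant treats every tubule as its own mitochondrion
#' (distance between connections); the longest-path variant greedily
#' extracts the longest admissible path, removes it, and repeats.
#'
#' @param clusters A `mito_clusters` object.
#' @param cluster Cluster index.
#' @param pixel_size Micrometers per pixel.
#' @return Numeric vector of lengths (micrometers).
#' @export
branchpoint_lengths <- function(clusters, cluster = 1L,
                                pixel_size = clusters$pixel_size) {
  ctx <- interp_context(clusters, cluster)
  if (!ctx$Tn) return(numeric(0))
  lens <- ctx$tub_len + ctx$base_extra
  ## add the junction-side terminal contribution of every junction slot
  for (jn in ctx$junctions) {
    for (s in seq_along(jn$slot_tub)) {
      t <- jn$slot_tub[s]
      if (!is.na(t)) lens[t] <- lens[t] + jn$dcon[s] + jn$extent / 2
    }
  }
  unname(lens) * pixel_size
}

#' @rdname branchpoint_lengths
#' @export
longest_path_lengths <- function(clusters, cluster = 1L,
                                 pixel_size = clusters$pixel_size) {
  ctx <- interp_context(clusters, cluster)
  if (!ctx$Tn) return(numeric(0))
  links <- tubule_link_map(ctx, clusters$elements)
  avail <- !ctx$ring
  out <- ctx$tub_len[ctx$ring] * pixel_size  # closed rings are own paths
  best <- NULL
  consider <- function(len, seq_ids) {
    key <- paste(ctx$tub_ids[seq_ids], collapse = ",")
    if (is.null(best) || len > best$len + 1e-9 ||
        (abs(len - best$len) <= 1e-9 && key < best$key)) {
      best <<- list(len = len, seq = seq_ids, key = key)
    }
  }
  ## DFS over simple tubule sequences; `len` includes everything up to and
  ## including tubule i, except the terminal contribution at i's exit side
  dfs <- function(i, enter_side, len, seq_ids, used) {
    exit <- other_slot(enter_side)
    lk <- links[[i]][[exit]]
    extended <- FALSE
    if (!is.null(lk) && lk$type == "junction") {
      jn <- ctx$junctions[[lk$j]]
      for (s2 in seq_along(jn$slot_tub)) {
        if (s2 == lk$slot) next
        t2 <- jn$slot_tub[s2]
        if (is.na(t2) || used[t2] || !avail[t2]) next
        side2 <- NA_integer_
        for (s in 1:2) {
          l2 <- links[[t2]][[s]]
          if (!is.null(l2) && l2$type == "junction" && l2$j == lk$j &&
              l2$slot == s2) { side2 <- s; break }
        }
        if (is.na(side2)) next
        extended <- TRUE
        dfs(t2, side2, len + jn$cross[lk$slot, s2] + ctx$tub_len[t2],
            c(seq_ids, t2), `[<-`(used, t2, TRUE))
      }
    }
    if (!extended)
      consider(len + side_terminal_px(ctx, links, i, exit), seq_ids)
  }
  while (any(avail)) {
    best <- NULL
    for (i in which(avail)) {
      for (s in 1:2) {
        used <- !avail
        used[i] <- TRUE
        dfs(i, s, ctx$tub_len[i] + side_terminal_px(ctx, links, i, s),
            i, used)
      }
    }
    out <- c(out, best$len * pixel_size)
    avail[best$seq] <- FALSE
  }
  unname(out)
}
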