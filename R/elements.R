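## Structural elements: typed, merged runs of skeleton pixels (end, tubule,
## junction) with slot-level adjacency. Tubules have two attachment slots
## (slot 1 = path start, slot 2 = path end); ends have one attachment;
## junctions have one slot per attached branch. All pixel coordinates are
## (row, col) matrices.

euclid <- function(a, b) sqrt(sum((a - b)^2))

path_length_px <- function(px) {
  if (nrow(px) < 2L) return(0)
  d <- diff(px)
  sum(sqrt(rowSums(d^2)))
}

new_end <- function(px, att = NA_integer_, cap_px = 0, step_px = 0) {
  list(kind = "end", px = px, att = att, cap_px = cap_px, step_px = step_px)
}

new_tubule <- function(px, att = c(NA_integer_, NA_integer_), closed = FALSE,
                       len_px = NULL) {
  len <- len_px %||% (path_length_px(px) +
    if (closed && nrow(px) > 2L) euclid(px[1L, ], px[nrow(px), ]) else 0)
  list(kind = "tubule", px = px, att = att, closed = closed, len_px = len)
}

new_junction <- function(px, slots) {
  list(kind = "junction", px = px, slots = slots,
       dcon = NULL, cross = NULL, cross_path = NULL, extent = 0)
}

## ---- small-graph shortest paths (junction geometry) ----------------------

## coords: n x 2; edges between Chebyshev-adjacent nodes, Euclidean weights.
## Returns list(dist, path) from node `from` to node `to`.
dijkstra_px <- function(coords, from, to) {
  n <- nrow(coords)
  dist <- rep(Inf, n); prev <- rep(NA_integer_, n)
  dist[from] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    if (u == to) break
    dd <- pmax(abs(coords[, 1L] - coords[u, 1L]),
               abs(coords[, 2L] - coords[u, 2L]))
    adj <- which(dd == 1L & !done)
    for (v in adj) {
      w <- dist[u] + euclid(coords[u, ], coords[v, ])
      if (w < dist[v]) { dist[v] <- w; prev[v] <- u }
    }
  }
  path <- integer(0)
  if (is.finite(dist[to])) {
    v <- to
    while (!is.na(v)) { path <- c(v, path); v <- prev[v] }
  }
  list(dist = dist[to], path = path)
}

## fill dcon / cross / extent / cross_path for one junction element
junction_geometry <- function(j, els) {
  ns <- nrow(j$slots)
  contacts <- matrix(0, ns, 2L)
  for (s in seq_len(ns)) {
    e <- els[[j$slots$elt[s]]]
    contacts[s, ] <- if (e$kind == "end") {
      e$px[1L, ]
    } else if (j$slots$elt_slot[s] == 1L) e$px[1L, ] else e$px[nrow(e$px), ]
  }
  jpx <- j$px
  nj <- nrow(jpx)
  j$dcon <- vapply(seq_len(ns), function(s) {
    min(sqrt((jpx[, 1L] - contacts[s, 1L])^2 +
             (jpx[, 2L] - contacts[s, 2L])^2))
  }, numeric(1))
  cross <- matrix(0, ns, ns)
  cross_path <- vector("list", ns * ns)
  if (ns >= 2L) {
    for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
      coords <- rbind(contacts[a, , drop = FALSE], jpx,
                      contacts[b, , drop = FALSE])
      res <- dijkstra_px(coords, 1L, nj + 2L)
      cross[a, b] <- cross[b, a] <- res$dist
      inner <- res$path[res$path > 1L & res$path < nj + 2L] - 1L
      cross_path[[(a - 1L) * ns + b]] <- jpx[inner, , drop = FALSE]
      cross_path[[(b - 1L) * ns + a]] <-
        jpx[rev(inner), , drop = FALSE]
    }
  }
  j$cross <- cross
  j$cross_path <- cross_path
  j$extent <- if (nj <= 1L) 0 else {
    mx <- 0
    for (a in seq_len(nj - 1L)) for (b in (a + 1L):nj) {
      mx <- max(mx, dijkstra_px(jpx, a, b)$dist)
    }
    mx
  }
  j
}

## ---- per-component assembly ----------------------------------------------

## order a set of pixels forming a path or ring; adj = list of integer
## vectors (indices into the set). Returns ordered indices; falls back to the
## BFS diameter path when the set branches (can happen after a junction is
## dissolved into tubule pixels).
order_path_idx <- function(adj) {
  n <- length(adj)
  if (n == 1L) return(1L)
  degs <- lengths(adj)
  if (any(degs > 2L)) return(bfs_diameter_path(adj))
  start <- which(degs <= 1L)
  ring <- length(start) == 0L
  start <- if (ring) 1L else min(start)
  ord <- integer(n); ord[1L] <- start
  prev <- 0L; cur <- start
  for (i in seq_len(n - 1L)) {
    nxt <- setdiff(adj[[cur]], prev)
    if (length(nxt) == 0L) { ord <- ord[seq_len(i)]; break }
    nxt <- min(nxt)
    ord[i + 1L] <- nxt
    prev <- cur; cur <- nxt
  }
  ord
}

bfs_diameter_path <- function(adj) {
  bfs <- function(src) {
    n <- length(adj)
    dist <- rep(NA_integer_, n); par <- rep(NA_integer_, n)
    dist[src] <- 0L; q <- src
    while (length(q)) {
      u <- q[1L]; q <- q[-1L]
      for (v in adj[[u]]) if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L; par[v] <- u; q <- c(q, v)
      }
    }
    list(dist = dist, par = par)
  }
  b1 <- bfs(1L)
  a <- which.max(b1$dist)
  b2 <- bfs(a)
  b <- which.max(b2$dist)
  path <- integer(0); v <- b
  while (!is.na(v)) { path <- c(v, path); v <- b2$par[v] }
  path
}

## label connected components within a subset of skeleton pixels;
## `members` are indices into the skeleton pixel list that `nbr` indexes
label_subset <- function(members, nbr) {
  lab <- rep(0L, length(members))
  inset <- logical(nrow(nbr))
  inset[members] <- TRUE
  lookup <- integer(nrow(nbr))
  lookup[members] <- seq_along(members)
  nxt <- 0L
  for (i in seq_along(members)) {
    if (lab[i] > 0L) next
    nxt <- nxt + 1L
    lab[i] <- nxt
    q <- members[i]
    while (length(q)) {
      u <- q[[1L]]; q <- q[-1L]
      nb <- nbr[u, ]
      nb <- nb[nb > 0L]
      nb <- nb[inset[nb]]
      for (v in nb) {
        li <- lookup[v]
        if (lab[li] == 0L) { lab[li] <- nxt; q <- c(q, v) }
      }
    }
  }
  lab
}

## canonical unbranched component: 1 tubule spanning every pixel + 2 ends on
## the terminal pixels (shared with the tubule), or a closed ring
build_unbranched <- function(gidx, coords, nbr, capv) {
  n <- length(gidx)
  adj <- lapply(seq_len(n), function(i) {
    nb <- nbr[gidx[i], ]; nb <- nb[nb > 0L]
    match(nb[nb %in% gidx], gidx)
  })
  degs <- lengths(adj)
  if (n >= 3L && all(degs == 2L)) {           # closed ring, no ends
    ord <- order_path_idx(adj)
    return(list(new_tubule(coords[gidx[ord], , drop = FALSE], closed = TRUE)))
  }
  ord <- order_path_idx(adj)
  px <- coords[gidx[ord], , drop = FALSE]
  tub <- new_tubule(px, att = c(2L, 3L))
  e1 <- new_end(px[1L, , drop = FALSE], att = 1L,
                cap_px = capv[gidx[ord[1L]]], step_px = 0)
  e2 <- new_end(px[nrow(px), , drop = FALSE], att = 1L,
                cap_px = capv[gidx[ord[length(ord)]]], step_px = 0)
  list(tub, e1, e2)
}

## general component containing junction pixels; iteratively dissolves
## junction elements with fewer than 3 attachments until the map is stable
build_branched <- function(gidx, coords, nbr, degv, capv) {
  kv <- ifelse(degv[gidx] <= 1L, 1L, ifelse(degv[gidx] == 2L, 2L, 3L))
  for (iter in seq_len(50L)) {
    if (!any(kv == 3L))
      return(build_unbranched(gidx, coords, nbr, capv))
    jmem <- gidx[kv == 3L]
    tmem <- gidx[kv == 2L]
    emem <- gidx[kv == 1L]
    jlab <- if (length(jmem)) label_subset(jmem, nbr) else integer(0)
    tlab <- if (length(tmem)) label_subset(tmem, nbr) else integer(0)
    nj <- if (length(jlab)) max(jlab) else 0L
    nt <- if (length(tlab)) max(tlab) else 0L
    ne <- length(emem)
    ## local element ids: junctions 1..nj, tubules nj+1..nj+nt, ends after
    owner <- integer(max(gidx))
    owner[jmem] <- jlab
    owner[tmem] <- nj + tlab
    if (ne) owner[emem] <- nj + nt + seq_len(ne)

    els <- vector("list", nj + nt + ne)
    for (k in seq_len(nj))
      els[[k]] <- new_junction(coords[jmem[jlab == k], , drop = FALSE],
                               slots = data.frame(elt = integer(0),
                                                  elt_slot = integer(0)))
    ## tubules: ordered paths + slot attachments
    for (k in seq_len(nt)) {
      tid <- nj + k
      mem <- tmem[tlab == k]
      adj <- lapply(seq_along(mem), function(i) {
        nb <- nbr[mem[i], ]; nb <- nb[nb > 0L]
        match(nb[nb %in% mem], mem)
      })
      ord <- order_path_idx(adj)
      mem <- mem[ord]
      px <- coords[mem, , drop = FALSE]
      tub <- new_tubule(px)
      ## externals of the first and last pixel
      ext_of <- function(g) {
        nb <- nbr[g, ]; nb <- nb[nb > 0L]
        nb <- nb[nb %in% gidx & !(nb %in% mem)]
        unique(owner[nb])
      }
      if (length(mem) == 1L) {
        ex <- sort(ext_of(mem[1L]))
        if (length(ex) == 1L) ex <- c(ex, ex)
        tub$att <- ex[1:2]
      } else {
        e1 <- ext_of(mem[1L]); e2 <- ext_of(mem[length(mem)])
        tub$att <- c(if (length(e1)) min(e1) else NA_integer_,
                     if (length(e2)) min(e2) else NA_integer_)
      }
      els[[tid]] <- tub
    }
    ## ends; an end pixel directly adjacent to a junction gets an explicit
    ## zero-length connector tubule so that every junction slot carries a
    ## tubule and the handshake lemma 2T = E + sum(junction degrees) holds
    for (k in seq_len(ne)) {
      eid <- nj + nt + k
      g <- emem[k]
      nb <- nbr[g, ]; nb <- nb[nb > 0L]; nb <- nb[nb %in% gidx]
      target <- if (length(nb)) owner[nb[1L]] else NA_integer_
      step <- if (length(nb)) euclid(coords[g, ], coords[nb[1L], ]) else 0
      els[[eid]] <- new_end(coords[g, , drop = FALSE], att = target,
                            cap_px = capv[g], step_px = step)
    }
    for (k in seq_len(ne)) {
      eid <- nj + nt + k
      a <- els[[eid]]$att
      if (!is.na(a) && a <= nj) {
        tid <- length(els) + 1L
        els[[tid]] <- new_tubule(els[[eid]]$px, att = c(eid, a), len_px = 0)
        els[[eid]]$att <- tid
        els[[eid]]$step_px <- 0
      }
    }
    ## junction slots from tubule attachments
    tub_ids_all <- which(vapply(els, function(e)
      !is.null(e) && e$kind == "tubule", logical(1)))
    for (tid in tub_ids_all) {
      for (s in 1:2) {
        a <- els[[tid]]$att[s]
        if (!is.na(a) && a <= nj)
          els[[a]]$slots <- rbind(els[[a]]$slots,
                                  data.frame(elt = tid, elt_slot = s))
      }
    }
    bad <- which(vapply(seq_len(nj), function(k) nrow(els[[k]]$slots) < 3L,
                        logical(1)))
    if (!length(bad)) {
      for (k in seq_len(nj)) els[[k]] <- junction_geometry(els[[k]], els)
      return(els)
    }
    ## dissolve under-connected junctions into tubule pixels and iterate
    kv[gidx %in% jmem[jlab %in% bad]] <- 2L
  }
  stop("element merge did not stabilise")  # nocov
}

#' Classify skeleton pixels and merge them into structural elements
#'
#' Each skeleton pixel is typed by its 8-connected neighbour count (1 = end,
#' 2 = tubule, >=3 = junction; isolated pixels become degenerate one-tubule
#' clusters) and adjacent pixels of the same type are merged iteratively into
#' elements; junction elements that end up with fewer than three attachments
#' are dissolved into tubule pixels and the map is rebuilt until stable.
#' Unbranched components are represented canonically as one tubule plus two
#' ends; junction-free cycles as a single closed tubule.
#'
#' @param skel A [skeletonize()] result.
#' @param mask Optional binary mask the skeleton came from (reserved for
#'   area book-keeping; element geometry is derived from the skeleton).
#' @return An object of class `mito_elements`: a list of elements plus the
#'   pixel size.
#' @export
classify_and_merge <- function(skel, mask = NULL) {
  if (!inherits(skel, "skeleton_graph")) skel <- skeletonize(skel)
  S <- skel$mask
  nr <- nrow(S)
  P <- which(S)
  out <- structure(list(elements = list(), pixel_size = skel$pixel_size,
                        dim = dim(S)), class = "mito_elements")
  if (!length(P)) return(out)
  coords <- cbind(row = ((P - 1L) %% nr) + 1L, col = ((P - 1L) %/% nr) + 1L)
  pid <- matrix(0L, nr, ncol(S)); pid[P] <- seq_along(P)
  nbr <- matrix(0L, length(P), 8L)
  for (k in seq_len(8L)) {
    rr <- coords[, 1L] + NB8[k, 1L]; cc <- coords[, 2L] + NB8[k, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(S)
    nbr[ok, k] <- pid[cbind(rr[ok], cc[ok])]
  }
  degv <- rowSums(nbr > 0L)
  ## ends contribute their own pixel length only (a single-pixel end adds
  ## nothing beyond the step to its neighbour); the rounded cap of the mask
  ## already compensates the medial-axis inset at tips
  capv <- rep(0, length(P))

  complab <- cpp_label8(S)[P]
  comps <- split(seq_along(P), complab)
  elements <- list()
  for (gidx in comps) {
    kinds <- degv[gidx]
    els <- if (any(kinds >= 3L)) {
      build_branched(gidx, coords, nbr, degv, capv)
    } else {
      build_unbranched(gidx, coords, nbr, capv)
    }
    ## re-id into the global list
    off <- length(elements)
    els <- lapply(els, function(e) {
      if (e$kind == "junction") {
        e$slots$elt <- e$slots$elt + off
      } else if (e$kind == "tubule") {
        e$att <- e$att + off
      } else e$att <- e$att + off
      e
    })
    elements <- c(elements, els)
  }
  for (i in seq_along(elements)) elements[[i]]$id <- i
  out$elements <- elements
  out
}

junction_degree <- function(e) nrow(e$slots)

#' @export
print.mito_elements <- function(x, ...) {
  kinds <- vapply(x$elements, `[[`, "", "kind")
  cat("mito_elements:", sum(kinds == "end"), "ends,",
      sum(kinds == "tubule"), "tubules,",
      sum(kinds == "junction"), "junctions\n")
  invisible(x)
}
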