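kinds_of <- function(cl) table(vapply(cl$elements, `[[`, "", "kind"))

test_that("pixel classification merges into the expected elements", {
  line <- clusters_of(draw_line(blank(), 50, 10, 50, 39))
  expect_equal(length(line$clusters), 1L)
  expect_equal(line$clusters[[1]][c("E", "T", "J")],
               list(E = 2L, T = 1L, J = 0L))

  ## degree-0 isolated pixel: degenerate 1 tubule + 2 ends cluster
  single <- clusters_of(`[<-`(blank(), cbind(5, 5), TRUE))
  expect_equal(single$clusters[[1]]$n_elements, 3L)
  expect_equal(single$clusters[[1]]$total_length_px, 0)

  y <- clusters_of(y_mask())
  expect_equal(length(y$clusters), 1L)
  expect_equal(y$clusters[[1]][c("E", "T", "J")],
               list(E = 3L, T = 3L, J = 1L))
  expect_equal(y$clusters[[1]]$n_elements, 7L)

  two <- clusters_of(draw_line(draw_line(blank(), 20, 10, 20, 40),
                               60, 10, 60, 40))
  expect_equal(length(two$clusters), 2L)
  for (cl in two$clusters) expect_equal(cl$n_elements, 3L)

  empty <- extract_clusters(split_four_way(classify_and_merge(
    skeletonize(blank(10, 10)))))
  expect_equal(length(empty$clusters), 0L)
})

test_that("4-way junctions are disconnected into crossing tubules", {
  el <- classify_and_merge(skeletonize(binary_image(plus_mask(), 1 / 15)))
  degs <- vapply(el$elements, function(e)
    if (e$kind == "junction") nrow(e$slots) else NA_integer_, integer(1))
  expect_equal(max(degs, na.rm = TRUE), 4L)
  ## before splitting, a degree-4 junction is not interpretable
  j <- el$elements[[which(degs == 4L)[1]]]
  expect_error(enumerate_local_interpretations(j), "split_four_way")

  cl <- extract_clusters(split_four_way(el))
  expect_equal(length(cl$clusters), 2L)
  k <- kinds_of(cl)
  expect_equal(as.integer(k[c("end", "tubule")]), c(4L, 2L))
  expect_false("junction" %in% names(k))

  ## degree-3 junctions pass through unchanged
  y <- clusters_of(y_mask())
  expect_equal(y$clusters[[1]]$J, 1L)
})

test_that("branch pairing maximizes collinearity (brute-force oracle)", {
  ## X with arms at 10/190 and 80/260 degrees
  ctr <- c(100, 100)
  ang <- c(10, 80, 190, 260) * pi / 180
  m <- blank(200, 200)
  for (a in ang)
    m <- draw_line(m, ctr[1], ctr[2],
                   round(ctr[1] + 60 * sin(a)), round(ctr[2] + 60 * cos(a)))
  cl <- clusters_of(m)
  expect_equal(length(cl$clusters), 2L)
  ## oracle: the 3 pairings of 4 branches, minimal summed angular deviation
  dirs <- cbind(sin(ang), cos(ang))
  pairings <- list(rbind(c(1, 2), c(3, 4)), rbind(c(1, 3), c(2, 4)),
                   rbind(c(1, 4), c(2, 3)))
  cost <- vapply(pairings, function(p) {
    sum(apply(p, 1, function(ij)
      acos(pmin(1, pmax(-1, -sum(dirs[ij[1], ] * dirs[ij[2], ]))))))
  }, numeric(1))
  expect_equal(which.min(cost), 2L)  # (10,190) with (80,260)
  ## each resulting tubule must span opposite arms: its pixel extremes lie
  ## on the 10/190 axis or the 80/260 axis
  for (cc in cl$clusters) {
    tub <- cl$elements[[cc$ids[vapply(cl$elements[cc$ids], `[[`, "",
                                      "kind") == "tubule"]]]
    pxs <- tub$px[c(1, nrow(tub$px)), ]
    v <- pxs[1, ] - pxs[2, ]
    a <- atan2(v[1], v[2]) %% pi
    expect_true(min(abs(a - c(10, 80) * pi / 180)) < 0.1)
  }
})

test_that("dense clusters are excluded, sparse ones kept", {
  solid <- blank(100, 100)
  solid[3:98, 3:98] <- TRUE
  cl <- extract_clusters(split_four_way(classify_and_merge(
    skeletonize(solid))))
  f <- filter_dense_clusters(cl, solid)
  expect_equal(length(f$excluded$clusters), length(cl$clusters))
  expect_equal(f$excluded_fraction, 100)

  thin <- clusters_of(draw_line(blank(), 50, 10, 50, 90))
  f2 <- filter_dense_clusters(thin, draw_line(blank(), 50, 10, 50, 90))
  expect_equal(length(f2$kept$clusters), 1L)
  expect_equal(f2$excluded_fraction, 0)

  f3 <- filter_dense_clusters(clusters_of(blank()), blank())
  expect_equal(f3$excluded_fraction, 0)
  expect_equal(length(f3$kept$clusters), 0L)
})

test_that("connectivity metrics match hand-computed cluster anatomy", {
  iso <- connectivity_metrics(clusters_of(draw_line(blank(), 50, 10, 50, 60)))
  expect_equal(iso$E_C, 3)
  expect_equal(iso$J_over_E, 0)

  y <- connectivity_metrics(clusters_of(y_mask()))
  expect_equal(y$E_C, 7)
  expect_equal(y$J_over_E, 1 / 3)

  h <- connectivity_metrics(clusters_of(h_mask()))
  expect_equal(h$E_C, 11)
  expect_equal(h$J_over_E, 0.5)
  expect_equal(h$per_cluster[c("E", "T", "J")],
               data.frame(E = 4L, T = 5L, J = 2L))

  expect_equal(y$pct_ends + y$pct_tubules + y$pct_junctions, 100)

  ## pure ring: no ends, J/E undefined
  expect_warning(r <- connectivity_metrics(clusters_of(circle_mask())),
                 "undefined")
  expect_true(is.na(r$J_over_E))
  expect_equal(r$n_rings, 1L)
})

test_that("donuts require a doubly-attached tubule leading to an end", {
  expect_equal(sum(detect_donuts(clusters_of(lollipop_mask()))), 1L)
  expect_equal(sum(detect_donuts(clusters_of(
    draw_line(blank(), 50, 10, 50, 90)))), 0L)
  ## theta: both junction third-branches lead to junctions, not ends
  expect_equal(sum(detect_donuts(clusters_of(theta_mask()))), 0L)
})

test_that("blob and short-isolated classification uses the 1 and 2 um cuts", {
  m <- blank(200, 200)
  m <- draw_line(m, 20, 20, 20, 27)      # ~0.5 um
  m <- draw_line(m, 60, 20, 60, 42)      # ~1.5 um
  m <- draw_line(m, 100, 20, 100, 80)    # 4 um
  cl <- clusters_of(m)
  b <- detect_blobs(cl)
  expect_equal(b$blob_count, 1L)
  expect_equal(b$isolated_1_2um_count, 1L)
  yb <- detect_blobs(clusters_of(y_mask()))
  expect_equal(yb$blob_count + yb$isolated_1_2um_count, 0L)
})

test_that("handshake lemma 2T = E + 3J holds on every acyclic cluster", {
  for (seed in c(9, 101)) {
    g <- generate_image(synthetic_spec(150, "D3", seed = seed))
    net <- suppressWarnings(mito_network(segment_synthetic(g$image, 0.5)))
    cls <- net$clusters
    for (cl in cls$clusters) {
      edges <- new.env(parent = emptyenv())
      multi <- FALSE
      for (e in cls$elements[cl$ids]) {
        if (e$kind != "tubule") next
        for (a in e$att) if (!is.na(a)) {
          k <- paste(sort(c(e$id, a)), collapse = "-")
          if (exists(k, envir = edges, inherits = FALSE)) multi <- TRUE
          assign(k, TRUE, envir = edges)
        }
      }
      acyclic <- !multi && !cl$is_ring &&
        length(ls(edges)) == cl$n_elements - 1L
      if (acyclic)
        expect_equal(2L * cl$T, cl$E + 3L * cl$J)
    }
  }
})
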