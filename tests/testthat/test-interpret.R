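test_that("interpretation table: generated, packaged and validated", {
  tab <- interpretation_table()
  gen <- mitomorph:::generate_junction_patterns(3L)
  expect_equal(tab$n_patterns, length(gen))
  ## every pattern covers each slot exactly once
  for (p in tab$degree3) {
    covered <- if (p$group) 1:3 else sort(c(unlist(p$pairs), p$terminate,
                                            p$abut))
    expect_equal(as.integer(covered), 1:3)
  }
  ## ends and tubule interiors admit a single pattern
  cl <- clusters_of(draw_line(blank(), 50, 10, 50, 60))
  kinds <- vapply(cl$elements, `[[`, "", "kind")
  expect_length(enumerate_local_interpretations(
    cl$elements[[which(kinds == "end")[1]]], tab), 1L)
  expect_length(enumerate_local_interpretations(
    cl$elements[[which(kinds == "tubule")[1]]], tab), 1L)
  y <- clusters_of(y_mask())
  jid <- which(vapply(y$elements, `[[`, "", "kind") == "junction")[1]
  expect_length(enumerate_local_interpretations(y$elements[[jid]], tab),
                tab$n_patterns)
})

test_that("junction-free clusters have one deterministic interpretation", {
  cl <- clusters_of(draw_line(blank(), 50, 10, 50, 55))  # 45 steps = 3 um
  s <- sample_interpretations(cl, 1, n_samples = 50, seed = 1)
  expect_length(s, 1L)
  expect_equal(s[[1]]$lengths_um, 3, tolerance = 1e-9)
  d <- cluster_distribution(s, 1 / 15)
  expect_true(all(d$sd == 0))
  expect_equal(d$expected_count, 1)
  expect_equal(sum(d$mass), 1)
  expect_equal(interpretation_lengths(s[[1]], 1 / 15), 3, tolerance = 1e-9)
})

test_that("junction patterns are sampled uniformly and reproducibly", {
  cl <- clusters_of(y_mask())
  n <- 2000L
  s <- sample_interpretations(cl, 1, n_samples = n, seed = 42)
  ch <- vapply(s, function(x) x$choices[1], numeric(1))
  tab <- interpretation_table()
  p0 <- 1 / tab$n_patterns
  freq <- tabulate(ch, tab$n_patterns) / n
  se <- sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(freq - p0) < 3 * se + 1e-12))

  s2 <- sample_interpretations(cl, 1, n_samples = 20, seed = 7)
  s3 <- sample_interpretations(cl, 1, n_samples = 20, seed = 7)
  expect_identical(lapply(s2, `[[`, "choices"), lapply(s3, `[[`, "choices"))
})

test_that("every tubule belongs to exactly one path; length conserved", {
  cl <- clusters_of(h_mask())
  tubs <- which(vapply(cl$elements, `[[`, "", "kind") == "tubule")
  s <- sample_interpretations(cl, 1, n_samples = 200, seed = 3)
  for (it in s[seq(1, 200, by = 20)]) {
    used <- unlist(it$paths)
    expect_setequal(used[used > 0], tubs)
    expect_false(any(duplicated(used)))
  }
  ## path through a junction is at least the sum of its member tubules
  lens <- vapply(cl$elements[tubs], `[[`, numeric(1), "len_px")
  for (it in s[1:20]) {
    for (k in seq_along(it$paths)) {
      member <- it$paths[[k]]
      if (length(member))
        expect_gte(it$lengths_px[k] + 1e-9, sum(lens[match(member, tubs)]))
    }
  }
})

test_that("cluster and image distributions average as hand-computed", {
  mk <- function(lens) list(lengths_um = lens, lengths_px = lens * 15)
  d <- cluster_distribution(list(mk(c(3, 3)), mk(6)), 1 / 15,
                            breaks = seq(0, 8, by = 0.5))
  i3 <- findInterval(3, seq(0, 8, by = 0.5))
  i6 <- findInterval(6, seq(0, 8, by = 0.5))
  expect_equal(d$mass[i3], 0.5)   # mean of normalized histograms
  expect_equal(d$mass[i6], 0.5)
  expect_equal(d$expected_count, 1.5)
  expect_equal(d$sd[i3], 0.5)

  ## image level: cluster A (2 mitochondria at 3 um) + B (1 at 6 um)
  brA <- seq(0, 8, by = 0.5)
  A <- mitomorph:::new_length_dist(brA, replace(rep(0, 16), i3, 1),
                                   rep(0, 16), 2, 1 / 15)
  B <- mitomorph:::new_length_dist(brA, replace(rep(0, 16), i6, 1),
                                   rep(0, 16), 1, 1 / 15)
  img <- image_distribution(list(A, B))
  expect_equal(img$mass[i3], 2 / 3)
  expect_equal(img$mass[i6], 1 / 3)
  expect_equal(img$expected_count, 3)
  expect_identical(image_distribution(list(A))$mass, A$mass)
  expect_error(image_distribution(list()), "no cluster")
  ## mismatched bins refused
  C <- mitomorph:::new_length_dist(seq(0, 4, by = 0.5), rep(1 / 8, 8),
                                   rep(0, 8), 1, 1 / 15)
  expect_error(image_distribution(list(A, C)), "share")
  expect_error(emd(A, C), "bin edges")
})

test_that("sampling converges to exhaustive enumeration", {
  g <- generate_image(synthetic_spec(120, "D3", seed = 31))
  net <- suppressWarnings(mito_network(segment_synthetic(g$image, 0.5)))
  cls <- net$clusters
  J <- vapply(cls$clusters, `[[`, numeric(1), "J")
  pick1 <- which(J == 1)[1]
  pick2 <- which(J >= 2 & J <= 3)[1]
  expect_false(is.na(pick1) || is.na(pick2))

  bf <- brute_force_enumerate(cls, pick1)
  s <- sample_interpretations(cls, pick1, n_samples = 2000, seed = 5)
  sd1 <- cluster_distribution(s, cls$pixel_size, breaks = bf$breaks)
  expect_lt(0.5 * sum(abs(sd1$mass - bf$mass)), 3 / sqrt(2000))

  bf2 <- brute_force_enumerate(cls, pick2)
  s2 <- sample_interpretations(cls, pick2, n_samples = 2000, seed = 6)
  sd2 <- cluster_distribution(s2, cls$pixel_size, breaks = bf2$breaks)
  expect_lt(abs(sd2$expected_count - bf2$expected_count) /
              bf2$expected_count, 0.05)

  ## junction-free: enumeration and sampling coincide exactly
  iso <- which(J == 0)[1]
  bf0 <- brute_force_enumerate(cls, iso)
  s0 <- cluster_distribution(sample_interpretations(cls, iso, n_samples = 5),
                             cls$pixel_size, breaks = bf0$breaks)
  expect_equal(s0$mass, bf0$mass)
})

test_that("branch-point and longest-path variants bracket the estimate", {
  y <- clusters_of(y_mask())
  bp <- sort(branchpoint_lengths(y, 1, pixel_size = 1))
  lp <- sort(longest_path_lengths(y, 1, pixel_size = 1))
  expect_length(bp, 3L)
  expect_length(lp, 2L)
  ## the two longest arms concatenate into the longest path
  expect_gt(max(lp), max(bp))
  expect_lt(length(lp), length(bp))
  ## straight line: both variants agree
  line <- clusters_of(draw_line(blank(), 50, 10, 50, 55))
  expect_equal(branchpoint_lengths(line, 1), longest_path_lengths(line, 1))

  ## H: fewer, longer entries under longest-path (brute-force graph check)
  h <- clusters_of(h_mask())
  bh <- branchpoint_lengths(h, 1)
  lh <- longest_path_lengths(h, 1)
  expect_lt(length(lh), length(bh))
  expect_gt(max(lh), max(bh))
  expect_equal(sum(order(-bh)[1:2] > 0), 2)  # sanity on structure

  ## ordering: branchpoint mean <= probabilistic mean <= longest-path mean
  g <- generate_image(synthetic_spec(120, "D3", seed = 31))
  net <- suppressWarnings(mito_network(segment_synthetic(g$image, 0.5)))
  cls <- net$clusters
  ## exact expected mean length = E[total] / E[paths] over all
  ## interpretations; the upper bound holds up to junction-interior
  ## bookkeeping (group patterns count three contact steps, a simple path
  ## counts two), which is below 1% of a path length
  tested <- 0L
  for (i in seq_along(cls$clusters)) {
    J <- cls$clusters[[i]]$J
    if (J > 3 || J < 1) next
    ctx <- mitomorph:::interp_context(cls, i)
    grid <- as.matrix(do.call(expand.grid,
                              rep(list(seq_len(ctx$n_patterns)), J)))
    tot <- n <- numeric(nrow(grid))
    for (k in seq_len(nrow(grid))) {
      r <- mitomorph:::apply_choices(ctx, grid[k, ])
      tot[k] <- sum(r$lengths_px)
      n[k] <- length(r$lengths_px)
    }
    pm <- mean(tot) / mean(n) * cls$pixel_size
    lp <- mean(longest_path_lengths(cls, i))
    expect_lte(mean(branchpoint_lengths(cls, i)), pm + 1e-9)
    expect_lte(pm, lp * 1.01 + 1e-9)
    tested <- tested + 1L
    if (tested >= 10L) break
  }
  expect_gte(tested, 5L)
})

test_that("lengths of a known input distribution are recovered", {
  covers <- means <- counts <- numeric(0)
  for (s in 1:2) {
    g <- generate_image(synthetic_spec(100, "D1", seed = 100 + s))
    net <- suppressWarnings(mito_network(segment_synthetic(g$image, 0.5)))
    ld <- length_distribution(net, seed = 1)
    ctr <- (head(ld$breaks, -1) + tail(ld$breaks, -1)) / 2
    means <- c(means, sum(ctr * ld$mass))
    counts <- c(counts, ld$expected_count)
    inp <- hist(g$truth$lengths_um, breaks = ld$breaks, plot = FALSE)$counts
    inp <- inp / sum(inp)
    ## band: +-1 SD with one-mitochondrion quantization floor
    covers <- c(covers, mean(abs(inp - ld$mass) <= ld$sd + 0.01))
  }
  expect_true(all(abs(means - 3) < 0.3))
  expect_true(all(abs(counts - 100) / 100 < 0.15))
  expect_true(all(covers >= 0.6))
})
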