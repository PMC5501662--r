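test_that("length models: means, modes and truncation", {
  sp1 <- synthetic_spec(10, "D1", seed = 1)
  x1 <- mitomorph:::with_seed(1, sample_length(sp1, 1e4))
  expect_lt(abs(mean(x1) - 3), 0.1)
  expect_true(all(x1 >= 1 & x1 <= 10))

  sp2 <- synthetic_spec(10, "D2", seed = 1)
  x2 <- mitomorph:::with_seed(2, sample_length(sp2, 1e4))
  h <- hist(x2, breaks = seq(1, 10, by = 0.5), plot = FALSE)
  dens <- h$counts
  ## bimodal with modes near 2.5 and 5 um
  lo <- which.max(dens[h$mids < 3.5])
  hi <- which.max(dens * (h$mids > 3.5))
  expect_lt(abs(h$mids[lo] - 2.5), 0.5)
  expect_lt(abs(h$mids[hi] - 5), 0.5)
  valley <- min(dens[h$mids > 3 & h$mids < 4.5])
  expect_lt(valley, 0.5 * min(dens[lo], dens[hi]))

  x3 <- mitomorph:::with_seed(3, sample_length(synthetic_spec(10, "D3"), 1e4))
  expect_true(all(x3 >= 1 & x3 <= 10))
  expect_lt(abs(x3[which.max(tabulate(cut(x3, 0:10)))] - 2), 2)
})

test_that("generation is seed-deterministic and conserves ground truth", {
  sp <- synthetic_spec(25, "D3", seed = 99)
  a <- generate_image(sp)
  b <- generate_image(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$paths, b$truth$paths)

  ## recorded lengths are the exact chain lengths, within one step of the
  ## drawn targets, and their total is conserved exactly
  chain <- vapply(a$truth$paths, function(p) {
    d <- diff(p); sum(sqrt(rowSums(d^2)))
  }, numeric(1))
  expect_equal(chain / 15, a$truth$lengths_um, tolerance = 1e-12)
  expect_equal(a$truth$total_length_um, sum(a$truth$lengths_um))
  expect_true(all(abs(a$truth$lengths_um - a$truth$target_lengths_um)
                  <= sqrt(2) / 15 + 1e-9))
})

test_that("no-overlap placement yields one component per mitochondrion", {
  g <- generate_image(synthetic_spec(10, "D1", allow_overlap = FALSE,
                                     seed = 5))
  mask <- segment_synthetic(g$image, 0.5)
  expect_equal(max(mitomorph:::cpp_label8(mask$mask)), 10L)
  expect_error(generate_image(synthetic_spec(5000, "D1",
                                             allow_overlap = FALSE,
                                             seed = 1), max_retries = 2L),
               "without overlap")
})

test_that("skeleton accuracy: identity, tolerance band, empty skeleton", {
  g <- generate_image(synthetic_spec(5, "D1", allow_overlap = FALSE,
                                     seed = 8))
  gt_mask <- mitomorph:::ground_truth_mask(g$truth)
  acc <- skeleton_accuracy(g$truth, gt_mask)
  expect_equal(acc$position_match, 1)
  expect_equal(acc$length_ratio, 1, tolerance = 1e-9)
  expect_true(acc$condition1_met)
  expect_error(skeleton_accuracy(g$truth, blank(500, 500)), "empty skeleton")
})

test_that("density sweep: monotone area, cell-range densities, table shape", {
  sw <- density_sweep(synthetic_spec(10, "D3"), c(100, 400, 900),
                      replicates = 2, seed = 3)
  expect_equal(nrow(sw), 3L)
  expect_true(all(diff(sw$area_fraction) > 0))
  ## 100 mitochondria sit in the low-density (cell periphery) range
  expect_lt(sw$area_fraction[1], 0.15)
  expect_gt(sw$area_fraction[1], 0.04)
  expect_error(density_sweep(synthetic_spec(10, "D3"), c(400, 100)),
               "sorted")
  one <- density_sweep(synthetic_spec(10, "D3"), 50, replicates = 1, seed = 1)
  expect_equal(nrow(one), 1L)
  imgs <- attr(sw, "images")
  expect_equal(nrow(imgs), 6L)
})
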