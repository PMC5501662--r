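test_that("emd closed forms and normalization", {
  br <- seq(0, 10, by = 0.5)
  at <- function(x) {
    m <- rep(0, length(br) - 1L)
    m[findInterval(x, br)] <- 1
    mitomorph:::new_length_dist(br, m, rep(0, length(m)), 1, 1 / 15)
  }
  expect_equal(emd(at(2), at(2)), 0)
  expect_equal(emd(at(2.2), at(5.2)), 3)     # unit mass moved 3 um
  expect_error(emd(rep(0.1, 10), rep(0.1, 10)), "bin edges missing")
  expect_warning(v <- emd(at(2)$mass * 2, at(5.2)$mass * 3, breaks = br),
                 "unnormalized")
  expect_equal(v, 3)
})

test_that("emd is a metric and matches the transport oracle", {
  br <- seq(0, 5, by = 0.5)
  ds <- lapply(1:6, function(s) rand_dist(br, s))
  for (a in 1:6) {
    expect_equal(emd(ds[[a]], ds[[a]]), 0)
    for (b in 1:6) {
      ab <- emd(ds[[a]], ds[[b]])
      expect_gte(ab, 0)
      expect_equal(ab, emd(ds[[b]], ds[[a]]))
      expect_equal(ab, transport_emd_oracle(ds[[a]]$mass, ds[[b]]$mass, br),
                   tolerance = 1e-10)
      for (cc in 1:6)
        expect_lte(ab, emd(ds[[a]], ds[[cc]]) + emd(ds[[cc]], ds[[b]]) + 1e-12)
    }
  }
})

test_that("emd is invariant under joint bin refinement", {
  br <- seq(0, 5, by = 0.5)
  d1 <- rand_dist(br, 11); d2 <- rand_dist(br, 12)
  ## refinement that preserves the underlying measure (bin mass sits at the
  ## bin onset under the CDF convention): mass goes to the first half-bin
  refine <- function(d) {
    br2 <- seq(0, 5, by = 0.25)
    m <- as.vector(rbind(d$mass, 0))
    mitomorph:::new_length_dist(br2, m, rep(0, length(m)), 10, 1 / 15)
  }
  expect_equal(emd(refine(d1), refine(d2)), emd(d1, d2), tolerance = 1e-9)
})

test_that("condition protocol: within vs between replicate comparisons", {
  br <- seq(0, 5, by = 0.5)
  base <- rand_dist(br, 21)
  shift2 <- function(d) {
    m <- c(0, 0, head(d$mass, -2))
    mitomorph:::new_length_dist(d$breaks, m / sum(m), d$sd, 10, 1 / 15)
  }
  ctrl <- list(base, rand_dist(br, 22), rand_dist(br, 23))
  trt <- lapply(ctrl, shift2)

  same <- condition_emd_protocol(list(C = list(base, base, base),
                                      T = list(base, base, base)))
  expect_equal(nrow(same), 12L)
  expect_true(all(same$value == 0))

  rep_ <- condition_emd_protocol(list(C = ctrl, T = trt))
  expect_equal(sum(rep_$comparison == "within"), 6L)
  expect_equal(sum(rep_$comparison == "between"), 6L)
  expect_gt(mean(rep_$value[rep_$comparison == "between"]),
            mean(rep_$value[rep_$comparison == "within"]))

  perm <- condition_emd_protocol(list(C = ctrl[c(2, 3, 1)], T = trt))
  expect_equal(sort(perm$value), sort(rep_$value))

  expect_error(condition_emd_protocol(list(C = ctrl)), "two conditions")
})

test_that("pooling clusters concatenates analysis units", {
  g1 <- generate_image(synthetic_spec(8, "D1", allow_overlap = FALSE,
                                      seed = 2))
  net <- mito_network(segment_synthetic(g1$image, 0.5))
  one <- pool_clusters(list(net$clusters))
  expect_identical(one, net$clusters)

  k3 <- pool_clusters(list(net$clusters, net$clusters, net$clusters))
  expect_equal(length(k3$clusters), 3L * length(net$clusters$clusters))
  d1 <- length_distribution(net$clusters, seed = 1)
  d3 <- length_distribution(k3, seed = 1)
  expect_equal(d3$expected_count, 3 * d1$expected_count)
  expect_equal(d3$mass, d1$mass, tolerance = 1e-9)
  expect_equal(connectivity_metrics(k3)$E_C, connectivity_metrics(net$clusters)$E_C)

  ## short-only + long-only sections pool into a bimodal mixture
  short <- clusters_of(draw_line(blank(200, 200), 20, 20, 20, 40))   # 1.3 um
  long <- clusters_of(draw_line(blank(200, 200), 100, 20, 100, 140)) # 8 um
  pooled <- length_distribution(pool_clusters(list(short, long)),
                                bin_width = 0.5)
  nz <- which(pooled$mass > 0)
  expect_equal(length(nz), 2L)
  expect_gt(diff(range(pooled$breaks[nz])), 5)
})

test_that("two-channel metric ratios", {
  m <- connectivity_metrics(clusters_of(h_mask()))
  same <- channel_metric_ratio(m, m)
  expect_equal(same$E_C_ratio, 1)
  expect_equal(same$J_over_E_ratio, 1)

  m2 <- m; m2$E_C <- 3; m2$J_over_E <- 0.25
  expect_equal(channel_metric_ratio(m, m2)$E_C_ratio, 11 / 3)
  m3 <- m; m3$J_over_E <- 0
  expect_warning(r <- channel_metric_ratio(m, m3), "zero or undefined")
  expect_true(is.na(r$J_over_E_ratio))
})

test_that("per-cell phenotype scatter normalizes to the control cloud", {
  pc <- data.frame(
    cell = 1:6,
    condition = c(rep("control", 4), "treated", "treated"),
    j_over_e = c(0.2, 0.25, 0.15, 0.2, 0.4, 0.2),
    mass_1um = c(0.2, 0.25, 0.15, 0.2, 0.2, 0))
  expect_warning(sc <- cell_phenotype_scatter(pc, "control"), "zero 1-um")
  ctrl <- sc[sc$condition == "control", ]
  expect_equal(mean(ctrl$connectivity), 1)
  expect_equal(mean(ctrl$length), 1)
  expect_equal(sc$connectivity[5], 0.4 / 0.2)
  expect_true(abs(sc$length[5] - 1) < 0.35)
  expect_true(is.na(sc$length[6]) && sc$flagged[6])
  expect_error(cell_phenotype_scatter(pc, "missing"), "no control")
})
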