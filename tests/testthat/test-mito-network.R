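test_that("the fitted network object carries the full pipeline", {
  g <- generate_image(synthetic_spec(12, "D1", allow_overlap = FALSE,
                                     seed = 6))
  net <- mito_network(g$image, threshold = 0.5)
  expect_s3_class(net, "mito_network")
  expect_equal(length(net$clusters$clusters), 12L)
  expect_equal(net$metrics$E_C, 3)
  cf <- coef(net)
  expect_true(all(c("E_C", "J_over_E", "total_length_um") %in% names(cf)))
  expect_output(print(net), "clusters kept")
  expect_output(summary(net), "area fraction")
  expect_error(residuals(net), "not defined")

  ## grayscale confocal path dispatches too
  net2 <- mito_network(g$image, params = seg_params(global_threshold = 0.8))
  expect_s3_class(net2, "mito_network")

  ## rerun with the same seed gives identical distributions
  d1 <- length_distribution(net, seed = 11)
  d2 <- length_distribution(net, seed = 11)
  expect_identical(d1$mass, d2$mass)
  expect_output(print(d1), "expected mitochondria")
})

test_that("simulate() closes the loop from fit to new synthetic images", {
  g <- generate_image(synthetic_spec(10, "D1", allow_overlap = FALSE,
                                     seed = 9))
  net <- mito_network(g$image, threshold = 0.5)
  sims <- simulate(net, nsim = 2, seed = 4, n_mitochondria = 5)
  expect_length(sims, 2L)
  expect_equal(length(sims[[1]]$truth$paths), 5L)
  expect_true(all(sims[[1]]$truth$lengths_um >= 0.5))
})

test_that("CSV and TIFF round trips preserve results", {
  g <- generate_image(synthetic_spec(10, "D1", allow_overlap = FALSE,
                                     seed = 2))
  net <- mito_network(g$image, threshold = 0.5)
  ld <- length_distribution(net, seed = 1)

  f <- tempfile(fileext = ".csv")
  write_distribution_csv(ld, f)
  back <- read_distribution_csv(f, pixel_size = 1 / 15)
  expect_equal(back$mass, as.numeric(signif(ld$mass, 6)), tolerance = 1e-6)
  expect_equal(back$breaks, ld$breaks, tolerance = 1e-6)

  f2 <- tempfile(fileext = ".csv")
  write_cluster_csv(net, f2)
  tab <- read.csv(f2)
  expect_equal(nrow(tab), length(net$clusters$clusters) + 1L)
  expect_true(all(c("E", "T", "J", "length_um", "donuts") %in% names(tab)))

  f3 <- tempfile(fileext = ".csv")
  rep_ <- condition_emd_protocol(list(C = list(ld, ld), T = list(ld, ld)))
  write_emd_csv(rep_, f3)
  expect_equal(nrow(read.csv(f3)), 8L)

  f4 <- tempfile(fileext = ".json")
  write_run_metadata(f4, seed = 42, params = list(bin_width = 0.5))
  meta <- jsonlite::read_json(f4)
  expect_equal(meta$seed, 42)
  expect_equal(meta$n_patterns, interpretation_table()$n_patterns)

  f5 <- tempfile(fileext = ".tif")
  write_mask_tiff(net$mask, f5)
  img <- read_gray_image(f5, pixel_size = 1 / 15)
  expect_equal(img$pixels > 0.5, unname(net$mask$mask))

  f6 <- tempfile(fileext = ".tif")
  write_gray_tiff(g$image, f6)
  expect_s3_class(read_gray_image(f6), "gray_image")

  f7 <- tempfile(fileext = ".yaml")
  writeLines(c("pixel_size: 0.0667", "n_samples: 500"), f7)
  cfg <- read_run_config(f7)
  expect_equal(cfg$n_samples, 500)
  expect_error(read_run_config(tempfile()), "not found")
})

test_that("plotting produces a device drawing without error", {
  g <- generate_image(synthetic_spec(8, "D1", allow_overlap = FALSE,
                                     seed = 3))
  net <- mito_network(g$image, threshold = 0.5)
  ld <- length_distribution(net, seed = 1)
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error({ plot(net); plot(ld) })
  grDevices::dev.off()
  expect_true(file.exists(f))
})
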