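## CSV and JSON bindings: length distributions, per-cluster tables, EMD
## reports and run metadata. Comma-separated, UTF-8, header row, '.'
## decimal, floats at 6 significant digits.

fmt6 <- function(x) signif(x, 6)

#' Read/write length distributions as CSV (bin_lo, bin_hi, mass, sd)
#'
#' @param dist A `mito_length_dist` object.
#' @param path CSV path.
#' @return `write_distribution_csv` returns the path invisibly;
#'   `read_distribution_csv` returns a `mito_length_dist`.
#' @export
write_distribution_csv <- function(dist, path) {
  df <- data.frame(bin_lo = fmt6(head(dist$breaks, -1L)),
                   bin_hi = fmt6(tail(dist$breaks, -1L)),
                   mass = fmt6(dist$mass),
                   sd = fmt6(dist$sd))
  attr(df, "expected_count") <- dist$expected_count
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @param pixel_size Micrometers per pixel recorded on the result.
#' @param expected_count Expected mitochondrion count to record.
#' @export
read_distribution_csv <- function(path, pixel_size = 1 / 15,
                                  expected_count = NA_real_) {
  df <- read.csv(path)
  new_length_dist(c(df$bin_lo, df$bin_hi[nrow(df)]), df$mass, df$sd,
                  expected_count, pixel_size, "image")
}

#' Write the per-cluster table of a fitted network as CSV
#'
#' One row per kept cluster (element counts, length, donut/blob flags) plus
#' one summary row carrying the image-level metrics.
#'
#' @param net A [mito_network()] fit.
#' @param path CSV path.
#' @export
write_cluster_csv <- function(net, path) {
  m <- net$metrics
  pc <- m$per_cluster
  pc$excluded <- FALSE
  summary_row <- data.frame(
    cluster = NA_integer_, n_elements = fmt6(m$E_C),
    E = m$n_ends, T = m$n_tubules, J = m$n_junctions,
    length_um = fmt6(m$total_length_um), is_ring = NA,
    donuts = m$donut_count, is_blob = NA, is_isolated_1_2um = NA,
    excluded = NA)
  out <- rbind(pc, summary_row)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an EMD report as CSV
#'
#' @param report A [condition_emd_protocol()] result.
#' @param path CSV path.
#' @export
write_emd_csv <- function(report, path) {
  report$value <- fmt6(report$value)
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' Serialize run metadata (parameters, seed, table) as a JSON sidecar
#'
#' @param path JSON path.
#' @param seed RNG seed used for the run.
#' @param params Named list of parameters to record.
#' @param table The [interpretation_table()] used.
#' @export
write_run_metadata <- function(path, seed = NULL, params = list(),
                               table = interpretation_table()) {
  meta <- list(
    package = "mitomorph",
    version = as.character(utils::packageVersion("mitomorph")),
    seed = seed,
    params = params,
    interpretation_table = table$degree3,
    n_patterns = table$n_patterns,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with segmentation/interpreter parameters.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_param("config file not found: ", path)
  yaml::read_yaml(path)
}
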