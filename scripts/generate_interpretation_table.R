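#!/usr/bin/env Rscript
## Regenerates the packaged data files under inst/extdata/:
##  - interpretation_table.json: the admissible local connection patterns of
##    a degree-3 junction (all-terminate; one pass-through pair with the
##    third branch terminating; one pass-through pair with the third branch
##    abutting-but-unconnected; true three-way junction), all equally
##    weighted. Edit or swap this file to change the interpretation model.
##  - d3_length_table.csv: fibroblast-like mitochondrial length density
##    (truncated log-normal shaped to span 1-10 um with mode near 2 um),
##    an editable surrogate for a measured fibroblast length distribution.
## Run from the repository root: Rscript scripts/generate_interpretation_table.R

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

degree <- 3L
pats <- list(list(pairs = list(), terminate = seq_len(degree),
                  abut = integer(0), group = FALSE))
prs <- combn(degree, 2L)
for (k in seq_len(ncol(prs))) {
  rest <- setdiff(seq_len(degree), prs[, k])
  pats[[length(pats) + 1L]] <- list(pairs = list(as.integer(prs[, k])),
                                    terminate = rest, abut = integer(0),
                                    group = FALSE)
  pats[[length(pats) + 1L]] <- list(pairs = list(as.integer(prs[, k])),
                                    terminate = integer(0), abut = rest,
                                    group = FALSE)
}
pats[[length(pats) + 1L]] <- list(pairs = list(), terminate = integer(0),
                                  abut = integer(0), group = TRUE)

jsonlite::write_json(
  list(degree = degree, n_patterns = length(pats), patterns = pats,
       note = paste("Each pattern covers the junction's attachment slots",
                    "exactly once and carries equal probability.")),
  "inst/extdata/interpretation_table.json", pretty = TRUE, digits = NA,
  auto_unbox = TRUE)

x <- seq(1, 10, by = 0.1)
d3 <- data.frame(length_um = x,
                 density = round(dlnorm(x, meanlog = log(2) + 0.55^2,
                                        sdlog = 0.55), 8))
write.csv(d3, "inst/extdata/d3_length_table.csv", row.names = FALSE)

cat("wrote", length(pats), "junction patterns and", nrow(d3),
    "length-table rows\n")
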