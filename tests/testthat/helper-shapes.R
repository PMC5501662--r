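## Geometric fixtures drawn in code: 1-px strokes and rendered tubes.

blank <- function(nr = 100L, nc = 100L) matrix(FALSE, nr, nc)

draw_line <- function(m, r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  m[cbind(rr, cc)] <- TRUE
  m
}

y_mask <- function() {
  m <- blank()
  m <- draw_line(m, 50, 50, 20, 50)
  m <- draw_line(m, 50, 50, 75, 25)
  draw_line(m, 50, 50, 75, 75)
}

plus_mask <- function() {
  m <- blank()
  m <- draw_line(m, 50, 50, 20, 50)
  m <- draw_line(m, 50, 50, 80, 50)
  m <- draw_line(m, 50, 50, 50, 20)
  draw_line(m, 50, 50, 50, 80)
}

h_mask <- function() {
  ## two uprights bridged by a rung: 2 junctions, 5 tubules, 4 ends
  m <- blank()
  m <- draw_line(m, 20, 30, 80, 30)
  m <- draw_line(m, 20, 70, 80, 70)
  draw_line(m, 50, 30, 50, 70)
}

circle_mask <- function(r = 15, ctr = c(50, 50)) {
  m <- blank()
  th <- seq(0, 2 * pi, length.out = 400)
  m[unique(cbind(round(ctr[1] + r * cos(th)),
                 round(ctr[2] + r * sin(th))))] <- TRUE
  m
}

lollipop_mask <- function() {
  m <- circle_mask()
  draw_line(m, 50, 65, 50, 90)
}

theta_mask <- function() {
  ## ring with a chord: two junctions, no ends
  m <- circle_mask()
  draw_line(m, 35, 50, 65, 50)
}

## n disjoint horizontal bars of `len` px placed on a grid
segments_mask <- function(n = 20L, len = 10L, nr = 500L, nc = 500L,
                          thick = 3L) {
  m <- matrix(FALSE, nr, nc)
  per_row <- floor(nc / (len + 20L))
  for (i in seq_len(n)) {
    r <- 20L + ((i - 1L) %/% per_row) * 25L
    c0 <- 20L + ((i - 1L) %% per_row) * (len + 20L)
    m[r:(r + thick - 1L), c0:(c0 + len - 1L)] <- TRUE
  }
  m
}

## fitted cluster set from a 1-px mask
clusters_of <- function(m, pixel_size = 1 / 15) {
  sk <- skeletonize(binary_image(m, pixel_size))
  extract_clusters(split_four_way(classify_and_merge(sk)))
}

## rendered straight tube image (Gaussian cross-section, unit peak)
straight_tube_image <- function(nr = 80, nc = 80, row = 40,
                                c0 = 15, c1 = 65, sigma = 2) {
  pts <- cbind(rep(row, length(seq(c0, c1, by = 0.5))),
               seq(c0, c1, by = 0.5))
  mitomorph:::cpp_render_paths(nr, nc, list(pts), sigma)
}

## independent greedy transport oracle for 1-D EMD on shared bins:
## move mass between sorted bins, cost = mass * centre distance
transport_emd_oracle <- function(m1, m2, breaks) {
  ctr <- (head(breaks, -1) + tail(breaks, -1)) / 2
  a <- m1 / sum(m1); b <- m2 / sum(m2)
  i <- 1L; j <- 1L; cost <- 0
  while (i <= length(a) && j <= length(b)) {
    if (a[i] <= 1e-15) { i <- i + 1L; next }
    if (b[j] <= 1e-15) { j <- j + 1L; next }
    mv <- min(a[i], b[j])
    cost <- cost + mv * abs(ctr[i] - ctr[j])
    a[i] <- a[i] - mv; b[j] <- b[j] - mv
  }
  cost
}

## uniform random distribution on given breaks
rand_dist <- function(breaks, seed) {
  set.seed(seed)
  m <- runif(length(breaks) - 1L)
  m <- m / sum(m)
  mitomorph:::new_length_dist(breaks, m, rep(0, length(m)), 10, 1 / 15,
                              "image")
}
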