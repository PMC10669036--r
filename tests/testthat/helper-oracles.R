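# Independent oracles used across test files.

# exhaustive nearest-centroid classification: plain double loop over pixels
# and components, no vectorization shared with the implementation
brute_force_classify <- function(image, centroids, roi) {
  h <- dim(image)[1]; w <- dim(image)[2]
  labels <- matrix(NA_integer_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!roi[i, j]) next
    best <- 0L; best_d <- Inf
    for (k in seq_len(nrow(centroids))) {
      d <- sum((image[i, j, ] - centroids[k, ])^2)
      if (d < best_d) { best_d <- d; best <- k }
    }
    labels[i, j] <- best
  }
  labels
}

# random blob-ish binary mask for morphology property tests
random_mask <- function(h = 40, w = 40, p = 0.35) {
  m <- matrix(runif(h * w) < p, h, w)
  # thicken a little so openings have something to keep
  m | rbind(m[-1, ], FALSE) | cbind(m[, -1], FALSE)
}

# rasterized disk mask
disk_mask <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  (rows - ctr)^2 + (cols - ctr)^2 <= r^2
}

# small three-group sample table with known means
toy_sample_table <- function(means = c(A = 10, B = 12, C = 15), n = 8,
                             sd = 1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(means), function(g) data.frame(
    group = g, direction = rep(c("theta", "z"), length.out = n),
    rat_id = paste0(g, "_r", rep(1:2, length.out = n)),
    y = rnorm(n, means[[g]], sd))))
}
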