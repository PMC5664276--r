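# Independent oracles used across tests. These deliberately re-derive each
# quantity by a different route than the package code.

# Exhaustive minimiser of the total within-class variance over all inter-bin
# boundaries of a histogram (bin-centre moments). Returns the boundary index
# k (classes = bins 1..k vs k+1..n), smallest k on ties, plus the variance
# curves.
otsu_oracle <- function(counts, mids) {
  n <- length(counts)
  total <- sum(counts)
  sw <- rep(NA_real_, n - 1)
  for (k in seq_len(n - 1)) {
    c0 <- counts[1:k]; m0 <- mids[1:k]
    c1 <- counts[(k + 1):n]; m1 <- mids[(k + 1):n]
    n0 <- sum(c0); n1 <- sum(c1)
    v0 <- if (n0 > 0) sum(c0 * (m0 - sum(c0 * m0) / n0)^2) / n0 else 0
    v1 <- if (n1 > 0) sum(c1 * (m1 - sum(c1 * m1) / n1)^2) / n1 else 0
    sw[k] <- (n0 * v0 + n1 * v1) / total
  }
  list(k = which.min(sw), sigma_w2 = sw)
}

# histogram total variance from bin-centre moments
hist_total_var <- function(counts, mids) {
  mu <- sum(counts * mids) / sum(counts)
  sum(counts * (mids - mu)^2) / sum(counts)
}

# Winding-number point-in-polygon (angle summation) - a different algorithm
# from the package's even-odd crossing test; valid for simple polygons.
winding_pip <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  if (poly_x[1] == poly_x[n] && poly_y[1] == poly_y[n]) {
    poly_x <- poly_x[-n]; poly_y <- poly_y[-n]; n <- n - 1
  }
  vapply(seq_along(px), function(i) {
    vx <- poly_x - px[i]; vy <- poly_y - py[i]
    vx2 <- c(poly_x[-1], poly_x[1]) - px[i]
    vy2 <- c(poly_y[-1], poly_y[1]) - py[i]
    ang <- atan2(vx * vy2 - vy * vx2, vx * vx2 + vy * vy2)
    abs(sum(ang)) > pi
  }, logical(1))
}

# star-shaped simple polygon around (cx, cy): random radii at sorted angles
random_star_polygon <- function(cx, cy, r_lo, r_hi, n_vertices = 12) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_lo, r_hi)
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# a closed regular polygon approximating a circle
circle_polygon <- function(cx, cy, r, n = 720) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# random histogram on n_bins over [0, 1] (some bins possibly empty)
random_histogram <- function(n_bins) {
  counts <- stats::rpois(n_bins, lambda = stats::runif(1, 0.5, 30))
  if (sum(counts > 0) < 2) counts[c(1, n_bins)] <- counts[c(1, n_bins)] + 1L
  h <- intensity_histogram(0.5, n_bins = n_bins)
  h$counts <- counts
  h$total <- sum(counts)
  h
}
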