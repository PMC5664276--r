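# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Pixel-centre coordinate grids for an nr x nc matrix.
# Convention: 0-based, x = column index, y = row index; pixel centres at
# integer coordinates; matrix element [y + 1, x + 1].
pixel_grid <- function(nr, nc = nr) {
  list(
    x = matrix(rep(0:(nc - 1L), each = nr), nr, nc),
    y = matrix(rep(0:(nr - 1L), times = nc), nr, nc)
  )
}

# Angle of (x - cx, y - cy) in degrees in [0, 360).
# 0 deg along +x (columns), increasing towards +y (rows); shared by the
# phantom generator and the sector module.
pixel_angle_deg <- function(x, y, center) {
  (atan2(y - center[2], x - center[1]) * 180 / pi) %% 360
}

# Vectorised even-odd point-in-polygon test over points (px, py).
# Points lying exactly on a polygon edge count as inside.
point_in_polygon <- function(px, py, poly_x, poly_y, tol = 1e-9) {
  n <- length(poly_x)
  stopifnot(n == length(poly_y), n >= 3)
  if (poly_x[1] == poly_x[n] && poly_y[1] == poly_y[n]) {
    poly_x <- poly_x[-n]
    poly_y <- poly_y[-n]
    n <- n - 1L
  }
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    # collinearity + bounding-box test for "on this edge"
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
      py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
    on_edge <- on_edge | (abs(cross) <= tol * max(1, abs(xi - xj), abs(yi - yj)) & within)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# Signed-area centroid of a polygon (falls back to the vertex mean for
# degenerate, zero-area polygons).
polygon_centroid <- function(poly_x, poly_y) {
  n <- length(poly_x)
  if (poly_x[1] == poly_x[n] && poly_y[1] == poly_y[n]) {
    poly_x <- poly_x[-n]; poly_y <- poly_y[-n]; n <- n - 1L
  }
  xi <- poly_x; yi <- poly_y
  xj <- c(poly_x[-1], poly_x[1]); yj <- c(poly_y[-1], poly_y[1])
  cr <- xi * yj - xj * yi
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(poly_x), mean(poly_y)))
  c(sum((xi + xj) * cr) / (6 * a), sum((yi + yj) * cr) / (6 * a))
}

# Total angular measure (degrees) of the union of wedges given as
# (start, span) pairs on the circle, handling wrap-around and overlap.
angular_union_deg <- function(starts, spans) {
  if (length(starts) == 0) return(0)
  if (any(spans >= 360)) return(360)
  s <- starts %% 360
  e <- s + spans
  segs <- list()
  for (i in seq_along(s)) {
    if (e[i] <= 360) {
      segs[[length(segs) + 1L]] <- c(s[i], e[i])
    } else {
      segs[[length(segs) + 1L]] <- c(s[i], 360)
      segs[[length(segs) + 1L]] <- c(0, e[i] - 360)
    }
  }
  m <- do.call(rbind, segs)
  m <- m[order(m[, 1]), , drop = FALSE]
  total <- 0
  cur <- m[1, ]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      if (m[i, 1] <= cur[2]) cur[2] <- max(cur[2], m[i, 2])
      else { total <- total + (cur[2] - cur[1]); cur <- m[i, ] }
    }
  }
  min(total + (cur[2] - cur[1]), 360)
}

# TRUE where angle theta (deg) lies in the half-open wedge [start, start+span).
angle_in_wedge <- function(theta, start, span) {
  ((theta - start) %% 360) < span
}

fail <- function(...) stop(sprintf(...), call. = FALSE)
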