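#' Epicardial/endocardial contour pair
#'
#' Ordered polygons in 0-based pixel coordinates (x = column, y = row)
#' delineating the LV myocardial borders. Polygons may be given open
#' (implicitly closed) or with first vertex repeated. The endocardium must
#' lie strictly inside the epicardium.
#'
#' @param epicardium,endocardium Two-column matrices or data.frames of (x, y)
#'   vertices, at least 3 distinct vertices each.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(epicardium, endocardium) {
  epi <- as.matrix(epicardium)
  endo <- as.matrix(endocardium)
  for (nm in c("epi", "endo")) {
    p <- if (nm == "epi") epi else endo
    if (ncol(p) < 2) fail("contour_set: %scardium needs (x, y) columns", nm)
    pu <- unique(p[, 1:2, drop = FALSE])
    if (nrow(pu) < 3) fail("contour_set: %scardium needs >= 3 distinct vertices", nm)
  }
  inside <- point_in_polygon(endo[, 1], endo[, 2], epi[, 1], epi[, 2])
  if (!all(inside))
    fail("contour_set: endocardium is not inside the epicardium (%d vertices outside)",
         sum(!inside))
  if (polygon_self_intersects(epi) || polygon_self_intersects(endo))
    warning("contour_set: self-intersecting contour accepted; check tracing")
  structure(list(epicardium = epi[, 1:2, drop = FALSE],
                 endocardium = endo[, 1:2, drop = FALSE]),
            class = "contour_set")
}

# Quadratic-time segment intersection scan; contours are short (tens of
# vertices), so this is cheap.
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (p[1, 1] == p[n, 1] && p[1, 2] == p[n, 2]) { p <- p[-n, , drop = FALSE]; n <- n - 1L }
  if (n < 4) return(FALSE)
  seg <- function(i) rbind(p[i, ], p[if (i == n) 1 else i + 1, ])
  ccw <- function(a, b, c) (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next           # shares the closing vertex
      a <- seg(i); b <- seg(j)
      if (ccw(a[1, ], b[1, ], b[2, ]) != ccw(a[2, ], b[1, ], b[2, ]) &&
          ccw(a[1, ], a[2, ], b[1, ]) != ccw(a[1, ], a[2, ], b[2, ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Annular myocardial mask
#'
#' @param mask Logical matrix, `TRUE` on myocardium.
#' @param center LV centre `(x, y)` in pixel coordinates, or `NULL`.
#' @return An object of class `myocardial_mask` with `mask`, `n_pixels`,
#'   `center`.
#' @export
myocardial_mask <- function(mask, center = NULL) {
  mask <- mask != 0
  n <- sum(mask)
  if (n == 0) fail("myocardial_mask: mask has no myocardial pixels")
  structure(list(mask = mask, n_pixels = n, center = center),
            class = "myocardial_mask")
}

#' @export
print.myocardial_mask <- function(x, ...) {
  cat(sprintf("<myocardial_mask> %d px, centre = (%s)\n", x$n_pixels,
              if (is.null(x$center)) "unset" else
                paste(sprintf("%.2f", x$center), collapse = ", ")))
  invisible(x)
}

#' Rasterise contours to the annular myocardial mask
#'
#' Myocardium = inside the epicardium AND NOT inside the endocardium, decided
#' per pixel centre by the even-odd rule (centres exactly on a contour edge
#' count as inside that contour).
#'
#' @param contours A [contour_set()].
#' @param image_shape `c(nrow, ncol)` of the target image.
#' @return A [myocardial_mask()] with the LV centre from [lv_center()].
#' @export
contours_to_mask <- function(contours, image_shape) {
  stopifnot(inherits(contours, "contour_set"))
  nr <- image_shape[1]; nc <- image_shape[2]
  epi <- contours$epicardium
  endo <- contours$endocardium
  # restrict the point-in-polygon tests to the epicardial bounding box
  xr <- range(epi[, 1]); yr <- range(epi[, 2])
  xs <- max(0L, floor(xr[1])):min(nc - 1L, ceiling(xr[2]))
  ys <- max(0L, floor(yr[1])):min(nr - 1L, ceiling(yr[2]))
  if (length(xs) == 0 || length(ys) == 0)
    fail("contours_to_mask: contours lie outside the image")
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  in_epi <- point_in_polygon(px, py, epi[, 1], epi[, 2])
  in_endo <- point_in_polygon(px, py, endo[, 1], endo[, 2])
  keep <- in_epi & !in_endo
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(py[keep] + 1L, px[keep] + 1L)] <- TRUE
  if (!any(mask)) fail("contours_to_mask: rasterised mask is empty")
  myocardial_mask(mask, center = lv_center(contours))
}

#' Locate the LV centre
#'
#' With contours, the centroid of the endocardial polygon. With only a mask,
#' the centroid of the cavity: the connected background component enclosed by
#' the annulus (background pixels not reachable from the image border). If no
#' cavity exists the mask centroid is returned with a warning.
#'
#' @param x A [contour_set()], [myocardial_mask()] or logical matrix.
#' @return Numeric `(x, y)` in pixel coordinates.
#' @export
lv_center <- function(x) {
  if (inherits(x, "contour_set"))
    return(polygon_centroid(x$endocardium[, 1], x$endocardium[, 2]))
  mask <- if (inherits(x, "myocardial_mask")) x$mask else (x != 0)
  bg <- !mask
  # flood the border-connected background by iterative 4-neighbour dilation
  reach <- matrix(FALSE, nrow(bg), ncol(bg))
  reach[1, ] <- bg[1, ]; reach[nrow(bg), ] <- bg[nrow(bg), ]
  reach[, 1] <- reach[, 1] | bg[, 1]; reach[, ncol(bg)] <- reach[, ncol(bg)] | bg[, ncol(bg)]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nrow(reach), ]
    grown[-nrow(reach), ] <- grown[-nrow(reach), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ncol(reach)]
    grown[, -ncol(reach)] <- grown[, -ncol(reach)] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  hole <- bg & !reach
  target <- if (any(hole)) hole else {
    warning("lv_center: no enclosed cavity found; using mask centroid")
    mask
  }
  idx <- which(target, arr.ind = TRUE)
  c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)   # (x, y), 0-based
}

#' Midline length-fraction of a lesion
#'
#' The mask-level analog of histological length-based infarct sizing: sample
#' the mid-wall circle - per angle, the midpoint radius between the inner and
#' outer myocardial boundary along that ray - at `n_samples` angles and
#' report the percentage of myocardium-hitting samples that land in the
#' lesion. A subendocardial lesion thinner than half the wall therefore
#' scores 0.
#'
#' @param mask A [myocardial_mask()] or logical matrix.
#' @param lesion_mask Logical lesion matrix, subset of `mask`.
#' @param center LV centre `(x, y)`; defaults to `lv_center(mask)`.
#' @param n_samples Number of equally spaced angles (default 3600).
#' @return Percentage in `[0, 100]`.
#' @export
midline_lesion_fraction <- function(mask, lesion_mask, center = NULL,
                                    n_samples = 3600) {
  m <- if (inherits(mask, "myocardial_mask")) mask$mask else mask
  if (any(lesion_mask & !m))
    fail("midline_lesion_fraction: lesion extends outside the myocardium")
  center <- center %||%
    (if (inherits(mask, "myocardial_mask") && !is.null(mask$center))
      mask$center else lv_center(m))
  nr <- nrow(m); nc <- ncol(m)
  # radial search window from the mask itself (vectorised ray casting)
  idx <- which(m, arr.ind = TRUE)
  dist <- sqrt((idx[, 2] - 1 - center[1])^2 + (idx[, 1] - 1 - center[2])^2)
  radii <- seq(max(0.25, min(dist) - 1), max(dist) + 1, by = 0.25)
  ar <- (seq_len(n_samples) - 1) * (2 * pi / n_samples)
  cosr <- cos(ar); sinr <- sin(ar)
  # sample points: rows = radii, columns = angles; nearest-pixel lookup
  xs <- round(center[1] + outer(radii, cosr))
  ys <- round(center[2] + outer(radii, sinr))
  inb <- xs >= 0 & xs < nc & ys >= 0 & ys < nr
  hit <- matrix(FALSE, length(radii), n_samples)
  hit[inb] <- m[cbind(ys[inb] + 1L, xs[inb] + 1L)]
  n_hits <- colSums(hit)
  th <- t(hit)
  i_first <- max.col(th, ties.method = "first")
  i_last <- max.col(th, ties.method = "last")
  mid_r <- ifelse(n_hits > 0, (radii[i_first] + radii[i_last]) / 2, NA_real_)
  bad <- is.na(mid_r)
  if (mean(bad) > 0.10)
    fail("midline_lesion_fraction: wall radius undefined at %.0f%% of angles",
         100 * mean(bad))
  xs <- round(center[1] + mid_r[!bad] * cosr[!bad])
  ys <- round(center[2] + mid_r[!bad] * sinr[!bad])
  ok <- xs >= 0 & xs < nc & ys >= 0 & ys < nr
  xs <- xs[ok]; ys <- ys[ok]
  in_myo <- m[cbind(ys + 1L, xs + 1L)]
  if (!any(in_myo))
    fail("midline_lesion_fraction: no midline sample lands in the myocardium")
  in_les <- lesion_mask[cbind(ys + 1L, xs + 1L)]
  100 * sum(in_les & in_myo) / sum(in_myo)
}
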