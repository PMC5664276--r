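#' Normalise myocardial intensities to [0, 1]
#'
#' Min-max normalisation restricted to the myocardial region of interest:
#' `v' = (v - min) / (max - min)` over ROI pixels only, so the ROI histogram
#' always spans exactly `[0, 1]`. A constant ROI cannot be normalised; it is
#' flagged degenerate and every ROI value is set to 0.5.
#'
#' @param image A [short_axis_image()] or numeric matrix.
#' @param mask A [myocardial_mask()] or logical matrix; must be non-empty.
#' @return An object of class `normalized_roi`: list with `values` (matrix,
#'   `NA` outside the ROI), `mask`, `range` (original min/max) and
#'   `degenerate` flag.
#' @export
normalize_intensity <- function(image, mask) {
  px <- if (inherits(image, "short_axis_image")) image$pixels else image
  m <- if (inherits(mask, "myocardial_mask")) mask$mask else mask
  if (!identical(dim(px), dim(m)))
    fail("normalize_intensity: image and mask dimensions differ")
  if (!any(m)) fail("normalize_intensity: empty myocardial mask")
  v <- px[m]
  lo <- min(v); hi <- max(v)
  out <- matrix(NA_real_, nrow(px), ncol(px))
  degenerate <- hi <= lo
  out[m] <- if (degenerate) 0.5 else (v - lo) / (hi - lo)
  structure(list(values = out, mask = m, range = c(lo, hi),
                 degenerate = degenerate),
            class = "normalized_roi")
}

#' Intensity histogram over [0, 1]
#'
#' Equal-width bins covering `[0, 1]`; bin `i` is `[edges[i], edges[i+1])`,
#' with the final bin closed so that a value of exactly 1 is counted.
#'
#' @param values Numeric values in `[0, 1]` (`NA`s dropped).
#' @param n_bins Number of bins (default 256, the 8-bit convention).
#' @return An object of class `intensity_histogram`: `counts`, `bin_edges`,
#'   `mids`, `total`.
#' @export
intensity_histogram <- function(values, n_bins = 256) {
  v <- values[!is.na(values)]
  if (length(v) == 0) fail("intensity_histogram: no values")
  if (any(v < 0 | v > 1)) fail("intensity_histogram: values must lie in [0, 1]")
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(floor(v * n_bins), n_bins - 1) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(counts = counts, bin_edges = edges,
                 mids = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 total = length(v)),
            class = "intensity_histogram")
}

#' Otsu's threshold from a histogram
#'
#' Exhaustively evaluates every inter-bin boundary `t_k` (classes = bins
#' `1..k` versus `k+1..n_bins`) and picks the one maximising the
#' between-class variance
#' `sigma_b^2(t) = w0 w1 (mu0 - mu1)^2`,
#' which is equivalent to minimising the total within-class variance. Ties
#' are broken toward the smallest candidate; the threshold is reported at the
#' upper edge of the last below-class bin.
#'
#' @param hist An [intensity_histogram()], or raw values in `[0, 1]` (then
#'   binned with `n_bins`).
#' @param n_bins Bin count used when `hist` is a value vector.
#' @return An object of class `otsu_result`: `threshold`, `sigma_b2`
#'   (between-class variance at every candidate boundary), `candidates`
#'   (their intensity positions), `k` (chosen boundary index),
#'   `class_counts` (pixels below / above).
#' @export
otsu_threshold <- function(hist, n_bins = 256) {
  if (!inherits(hist, "intensity_histogram"))
    hist <- intensity_histogram(hist, n_bins = n_bins)
  counts <- as.numeric(hist$counts)
  if (hist$total <= 0) fail("otsu_threshold: empty histogram")
  if (sum(counts > 0) < 2)
    fail("otsu_threshold: needs at least 2 nonempty bins (constant region)")
  n <- length(counts)
  mids <- hist$mids
  w <- cumsum(counts)                       # pixels in bins 1..k
  mu <- cumsum(counts * mids)               # unnormalised first moment
  tot_n <- w[n]
  tot_mu <- mu[n]
  k_all <- seq_len(n - 1)
  w0 <- w[k_all]
  w1 <- tot_n - w0
  sigma_b2 <- rep(0, n - 1)
  ok <- w0 > 0 & w1 > 0
  mu0 <- mu[k_all][ok] / w0[ok]
  mu1 <- (tot_mu - mu[k_all][ok]) / w1[ok]
  sigma_b2[ok] <- (w0[ok] / tot_n) * (w1[ok] / tot_n) * (mu0 - mu1)^2
  k <- which.max(sigma_b2)                  # which.max takes the first tie
  structure(
    list(threshold = hist$bin_edges[k + 1],
         sigma_b2 = sigma_b2,
         candidates = hist$bin_edges[k_all + 1],
         k = k,
         class_counts = c(below = w[k], above = tot_n - w[k]),
         histogram = hist),
    class = "otsu_result"
  )
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("<otsu_result> threshold = %.4f (below %d px, above %d px)\n",
              x$threshold, x$class_counts[1], x$class_counts[2]))
  invisible(x)
}

#' Segment enhanced pixels under a modality's polarity
#'
#' Hyperenhancing lesions (gadolinium in nonviable myocardium) are the pixels
#' strictly above the threshold; hypoenhancing lesions (manganese deficit,
#' iron-oxide T2* dropout) are those strictly below. Pixels exactly at the
#' threshold belong to the below class in both cases. For a degenerate
#' (constant) ROI the lesion is empty, with a warning.
#'
#' @param norm A [normalize_intensity()] result (or numeric matrix of
#'   normalised ROI values with `NA` outside the ROI).
#' @param otsu An [otsu_result][otsu_threshold()].
#' @param polarity `"hyper"` or `"hypo"`.
#' @return Logical lesion matrix (`FALSE` outside the ROI).
#' @export
segment_enhanced <- function(norm, otsu, polarity = c("hyper", "hypo")) {
  polarity <- match.arg(polarity)
  vals <- if (inherits(norm, "normalized_roi")) norm$values else norm
  degenerate <- inherits(norm, "normalized_roi") && norm$degenerate
  if (degenerate) {
    warning("segment_enhanced: degenerate (constant) ROI; empty lesion returned")
    lesion <- !is.na(vals) & FALSE
  } else if (polarity == "hyper") {
    lesion <- !is.na(vals) & vals > otsu$threshold
  } else {
    lesion <- !is.na(vals) & vals < otsu$threshold
  }
  lesion
}

#' Area-based enhancement percentage
#'
#' The enhanced lesion size divided by the LV myocardium size, in percent of
#' pixels.
#'
#' @param lesion_mask Logical lesion matrix, a subset of `mask`.
#' @param mask A [myocardial_mask()] or logical matrix; must be non-empty.
#' @return Percentage in `[0, 100]`.
#' @export
area_fraction <- function(lesion_mask, mask) {
  m <- if (inherits(mask, "myocardial_mask")) mask$mask else mask
  if (!any(m)) fail("area_fraction: empty myocardium mask")
  if (any(lesion_mask & !m))
    fail("area_fraction: lesion mask extends outside the myocardium")
  100 * sum(lesion_mask) / sum(m)
}
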