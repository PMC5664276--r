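#' Quantify enhanced lesion extent on one slice
#'
#' The central per-slice estimator. Myocardial intensities are min-max
#' normalised over the ROI, Otsu's threshold is computed from their 256-bin
#' histogram, and the enhancement percentage is read out geometrically:
#' \describe{
#'   \item{area}{enhanced pixels / myocardial pixels.}
#'   \item{sector}{the myocardium is registered to 360 one-degree radial
#'     sectors around the LV centre; sector means are Otsu-thresholded
#'     (64 bins) and the percentage is enhanced / valid sectors.}
#' }
#'
#' @param image A [short_axis_image()] or numeric matrix.
#' @param roi A [myocardial_mask()], logical matrix, or [contour_set()]
#'   (rasterised on the fly).
#' @param polarity `"hyper"` (lesion brighter than myocardium, e.g. late
#'   gadolinium enhancement) or `"hypo"` (lesion darker, e.g.
#'   manganese-deficit or iron-oxide dropout).
#' @param methods Subset of `c("area", "sector")`.
#' @param n_bins Histogram bins for the pixel-level Otsu (default 256).
#' @param sector_bins Histogram bins for the sector-level Otsu (default 64).
#' @param angle_offset Degrees added to pixel angles before sector binning.
#' @param center Optional LV centre override.
#' @return An object of class `lesion_quant` with one element per method
#'   (each holding `enhancement_pct`, `threshold`, `n_total`, `n_enhanced`,
#'   and method-specific detail), plus `polarity`, `norm`, `mask` and image
#'   metadata.
#' @examples
#' ph <- generate_phantom(phantom_spec(wedges = lesion_wedge(30, 120)))
#' q <- quantify_slice(ph$image, ph$truth$myocardium_mask, "hyper")
#' q$area$enhancement_pct    # ~ 33.3
#' @export
quantify_slice <- function(image, roi, polarity = c("hyper", "hypo"),
                           methods = c("area", "sector"), n_bins = 256,
                           sector_bins = 64, angle_offset = 0,
                           center = NULL) {
  polarity <- match.arg(polarity)
  methods <- match.arg(methods, c("area", "sector"), several.ok = TRUE)
  px <- if (inherits(image, "short_axis_image")) image$pixels else image
  mask <- if (inherits(roi, "contour_set"))
    contours_to_mask(roi, dim(px))
  else if (inherits(roi, "myocardial_mask")) roi
  else myocardial_mask(roi)

  norm <- normalize_intensity(px, mask)
  out <- list(polarity = polarity, mask = mask, norm = norm,
              subject_id = if (inherits(image, "short_axis_image"))
                image$subject_id else NA_character_,
              slice_index = if (inherits(image, "short_axis_image"))
                image$slice_index else NA_integer_,
              modality = if (inherits(image, "short_axis_image"))
                image$modality else NA_character_)

  if ("area" %in% methods) {
    if (norm$degenerate) {
      warning("quantify_slice: degenerate (constant) ROI; empty lesion")
      lesion <- mask$mask & FALSE
      out$area <- list(enhancement_pct = 0, threshold = NA_real_,
                       n_total = mask$n_pixels, n_enhanced = 0L,
                       lesion_mask = lesion, otsu = NULL)
    } else {
      ot <- otsu_threshold(norm$values[mask$mask], n_bins = n_bins)
      lesion <- segment_enhanced(norm, ot, polarity)
      out$area <- list(enhancement_pct = area_fraction(lesion, mask),
                       threshold = ot$threshold, n_total = mask$n_pixels,
                       n_enhanced = sum(lesion), lesion_mask = lesion,
                       otsu = ot)
    }
  }
  if ("sector" %in% methods) {
    prof <- sector_values(px, mask, center = center,
                          angle_offset = angle_offset)
    sq <- sector_quantify(prof, polarity, n_bins = sector_bins)
    out$sector <- list(enhancement_pct = sq$fraction,
                       threshold = sq$threshold,
                       n_total = sq$valid_sectors,
                       n_enhanced = sq$enhanced_sectors,
                       profile = prof, quant = sq)
  }
  structure(out, class = "lesion_quant")
}

#' @export
print.lesion_quant <- function(x, ...) {
  cat(sprintf("<lesion_quant> subject=%s modality=%s slice=%s polarity=%s\n",
              x$subject_id, x$modality, x$slice_index, x$polarity))
  for (m in intersect(c("area", "sector"), names(x)))
    cat(sprintf("  %-7s %6.2f %%  (threshold %.3f, %d / %d %s)\n", m,
                x[[m]]$enhancement_pct, x[[m]]$threshold,
                x[[m]]$n_enhanced, x[[m]]$n_total,
                if (m == "area") "pixels" else "sectors"))
  invisible(x)
}

#' @export
summary.lesion_quant <- function(object, ...) {
  rows <- lapply(intersect(c("area", "sector"), names(object)), function(m)
    data.frame(subject = object$subject_id, slice = object$slice_index,
               modality = object$modality, method = m,
               enhancement_pct = object[[m]]$enhancement_pct,
               threshold = object[[m]]$threshold,
               n_total = object[[m]]$n_total,
               n_enhanced = object[[m]]$n_enhanced,
               stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @export
plot.lesion_quant <- function(x, which = c("histogram", "profile"), ...) {
  which <- match.arg(which)
  if (which == "histogram") {
    if (is.null(x$area$otsu)) fail("plot.lesion_quant: no area result to plot")
    h <- x$area$otsu$histogram
    plot(h$mids, h$counts, type = "h", xlab = "normalised signal intensity",
         ylab = "pixel count", main = "ROI histogram with Otsu threshold", ...)
    graphics::abline(v = x$area$threshold, lty = 2)
  } else {
    if (is.null(x$sector)) fail("plot.lesion_quant: no sector result to plot")
    p <- x$sector$profile
    plot(0:359, p$values, type = "l", xlab = "sector (deg)",
         ylab = "normalised intensity", main = "Radial profile", ...)
    graphics::abline(h = x$sector$threshold, lty = 2)
  }
  invisible(x)
}

#' Quantify a whole study into a long-format table
#'
#' Runs [quantify_slice()] on every image and stacks the results as one row
#' per (subject, slice, modality, method). When ground truths are supplied
#' (synthetic studies), `midline` rows (midline length-fraction of the true
#' lesion, the histology analog) and `truth` rows (true area percentage) are
#' appended for the methods requested.
#'
#' @param images List of [short_axis_image()].
#' @param rois List of ROIs (masks or contour sets) parallel to `images`.
#' @param polarity_map Named character vector, modality -> polarity.
#' @param methods Subset of `c("area", "sector", "midline", "truth")`.
#' @param truths Optional list of `ground_truth` objects parallel to
#'   `images` (required for `midline` and `truth` rows).
#' @param ... Passed to [quantify_slice()].
#' @return data.frame with columns `subject`, `slice`, `modality`, `method`,
#'   `enhancement_pct`, `threshold`, `n_total`, `n_enhanced`.
#' @export
quantify_study <- function(images, rois, polarity_map,
                           methods = c("area", "sector"), truths = NULL,
                           ...) {
  methods <- match.arg(methods, c("area", "sector", "midline", "truth"),
                       several.ok = TRUE)
  needs_truth <- intersect(methods, c("midline", "truth"))
  if (length(needs_truth) > 0 && is.null(truths))
    fail("quantify_study: methods %s need ground truths",
         paste(needs_truth, collapse = ", "))
  img_methods <- intersect(methods, c("area", "sector"))
  # locate each LV centre once; sector and midline read-outs share it
  rois <- lapply(rois, function(r) {
    if (inherits(r, "myocardial_mask") && is.null(r$center))
      r$center <- lv_center(r$mask)
    r
  })
  rows <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    pol <- if (img$modality %in% names(polarity_map))
      polarity_map[[img$modality]] else NULL
    if (is.null(pol) || is.na(pol))
      fail("quantify_study: no polarity configured for modality '%s'",
           img$modality)
    meta <- data.frame(subject = img$subject_id, slice = img$slice_index,
                       modality = img$modality, stringsAsFactors = FALSE)
    if (length(img_methods) > 0) {
      q <- quantify_slice(img, rois[[i]], pol, methods = img_methods, ...)
      s <- summary(q)
      rows[[length(rows) + 1L]] <- s
    }
    if ("midline" %in% methods) {
      tr <- truths[[i]]
      mk <- if (inherits(rois[[i]], "myocardial_mask")) rois[[i]]
            else myocardial_mask(tr$myocardium_mask)
      ml <- midline_lesion_fraction(mk, tr$lesion_mask)
      rows[[length(rows) + 1L]] <- cbind(meta, data.frame(
        method = "midline", enhancement_pct = ml, threshold = NA_real_,
        n_total = NA_integer_, n_enhanced = NA_integer_))
    }
    if ("truth" %in% methods) {
      tr <- truths[[i]]
      rows[[length(rows) + 1L]] <- cbind(meta, data.frame(
        method = "truth", enhancement_pct = tr$true_fraction_area,
        threshold = NA_real_, n_total = sum(tr$myocardium_mask),
        n_enhanced = sum(tr$lesion_mask)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
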