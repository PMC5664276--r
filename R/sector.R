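#' Register the myocardium to 360 radial sectors
#'
#' Every myocardial pixel is assigned to the 1-degree sector
#' `floor(angle(pixel centre - LV centre))`, half-open bins `[k, k+1)`
#' degrees, using the package's shared angle convention (0 degrees along +x,
#' increasing with +y). The sector value is the mean min-max-normalised
#' intensity of its member pixels; sectors with no pixels carry `NA`.
#'
#' @param image A [short_axis_image()] or numeric matrix.
#' @param mask A [myocardial_mask()] or logical matrix.
#' @param center LV centre `(x, y)`; defaults to the mask's centre or
#'   [lv_center()].
#' @param angle_offset Degrees added to every pixel angle before binning
#'   (anatomical alignment); default 0.
#' @return An object of class `sector_profile`: `values` (length 360, `NA`
#'   where empty), `pixel_counts`, `center`, `angle_offset`, `degenerate`.
#' @export
sector_values <- function(image, mask, center = NULL, angle_offset = 0) {
  m <- if (inherits(mask, "myocardial_mask")) mask$mask else mask
  center <- center %||%
    (if (inherits(mask, "myocardial_mask") && !is.null(mask$center))
      mask$center else lv_center(m))
  px <- if (inherits(image, "short_axis_image")) image$pixels else image
  if (center[1] < 0 || center[1] >= ncol(px) ||
      center[2] < 0 || center[2] >= nrow(px))
    fail("sector_values: centre lies outside the image")
  norm <- normalize_intensity(px, m)
  idx <- which(m, arr.ind = TRUE)
  x <- idx[, 2] - 1
  y <- idx[, 1] - 1
  theta <- (pixel_angle_deg(x, y, center) + angle_offset) %% 360
  sec <- pmin(floor(theta), 359) + 1L
  vals <- norm$values[m]
  counts <- tabulate(sec, nbins = 360)
  sums <- vapply(split(vals, factor(sec, levels = 1:360)), sum, numeric(1))
  values <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  n_empty <- sum(counts == 0)
  if (n_empty > 0.25 * 360)
    fail("sector_values: %d of 360 sectors are empty; centre likely outside the cavity",
         n_empty)
  structure(list(values = unname(values), pixel_counts = counts,
                 center = center, angle_offset = angle_offset,
                 degenerate = norm$degenerate),
            class = "sector_profile")
}

#' Otsu-threshold the sector profile
#'
#' The valid (non-empty) sector values are histogrammed on 64 bins over
#' `[0, 1]` and thresholded with Otsu's method; sectors strictly above
#' (hyper) or strictly below (hypo) the threshold count as enhanced. Empty
#' sectors take part in neither numerator nor denominator.
#'
#' @param profile A [sector_values()] result.
#' @param polarity `"hyper"` or `"hypo"`.
#' @param n_bins Histogram bins for the sector values (default 64; there are
#'   at most 360 samples, so finer binning invites empty-bin artifacts).
#' @return An object of class `sector_quantification`: `threshold`,
#'   `enhanced` (logical per sector, `NA` where empty), `enhanced_sectors`,
#'   `valid_sectors`, `fraction` (percent), `otsu`.
#' @export
sector_quantify <- function(profile, polarity = c("hyper", "hypo"),
                            n_bins = 64) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(profile, "sector_profile"))
  valid <- !is.na(profile$values)
  v <- profile$values[valid]
  if (length(unique(v)) < 2)
    fail("sector_quantify: all sector values equal; no threshold exists")
  ot <- otsu_threshold(v, n_bins = n_bins)
  enh <- rep(NA, 360)
  enh[valid] <- if (polarity == "hyper") v > ot$threshold else v < ot$threshold
  n_enh <- sum(enh, na.rm = TRUE)
  n_val <- sum(valid)
  structure(list(threshold = ot$threshold, enhanced = enh,
                 enhanced_sectors = n_enh, valid_sectors = n_val,
                 fraction = 100 * n_enh / n_val, polarity = polarity,
                 otsu = ot),
            class = "sector_quantification")
}

#' @export
print.sector_quantification <- function(x, ...) {
  cat(sprintf("<sector_quantification> %d/%d sectors enhanced (%.1f%%), threshold %.3f (%s)\n",
              x$enhanced_sectors, x$valid_sectors, x$fraction, x$threshold,
              x$polarity))
  invisible(x)
}

#' Export the radial profile as TSV (and optionally a QC plot)
#'
#' Writes one row per sector: index (0-359), mean normalised value, pixel
#' count and enhanced flag.
#'
#' @param profile A [sector_values()] result.
#' @param quant A [sector_quantify()] result, or `NULL` (enhanced column
#'   then all `NA`).
#' @param path Output TSV path.
#' @param plot_path Optional PNG path for a radial-profile plot with the
#'   threshold line.
#' @return `path`, invisibly.
#' @export
radial_profile_export <- function(profile, quant = NULL, path,
                                  plot_path = NULL) {
  stopifnot(inherits(profile, "sector_profile"))
  enh <- if (is.null(quant)) rep(NA, 360) else quant$enhanced
  df <- data.frame(sector = 0:359,
                   value = profile$values,
                   pixel_count = profile$pixel_counts,
                   enhanced = as.integer(enh))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 900, height = 420)
    on.exit(grDevices::dev.off())
    plot(df$sector, df$value, type = "l", xlab = "sector (deg)",
         ylab = "normalised intensity", main = "Radial profile")
    if (!is.null(quant)) {
      graphics::abline(h = quant$threshold, lty = 2)
      on_sec <- which(enh %in% TRUE) - 1L
      graphics::points(on_sec, df$value[on_sec + 1L], col = "darkgreen", pch = 16,
                       cex = 0.6)
    }
  }
  invisible(path)
}
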