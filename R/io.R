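#' Read a short-axis image (NIfTI-1, TIFF or PNG)
#'
#' Integer pixel data round-trip losslessly: 16-bit TIFF and 8-bit PNG are
#' returned on their native integer scales (0..65535 / 0..255), NIfTI on its
#' stored scale. Downstream quantification is invariant to affine intensity
#' scaling because normalisation is min-max over the ROI. Metadata
#' (subject, modality, slice) is recovered from the filename pattern
#' `<subject>_<modality>_s<slice>.<ext>` when it matches.
#'
#' @param path Image file path.
#' @param format `"auto"` (by extension), `"nifti"`, `"tiff"` or `"png"`.
#' @return A [short_axis_image()], or a list of them when a 3D NIfTI volume
#'   is read (one per slice).
#' @export
read_image <- function(path, format = c("auto", "nifti", "tiff", "png")) {
  format <- match.arg(format)
  if (!file.exists(path)) fail("read_image: no such file: %s", path)
  if (format == "auto") format <- guess_format(path)
  meta <- parse_image_filename(basename(path))
  px <- switch(format,
    nifti = {
      arr <- tryCatch(as.array(RNifti::readNifti(path)),
                      error = function(e)
                        fail("read_image: cannot parse %s as NIfTI: %s",
                             path, conditionMessage(e)))
      arr
    },
    tiff = tryCatch(round(tiff::readTIFF(path, as.is = TRUE)),
                    error = function(e)
                      fail("read_image: cannot parse %s as TIFF: %s",
                           path, conditionMessage(e))),
    png = tryCatch(round(png::readPNG(path) * 255),
                   error = function(e)
                     fail("read_image: cannot parse %s as PNG: %s",
                          path, conditionMessage(e)))
  )
  if (length(dim(px)) == 3 && dim(px)[3] > 1) {
    return(lapply(seq_len(dim(px)[3]), function(s)
      short_axis_image(px[, , s], subject_id = meta$subject,
                       slice_index = s, modality = meta$modality)))
  }
  if (length(dim(px)) == 3) px <- px[, , 1]
  short_axis_image(px, subject_id = meta$subject,
                   slice_index = meta$slice, modality = meta$modality)
}

#' Write a short-axis image
#'
#' NIfTI stores intensities exactly (float64). TIFF is written 16-bit and PNG
#' 8-bit; integer inputs on the full native scale (0..65535 / 0..255) are
#' stored losslessly, values in `[0, 1]` are quantised to the bit depth.
#'
#' @param image A [short_axis_image()] or numeric matrix.
#' @param path Output path; format chosen by extension unless given.
#' @param format `"auto"`, `"nifti"`, `"tiff"` or `"png"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, format = c("auto", "nifti", "tiff", "png")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  px <- if (inherits(image, "short_axis_image")) image$pixels else image
  switch(format,
    nifti = RNifti::writeNifti(RNifti::asNifti(px), path, datatype = "double"),
    tiff = {
      scaled <- if (max(px) > 2) px / 65535 else pmin(pmax(px, 0), 1)
      tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
    },
    png = {
      scaled <- if (max(px) > 2) px / 255 else pmin(pmax(px, 0), 1)
      png::writePNG(scaled, path)
    }
  )
  invisible(path)
}

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else if (grepl("\\.tiff?$", low)) "tiff"
  else if (grepl("\\.png$", low)) "png"
  else fail("unrecognised image extension: %s", path)
}

parse_image_filename <- function(name) {
  m <- regmatches(name,
    regexec("^(.+)_([^_]+)_s([0-9]+)\\.(nii(\\.gz)?|tiff?|png)$", name))[[1]]
  if (length(m) == 0)
    return(list(subject = NA_character_, modality = NA_character_,
                slice = NA_integer_))
  list(subject = m[2], modality = m[3], slice = as.integer(m[4]))
}

image_filename <- function(subject, modality, slice, ext = "nii") {
  sprintf("%s_%s_s%d.%s", subject, modality, slice, ext)
}

#' Read myocardial contours from CSV
#'
#' Expects columns `subject, slice, structure, point_index, x, y` with
#' `structure` in `{epi, endo}`; vertices are ordered by `point_index` and
#' assembled into one [contour_set()] per `(subject, slice)`.
#'
#' @param path CSV path.
#' @return Named list of `contour_set`, names `"<subject>:<slice>"`.
#' @export
read_contours <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject", "slice", "structure", "point_index", "x", "y")
  if (!all(req %in% names(df)))
    fail("read_contours: %s must have columns %s", path,
         paste(req, collapse = ", "))
  if (!all(df$structure %in% c("epi", "endo")))
    fail("read_contours: structure must be 'epi' or 'endo'")
  out <- list()
  for (key in unique(paste(df$subject, df$slice, sep = ":"))) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    sub <- df[df$subject == parts[1] & df$slice == as.integer(parts[2]), ]
    epi <- sub[sub$structure == "epi", ]
    endo <- sub[sub$structure == "endo", ]
    if (nrow(epi) == 0 || nrow(endo) == 0)
      fail("read_contours: slice %s is missing an %s contour", key,
           if (nrow(epi) == 0) "epicardial" else "endocardial")
    epi <- epi[order(epi$point_index), ]
    endo <- endo[order(endo$point_index), ]
    out[[key]] <- contour_set(cbind(x = epi$x, y = epi$y),
                              cbind(x = endo$x, y = endo$y))
  }
  out
}

#' Write contours to CSV
#'
#' Inverse of [read_contours()].
#'
#' @param contours Named list of [contour_set()], names `"<subject>:<slice>"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  rows <- list()
  for (key in names(contours)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    cs <- contours[[key]]
    for (st in c("epi", "endo")) {
      p <- if (st == "epi") cs$epicardium else cs$endocardium
      rows[[length(rows) + 1L]] <- data.frame(
        subject = parts[1], slice = as.integer(parts[2]), structure = st,
        point_index = seq_len(nrow(p)), x = p[, 1], y = p[, 2],
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a study results table as TSV
#'
#' One row per (subject, slice, modality, method); numeric columns are
#' serialised at full precision. Header comment lines (prefixed `#`) may
#' carry provenance (seed, package version) and are skipped on read.
#'
#' @param rows data.frame (long-format study table).
#' @param path Output TSV path.
#' @param comments Character vector of provenance lines, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study results table written by [write_results_table()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a binary mask as an inspectable PNG (0/255)
#'
#' @param mask Logical matrix or [myocardial_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "myocardial_mask")) mask$mask else mask
  png::writePNG(m * 1, path)
  invisible(path)
}

#' Read a 0/255 (or 0/1) mask PNG back as a logical matrix
#'
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  png::readPNG(path) > 0.5
}
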