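#' Pipeline run configuration
#'
#' Assembles and validates the configuration shared by the pipeline steps.
#' Every field can come from a YAML file (see [load_config()]) and be
#' overridden programmatically or by CLI flags.
#'
#' @param out_dir Output directory (created if absent).
#' @param images_dir Directory of input/output images (default
#'   `file.path(out_dir, "images")`).
#' @param masks_dir Directory of mask PNGs (default
#'   `file.path(out_dir, "masks")`).
#' @param table Path of the study results TSV (default
#'   `file.path(out_dir, "study_table.tsv")`).
#' @param seed Integer seed for all randomness.
#' @param n_subjects,slices_per_subject,border_margin_deg,cross_modality_rho,noise_sigma
#'   Study-generator settings (see [study_spec()]).
#' @param polarity_map Named character vector, modality -> "hyper"/"hypo";
#'   default from [default_modalities()].
#' @param methods Quantification methods, subset of
#'   `c("area", "sector", "midline", "truth")` or `"all"`.
#' @param bins,sector_bins,angle_offset Thresholding/sector settings.
#' @param format Image format for simulated output: "nifti", "tiff" or "png".
#' @param qc_figures Emit per-slice QC figures (histogram + radial profile).
#' @param allow_empty Exit cleanly on an empty input set.
#' @param verbose Print progress messages.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir = "cmrquant_out", images_dir = NULL,
                       masks_dir = NULL, table = NULL, seed = 1L,
                       n_subjects = 14, slices_per_subject = 4,
                       border_margin_deg = 15, cross_modality_rho = 0.5,
                       noise_sigma = 0.05,
                       polarity_map = NULL, methods = "all",
                       bins = 256, sector_bins = 64, angle_offset = 0,
                       format = c("nifti", "tiff", "png"),
                       qc_figures = FALSE, allow_empty = FALSE,
                       verbose = TRUE) {
  format <- match.arg(format)
  if (identical(methods, "all")) methods <- c("area", "sector", "midline", "truth")
  methods <- match.arg(methods, c("area", "sector", "midline", "truth"),
                       several.ok = TRUE)
  if (is.null(polarity_map)) {
    dm <- default_modalities()
    polarity_map <- stats::setNames(dm$polarity, dm$name)
  }
  if (!all(polarity_map %in% c("hyper", "hypo")))
    fail("run_config: every modality's polarity must be 'hyper' or 'hypo'")
  cfg <- list(out_dir = out_dir,
              images_dir = images_dir %||% file.path(out_dir, "images"),
              masks_dir = masks_dir %||% file.path(out_dir, "masks"),
              table = table %||% file.path(out_dir, "study_table.tsv"),
              seed = as.integer(seed), n_subjects = n_subjects,
              slices_per_subject = slices_per_subject,
              border_margin_deg = border_margin_deg,
              cross_modality_rho = cross_modality_rho,
              noise_sigma = noise_sigma,
              polarity_map = polarity_map, methods = methods,
              bins = bins, sector_bins = sector_bins,
              angle_offset = angle_offset, format = format,
              qc_figures = isTRUE(qc_figures),
              allow_empty = isTRUE(allow_empty), verbose = isTRUE(verbose))
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `overrides` (e.g. parsed CLI
#' flags) take precedence over the file.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @param overrides Named list of overriding values.
#' @return A `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      fail("load_config: the 'yaml' package is required to read config files")
    if (!file.exists(path)) fail("load_config: no such config file: %s", path)
    vals <- yaml::read_yaml(path)
    if (!is.null(vals$polarity_map))
      vals$polarity_map <- unlist(vals$polarity_map)
  }
  for (nm in names(overrides))
    if (!is.null(overrides[[nm]])) vals[[nm]] <- overrides[[nm]]
  do.call(run_config, vals)
}

config_fingerprint <- function(cfg) {
  # exclude paths and verbosity: the fingerprint identifies the scientific
  # configuration, so identical analyses in different directories match
  flat <- cfg[setdiff(names(cfg),
                      c("verbose", "out_dir", "images_dir", "masks_dir",
                        "table"))]
  substr(tools::md5sum(local({
    f <- tempfile()
    writeLines(paste(names(flat), vapply(flat, function(v)
      paste(format(v), collapse = ","), character(1)), sep = "="), f)
    f
  })), 1, 12)
}

provenance_lines <- function(cfg) {
  c(sprintf("cmrquant %s", as.character(utils::packageVersion("cmrquant"))),
    sprintf("seed=%d", cfg$seed),
    sprintf("config=%s", unname(config_fingerprint(cfg))))
}

say <- function(cfg, ...) if (cfg$verbose) message(sprintf(...))

#' Pipeline step 1: simulate a study to disk
#'
#' Generates the seeded synthetic study of [generate_study()] and writes one
#' image file per subject x slice x modality (named
#' `<subject>_<modality>_s<slice>.<ext>`), per-slice myocardium and lesion
#' mask PNGs, and the ground-truth TSV `truth.tsv`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the file manifest and the truth table.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$images_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(cfg$masks_dir, recursive = TRUE, showWarnings = FALSE)
  dm <- default_modalities()
  dm <- dm[dm$name %in% names(cfg$polarity_map), , drop = FALSE]
  dm$polarity <- unname(cfg$polarity_map[dm$name])
  spec <- study_spec(n_subjects = cfg$n_subjects,
                     slices_per_subject = cfg$slices_per_subject,
                     modalities = dm,
                     border_margin_deg = cfg$border_margin_deg,
                     cross_modality_rho = cfg$cross_modality_rho,
                     noise_sigma = cfg$noise_sigma, seed = cfg$seed)
  say(cfg, "simulate: seed=%d, %d subjects x %d slices x %d modalities",
      cfg$seed, spec$n_subjects, spec$slices_per_subject, nrow(dm))
  study <- generate_study(spec)
  ext <- switch(cfg$format, nifti = "nii", tiff = "tif", png = "png")
  files <- character(length(study$images))
  for (i in seq_along(study$images)) {
    img <- study$images[[i]]
    fn <- image_filename(img$subject_id, img$modality, img$slice_index, ext)
    write_image(img, file.path(cfg$images_dir, fn), format = cfg$format)
    files[i] <- fn
    tr <- study$truths[[i]]
    base <- sub(paste0("\\.", ext, "$"), "", fn)
    write_mask_png(tr$myocardium_mask,
                   file.path(cfg$masks_dir, paste0(base, "_myo.png")))
    write_mask_png(tr$lesion_mask,
                   file.path(cfg$masks_dir, paste0(base, "_lesion.png")))
  }
  write_results_table(study$truth_table, file.path(cfg$out_dir, "truth.tsv"),
                      comments = provenance_lines(cfg))
  say(cfg, "simulate: wrote %d images to %s", length(files), cfg$images_dir)
  invisible(list(files = files, truth_table = study$truth_table))
}

#' Pipeline step 2: quantify a directory of images
#'
#' Reads every image in `cfg$images_dir` (metadata from the filename
#' pattern), pairs it with its myocardium mask PNG in `cfg$masks_dir`, runs
#' [quantify_study()] for the configured methods, and writes the long-format
#' study table. Images with no mask are skipped with a warning.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the study table data.frame.
#' @export
run_quantify <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  paths <- list.files(cfg$images_dir, pattern = "\\.(nii|nii\\.gz|tif|tiff|png)$",
                      full.names = TRUE)
  images <- list(); rois <- list(); truths <- list()
  n_skipped <- 0L
  for (p in sort(paths)) {
    meta <- parse_image_filename(basename(p))
    if (is.na(meta$subject)) { n_skipped <- n_skipped + 1L; next }
    base <- sub("\\.(nii|nii\\.gz|tif|tiff|png)$", "", basename(p))
    myo_p <- file.path(cfg$masks_dir, paste0(base, "_myo.png"))
    if (!file.exists(myo_p)) {
      warning(sprintf("run_quantify: no mask for %s; skipped", basename(p)))
      n_skipped <- n_skipped + 1L
      next
    }
    images[[length(images) + 1L]] <- read_image(p)
    rois[[length(rois) + 1L]] <- myocardial_mask(read_mask_png(myo_p))
    les_p <- file.path(cfg$masks_dir, paste0(base, "_lesion.png"))
    truths[[length(truths) + 1L]] <- if (file.exists(les_p)) {
      lm <- read_mask_png(les_p)
      structure(list(lesion_mask = lm,
                     myocardium_mask = rois[[length(rois)]]$mask,
                     true_fraction_area =
                       100 * sum(lm) / rois[[length(rois)]]$n_pixels,
                     true_fraction_angle = NA_real_),
                class = "ground_truth")
    } else NULL
  }
  if (length(images) == 0) {
    if (cfg$allow_empty) {
      tab <- data.frame(subject = character(), slice = integer(),
                        modality = character(), method = character(),
                        enhancement_pct = numeric(), threshold = numeric(),
                        n_total = integer(), n_enhanced = integer())
      write_results_table(tab, cfg$table, comments = provenance_lines(cfg))
      warning("run_quantify: no quantifiable images found (empty table written)")
      return(invisible(tab))
    }
    fail("run_quantify: no quantifiable images in %s", cfg$images_dir)
  }
  methods <- cfg$methods
  have_truth <- !any(vapply(truths, is.null, logical(1)))
  if (!have_truth) methods <- intersect(methods, c("area", "sector"))
  tab <- quantify_study(images, rois, cfg$polarity_map, methods = methods,
                        truths = if (have_truth) truths else NULL,
                        n_bins = cfg$bins, sector_bins = cfg$sector_bins,
                        angle_offset = cfg$angle_offset)
  write_results_table(tab, cfg$table, comments = provenance_lines(cfg))
  if (cfg$qc_figures) write_qc_figures(cfg, images, rois)
  say(cfg, "quantify: %d rows (%d images, %d skipped) -> %s",
      nrow(tab), length(images), n_skipped, cfg$table)
  invisible(tab)
}

write_qc_figures <- function(cfg, images, rois) {
  qc_dir <- file.path(cfg$out_dir, "qc")
  dir.create(qc_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(images)) {
    img <- images[[i]]
    q <- quantify_slice(img, rois[[i]], cfg$polarity_map[[img$modality]],
                        n_bins = cfg$bins, sector_bins = cfg$sector_bins,
                        angle_offset = cfg$angle_offset)
    base <- sprintf("%s_%s_s%d", img$subject_id, img$modality,
                    img$slice_index)
    grDevices::png(file.path(qc_dir, paste0(base, "_qc.png")),
                   width = 960, height = 420)
    graphics::par(mfrow = c(1, 2))
    plot(q, "histogram")
    plot(q, "profile")
    grDevices::dev.off()
    radial_profile_export(q$sector$profile, q$sector$quant,
                          file.path(qc_dir, paste0(base, "_profile.tsv")))
  }
}

#' Pipeline step 3: statistical comparison report
#'
#' Reads the study table, runs [compare_study()], and writes the report
#' tables (`report_anova.tsv`, `report_tukey.tsv`, `report_agreement.tsv`,
#' `report_correlations.tsv`, `report_truth.tsv`) plus a human-readable
#' `report.txt` into `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @param table_path Study-table TSV (default `cfg$table`).
#' @return Invisibly, the [compare_study()] result.
#' @export
run_compare <- function(cfg, table_path = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  table_path <- table_path %||% cfg$table
  tab <- read_results_table(table_path)
  if (nrow(tab) == 0) {
    if (cfg$allow_empty) {
      warning("run_compare: empty study table; nothing to compare")
      return(invisible(NULL))
    }
    fail("run_compare: study table %s is empty", table_path)
  }
  cmp <- compare_study(tab)
  tabs <- comparison_tables(cmp)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    write_results_table(tabs[[nm]],
                        file.path(cfg$out_dir, sprintf("report_%s.tsv", nm)),
                        comments = provenance_lines(cfg))
  }
  txt <- file.path(cfg$out_dir, "report.txt")
  con <- file(txt, "w")
  writeLines(paste0("# ", provenance_lines(cfg)), con)
  sink(con); print(cmp); sink()
  close(con)
  say(cfg, "compare: report written to %s", cfg$out_dir)
  invisible(cmp)
}

#' Run the full simulate -> quantify -> compare pipeline
#'
#' Deterministic under `cfg$seed`: re-running with the same configuration
#' reproduces every output file byte for byte.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the [compare_study()] result.
#' @export
run_pipeline <- function(cfg) {
  run_simulate(cfg)
  run_quantify(cfg)
  run_compare(cfg)
}
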