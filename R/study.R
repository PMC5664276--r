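#' Default modality table
#'
#' Three contrast mechanisms as used in small-animal infarct imaging: late
#' gadolinium enhancement (LGE, infarct hyperintense), manganese-enhanced MRI
#' (MEMRI, infarct hypointense because Mn2+ only enters viable myocytes) and
#' iron-oxide nanoparticle MRI (MNP, inflamed tissue hypointense). Mean and SD
#' of the transmural wedge span are chosen so that span/360 reproduces
#' typical per-slice enhancement percentages for each mechanism (infarct
#' around 41-44% of the LV, inflammation around 57% once the border margin is
#' added).
#'
#' @return A data.frame with columns `name`, `polarity`, `mean_span_deg`,
#'   `sd_span_deg`.
#' @export
default_modalities <- function() {
  data.frame(
    name = c("LGE", "MEMRI", "MNP"),
    polarity = c("hyper", "hypo", "hypo"),
    mean_span_deg = c(147, 159, 176),
    sd_span_deg = c(42, 54, 36),
    stringsAsFactors = FALSE
  )
}

#' Multi-subject synthetic study specification
#'
#' Describes a cohort: `n_subjects` animals, each imaged with every modality
#' on `slices_per_subject` short-axis slices. Per subject, wedge spans for
#' the modalities are drawn from a Gaussian copula with pairwise correlation
#' `cross_modality_rho`; the inflammation modality's wedge is the drawn wedge
#' widened by `border_margin_deg` on each side (the peri-infarct zone where
#' macrophages accumulate), capped at 360 degrees. A per-slice span
#' perturbation, shared across modalities within a slice, emulates
#' apex-to-base variation of lesion extent.
#'
#' @param n_subjects Number of subjects.
#' @param slices_per_subject Slices per subject (default 4, the slices below
#'   the mid-ventricular level).
#' @param modalities Modality table as from [default_modalities()]: columns
#'   `name`, `polarity` (`"hyper"` or `"hypo"`), `mean_span_deg`,
#'   `sd_span_deg`.
#' @param inflammation_modality Name of the modality that images the
#'   inflammatory border zone rather than the necrotic core.
#' @param border_margin_deg Degrees added per side to the inflammation
#'   modality's wedge; `>= 0`.
#' @param cross_modality_rho Target pairwise correlation of subject-level
#'   wedge spans across modalities, in `[-1, 1]`.
#' @param slice_sd_span_deg SD (degrees) of the shared per-slice span
#'   perturbation.
#' @param transmurality Wedge transmurality in `(0, 1]`.
#' @param image_size,r_endo,r_epi Phantom geometry (pixels).
#' @param background_level Background intensity.
#' @param contrast Absolute myocardium-lesion intensity difference; levels are
#'   placed at `0.5 +/- contrast/2` with the sign set by each modality's
#'   polarity.
#' @param noise_sigma Rician noise scale.
#' @param seed Integer seed; the whole study is a deterministic function of it.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(n_subjects = 14, slices_per_subject = 4,
                       modalities = default_modalities(),
                       inflammation_modality = "MNP",
                       border_margin_deg = 15, cross_modality_rho = 0.5,
                       slice_sd_span_deg = 10, transmurality = 1,
                       image_size = 256, r_endo = 40, r_epi = 60,
                       background_level = 0.1, contrast = 0.4,
                       noise_sigma = 0.05, seed = 1L) {
  if (slices_per_subject < 1) fail("study_spec: slices_per_subject must be >= 1")
  if (border_margin_deg < 0) fail("study_spec: border_margin_deg must be >= 0")
  if (abs(cross_modality_rho) > 1)
    fail("study_spec: cross_modality_rho must lie in [-1, 1]")
  req <- c("name", "polarity", "mean_span_deg", "sd_span_deg")
  if (!all(req %in% names(modalities)))
    fail("study_spec: modalities needs columns %s", paste(req, collapse = ", "))
  if (!all(modalities$polarity %in% c("hyper", "hypo")))
    fail("study_spec: polarity must be 'hyper' or 'hypo'")
  if (!is.null(inflammation_modality) &&
      !inflammation_modality %in% modalities$name)
    fail("study_spec: inflammation_modality '%s' not in modality table",
         inflammation_modality)
  structure(
    list(n_subjects = as.integer(n_subjects),
         slices_per_subject = as.integer(slices_per_subject),
         modalities = modalities,
         inflammation_modality = inflammation_modality,
         border_margin_deg = border_margin_deg,
         cross_modality_rho = cross_modality_rho,
         slice_sd_span_deg = slice_sd_span_deg,
         transmurality = transmurality,
         image_size = as.integer(image_size),
         r_endo = r_endo, r_epi = r_epi,
         background_level = background_level, contrast = contrast,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "study_spec"
  )
}

# Draw n rows of k equicorrelated standard normals (Gaussian copula driver).
equicorrelated_normals <- function(n, k, rho) {
  sigma <- matrix(rho, k, k)
  diag(sigma) <- 1
  # nearest chol-able matrix; equicorrelation is PD for rho in (-1/(k-1), 1)
  l <- tryCatch(chol(sigma), error = function(e)
    fail("generate_study: correlation %s not positive definite for %d modalities",
         format(rho), k))
  z <- matrix(stats::rnorm(n * k), n, k)
  z %*% l
}

#' Draw the wedge-span schedule of a study
#'
#' The stochastic core of [generate_study()], exposed so the sampler can be
#' validated directly: subject-level spans per modality from the Gaussian
#' copula (clamped to `[1, 360]` degrees), subject centre angles, the shared
#' per-slice span perturbation, and per-phantom noise seeds. Deterministic
#' under `spec$seed`.
#'
#' @param spec A [study_spec()].
#' @return A list with `spans` (`n_subjects x n_modalities`, degrees, before
#'   slice perturbation and border widening), `centers`, `slice_jit`
#'   (`n_subjects x slices_per_subject`) and `noise_seeds`.
#' @export
study_spans <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  mods <- spec$modalities
  k <- nrow(mods)
  ns <- spec$n_subjects
  nsl <- spec$slices_per_subject
  with_seed(spec$seed, {
    z <- equicorrelated_normals(ns, k, spec$cross_modality_rho)
    spans <- sweep(sweep(z, 2, mods$sd_span_deg, `*`), 2,
                   mods$mean_span_deg, `+`)
    list(
      spans = pmin(pmax(spans, 1), 360),
      centers = stats::runif(ns, 0, 360),
      slice_jit = matrix(stats::rnorm(ns * nsl, 0, spec$slice_sd_span_deg),
                         ns, nsl),
      noise_seeds = matrix(sample.int(.Machine$integer.max, ns * nsl * k),
                           ns, nsl * k)
    )
  })
}

#' Generate a full synthetic study
#'
#' Draws subject-level wedge spans across modalities from a Gaussian copula
#' (spans clamped to `[1, 360]` degrees), widens the inflammation modality's
#' wedge by the border margin, applies a shared per-slice span perturbation,
#' and rasterises one phantom per subject x slice x modality. All wedges of a
#' subject share a common centre angle so the three modalities image the same
#' physical lesion.
#'
#' @param spec A [study_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{images}{List of [short_axis_image()], one per
#'       subject x slice x modality.}
#'     \item{truths}{Parallel list of `ground_truth` objects.}
#'     \item{truth_table}{data.frame with columns `subject`, `slice`,
#'       `modality`, `polarity`, `true_area_pct`, `true_angle_pct`, `seed`.}
#'   }
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  mods <- spec$modalities
  k <- nrow(mods)
  ns <- spec$n_subjects
  nsl <- spec$slices_per_subject

  draws <- study_spans(spec)

  half_contrast <- spec$contrast / 2
  images <- vector("list", ns * nsl * k)
  truths <- vector("list", ns * nsl * k)
  rows <- vector("list", ns * nsl * k)
  idx <- 0L
  for (i in seq_len(ns)) {
    for (s in seq_len(nsl)) {
      for (m in seq_len(k)) {
        span <- draws$spans[i, m] + draws$slice_jit[i, s]
        if (!is.null(spec$inflammation_modality) &&
            mods$name[m] == spec$inflammation_modality)
          span <- span + 2 * spec$border_margin_deg
        span <- min(max(span, 1), 360)
        start <- (draws$centers[i] - span / 2) %% 360
        hyper <- mods$polarity[m] == "hyper"
        ps <- phantom_spec(
          image_size = spec$image_size,
          r_endo = spec$r_endo, r_epi = spec$r_epi,
          wedges = list(lesion_wedge(start, span, spec$transmurality)),
          background_level = spec$background_level,
          myocardium_level = if (hyper) 0.5 - half_contrast else 0.5 + half_contrast,
          lesion_level = if (hyper) 0.5 + half_contrast else 0.5 - half_contrast,
          noise_sigma = spec$noise_sigma,
          seed = draws$noise_seeds[i, (s - 1L) * k + m]
        )
        ph <- generate_phantom(ps, subject_id = sprintf("sub%02d", i),
                               slice_index = s, modality = mods$name[m])
        idx <- idx + 1L
        images[[idx]] <- ph$image
        truths[[idx]] <- ph$truth
        rows[[idx]] <- data.frame(
          subject = sprintf("sub%02d", i), slice = s,
          modality = mods$name[m], polarity = mods$polarity[m],
          true_area_pct = ph$truth$true_fraction_area,
          true_angle_pct = ph$truth$true_fraction_angle,
          seed = spec$seed, stringsAsFactors = FALSE
        )
      }
    }
  }
  list(images = images, truths = truths,
       truth_table = do.call(rbind, rows))
}
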