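#' Short-axis image container
#'
#' A single 2D grayscale short-axis slice with acquisition metadata. Pixels
#' are stored as a numeric matrix indexed `[y + 1, x + 1]` with 0-based
#' pixel-centre coordinates (x = column, y = row).
#'
#' @param pixels Numeric matrix of nonnegative, finite intensities.
#' @param pixel_spacing Pixel size in mm (default 30/256, a 30 mm field of
#'   view on a 256 matrix).
#' @param subject_id,slice_index,modality Metadata labels.
#' @return An object of class `short_axis_image`.
#' @export
short_axis_image <- function(pixels, pixel_spacing = 30 / 256,
                             subject_id = NA_character_,
                             slice_index = NA_integer_,
                             modality = NA_character_) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    fail("short_axis_image: pixel intensities must be finite numerics")
  # drop any reader-specific attributes (NIfTI headers etc.)
  pixels <- matrix(as.numeric(pixels), nrow(pixels), ncol(pixels))
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing,
         subject_id = as.character(subject_id),
         slice_index = as.integer(slice_index),
         modality = as.character(modality)),
    class = "short_axis_image"
  )
}

#' @export
print.short_axis_image <- function(x, ...) {
  cat(sprintf("<short_axis_image> %dx%d px, %.4f mm/px, subject=%s modality=%s slice=%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing,
              x$subject_id, x$modality, x$slice_index))
  invisible(x)
}

#' Transmural wedge lesion descriptor
#'
#' An angular wedge of lesion within the myocardial annulus. Angles follow
#' the package convention: 0 degrees along the +x image axis, increasing with
#' +y, membership on the half-open interval `[start_angle, start_angle + span)`.
#' Transmurality is the occupied fraction of wall thickness measured from the
#' endocardium outward.
#'
#' @param start_angle Degrees in `[0, 360)`.
#' @param span Degrees in `(0, 360]`.
#' @param transmurality Fraction of wall thickness in `(0, 1]`.
#' @return An object of class `lesion_wedge`.
#' @export
lesion_wedge <- function(start_angle, span, transmurality = 1) {
  if (!is.numeric(span) || span <= 0 || span > 360)
    fail("lesion_wedge: span must lie in (0, 360], got %s", format(span))
  if (!is.numeric(transmurality) || transmurality <= 0 || transmurality > 1)
    fail("lesion_wedge: transmurality must lie in (0, 1], got %s",
         format(transmurality))
  structure(list(start_angle = start_angle %% 360, span = span,
                 transmurality = transmurality),
            class = "lesion_wedge")
}

#' Phantom geometry and contrast specification
#'
#' Describes one synthetic short-axis slice: an annular left-ventricular
#' myocardium between `r_endo` and `r_epi` centred at `center`, carrying zero
#' or more wedge lesions, on a uniform background, with optional Rician
#' magnitude noise.
#'
#' @param image_size Square image side in pixels.
#' @param center LV centre `(x, y)` in pixel coordinates; default image centre.
#' @param r_endo,r_epi Endocardial and epicardial radii in pixels;
#'   `0 < r_endo < r_epi < image_size / 2`.
#' @param wedges List of [lesion_wedge()] objects.
#' @param background_level,myocardium_level,lesion_level Normalised
#'   intensities in `[0, 1]`.
#' @param noise_sigma Rician noise scale on the normalised intensity scale
#'   (standard deviation of each Gaussian channel); `>= 0`.
#' @param seed Integer seed for the noise draw, or `NULL`.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(image_size = 256, center = NULL,
                         r_endo = 40, r_epi = 60, wedges = list(),
                         background_level = 0.1, myocardium_level = 0.3,
                         lesion_level = 0.7, noise_sigma = 0, seed = NULL) {
  center <- center %||% c((image_size - 1) / 2, (image_size - 1) / 2)
  if (!(r_endo > 0))
    fail("phantom_spec: invariant 0 < r_endo violated (r_endo = %s)", format(r_endo))
  if (!(r_endo < r_epi))
    fail("phantom_spec: invariant r_endo < r_epi violated (%s >= %s)",
         format(r_endo), format(r_epi))
  if (!(r_epi < image_size / 2))
    fail("phantom_spec: invariant r_epi < image_size/2 violated (%s >= %s)",
         format(r_epi), format(image_size / 2))
  levels <- c(background_level, myocardium_level, lesion_level)
  if (any(levels < 0 | levels > 1))
    fail("phantom_spec: intensity levels must lie in [0, 1]")
  if (noise_sigma < 0)
    fail("phantom_spec: noise_sigma must be >= 0, got %s", format(noise_sigma))
  if (inherits(wedges, "lesion_wedge")) wedges <- list(wedges)
  for (w in wedges)
    if (!inherits(w, "lesion_wedge")) fail("phantom_spec: wedges must be lesion_wedge objects")
  structure(
    list(image_size = as.integer(image_size), center = center,
         r_endo = r_endo, r_epi = r_epi, wedges = wedges,
         background_level = background_level,
         myocardium_level = myocardium_level, lesion_level = lesion_level,
         noise_sigma = noise_sigma, seed = seed),
    class = "phantom_spec"
  )
}

#' Generate one synthetic short-axis phantom slice with ground truth
#'
#' Rasterises the annular myocardium and its wedge lesions by pixel-centre
#' polar classification, paints the three intensity levels, and applies
#' Rician noise last. The returned ground-truth masks are noise-free.
#'
#' @param spec A [phantom_spec()].
#' @param subject_id,slice_index,modality Metadata propagated to the image.
#' @return A list with components:
#'   \describe{
#'     \item{image}{[short_axis_image()] (noisy when `noise_sigma > 0`).}
#'     \item{truth}{A `ground_truth` list: `lesion_mask`, `myocardium_mask`
#'       (logical matrices, lesion always a subset of myocardium),
#'       `true_fraction_area` (lesion pixels / myocardium pixels, percent)
#'       and `true_fraction_angle` (union of wedge spans / 360, percent).}
#'   }
#' @examples
#' ph <- generate_phantom(phantom_spec(wedges = lesion_wedge(0, 90)))
#' ph$truth$true_fraction_angle   # 25
#' @export
generate_phantom <- function(spec, subject_id = NA, slice_index = NA,
                             modality = NA) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  g <- pixel_grid(n)
  r <- sqrt((g$x - spec$center[1])^2 + (g$y - spec$center[2])^2)
  theta <- pixel_angle_deg(g$x, g$y, spec$center)

  myo <- r >= spec$r_endo & r <= spec$r_epi
  lesion <- matrix(FALSE, n, n)
  wall <- spec$r_epi - spec$r_endo
  for (w in spec$wedges) {
    r_out <- spec$r_endo + w$transmurality * wall
    lesion <- lesion |
      (myo & r <= r_out & angle_in_wedge(theta, w$start_angle, w$span))
  }

  img <- matrix(spec$background_level, n, n)
  img[myo] <- spec$myocardium_level
  img[lesion] <- spec$lesion_level
  if (spec$noise_sigma > 0)
    img <- add_rician_noise(img, spec$noise_sigma, seed = spec$seed)

  n_myo <- sum(myo)
  truth <- structure(
    list(lesion_mask = lesion, myocardium_mask = myo,
         true_fraction_area = if (n_myo > 0) 100 * sum(lesion) / n_myo else NA_real_,
         true_fraction_angle = 100 * angular_union_deg(
           vapply(spec$wedges, `[[`, numeric(1), "start_angle"),
           vapply(spec$wedges, `[[`, numeric(1), "span")) / 360),
    class = "ground_truth"
  )
  list(
    image = short_axis_image(img, subject_id = subject_id,
                             slice_index = slice_index, modality = modality),
    truth = truth
  )
}

#' Add Rician magnitude noise to an image
#'
#' Models magnitude-MR noise: the output is the magnitude of the input signal
#' plus a complex Gaussian perturbation with standard deviation `sigma` per
#' channel, `sqrt((v + n1)^2 + n2^2)`. `sigma = 0` returns the input
#' unchanged; an identical seed reproduces the draw bit for bit.
#'
#' @param image A [short_axis_image()] or numeric matrix.
#' @param sigma Noise scale (per-channel Gaussian SD) on the intensity scale;
#'   must be `>= 0`.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Same type as `image`.
#' @export
add_rician_noise <- function(image, sigma, seed = NULL) {
  if (!is.numeric(sigma) || sigma < 0)
    fail("add_rician_noise: sigma must be >= 0, got %s", format(sigma))
  px <- if (inherits(image, "short_axis_image")) image$pixels else image
  if (sigma > 0) {
    noisy <- with_seed(seed, {
      n1 <- stats::rnorm(length(px), 0, sigma)
      n2 <- stats::rnorm(length(px), 0, sigma)
      sqrt((px + n1)^2 + n2^2)
    })
    px <- matrix(noisy, nrow(px), ncol(px))
  }
  if (inherits(image, "short_axis_image")) {
    image$pixels <- px
    image
  } else px
}
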