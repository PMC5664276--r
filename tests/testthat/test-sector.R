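wedge_phantom <- function(span, start = 0, contrast_level = 0.7, sigma = 0,
                          seed = NULL) {
  generate_phantom(phantom_spec(wedges = lesion_wedge(start, span, 1),
                                lesion_level = contrast_level,
                                noise_sigma = sigma, seed = seed))
}

test_that("a uniform annulus yields 360 equal sector values", {
  ph <- generate_phantom(phantom_spec())
  prof <- sector_values(ph$image, ph$truth$myocardium_mask,
                        center = c(127.5, 127.5))
  expect_length(prof$values, 360)
  expect_true(all(prof$values == 0.5))  # degenerate normalisation
  expect_true(prof$degenerate)
  expect_error(sector_quantify(prof, "hyper"), "no threshold")
})

test_that("sector pixel counts conserve the myocardium pixel count", {
  ph <- wedge_phantom(120, 33)
  prof <- sector_values(ph$image, ph$truth$myocardium_mask,
                        center = c(127.5, 127.5))
  expect_equal(sum(prof$pixel_counts), sum(ph$truth$myocardium_mask))
})

test_that("sector assignment agrees with a per-pixel atan2 oracle", {
  ph <- wedge_phantom(90, 10)
  m <- ph$truth$myocardium_mask
  ctr <- c(127.5, 127.5)
  prof <- sector_values(ph$image, m, center = ctr)
  idx <- which(m, arr.ind = TRUE)
  ang <- (atan2(idx[, 1] - 1 - ctr[2], idx[, 2] - 1 - ctr[1]) * 180 / pi) %% 360
  oracle_counts <- tabulate(floor(ang) + 1L, nbins = 360)
  expect_equal(prof$pixel_counts, oracle_counts)
})

test_that("a 90-degree wedge elevates 90 +/- 2 sectors", {
  ph <- wedge_phantom(90, 200)
  prof <- sector_values(ph$image, ph$truth$myocardium_mask,
                        center = c(127.5, 127.5))
  mid <- (min(prof$values) + max(prof$values)) / 2
  n_hi <- sum(prof$values > mid)
  expect_gte(n_hi, 88)
  expect_lte(n_hi, 92)
})

test_that("rotating the image by 90 degrees rotates the profile by 90 sectors", {
  ph <- wedge_phantom(75, 15)
  ctr <- c(127.5, 127.5)
  rot90 <- function(m) t(m)[, ncol(m):1]   # +90 deg about the grid centre
  prof <- sector_values(ph$image$pixels, ph$truth$myocardium_mask,
                        center = ctr)
  prof_r <- sector_values(rot90(ph$image$pixels),
                          rot90(ph$truth$myocardium_mask), center = ctr)
  # values at sector k of the rotated image = values at sector k - 90
  expect_equal(prof_r$values, c(prof$values[271:360], prof$values[1:270]))
  expect_equal(prof_r$pixel_counts,
               c(prof$pixel_counts[271:360], prof$pixel_counts[1:270]))
})

test_that("sector Otsu reproduces the two-level worked example", {
  prof <- structure(list(values = c(rep(0.9, 90), rep(0.2, 270)),
                         pixel_counts = rep(10L, 360),
                         center = c(0, 0), angle_offset = 0,
                         degenerate = FALSE),
                    class = "sector_profile")
  sq <- sector_quantify(prof, "hyper")
  expect_equal(sq$fraction, 25)
  expect_equal(sq$enhanced_sectors, 90)
  expect_equal(sq$valid_sectors, 360)
  sq2 <- sector_quantify(prof, "hypo")
  expect_equal(sq2$fraction, 75)
})

test_that("a noiseless 144-degree wedge measures 40% by sectors", {
  ph <- wedge_phantom(144, 100)
  q <- quantify_slice(ph$image, ph$truth$myocardium_mask, "hyper",
                      methods = "sector", center = c(127.5, 127.5))
  expect_lt(abs(q$sector$enhancement_pct - 40), 1)
})

test_that("empty sectors are excluded and too many of them abort", {
  # half annulus: mask only where x > centre
  ph <- wedge_phantom(90)
  m <- ph$truth$myocardium_mask
  m[, 1:128] <- FALSE
  expect_error(sector_values(ph$image, m, center = c(127.5, 127.5)),
               "empty")
  # off-image centre
  expect_error(sector_values(ph$image, ph$truth$myocardium_mask,
                             center = c(-5, 10)), "outside")
})

test_that("radial profiles export, flag enhanced sectors, and round-trip", {
  ph <- wedge_phantom(144, 100)
  prof <- sector_values(ph$image, ph$truth$myocardium_mask,
                        center = c(127.5, 127.5))
  sq <- sector_quantify(prof, "hyper")
  p <- tempfile(fileext = ".tsv")
  radial_profile_export(prof, sq, p)
  back <- utils::read.delim(p)
  expect_equal(nrow(back), 360)
  expect_equal(sum(back$enhanced, na.rm = TRUE), sq$enhanced_sectors)
  expect_lt(max(abs(back$value - prof$values), na.rm = TRUE), 1e-6)
})
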