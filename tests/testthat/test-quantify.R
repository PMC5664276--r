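test_that("quantify_slice recovers hyper- and hypoenhanced wedges alike", {
  for (pol in c("hyper", "hypo")) {
    lev <- if (pol == "hyper") c(0.3, 0.7) else c(0.7, 0.3)
    ph <- generate_phantom(phantom_spec(
      wedges = lesion_wedge(250, 108, 1),
      myocardium_level = lev[1], lesion_level = lev[2]))
    q <- quantify_slice(ph$image, ph$truth$myocardium_mask, pol,
                        center = c(127.5, 127.5))
    expect_lt(abs(q$area$enhancement_pct - 30), 1)
    expect_lt(abs(q$sector$enhancement_pct - 30), 1)
    expect_s3_class(q, "lesion_quant")
  }
})

test_that("summary.lesion_quant emits tidy per-method rows", {
  ph <- generate_phantom(phantom_spec(wedges = lesion_wedge(0, 90)))
  img <- ph$image
  img$subject_id <- "m01"; img$slice_index <- 2L; img$modality <- "LGE"
  q <- quantify_slice(img, ph$truth$myocardium_mask, "hyper",
                      center = c(127.5, 127.5))
  s <- summary(q)
  expect_equal(s$method, c("area", "sector"))
  expect_equal(unique(s$subject), "m01")
  expect_true(all(c("enhancement_pct", "threshold", "n_total",
                    "n_enhanced") %in% names(s)))
})

test_that("quantify_slice accepts contours as the ROI", {
  ph <- generate_phantom(phantom_spec(wedges = lesion_wedge(0, 180)))
  cs <- contour_set(circle_polygon(127.5, 127.5, 60),
                    circle_polygon(127.5, 127.5, 40))
  q <- quantify_slice(ph$image, cs, "hyper", methods = "area")
  expect_lt(abs(q$area$enhancement_pct - 50), 2)
})

test_that("quantify_study stacks rows and appends midline/truth when truths exist", {
  spec <- study_spec(n_subjects = 1, slices_per_subject = 2,
                     image_size = 128, r_endo = 20, r_epi = 32,
                     noise_sigma = 0, seed = 13)
  st <- generate_study(spec)
  pol <- setNames(default_modalities()$polarity, default_modalities()$name)
  rois <- lapply(st$truths, function(t) myocardial_mask(t$myocardium_mask))
  tab <- quantify_study(st$images, rois, pol,
                        methods = c("area", "sector", "midline", "truth"),
                        truths = st$truths)
  expect_equal(nrow(tab), length(st$images) * 4)
  expect_setequal(unique(tab$method), c("area", "sector", "midline", "truth"))
  # noiseless: every estimate within 1.5 points of its slice's truth
  key <- paste(tab$subject, tab$slice, tab$modality)
  tr <- tab[tab$method == "truth", ]
  for (m in c("area", "sector", "midline")) {
    est <- tab[tab$method == m, ]
    truth <- tr$enhancement_pct[match(paste(est$subject, est$slice,
                                            est$modality),
                                      paste(tr$subject, tr$slice,
                                            tr$modality))]
    expect_lt(max(abs(est$enhancement_pct - truth)), 1.5)
  }

  expect_error(quantify_study(st$images, rois, pol, methods = "midline"),
               "ground truths")
  expect_error(quantify_study(st$images, rois, c(BAD = "hyper")),
               "polarity")
})

test_that("compare_study assembles all sections on a complete table", {
  spec <- study_spec(n_subjects = 4, slices_per_subject = 2,
                     image_size = 128, r_endo = 20, r_epi = 32,
                     noise_sigma = 0, seed = 5)
  st <- generate_study(spec)
  pol <- setNames(default_modalities()$polarity, default_modalities()$name)
  rois <- lapply(st$truths, function(t) myocardial_mask(t$myocardium_mask))
  tab <- quantify_study(st$images, rois, pol,
                        methods = c("area", "sector", "truth"),
                        truths = st$truths)
  cmp <- compare_study(tab)
  expect_s3_class(cmp, "study_comparison")
  expect_true(all(c("area", "sector") %in% names(cmp$anova)))
  expect_true("pooled" %in% names(cmp$agreement))
  expect_gt(length(cmp$cross), 0)
  expect_true(all(c("area", "sector") %in% names(cmp$truth)))
  # area vs sector agree tightly on noiseless phantoms
  expect_lt(abs(cmp$agreement$pooled$bias), 1)
  tabs <- comparison_tables(cmp)
  expect_true(all(c("anova", "tukey", "agreement", "correlations", "truth")
                  %in% names(tabs)))
  expect_output(print(cmp), "Method agreement")
})

test_that("compare_study degrades gracefully with a single method", {
  tab <- data.frame(subject = rep(sprintf("s%d", 1:6), each = 3),
                    slice = 1L,
                    modality = rep(c("LGE", "MEMRI", "MNP"), 6),
                    method = "area",
                    enhancement_pct = runif(18, 20, 80))
  cmp <- compare_study(tab)
  expect_length(cmp$agreement, 0)
  expect_true(any(grepl("Bland-Altman", cmp$notes)))
  expect_true("area" %in% names(cmp$anova))
})
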