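test_that("Bland-Altman matches hand arithmetic and its invariants", {
  ba <- bland_altman(c(10, 20, 30), c(12, 18, 33))
  # d = (-2, 2, -3): bias -1, sd sqrt(7)
  expect_equal(ba$bias, -1, tolerance = 1e-12)
  expect_equal(ba$sd_diff, sqrt(7), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1 - 1.96 * sqrt(7), tolerance = 1e-12)
  expect_equal(ba$loa_high, -1 + 1.96 * sqrt(7), tolerance = 1e-12)
  expect_equal(ba$n_pairs, 3)

  # identical pairs
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))

  # antisymmetry
  set.seed(2)
  a <- runif(10, 0, 100); b <- runif(10, 0, 100)
  f <- bland_altman(a, b); r <- bland_altman(b, a)
  expect_equal(r$bias, -f$bias, tolerance = 1e-12)
  expect_equal(r$loa_low, -f$loa_high, tolerance = 1e-12)
  expect_equal(r$loa_high, -f$loa_low, tolerance = 1e-12)

  expect_error(bland_altman(1, 2), "2 complete pairs")
})

test_that("correlations match closed forms and the stats package", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$r, 1)
  expect_equal(correlate(x, c(1, 3, 2, 4), "spearman")$r, 0.8,
               tolerance = 1e-12)

  set.seed(8)
  for (i in 1:5) {
    xr <- rnorm(20); yr <- 0.5 * xr + rnorm(20)
    cp <- correlate(xr, yr, "pearson")
    ref <- stats::cor.test(xr, yr)
    expect_equal(cp$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(cp$p_value, ref$p.value, tolerance = 1e-6)
    expect_equal(cp$ci95, as.numeric(ref$conf.int), tolerance = 1e-6)

    cs <- correlate(xr, yr, "spearman")
    refs <- stats::cor.test(xr, yr, method = "spearman", exact = FALSE)
    expect_equal(cs$r, unname(refs$estimate), tolerance = 1e-12)
  }

  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlate(1:2, 1:2), "3 complete pairs")
})

test_that("spearman uses average ranks for ties", {
  x <- c(1, 2, 2, 4, 5)
  y <- c(2, 1, 4, 4, 6)
  got <- correlate(x, y, "spearman")$r
  ref <- stats::cor(rank(x), rank(y))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("OLS matches lm and its band widens away from the mean", {
  expect_equal(linear_fit(c(0, 1, 2), c(0, 1, 2))$slope, 1)
  expect_equal(linear_fit(c(0, 1, 2), c(0, 1, 2))$intercept, 0)

  set.seed(3)
  x <- runif(30, 0, 10); y <- 3 + 1.7 * x + rnorm(30)
  fit <- linear_fit(x, y)
  ref <- stats::lm(y ~ x)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-12)
  expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-12)
  x0 <- seq(0, 10, by = 0.5)
  band <- fit$band(x0)
  refb <- stats::predict(ref, data.frame(x = x0), interval = "confidence")
  expect_equal(band$fit, unname(refb[, "fit"]), tolerance = 1e-10)
  expect_equal(band$lwr, unname(refb[, "lwr"]), tolerance = 1e-10)
  expect_equal(band$upr, unname(refb[, "upr"]), tolerance = 1e-10)

  # width minimal at xbar, monotone on either side
  w <- band$upr - band$lwr
  widths_left <- w[x0 <= mean(x)]
  widths_right <- w[x0 >= mean(x)]
  expect_true(all(diff(widths_left) <= 1e-12))
  expect_true(all(diff(widths_right) >= -1e-12))
  expect_error(linear_fit(1:2, 1:2), "3 points")
})

make_table <- function(y) {
  # y: n x k matrix -> long study table
  n <- nrow(y); k <- ncol(y)
  data.frame(subject = rep(sprintf("s%02d", rep(1:(n / 2), each = 2)), k),
             slice = rep(rep(1:2, n / 2), k),
             modality = rep(LETTERS[1:k], each = n),
             method = "area",
             enhancement_pct = pmin(pmax(as.vector(y), 0), 100))
}

test_that("repeated-measures ANOVA agrees with aov's within-unit error stratum", {
  set.seed(12)
  y <- matrix(rnorm(30 * 3, 45, 10), 30, 3)
  y[, 3] <- y[, 3] + 5
  tab <- make_table(y)
  got <- paired_modalities_test(tab)
  df <- tab
  df$unit <- paste(df$subject, df$slice)
  ref <- stats::aov(enhancement_pct ~ modality + Error(unit),
                    data = df)
  refsum <- summary(ref)[["Error: Within"]][[1]]
  expect_equal(got$F, refsum["modality", "F value"], tolerance = 1e-10)
  expect_equal(got$p_value, refsum["modality", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(got$df, unname(refsum$Df))
  expect_true(all(got$tukey$p_adj >= 0 & got$tukey$p_adj <= 1))
  expect_true(is.finite(got$shapiro_p))
})

test_that("identical modality columns give F ~ 0 and Tukey p ~ 1", {
  y <- matrix(rep(rnorm(20, 50, 8), 3), 20, 3)
  got <- paired_modalities_test(make_table(y))
  expect_lt(got$F, 1e-8)
  expect_gt(min(got$tukey$p_adj), 0.999)
})

test_that("a +15 point offset on one modality is detected with high power", {
  set.seed(55)
  hits <- 0L
  for (r in 1:100) {
    y <- matrix(rnorm(56 * 3, 45, 5), 56, 3)
    y[, 2] <- y[, 2] + 15
    got <- paired_modalities_test(make_table(y))
    ps <- got$tukey$p_adj[grepl("B", got$tukey$contrast)]
    if (all(ps < 0.001)) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("incomplete blocks are dropped listwise with a warning", {
  y <- matrix(rnorm(20 * 3, 50, 5), 20, 3)
  tab <- make_table(y)
  tab <- tab[-c(1, 25), ]   # break two units
  expect_warning(got <- paired_modalities_test(tab), "incomplete")
  expect_equal(got$n_units, 18)
  expect_equal(got$n_dropped, 2)
})

test_that("subject-level aggregation reduces the repeated unit to subjects", {
  set.seed(9)
  y <- matrix(rnorm(20 * 3, 50, 5), 20, 3)
  got <- paired_modalities_test(make_table(y), subject_level = TRUE)
  expect_equal(got$n_units, 10)   # 20 slices over 10 subjects
  expect_equal(got$unit, "subject")
})
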