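#' Bland-Altman method agreement
#'
#' Classical limits-of-agreement analysis of paired measurements: bias is the
#' mean of the differences `a - b`, and the limits of agreement are
#' `bias +/- 1.96 * SD` of the differences (sample SD, `n - 1` denominator).
#'
#' @param a,b Paired numeric vectors (e.g. enhancement percentages by two
#'   methods); `n >= 2`.
#' @return An object of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `n_pairs`, plus the per-pair `means` and `diffs` for
#'   plotting.
#' @examples
#' ba <- bland_altman(c(10, 20, 30), c(12, 18, 33))
#' ba$bias       # -1
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) fail("bland_altman: a and b differ in length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) fail("bland_altman: need at least 2 complete pairs, got %d", n)
  d <- a - b
  bias <- mean(d)
  sd_d <- sqrt(sum((d - bias)^2) / (n - 1))
  structure(list(bias = bias, loa_low = bias - 1.96 * sd_d,
                 loa_high = bias + 1.96 * sd_d, sd_diff = sd_d, n_pairs = n,
                 means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias = %.3f, limits of agreement [%.3f, %.3f]\n",
              x$n_pairs, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods",
                              ylab = "difference", ...) {
  plot(x$means, x$diffs, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high), lty = c(2, 1, 2))
  invisible(x)
}

# average ranks with ties (midranks)
midranks <- function(v) rank(v, ties.method = "average")

#' Pearson or Spearman correlation from closed forms
#'
#' Pearson is the product-moment coefficient; Spearman is Pearson applied to
#' midranks. The two-sided p-value uses the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df; for Pearson a 95%
#' confidence interval is obtained by the Fisher z transform.
#'
#' @param x,y Numeric vectors, `n >= 3`, finite, non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return An object of class `correlation_result`: `r`, `p_value`, `method`,
#'   `n`, `ci95` (Pearson only, else `NULL`).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) fail("correlate: x and y differ in length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) fail("correlate: need at least 3 complete pairs, got %d", n)
  if (method == "spearman") { x <- midranks(x); y <- midranks(y) }
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    fail("correlate: zero variance; correlation undefined")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(min(r, 1), -1)
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  ci <- NULL
  if (method == "pearson" && n > 3 && abs(r) < 1) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  structure(list(r = r, p_value = p, method = method, n = n, ci95 = ci),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation (n = %d): r = %.4f, p = %.4g%s\n",
              tools::toTitleCase(x$method), x$n, x$r, x$p_value,
              if (!is.null(x$ci95))
                sprintf(", 95%% CI [%.4f, %.4f]", x$ci95[1], x$ci95[2])
              else ""))
  invisible(x)
}

#' Ordinary least-squares line with pointwise confidence band
#'
#' Closed-form simple linear regression. The 95% band is the pointwise
#' confidence interval of the mean response,
#' `yhat(x0) +/- t(0.975, n-2) * s * sqrt(1/n + (x0 - xbar)^2 / Sxx)`,
#' narrowest at `xbar` and widening monotonically away from it.
#'
#' @param x,y Numeric vectors, `n >= 3`.
#' @return An object of class `linear_fit`: `slope`, `intercept`, `sigma`
#'   (residual SE), `n`, `r_squared`, and `band(x0)` - a function returning a
#'   data.frame `fit/lwr/upr` at new x values.
#' @export
linear_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) fail("linear_fit: need at least 3 points, got %d", n)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) fail("linear_fit: x is constant")
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  res <- y - (intercept + slope * x)
  rss <- sum(res^2)
  sigma <- sqrt(rss / (n - 2))
  tss <- sum((y - ybar)^2)
  band <- function(x0) {
    se <- sigma * sqrt(1 / n + (x0 - xbar)^2 / sxx)
    tcrit <- stats::qt(0.975, df = n - 2)
    fit <- intercept + slope * x0
    data.frame(x = x0, fit = fit, lwr = fit - tcrit * se,
               upr = fit + tcrit * se)
  }
  structure(list(slope = slope, intercept = intercept, sigma = sigma, n = n,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 xbar = xbar, sxx = sxx, band = band, residuals = res),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): y = %.4f + %.4f x, R^2 = %.4f, sigma = %.4f\n",
              x$n, x$intercept, x$slope, x$r_squared, x$sigma))
  invisible(x)
}

#' @export
predict.linear_fit <- function(object, newdata, ...) {
  object$band(newdata)
}
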