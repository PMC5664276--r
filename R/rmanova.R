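#' Repeated-measures comparison of modalities
#'
#' One-way repeated-measures ANOVA of enhancement percentages across
#' modalities, with the slice (subject x slice pair) as the repeated unit -
#' each slice is imaged by every modality, so modality is a within-unit
#' factor. Pairwise modality contrasts use Tukey's studentised-range test on
#' the within-unit error term. A Shapiro-Wilk test of the within-unit
#' residuals is reported alongside as the normality check. Units missing any
#' modality are dropped listwise with a warning.
#'
#' The classical decomposition for n complete units and k modalities:
#' `SS_total = SS_units + SS_modality + SS_error`, with
#' `F = MS_modality / MS_error` on `(k - 1, (k - 1)(n - 1))` df.
#'
#' @param table Long-format study table with columns `subject`, `slice`,
#'   `modality` and `enhancement_pct` (a `method` column, if present, must be
#'   filtered to one method first or passed via `method`).
#' @param method Optional value of the `method` column to select (e.g.
#'   `"area"`).
#' @param subject_level If `TRUE`, slices are first averaged within subject
#'   so the subject is the repeated unit (slices within an animal are not
#'   independent; the per-slice analysis treats them as such).
#' @return An object of class `paired_comparison`: `group_means` (mean, sd, n
#'   per modality), `F`, `df`, `p_value`, `tukey` (data.frame of pairwise
#'   contrasts with Tukey-adjusted p), `shapiro_p`, `n_units`,
#'   `n_dropped`.
#' @export
paired_modalities_test <- function(table, method = NULL,
                                   subject_level = FALSE) {
  df <- as.data.frame(table)
  if (!is.null(method) && "method" %in% names(df))
    df <- df[df$method == method, ]
  req <- c("subject", "slice", "modality", "enhancement_pct")
  if (!all(req %in% names(df)))
    fail("paired_modalities_test: table needs columns %s",
         paste(req, collapse = ", "))
  if (subject_level) {
    agg <- stats::aggregate(enhancement_pct ~ subject + modality, df, mean)
    agg$slice <- 1L
    df <- agg
  }
  df$unit <- paste(df$subject, df$slice, sep = ":")
  mods <- sort(unique(df$modality))
  k <- length(mods)
  if (k < 2) fail("paired_modalities_test: need >= 2 modalities, got %d", k)
  wide <- stats::reshape(
    df[, c("unit", "modality", "enhancement_pct")],
    idvar = "unit", timevar = "modality", direction = "wide")
  y <- as.matrix(wide[, paste0("enhancement_pct.", mods), drop = FALSE])
  complete <- stats::complete.cases(y)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    warning(sprintf("paired_modalities_test: dropped %d incomplete unit(s)",
                    n_dropped))
  y <- y[complete, , drop = FALSE]
  n <- nrow(y)
  if (n < 2) fail("paired_modalities_test: fewer than 2 complete units")

  fit <- rm_anova_fit(y)
  mod_means <- colMeans(y)
  group_means <- data.frame(
    modality = mods, mean = mod_means,
    sd = apply(y, 2, stats::sd), n = n, row.names = NULL)

  # Tukey HSD on the within-unit error term
  se <- sqrt(fit$ms_error / n)
  pairs <- utils::combn(k, 2)
  tukey <- data.frame(
    contrast = apply(pairs, 2, function(p) paste(mods[p[2]], "-", mods[p[1]])),
    diff = apply(pairs, 2, function(p) mod_means[p[2]] - mod_means[p[1]]),
    stringsAsFactors = FALSE)
  tukey$q <- if (se > 0) abs(tukey$diff) / se else
    ifelse(abs(tukey$diff) > 0, Inf, 0)
  tukey$p_adj <- stats::ptukey(tukey$q, nmeans = k, df = fit$df_error,
                               lower.tail = FALSE)

  resid <- y - rowMeans(y) -
    matrix(mod_means, n, k, byrow = TRUE) + mean(y)
  shapiro_p <- tryCatch(stats::shapiro.test(as.vector(resid))$p.value,
                        error = function(e) NA_real_)

  structure(
    list(group_means = group_means, F = fit$F,
         df = c(fit$df_modality, fit$df_error), p_value = fit$p,
         tukey = tukey, shapiro_p = shapiro_p,
         n_units = n, n_dropped = n_dropped,
         unit = if (subject_level) "subject" else "slice"),
    class = "paired_comparison"
  )
}

# Closed-form one-way RM-ANOVA on an n x k complete matrix.
rm_anova_fit <- function(y) {
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  ss_units <- k * sum((rowMeans(y) - grand)^2)
  ss_mod <- n * sum((colMeans(y) - grand)^2)
  ss_err <- ss_total - ss_units - ss_mod
  df_mod <- k - 1
  df_err <- (k - 1) * (n - 1)
  ms_mod <- ss_mod / df_mod
  ms_err <- ss_err / df_err
  f <- if (ms_err > 0) ms_mod / ms_err else ifelse(ms_mod > 0, Inf, 0)
  list(F = f, p = stats::pf(f, df_mod, df_err, lower.tail = FALSE),
       df_modality = df_mod, df_error = df_err,
       ms_modality = ms_mod, ms_error = ms_err,
       ss = c(units = ss_units, modality = ss_mod, error = ss_err))
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%s as unit, n = %d):\n", x$unit,
              x$n_units))
  gm <- x$group_means
  for (i in seq_len(nrow(gm)))
    cat(sprintf("  %-8s %6.1f +/- %.1f %%\n", gm$modality[i], gm$mean[i],
                gm$sd[i]))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g (Shapiro-Wilk residual p = %.3g)\n",
              x$df[1], x$df[2], x$F, x$p_value, x$shapiro_p))
  cat("  Tukey contrasts:\n")
  for (i in seq_len(nrow(x$tukey)))
    cat(sprintf("    %-16s diff = %7.2f, p_adj = %.4g\n",
                x$tukey$contrast[i], x$tukey$diff[i], x$tukey$p_adj[i]))
  invisible(x)
}
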