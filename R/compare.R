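#' Full statistical comparison of a study table
#'
#' Reproduces the standard comparison battery on a long-format study table:
#' \itemize{
#'   \item per method, modality means +/- SD with repeated-measures ANOVA and
#'     Tukey contrasts (slice as repeated unit);
#'   \item method agreement: Bland-Altman of area- versus sector-based
#'     percentages, per modality and pooled;
#'   \item cross-modality association: Pearson and Spearman correlation and
#'     an OLS fit of each infarct modality against the inflammation modality,
#'     per method;
#'   \item when `truth` rows are present, per-modality agreement of every
#'     estimated method against ground truth (correlation + mean absolute
#'     error).
#' }
#' Sections whose inputs are missing (a single method, a single modality) are
#' omitted with a notice in `$notes`.
#'
#' @param table data.frame with columns `subject`, `slice`, `modality`,
#'   `method`, `enhancement_pct`.
#' @param inflammation_modality Modality treated as the inflammation marker
#'   for cross-modality correlations (default `"MNP"`; skipped when absent).
#' @param subject_level Passed to [paired_modalities_test()].
#' @return An object of class `study_comparison`.
#' @export
compare_study <- function(table, inflammation_modality = "MNP",
                          subject_level = FALSE) {
  df <- as.data.frame(table)
  req <- c("subject", "slice", "modality", "method", "enhancement_pct")
  if (!all(req %in% names(df)))
    fail("compare_study: table needs columns %s", paste(req, collapse = ", "))
  notes <- character()
  est_methods <- intersect(c("area", "sector", "midline"),
                           unique(df$method))
  modalities <- sort(unique(df$modality))

  # modality comparison per estimated method
  anova <- list()
  for (m in setdiff(est_methods, "midline")) {
    sub <- df[df$method == m, ]
    if (length(unique(sub$modality)) >= 2 && nrow(sub) >= 4) {
      anova[[m]] <- paired_modalities_test(sub, subject_level = subject_level)
    } else notes <- c(notes, sprintf(
      "modality comparison for method '%s' skipped: <2 modalities", m))
  }

  key <- function(d) paste(d$subject, d$slice, d$modality, sep = ":")

  # Bland-Altman area vs sector
  agreement <- list()
  if (all(c("area", "sector") %in% est_methods)) {
    a <- df[df$method == "area", ]
    s <- df[df$method == "sector", ]
    s <- s[match(key(a), key(s)), ]
    ok <- !is.na(s$enhancement_pct)
    agreement$pooled <- bland_altman(a$enhancement_pct[ok],
                                     s$enhancement_pct[ok])
    for (mod in modalities) {
      sel <- ok & a$modality == mod
      if (sum(sel) >= 2)
        agreement[[mod]] <- bland_altman(a$enhancement_pct[sel],
                                         s$enhancement_pct[sel])
    }
  } else notes <- c(notes,
    "Bland-Altman section omitted: needs both area and sector methods")

  # cross-modality correlations per method
  cross <- list()
  if (inflammation_modality %in% modalities && length(modalities) >= 2) {
    for (m in est_methods) {
      sub <- df[df$method == m, ]
      infl <- sub[sub$modality == inflammation_modality, ]
      for (mod in setdiff(modalities, inflammation_modality)) {
        oth <- sub[sub$modality == mod, ]
        oth <- oth[match(paste(infl$subject, infl$slice),
                         paste(oth$subject, oth$slice)), ]
        ok <- !is.na(oth$enhancement_pct)
        if (sum(ok) >= 3) {
          nm <- sprintf("%s:%s_vs_%s", m, mod, inflammation_modality)
          x <- oth$enhancement_pct[ok]
          y <- infl$enhancement_pct[ok]
          cross[[nm]] <- list(
            pearson = correlate(x, y, "pearson"),
            spearman = correlate(x, y, "spearman"),
            fit = linear_fit(x, y))
        }
      }
    }
  } else notes <- c(notes, sprintf(
    "cross-modality correlations skipped: inflammation modality '%s' absent or <2 modalities",
    inflammation_modality))

  # agreement with ground truth
  truth_cmp <- list()
  if ("truth" %in% unique(df$method)) {
    tr <- df[df$method == "truth", ]
    for (m in est_methods) {
      sub <- df[df$method == m, ]
      trm <- tr[match(key(sub), key(tr)), ]
      ok <- !is.na(trm$enhancement_pct)
      if (sum(ok) >= 3) {
        est <- sub$enhancement_pct[ok]
        tru <- trm$enhancement_pct[ok]
        truth_cmp[[m]] <- list(
          spearman = correlate(est, tru, "spearman"),
          mae = mean(abs(est - tru)),
          bias = mean(est - tru), n = sum(ok))
      }
    }
  }

  structure(
    list(anova = anova, agreement = agreement, cross = cross,
         truth = truth_cmp, notes = notes, methods = est_methods,
         modalities = modalities, n_rows = nrow(df)),
    class = "study_comparison"
  )
}

#' @export
print.study_comparison <- function(x, ...) {
  cat(sprintf("<study_comparison> methods: %s | modalities: %s\n",
              paste(x$methods, collapse = ", "),
              paste(x$modalities, collapse = ", ")))
  for (m in names(x$anova)) {
    cat(sprintf("\n== Modality comparison (%s-based) ==\n", m))
    print(x$anova[[m]])
  }
  if (length(x$agreement) > 0) {
    cat("\n== Method agreement: area vs sector ==\n")
    for (nm in names(x$agreement)) {
      cat(sprintf("  [%s] ", nm)); print(x$agreement[[nm]])
    }
  }
  if (length(x$cross) > 0) {
    cat("\n== Cross-modality correlation ==\n")
    for (nm in names(x$cross)) {
      cat(sprintf("  [%s]\n    ", nm))
      print(x$cross[[nm]]$pearson)
      cat("    ")
      print(x$cross[[nm]]$spearman)
    }
  }
  if (length(x$truth) > 0) {
    cat("\n== Agreement with ground truth ==\n")
    for (nm in names(x$truth)) {
      t <- x$truth[[nm]]
      cat(sprintf("  %-8s MAE = %.2f pct pts, bias = %+.2f, Spearman r = %.3f (n = %d)\n",
                  nm, t$mae, t$bias, t$spearman$r, t$n))
    }
  }
  if (length(x$notes) > 0)
    cat("\nNotes:\n", paste(" -", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Flatten a study comparison into tidy report tables
#'
#' @param x A [compare_study()] result.
#' @return Named list of data.frames: `anova`, `tukey`, `agreement`,
#'   `correlations`, `truth`.
#' @export
comparison_tables <- function(x) {
  stopifnot(inherits(x, "study_comparison"))
  an <- do.call(rbind, lapply(names(x$anova), function(m) {
    a <- x$anova[[m]]
    cbind(method = m, a$group_means,
          F = a$F, p_value = a$p_value, shapiro_p = a$shapiro_p)
  }))
  tk <- do.call(rbind, lapply(names(x$anova), function(m)
    cbind(method = m, x$anova[[m]]$tukey)))
  ag <- do.call(rbind, lapply(names(x$agreement), function(nm) {
    b <- x$agreement[[nm]]
    data.frame(group = nm, bias = b$bias, loa_low = b$loa_low,
               loa_high = b$loa_high, n_pairs = b$n_pairs)
  }))
  cr <- do.call(rbind, lapply(names(x$cross), function(nm) {
    cc <- x$cross[[nm]]
    data.frame(comparison = nm,
               pearson_r = cc$pearson$r, pearson_p = cc$pearson$p_value,
               spearman_r = cc$spearman$r, spearman_p = cc$spearman$p_value,
               slope = cc$fit$slope, intercept = cc$fit$intercept,
               n = cc$pearson$n)
  }))
  tr <- do.call(rbind, lapply(names(x$truth), function(nm) {
    t <- x$truth[[nm]]
    data.frame(method = nm, mae = t$mae, bias = t$bias,
               spearman_r = t$spearman$r, spearman_p = t$spearman$p_value,
               n = t$n)
  }))
  list(anova = an, tukey = tk, agreement = ag, correlations = cr, truth = tr)
}
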