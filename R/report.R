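# End-to-end analysis of a cohort score table, mirroring the original
# report structure: normality screen, three Friedman omnibus tests
# (condition totals, first syllables, second syllables), pairwise
# post-hocs under Bonferroni, sex contrasts on all nine measures, and
# Spearman correlations between condition scores with shared variance.

MEASURES <- c("RH", "NR", "UnSc", "RH1", "RH2", "NR1", "NR2",
              "UnSc1", "UnSc2")

#' Run the full nonparametric analysis of a score table
#'
#' @param scores a `wrrc_scores` data.frame (one row per listener with the
#'   nine measures, `sex`, `listener_id`).
#' @param nominal_alpha nominal alpha; post-hoc and correlation families
#'   of three use `round(nominal_alpha / 3, 3)` under Bonferroni.
#' @param posthoc_method passed to [pairwise_posthoc()].
#' @return a `wrrc_analysis_report`: `normality` (data.frame),
#'   `omnibus` (named list of three `wrrc_test_result`s), `posthoc`
#'   (named list of data.frames, only for significant omnibus families),
#'   `sex_contrasts` (data.frame, 9 rows), `correlations` (data.frame
#'   with r_s, p, shared/unexplained variance), `alpha` settings.
#' @export
run_full_analysis <- function(scores, nominal_alpha = 0.05,
                              posthoc_method = "mann_whitney") {
  if (!all(c(MEASURES, "sex") %in% names(scores)))
    stop("score table lacks required columns", call. = FALSE)
  if (nrow(scores) < 2) stop("need at least 2 listeners", call. = FALSE)
  alpha3 <- round(nominal_alpha / 3, 3)

  normality <- do.call(rbind, lapply(MEASURES, function(mname) {
    ns <- normality_screen(scores[[mname]])
    data.frame(measure = mname, z_skew = ns$z_skew, z_kurt = ns$z_kurt,
               normal = ns$normal, stringsAsFactors = FALSE)
  }))

  fams <- list(total = c("RH", "NR", "UnSc"),
               syllable1 = c("RH1", "NR1", "UnSc1"),
               syllable2 = c("RH2", "NR2", "UnSc2"))
  omnibus <- lapply(fams, function(cols) {
    tr <- friedman(scores[, cols])
    tr$alpha <- nominal_alpha
    tr$significant <- tr$p_value < nominal_alpha
    tr
  })

  posthoc <- list()
  for (fam in names(fams)) {
    if (isTRUE(omnibus[[fam]]$significant)) {
      posthoc[[fam]] <- pairwise_posthoc(scores[, fams[[fam]]],
                                         nominal_alpha = nominal_alpha,
                                         method = posthoc_method)
    }
  }

  male <- scores[scores$sex == "male", ]
  female <- scores[scores$sex == "female", ]
  sex_contrasts <- do.call(rbind, lapply(MEASURES, function(mname) {
    tr <- mann_whitney(female[[mname]], male[[mname]])
    data.frame(measure = mname, U = tr$statistic, p_value = tr$p_value,
               alpha = nominal_alpha,
               significant = tr$p_value < nominal_alpha,
               direction = if (stats::median(female[[mname]]) >=
                               stats::median(male[[mname]]))
                 "female >= male" else "male > female",
               stringsAsFactors = FALSE)
  }))

  tot_pairs <- list(c("RH", "NR"), c("RH", "UnSc"), c("NR", "UnSc"))
  corr_rows <- lapply(tot_pairs, function(pr) {
    sp <- spearman_with_shared_variance(scores[[pr[1]]], scores[[pr[2]]])
    data.frame(pair = paste(pr, collapse = " vs "), level = "total",
               r_s = sp$r_s, p_value = sp$p_value,
               shared_pct = sp$shared_pct,
               unexplained_pct = sp$unexplained_pct,
               alpha_adj = alpha3, significant = sp$p_value < alpha3,
               stringsAsFactors = FALSE)
  })
  correlations <- do.call(rbind, corr_rows)
  # syllable-level follow-up of any total pair reaching uncorrected 0.05
  for (j in which(correlations$p_value < nominal_alpha)) {
    pr <- strsplit(correlations$pair[j], " vs ")[[1]]
    for (s in 1:2) {
      sp <- spearman_with_shared_variance(
        scores[[paste0(pr[1], s)]], scores[[paste0(pr[2], s)]])
      correlations <- rbind(correlations, data.frame(
        pair = paste0(pr[1], s, " vs ", pr[2], s),
        level = paste0("syllable", s), r_s = sp$r_s, p_value = sp$p_value,
        shared_pct = sp$shared_pct, unexplained_pct = sp$unexplained_pct,
        alpha_adj = alpha3, significant = sp$p_value < alpha3,
        stringsAsFactors = FALSE))
    }
  }

  structure(list(n = nrow(scores),
                 n_male = nrow(male), n_female = nrow(female),
                 normality = normality, omnibus = omnibus,
                 posthoc = posthoc, sex_contrasts = sex_contrasts,
                 correlations = correlations,
                 alpha = list(nominal = nominal_alpha,
                              bonferroni3 = alpha3)),
            class = "wrrc_analysis_report")
}

#' @export
print.wrrc_analysis_report <- function(x, ...) {
  cat(sprintf("== Analysis report (n = %d: %d male, %d female) ==\n",
              x$n, x$n_male, x$n_female))
  cat(sprintf("Normality screen: %d of %d measures within z in (-1.96, 1.96)\n",
              sum(x$normality$normal), nrow(x$normality)))
  cat("\nOmnibus (Friedman):\n")
  for (fam in names(x$omnibus)) {
    tr <- x$omnibus[[fam]]
    cat(sprintf("  %-10s chi2(%d) = %.3f, p = %.3f%s\n", fam, tr$df,
                tr$statistic, tr$p_value,
                if (isTRUE(tr$significant)) " *" else ""))
  }
  if (length(x$posthoc)) {
    cat(sprintf("\nPost-hoc pairs (alpha = %.3f):\n", x$alpha$bonferroni3))
    for (fam in names(x$posthoc)) {
      ph <- x$posthoc[[fam]]
      for (i in seq_len(nrow(ph)))
        cat(sprintf("  %-10s %-14s p = %.3f%s\n", fam, ph$pair[i],
                    ph$p_value[i], if (ph$significant[i]) " *" else ""))
    }
  }
  cat("\nSex contrasts (Mann-Whitney):\n")
  sc <- x$sex_contrasts
  for (i in seq_len(nrow(sc)))
    if (sc$significant[i])
      cat(sprintf("  %-6s U = %.1f, p = %.3f * (%s)\n", sc$measure[i],
                  sc$U[i], sc$p_value[i], sc$direction[i]))
  if (!any(sc$significant)) cat("  none significant\n")
  cat(sprintf("\nCorrelations (alpha = %.3f):\n", x$alpha$bonferroni3))
  co <- x$correlations
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-16s r_s = %+.3f, p = %.3f, shared %4.1f%%%s\n",
                co$pair[i], co$r_s[i], co$p_value[i], co$shared_pct[i],
                if (co$significant[i]) " *" else ""))
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report a `wrrc_analysis_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path) {
  stopifnot(inherits(report, "wrrc_analysis_report"))
  om <- lapply(report$omnibus, function(tr)
    list(statistic = tr$statistic, df = tr$df, p_value = tr$p_value,
         alpha = tr$alpha, significant = tr$significant))
  jsonlite::write_json(
    list(n = report$n, n_male = report$n_male, n_female = report$n_female,
         normality = report$normality, omnibus = om,
         posthoc = report$posthoc, sex_contrasts = report$sex_contrasts,
         correlations = report$correlations, alpha = report$alpha),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
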