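#' Descriptive group comparison between IFC and non-IFC pregnancies
#'
#' Produces the descriptive comparison table: continuous variables are
#' summarised as mean (SD) and median (IQR) per outcome group and compared
#' with the Mann-Whitney test (normal approximation with tie correction);
#' categorical variables are summarised as count (%) per level and compared
#' with the Pearson chi-square test without continuity correction (Fisher's
#' exact test available for small cells). Variables that are entirely
#' missing are skipped with a message.
#'
#' @param cohort Data frame with the logical outcome column `ifc`.
#' @param variables Character vector of columns to compare.
#' @param fisher_exact Use Fisher's exact test for categorical variables.
#' @return A tibble with one row per continuous variable and one row per
#'   level of each categorical variable: `variable`, `level`, `test`,
#'   formatted summaries `summary_no_ifc`, `summary_ifc`, the underlying
#'   numeric summaries, and `p_value`.
#' @export
compare_groups <- function(cohort, variables, fisher_exact = FALSE) {
  stopifnot("ifc" %in% names(cohort))
  g <- as.logical(cohort$ifc)
  rows <- purrr::map(variables, function(v) {
    if (!v %in% names(cohort)) {
      stop(sprintf("variable `%s` not in cohort", v), call. = FALSE)
    }
    x <- cohort[[v]]
    if (all(is.na(x))) {
      message(sprintf("skipping `%s`: all values missing", v))
      return(NULL)
    }
    if (is.numeric(x)) {
      p <- stats::wilcox.test(x[!g], x[g], exact = FALSE,
                              correct = FALSE)$p.value
      summarise_cont <- function(xx) {
        q <- stats::quantile(xx, c(0.25, 0.5, 0.75), na.rm = TRUE)
        list(mean = mean(xx, na.rm = TRUE), sd = stats::sd(xx, na.rm = TRUE),
             median = q[[2]], q25 = q[[1]], q75 = q[[3]])
      }
      s0 <- summarise_cont(x[!g])
      s1 <- summarise_cont(x[g])
      fmt <- function(s) sprintf("%.1f (%.1f); %.1f (%.1f, %.1f)",
                                 s$mean, s$sd, s$median, s$q25, s$q75)
      tibble::tibble(
        variable = v, level = NA_character_, test = "mann_whitney",
        summary_no_ifc = fmt(s0), summary_ifc = fmt(s1),
        mean_no_ifc = s0$mean, sd_no_ifc = s0$sd, median_no_ifc = s0$median,
        mean_ifc = s1$mean, sd_ifc = s1$sd, median_ifc = s1$median,
        p_value = p
      )
    } else {
      f <- factor(x)
      tab <- table(f, factor(g, levels = c(FALSE, TRUE)))
      p <- if (fisher_exact) {
        stats::fisher.test(tab)$p.value
      } else {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      }
      # a table with identical proportions has statistic 0 and p = 1
      purrr::map_dfr(levels(f), function(lev) {
        n0 <- tab[lev, "FALSE"]
        n1 <- tab[lev, "TRUE"]
        tibble::tibble(
          variable = v, level = lev, test = if (fisher_exact) "fisher" else "chi_square",
          summary_no_ifc = sprintf("%d (%.1f%%)", n0, 100 * n0 / sum(!g)),
          summary_ifc = sprintf("%d (%.1f%%)", n1, 100 * n1 / sum(g)),
          mean_no_ifc = NA_real_, sd_no_ifc = NA_real_,
          median_no_ifc = NA_real_, mean_ifc = NA_real_, sd_ifc = NA_real_,
          median_ifc = NA_real_, p_value = p
        )
      })
    }
  })
  dplyr::bind_rows(rows)
}
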