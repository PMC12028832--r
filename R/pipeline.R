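cohort_required_cols <- c("subject_id", "ga_scan20_wk", "ga_scan3t_wk",
                          "efw20_g", "efw3t_g", "ua_pi", "mca_pi", "ifc")

cohort_known_cols <- c(
  cohort_required_cols, "maternal_age", "maternal_height_cm",
  "maternal_weight_kg", "bmi", "nulliparous", "smoking", "fetal_sex",
  "interval_days", "ga_delivery_wk", "labor_onset", "birthweight_g",
  "apgar5", "cord_ph", "neonatal_disposition",
  paste0(rep(c("bpd", "hc", "ac", "fl"), 2), rep(c("20", "3t"), each = 4), "_cm")
)

#' Read and validate a cohort CSV
#'
#' Reads a one-row-per-pregnancy cohort file, checks the mandatory columns,
#' and applies row-level validation: positive EFW, pulsatility indices in
#' (0, 5), gestational ages in plausible ranges, examination-to-delivery
#' interval within 0--14 days (the inclusion criterion: delivery within two
#' weeks of the scan), and third-trimester scan not after delivery. Invalid
#' rows are rejected, each with the violated rule recorded; unknown columns
#' produce a warning but are kept.
#'
#' @param path Path to the CSV.
#' @return A tibble of accepted records, with attributes `n_accepted`,
#'   `n_rejected` and `problems` (a tibble of `row`, `problem`).
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(cohort_required_cols, names(raw))
  if (length(missing)) {
    stop("cohort file is missing mandatory columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), cohort_known_cols)
  if (length(unknown)) {
    warning("unknown cohort columns kept as-is: ",
            paste(unknown, collapse = ", "))
  }
  raw$ifc <- as.logical(raw$ifc)
  if ("interval_days" %in% names(raw)) {
    raw$interval_days <- as.integer(raw$interval_days)
  }

  problems <- list()
  flag <- function(bad, rule) {
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      problems[[length(problems) + 1]] <<-
        tibble::tibble(row = which(bad), problem = rule)
    }
    bad
  }
  bad <- flag(is.na(raw$ifc), "ifc missing") |
    flag(raw$efw20_g <= 0 | raw$efw3t_g <= 0, "EFW must be positive") |
    flag(raw$ua_pi <= 0 | raw$ua_pi >= 5 | raw$mca_pi <= 0 | raw$mca_pi >= 5,
         "pulsatility index must lie in (0, 5)") |
    flag(raw$ga_scan20_wk < 12 | raw$ga_scan20_wk > 43 |
           raw$ga_scan3t_wk < 12 | raw$ga_scan3t_wk > 43,
         "gestational age must lie in [12, 43] weeks")
  if ("interval_days" %in% names(raw)) {
    bad <- bad | flag(raw$interval_days < 0 | raw$interval_days > 14,
                      "interval_days must lie in [0, 14]")
  }
  if ("ga_delivery_wk" %in% names(raw)) {
    bad <- bad | flag(raw$ga_scan3t_wk > raw$ga_delivery_wk,
                      "third-trimester scan after delivery")
  }
  out <- raw[!bad, ]
  attr(out, "n_accepted") <- nrow(out)
  attr(out, "n_rejected") <- sum(bad)
  attr(out, "problems") <- if (length(problems)) {
    dplyr::arrange(dplyr::bind_rows(problems), .data$row)
  } else {
    tibble::tibble(row = integer(), problem = character())
  }
  out
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

write_stamped_tsv <- function(x, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  # fixed-format numbers so identical runs give identical bytes
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.numeric), ~ ifelse(is.na(.x), NA, sprintf("%.6g", .x))
  ))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Run the full IFC prediction analysis
#'
#' Executes the whole analysis on a cohort: per-pregnancy growth/Doppler
#' assessment, descriptive group comparison, the univariable screen, the
#' eight predefined multivariable logistic models, ROC analysis of every
#' model, and the AIC ranking. When `cohort` is `NULL`, a synthetic cohort is
#' generated from `spec` with the given seed. Results are returned and,
#' when `out_dir` is given, written as a reproducible bundle:
#' `table1.tsv` (group comparison), `table2.tsv` (univariable screen),
#' `table3.tsv`/`table4.tsv` (MCA- and CPR-based multivariable models,
#' term level), `table5.tsv` (AIC ranking with detection rates),
#' `roc/<model>.tsv` (threshold, fpr, tpr) and `run_metadata.json`. Every
#' table carries a header comment with the seed and a config fingerprint.
#' If a stage fails, partial outputs are removed and the error names the
#' stage.
#'
#' @param cohort A cohort tibble (e.g. from [read_cohort()]), or `NULL` to
#'   simulate one from `spec`.
#' @param spec A [cohort_spec()], used only when `cohort` is `NULL`.
#' @param seed Integer seed (mandatory; stamps the bundle even when no
#'   simulation is involved).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param refs Reference curves.
#' @param enforce_windows,fisher_exact Passed through to [assess_growth()]
#'   and [compare_groups()].
#' @return An object of class `ifc_report`: list with the assessed cohort,
#'   `table1` ... `table5`, the fitted models (`fits`), and `metadata`.
#' @export
run_ifc_pipeline <- function(cohort = NULL, spec = cohort_spec(), seed,
                             out_dir = NULL, refs = default_references(),
                             enforce_windows = TRUE, fisher_exact = FALSE) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written, recursive = TRUE)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (is.null(cohort)) {
    cohort <- stage("simulate", simulate_cohort(spec, seed = seed, refs = refs))
  }
  assessed <- stage("assess",
                    assess_growth(cohort, refs = refs,
                                  enforce_windows = enforce_windows))

  desc_vars <- intersect(
    c("maternal_age", "maternal_weight_kg", "maternal_height_cm", "bmi",
      "ga_scan3t_wk", "ga_delivery_wk", "efw20_g", "efw20_mom", "ua_pi_mom",
      "mca_pi_mom", "cpr_mom", "efw3t_g", "efwc_local", "efwc_ig",
      "exfw3t_g", "pct_exfw3t", "interval_days", "birthweight_g",
      "nulliparous", "smoking", "fetal_sex", "labor_onset"),
    names(assessed)
  )
  table1 <- stage("compare_groups",
                  compare_groups(assessed, desc_vars,
                                 fisher_exact = fisher_exact))

  models <- predefined_models()
  uni <- models$model[models$type == "univariable"]
  table2 <- stage("univariable_screen", univariable_screen(assessed, uni))
  uni_fits <- Filter(function(f) inherits(f, "ifc_fit"),
                     attr(table2, "fits"))

  multi <- models[models$type == "multivariable", ]
  multi_fits <- stage("multivariable_fits", purrr::map2(
    multi$predictors, multi$model,
    function(p, nm) fit_ifc(assessed, p, name = nm)
  ))
  names(multi_fits) <- multi$model

  term_table <- function(fits) {
    purrr::map_dfr(fits, function(f) {
      dplyr::mutate(tidy(f), model = f$name, AIC = f$aic, auc = f$roc$auc,
                    .before = 1)
    })
  }
  table3 <- term_table(multi_fits[1:4])
  table4 <- term_table(multi_fits[5:8])

  all_fits <- c(uni_fits, multi_fits)
  table5 <- stage("rank_models", {
    ranked <- rank_models_by_aic(all_fits)
    extra <- purrr::map_dfr(all_fits, function(f) {
      lrt <- f$glm$null.deviance - f$glm$deviance
      tibble::tibble(
        model = f$name,
        dr_fpr5 = dr_at_fpr(f$roc, 0.05),
        dr_fpr10 = dr_at_fpr(f$roc, 0.10),
        p_value = stats::pchisq(lrt, df = f$n_params - 1, lower.tail = FALSE)
      )
    })
    dplyr::left_join(ranked, extra, by = "model")
  })

  metadata <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("ifcgrowth")),
    n_records = nrow(assessed),
    n_events = sum(assessed$ifc),
    curves = purrr::map_chr(refs, "provenance"),
    flags = list(enforce_windows = enforce_windows,
                 fisher_exact = fisher_exact,
                 dr_convention = "step (no interpolation)",
                 ci_method = "Wald (terms), DeLong (AUC)",
                 multiple_testing = "none (univariable screen unadjusted)")
  )
  metadata$config_hash <- config_fingerprint(list(spec = unclass(spec),
                                          flags = metadata$flags,
                                          curves = metadata$curves))

  result <- structure(
    list(cohort = assessed, table1 = table1, table2 = table2, table3 = table3,
         table4 = table4, table5 = table5, fits = all_fits,
         metadata = metadata),
    class = "ifc_report"
  )

  if (!is.null(out_dir)) {
    stage("write_bundle", {
      dir.create(file.path(out_dir, "roc"), recursive = TRUE,
                 showWarnings = FALSE)
      stamp <- sprintf("# seed=%d config=%s ifcgrowth=%s", seed,
                       metadata$config_hash, metadata$package_version)
      for (i in 1:5) {
        p <- file.path(out_dir, sprintf("table%d.tsv", i))
        tab <- result[[sprintf("table%d", i)]]
        if (i == 2) attr(tab, "fits") <- NULL
        write_stamped_tsv(tab, p, stamp)
        written <- c(written, p)
      }
      for (nm in names(all_fits)) {
        safe <- gsub("[^A-Za-z0-9]+", "_", nm)
        p <- file.path(out_dir, "roc", paste0(safe, ".tsv"))
        write_stamped_tsv(all_fits[[nm]]$roc$points, p, stamp)
        written <- c(written, p)
      }
      p <- file.path(out_dir, "run_metadata.json")
      jsonlite::write_json(metadata, p, auto_unbox = TRUE, pretty = TRUE)
      written <- c(written, p)
    })
  }
  result
}

#' @export
print.ifc_report <- function(x, ...) {
  cat(sprintf("<ifc_report> %d pregnancies, %d IFC events (%.1f%%), seed %d\n",
              x$metadata$n_records, x$metadata$n_events,
              100 * x$metadata$n_events / x$metadata$n_records,
              x$metadata$seed))
  cat("Model ranking (best first):\n")
  print(utils::head(x$table5, 5))
  invisible(x)
}

#' AIC ranking plot
#'
#' Dot plot of AIC (lower is better) for every model in a pipeline report,
#' coloured by model type, with the two-AIC-unit band around the best model.
#'
#' @param report An `ifc_report` from [run_ifc_pipeline()].
#' @return A ggplot.
#' @export
plot_aic_ranking <- function(report) {
  stopifnot(inherits(report, "ifc_report"))
  tab <- dplyr::mutate(
    report$table5,
    type = ifelse(.data$df > 2, "multivariable", "univariable"),
    model = stats::reorder(.data$model, -.data$AIC)
  )
  best <- min(tab$AIC)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$AIC, y = .data$model,
                                    colour = .data$type)) +
    ggplot2::annotate("rect", xmin = best, xmax = best + 2, ymin = -Inf,
                      ymax = Inf, alpha = 0.15, fill = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "AIC (lower is better)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
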