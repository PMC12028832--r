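#' Fit a logistic IFC prediction model
#'
#' Maximum-likelihood logistic regression of the binary IFC outcome on a set
#' of predictor columns, fitted by iteratively reweighted least squares
#' (via [stats::glm()]), with Wald standard errors from the observed
#' information matrix. Rows with missing values in the outcome or any
#' predictor are dropped (complete-case per model) and the dropped count is
#' recorded. Apparent perfect separation (a diverging coefficient,
#' `|beta| > 15`, or non-convergence of the IRLS loop) is flagged through
#' `converged = FALSE`, never silently.
#'
#' @param cohort Data frame with a logical/0-1 column `ifc` and the
#'   predictor columns.
#' @param predictors Character vector of predictor column names.
#' @param name Optional model label (defaults to `predictor1 + predictor2`).
#' @return An object of class `ifc_fit`; see [tidy.ifc_fit()] and
#'   [glance.ifc_fit()].
#' @export
fit_ifc <- function(cohort, predictors, name = NULL) {
  stopifnot(is.character(predictors), length(predictors) >= 1,
            !anyDuplicated(predictors))
  cohort <- tibble::as_tibble(cohort)
  if (!"ifc" %in% names(cohort)) stop("cohort has no `ifc` column", call. = FALSE)
  missing_cols <- setdiff(predictors, names(cohort))
  if (length(missing_cols)) {
    stop("predictor column(s) not in cohort: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dat <- cohort[c("ifc", predictors)]
  n0 <- nrow(dat)
  dat <- dat[stats::complete.cases(dat), ]
  n_dropped <- n0 - nrow(dat)
  y <- as.logical(dat$ifc)
  if (sum(y) < 1 || sum(!y) < 1) {
    stop("need at least one event and one non-event", call. = FALSE)
  }
  for (p in predictors) {
    if (length(unique(dat[[p]])) < 2) {
      stop(sprintf("predictor `%s` is constant", p), call. = FALSE)
    }
  }
  fml <- stats::reformulate(predictors, response = "ifc")
  fit <- suppressWarnings(stats::glm(
    fml, family = stats::binomial(), data = dat,
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # diverging slope coefficients indicate (quasi-)separation; the intercept
  # is excluded since its magnitude depends on predictor location, not fit
  # pathology (e.g. ~13 with height in cm and %ExFW3t in percent)
  converged <- fit$converged && all(abs(beta[-1]) <= 15)
  zcrit <- stats::qnorm(0.975)
  terms <- tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(beta / se),
    p.value = 2 * stats::pnorm(-abs(unname(beta / se))),
    or = exp(unname(beta)),
    or_low = exp(unname(beta) - zcrit * unname(se)),
    or_high = exp(unname(beta) + zcrit * unname(se))
  )
  ll <- as.numeric(stats::logLik(fit))
  k <- length(beta)
  eta <- stats::predict(fit, type = "link")
  roc <- roc_ifc(eta, y, direction = "higher_risk")
  if (is.null(name)) name <- paste(predictors, collapse = " + ")
  structure(
    list(name = name, predictors = predictors, terms = terms,
         loglik = ll, aic = 2 * k - 2 * ll, n = nrow(dat),
         n_events = sum(y), n_dropped = n_dropped, n_params = k,
         converged = converged, roc = roc, glm = fit),
    class = "ifc_fit"
  )
}

#' @export
print.ifc_fit <- function(x, ...) {
  cat(sprintf("<ifc_fit> %s  (n = %d, events = %d%s)\n", x$name, x$n,
              x$n_events,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(x$terms)
  cat(sprintf("logLik %.2f  AIC %.1f  AUC %.3f\n", x$loglik, x$aic,
              x$roc$auc))
  invisible(x)
}

#' Tidy a fitted IFC model
#'
#' @param x An `ifc_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate` (log
#'   odds), `std.error`, `statistic`, `p.value` (Wald), `or` and the Wald
#'   95% interval `or_low`, `or_high`.
#' @method tidy ifc_fit
#' @export
tidy.ifc_fit <- function(x, ...) x$terms

#' Model-level summary of a fitted IFC model
#'
#' @param x An `ifc_fit`.
#' @param ... Unused.
#' @return One-row tibble: `model`, `n`, `n_events`, `n_dropped`, `df`,
#'   `logLik`, `AIC`, `auc`, `converged`.
#' @method glance ifc_fit
#' @export
glance.ifc_fit <- function(x, ...) {
  tibble::tibble(model = x$name, n = x$n, n_events = x$n_events,
                 n_dropped = x$n_dropped, df = x$n_params,
                 logLik = x$loglik, AIC = x$aic, auc = x$roc$auc,
                 converged = x$converged)
}

#' Odds ratio from a log-odds coefficient
#'
#' @param beta Finite log-odds coefficient(s).
#' @return `exp(beta)`.
#' @examples
#' odds_ratio(0) # 1
#' @export
odds_ratio <- function(beta) {
  if (any(!is.finite(beta))) stop("`beta` must be finite", call. = FALSE)
  exp(beta)
}

#' Univariable screen of candidate predictors
#'
#' Fits one single-predictor logistic model per candidate column and collects
#' the coefficient, odds ratio with Wald 95% CI, Wald p-value, AIC, AUC and
#' detection rates at 5% and 10% FPR. A candidate whose fit fails (e.g. a
#' constant column) gets its error message recorded in the `error` column
#' and the screen continues. No multiple-testing correction is applied.
#'
#' @param cohort Data frame with `ifc` and the candidate columns.
#' @param candidates Character vector of column names; rows are returned in
#'   this order.
#' @return A tibble, one row per candidate, with the fitted `ifc_fit`
#'   objects in the attribute `"fits"`.
#' @export
univariable_screen <- function(cohort, candidates) {
  fits <- purrr::map(candidates, function(p) {
    tryCatch(fit_ifc(cohort, p), error = function(e) conditionMessage(e))
  })
  rows <- purrr::map2(candidates, fits, function(p, f) {
    if (!inherits(f, "ifc_fit")) {
      return(tibble::tibble(predictor = p, estimate = NA_real_, or = NA_real_,
                            or_low = NA_real_, or_high = NA_real_,
                            p.value = NA_real_, aic = NA_real_,
                            auc = NA_real_, dr_fpr5 = NA_real_,
                            dr_fpr10 = NA_real_, error = f))
    }
    tt <- f$terms[f$terms$term != "(Intercept)", ][1, ]
    tibble::tibble(predictor = p, estimate = tt$estimate, or = tt$or,
                   or_low = tt$or_low, or_high = tt$or_high,
                   p.value = tt$p.value, aic = f$aic, auc = f$roc$auc,
                   dr_fpr5 = dr_at_fpr(f$roc, 0.05),
                   dr_fpr10 = dr_at_fpr(f$roc, 0.10),
                   error = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- stats::setNames(fits, candidates)
  out
}

#' The predefined model set
#'
#' The twelve univariable candidates and the eight multivariable models
#' compared in the analysis. Every multivariable model contains a cerebral
#' Doppler term (MCA PI MoM for models 1--4, CPR MoM for models 5--8),
#' combined with a fetal-weight term (local EFW centile or %ExFW3t), with
#' models 3, 4, 7 and 8 additionally adjusted for maternal height.
#'
#' @return A tibble with columns `model` (label), `type`
#'   (`"univariable"`/`"multivariable"`) and `predictors` (list column of
#'   character vectors).
#' @export
predefined_models <- function() {
  uni <- c("maternal_weight_kg", "smoking", "fetal_sex", "maternal_age",
           "nulliparous", "ua_pi_mom", "maternal_height_cm", "efwc_ig",
           "efwc_local", "pct_exfw3t", "cpr_mom", "mca_pi_mom")
  multi <- list(
    "Model 1: MCA PI MoM + EFWc (local)" = c("mca_pi_mom", "efwc_local"),
    "Model 2: MCA PI MoM + %ExFW3t" = c("mca_pi_mom", "pct_exfw3t"),
    "Model 3: MCA PI MoM + EFWc (local) + maternal height" =
      c("mca_pi_mom", "efwc_local", "maternal_height_cm"),
    "Model 4: MCA PI MoM + %ExFW3t + maternal height" =
      c("mca_pi_mom", "pct_exfw3t", "maternal_height_cm"),
    "Model 5: CPR MoM + EFWc (local)" = c("cpr_mom", "efwc_local"),
    "Model 6: CPR MoM + %ExFW3t" = c("cpr_mom", "pct_exfw3t"),
    "Model 7: CPR MoM + EFWc (local) + maternal height" =
      c("cpr_mom", "efwc_local", "maternal_height_cm"),
    "Model 8: CPR MoM + %ExFW3t + maternal height" =
      c("cpr_mom", "pct_exfw3t", "maternal_height_cm")
  )
  dplyr::bind_rows(
    tibble::tibble(model = uni, type = "univariable",
                   predictors = as.list(uni)),
    tibble::tibble(model = names(multi), type = "multivariable",
                   predictors = unname(multi))
  )
}

#' Rank fitted models by AIC
#'
#' Sorts fits ascending by AIC (lower is better). Adjacent models are flagged
#' as `distinguishable` when their AIC difference is at least 2 units, the
#' conventional threshold for a meaningful difference. Ties are broken by
#' higher AUC, then by fewer parameters. All fits must be on the same number
#' of observations, otherwise AIC values are not comparable.
#'
#' @param fits A list of `ifc_fit` objects.
#' @return A tibble sorted by rank with columns `rank`, `model`, `df`,
#'   `logLik`, `AIC`, `delta_aic` (to the best model), `distinguishable`
#'   (from the previous row), `auc`, `converged`.
#' @export
rank_models_by_aic <- function(fits) {
  stopifnot(length(fits) >= 1, all(purrr::map_lgl(fits, inherits, "ifc_fit")))
  ns <- purrr::map_int(fits, "n")
  if (length(unique(ns)) > 1) {
    stop("fits are on differing n; AIC values are not comparable",
         call. = FALSE)
  }
  tab <- purrr::map_dfr(fits, glance)
  tab <- dplyr::arrange(tab, .data$AIC, dplyr::desc(.data$auc), .data$df)
  tab$rank <- seq_len(nrow(tab))
  tab$delta_aic <- tab$AIC - tab$AIC[1]
  tab$distinguishable <- c(NA, diff(tab$AIC) >= 2)
  dplyr::select(tab, "rank", "model", "df", "logLik", "AIC", "delta_aic",
                "distinguishable", "auc", "converged")
}
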