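#' Empirical ROC analysis of a risk marker
#'
#' Builds the empirical ROC curve over all unique thresholds, computes the
#' area under it by the trapezoidal rule (equivalent to the Mann-Whitney
#' U statistic divided by `n_pos * n_neg`, ties counted half), a DeLong 95%
#' confidence interval for the AUC, and detection rates at 5% and 10%
#' false-positive rates. Markers whose low values indicate risk (MCA PI MoM,
#' CPR MoM, EFW centiles, %ExFW3t, maternal height) are handled by
#' `direction = "lower_risk"`, which negates the scores first.
#'
#' @param scores Numeric marker values, one per subject.
#' @param labels Logical (or 0/1) outcome, `TRUE` = event.
#' @param direction `"higher_risk"` (default) if larger scores mean higher
#'   event risk, `"lower_risk"` otherwise.
#' @return An object of class `ifc_roc`: a list with `auc`, `auc_ci95`,
#'   `dr_at_fpr5`, `dr_at_fpr10` (percentages), `n_pos`, `n_neg`, and
#'   `points`, a tibble of `(threshold, fpr, tpr)` from (0,0) to (1,1).
#' @export
roc_ifc <- function(scores, labels, direction = c("higher_risk", "lower_risk")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  if (direction == "lower_risk") scores <- -scores

  # one ROC point per unique threshold: sort descending, take cumulative
  # event/non-event counts at the end of each tie group
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- which(!duplicated(s, fromLast = TRUE))
  points <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, cumsum(!y)[last] / n_neg),
    tpr = c(0, cumsum(y)[last] / n_pos)
  )
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  out <- structure(
    list(auc = auc, n_pos = n_pos, n_neg = n_neg, points = points,
         scores = scores, labels = labels),
    class = "ifc_roc"
  )
  out$degenerate <- auc %in% c(0, 1)
  out$auc_ci95 <- tryCatch(suppressWarnings(auc_ci(out)),
                           error = function(e) c(NA_real_, NA_real_))
  out$dr_at_fpr5 <- dr_at_fpr(out, 0.05)
  out$dr_at_fpr10 <- dr_at_fpr(out, 0.10)
  out
}

#' @export
print.ifc_roc <- function(x, ...) {
  cat(sprintf(paste0("<ifc_roc> AUC %.3f, 95%% CI [%.3f, %.3f] ",
                     "(%d events / %d non-events)\n"),
              x$auc, x$auc_ci95[1], x$auc_ci95[2], x$n_pos, x$n_neg))
  cat(sprintf("DR %.1f%% at 5%% FPR, %.1f%% at 10%% FPR\n",
              x$dr_at_fpr5, x$dr_at_fpr10))
  invisible(x)
}

#' DeLong 95% confidence interval for the AUC
#'
#' Variance of the empirical AUC from the DeLong placement-value estimator;
#' the interval is `auc +/- 1.96 * se`, clipped to `[0, 1]`. A degenerate AUC
#' of exactly 0 or 1 collapses the interval to a point and is flagged with a
#' warning.
#'
#' @param roc An `ifc_roc` object.
#' @return Length-2 numeric `c(low, high)`.
#' @export
auc_ci <- function(roc) {
  stopifnot(inherits(roc, "ifc_roc"))
  if (roc$n_pos < 2 || roc$n_neg < 2) {
    stop("need at least 2 events and 2 non-events for a DeLong interval",
         call. = FALSE)
  }
  # placement values via midranks: for each event, the fraction of
  # non-events it beats (ties count half), and vice versa
  ev <- roc$labels
  r_all <- rank(roc$scores, ties.method = "average")
  v10 <- (r_all[ev] - rank(roc$scores[ev], ties.method = "average")) / roc$n_neg
  v01 <- 1 - (r_all[!ev] - rank(roc$scores[!ev], ties.method = "average")) / roc$n_pos
  v <- stats::var(v10) / roc$n_pos + stats::var(v01) / roc$n_neg
  if (roc$auc %in% c(0, 1) || v == 0) {
    warning("degenerate AUC; confidence interval collapses to a point")
    return(c(roc$auc, roc$auc))
  }
  se <- sqrt(v)
  pmin(pmax(roc$auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
}

#' Detection rate at a fixed false-positive rate
#'
#' Reads the sensitivity off the empirical ROC at the most permissive
#' threshold whose FPR does not exceed the target (step-function convention,
#' no interpolation, the conservative choice). A linearly interpolated
#' variant is available for sensitivity analysis.
#'
#' @param roc An `ifc_roc` object.
#' @param fpr_target Target false-positive rate, e.g. 0.05 or 0.10.
#' @param interpolate Use linear interpolation between ROC points instead of
#'   the step convention (default `FALSE`).
#' @return Detection rate as a percentage in `[0, 100]`.
#' @export
dr_at_fpr <- function(roc, fpr_target, interpolate = FALSE) {
  stopifnot(inherits(roc, "ifc_roc"), fpr_target >= 0, fpr_target <= 1)
  pts <- roc$points
  if (interpolate) {
    return(100 * stats::approx(pts$fpr, pts$tpr, xout = fpr_target,
                               ties = max)$y)
  }
  100 * max(pts$tpr[pts$fpr <= fpr_target])
}

#' ROC curve plot
#'
#' @param object An `ifc_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ifc_roc
#' @export
autoplot.ifc_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate", y = "Detection rate",
      title = sprintf("AUC %.2f, 95%% CI [%.2f, %.2f]", object$auc,
                      object$auc_ci95[1], object$auc_ci95[2])
    ) +
    ggplot2::theme_minimal()
}

#' Overlayed ROC curves for several fitted models
#'
#' @param fits Named list of `ifc_fit` objects.
#' @return A ggplot with one step curve per model.
#' @export
plot_roc_curves <- function(fits) {
  stopifnot(all(purrr::map_lgl(fits, inherits, "ifc_fit")))
  dat <- purrr::map_dfr(fits, function(f) {
    dplyr::mutate(f$roc$points,
                  model = sprintf("%s (AUC %.2f)", f$name, f$roc$auc))
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "Detection rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
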