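# A reference curve with a constant median, handy for exact-value checks.
constant_curve <- function(m, index = "EFW", log_sd = 0.15,
                           range = c(12, 43)) {
  reference_curve(index, function(ga) rep_len(m, length(ga)),
                  log_sd = log_sd, valid_range = range,
                  provenance = "test constant")
}

# A tiny hand-built cohort (every measurement on its reference median),
# useful for identity checks of the assessment composition.
median_cohort <- function(n = 5, refs = default_references()) {
  ga20 <- rep(20, n)
  ga3t <- seq(34, 39, length.out = n)
  tibble::tibble(
    subject_id = sprintf("T%02d", seq_len(n)),
    maternal_height_cm = rep(162, n),
    ga_scan20_wk = ga20,
    efw20_g = median_at(refs$efw_local, ga20),
    ga_scan3t_wk = ga3t,
    efw3t_g = median_at(refs$efw_local, ga3t),
    ua_pi = median_at(refs$ua_pi, ga3t),
    mca_pi = median_at(refs$mca_pi, ga3t),
    ifc = c(TRUE, rep(FALSE, n - 1))
  )
}

# Closed-form log odds ratio of a 2x2 table (events by binary predictor).
logor_2x2 <- function(y, x) {
  a <- sum(y & x); b <- sum(y & !x); c <- sum(!y & x); d <- sum(!y & !x)
  log(a * d / (b * c))
}

# Brute-force Mann-Whitney U AUC: pairwise comparisons, ties count half.
auc_by_u <- function(scores, labels) {
  x <- scores[as.logical(labels)]
  y <- scores[!as.logical(labels)]
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u / (length(x) * length(y))
}
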