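# Log-normal parameterisation from a target mean and SD on the natural scale.
lnorm_pars <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Log-normal parameterisation from a median and IQR (used where a printed
# mean is internally inconsistent, e.g. BMI).
lnorm_pars_median <- function(median, q25, q75) {
  c(meanlog = log(median),
    sdlog = (log(q75) - log(q25)) / (2 * stats::qnorm(0.75)))
}

run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic screening cohort
#'
#' Describes the group-conditional generative laws for a two-group
#' (IFC / no-IFC) pregnancy cohort. Defaults emulate a 777-pregnancy
#' population with 52 IFC events in which the compromised group shows lower
#' MCA PI MoM, higher UA PI MoM, shorter mothers and a lower percentage of
#' expected weight achieved, while the 20-week EFW MoM is drawn identically
#' in both groups (growth potential is the same; only its realisation
#' differs). Continuous positive quantities (MoMs, %ExFW3t, BMI) are
#' log-normal; height and age are normal. Locations and scales are
#' `(mean, sd)` on the natural scale.
#'
#' @param n_total Cohort size (default 777).
#' @param n_ifc Number of IFC events, fixed by count (default 52).
#' @param mca_pi_mom,ua_pi_mom,maternal_height_cm,pct_exfw3t Named lists with
#'   elements `no_ifc` and `ifc`, each `c(mean, sd)`.
#' @param efw20_mom `c(mean, sd)`, shared across groups.
#' @param rank_cor_mca_ua Target rank correlation between the MCA and UA
#'   MoMs (Gaussian copula); the default -0.2 encodes mild haemodynamic
#'   redistribution and is an assumption, not an estimated value.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_total = 777, n_ifc = 52,
                        mca_pi_mom = list(no_ifc = c(0.97, 0.22), ifc = c(0.81, 0.21)),
                        ua_pi_mom = list(no_ifc = c(1.09, 0.24), ifc = c(1.19, 0.33)),
                        maternal_height_cm = list(no_ifc = c(162.9, 6.0), ifc = c(160.2, 7.8)),
                        pct_exfw3t = list(no_ifc = c(97.52, 13.5), ifc = c(89.9, 13.0)),
                        efw20_mom = c(0.97, 0.10),
                        rank_cor_mca_ua = -0.2) {
  if (!(n_ifc > 0 && n_ifc < n_total)) {
    stop("need 0 < n_ifc < n_total", call. = FALSE)
  }
  laws <- list(mca_pi_mom = mca_pi_mom, ua_pi_mom = ua_pi_mom,
               maternal_height_cm = maternal_height_cm,
               pct_exfw3t = pct_exfw3t)
  for (nm in names(laws)) {
    for (g in c("no_ifc", "ifc")) {
      v <- laws[[nm]][[g]]
      if (length(v) != 2 || v[1] <= 0 || v[2] < 0) {
        stop(sprintf("law `%s$%s` must be c(mean > 0, sd >= 0)", nm, g),
             call. = FALSE)
      }
    }
  }
  if (abs(rank_cor_mca_ua) >= 1) {
    stop("`rank_cor_mca_ua` must lie in (-1, 1)", call. = FALSE)
  }
  structure(
    c(list(n_total = n_total, n_ifc = n_ifc), laws,
      list(efw20_mom = efw20_mom, rank_cor_mca_ua = rank_cor_mca_ua)),
    class = "cohort_spec"
  )
}

# Draw a (possibly degenerate) law on the natural scale from a latent
# standard normal, log-normal or normal family.
draw_from_law <- function(z, law, family = c("lognormal", "normal")) {
  family <- match.arg(family)
  if (law[2] == 0) return(rep_len(law[1], length(z)))
  if (family == "normal") {
    law[1] + law[2] * z
  } else {
    p <- lnorm_pars(law[1], law[2])
    exp(p["meanlog"] + p["sdlog"] * z)
  }
}

#' Generate a synthetic pregnancy cohort
#'
#' Draws group labels first (the IFC count is fixed, so the 52/777 prevalence
#' is exact by construction), then covariates from the group-conditional laws
#' in `spec`. The MCA and UA MoMs are drawn jointly through a Gaussian copula
#' at the spec's rank correlation; the CPR is derived as the ratio of the raw
#' pulsatility indices. Raw scan values (EFW in grams, raw PIs) are
#' back-solved from the drawn MoMs through the reference curves, so
#' [assess_growth()] run on the generated cohort recovers the drawn MoMs and
#' the whole pipeline can be exercised end to end. Descriptive nuisance
#' columns (age, weight, BMI, parity, smoking, fetal sex, labor onset,
#' delivery data) are generated to the study population's margins.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical spec + seed give an identical cohort.
#' @param refs Reference curves used for the back-solve.
#' @return A tibble, one row per pregnancy, with the cohort CSV columns (see
#'   [read_cohort()]) including the logical outcome column `ifc`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed,
                            refs = default_references()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  run_seeded(seed, {
    n <- spec$n_total
    ifc <- c(rep(TRUE, spec$n_ifc), rep(FALSE, n - spec$n_ifc))
    grp <- ifelse(ifc, "ifc", "no_ifc")

    # Gaussian copula for (MCA, UA): Pearson correlation on the latent
    # normals r = 2 sin(pi * rho_s / 6) hits the target Spearman rho_s.
    r <- 2 * sin(pi * spec$rank_cor_mca_ua / 6)
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)

    pick <- function(law) rbind(law$no_ifc, law$ifc)[1 + ifc, , drop = FALSE]
    draw2 <- function(z, law, family) {
      m <- pick(law)
      vapply(seq_len(n), function(i) {
        draw_from_law(z[i], m[i, ], family)
      }, numeric(1))
    }

    mca_mom <- draw2(z1, spec$mca_pi_mom, "lognormal")
    ua_mom <- draw2(z2, spec$ua_pi_mom, "lognormal")
    height <- draw2(stats::rnorm(n), spec$maternal_height_cm, "normal")
    pct <- draw2(stats::rnorm(n), spec$pct_exfw3t, "lognormal")
    efw20_mom <- draw_from_law(stats::rnorm(n), spec$efw20_mom, "lognormal")

    # scan timing, within the protocol windows
    ga20 <- pmin(pmax(stats::rnorm(n, 20, 0.35), 19), 21)
    ga3t_law <- rbind(c(39, 1.2), c(38.5, 2.1))[1 + ifc, ]
    ga3t <- pmin(pmax(stats::rnorm(n, ga3t_law[, 1], ga3t_law[, 2]), 30), 40 + 6 / 7)
    interval_law <- rbind(c(6.5, 3.9), c(5.2, 4.5))[1 + ifc, ]
    interval <- round(pmin(pmax(stats::rnorm(n, interval_law[, 1], interval_law[, 2]), 0), 14))
    ga_delivery <- ga3t + interval / 7

    # back-solve raw scans from the drawn MoMs
    efw20_g <- efw20_mom * median_at(refs$efw_local, ga20)
    exfw3t_g <- efw20_mom * median_at(refs$efw_local, ga3t)
    efw3t_g <- pct / 100 * exfw3t_g
    ua_pi <- ua_mom * median_at(refs$ua_pi, ga3t)
    mca_pi <- mca_mom * median_at(refs$mca_pi, ga3t)

    # nuisance columns at the study's descriptive margins
    age_law <- rbind(c(32.5, 5.2), c(33.6, 4.3))[1 + ifc, ]
    weight_law <- rbind(c(62.3, 11.7), c(63.0, 12.6))[1 + ifc, ]
    bmi_pars <- rbind(lnorm_pars_median(23, 21, 25),
                      lnorm_pars_median(23, 22, 27.7))[1 + ifc, ]
    bw_growth <- median_at(refs$efw_local, pmin(ga_delivery, 42)) /
      median_at(refs$efw_local, ga3t)
    birthweight_g <- efw3t_g * bw_growth * exp(stats::rnorm(n, 0, 0.045))

    out <- tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      maternal_age = round(stats::rnorm(n, age_law[, 1], age_law[, 2]), 1),
      maternal_height_cm = round(height, 1),
      maternal_weight_kg = round(pmax(stats::rnorm(n, weight_law[, 1], weight_law[, 2]), 38), 1),
      bmi = round(exp(stats::rnorm(n, bmi_pars[, 1], bmi_pars[, 2])), 1),
      nulliparous = stats::runif(n) < ifelse(ifc, 0.635, 0.521),
      smoking = stats::runif(n) < ifelse(ifc, 0.096, 0.145),
      fetal_sex = ifelse(stats::runif(n) < ifelse(ifc, 0.577, 0.495),
                         "male", "female"),
      ga_scan20_wk = ga20,
      efw20_g = efw20_g,
      ga_scan3t_wk = ga3t,
      efw3t_g = efw3t_g,
      ua_pi = ua_pi,
      mca_pi = mca_pi,
      interval_days = as.integer(interval),
      ga_delivery_wk = ga_delivery,
      labor_onset = ifelse(stats::runif(n) < ifelse(ifc, 0.865, 0.48),
                           "induction", "spontaneous"),
      birthweight_g = round(birthweight_g),
      ifc = ifc
    )
    # shuffle so record order carries no outcome information
    out <- out[sample.int(n), ]
    out$subject_id <- sprintf("S%04d", seq_len(n))
    out
  })
}

#' Default covariate law for logistic-model simulation
#'
#' Draws model covariates at the study population's overall margins (both
#' outcome groups pooled): MCA and UA PI MoM (log-normal, Gaussian copula at
#' rank correlation -0.2), their ratio as CPR MoM, %ExFW3t (log-normal), the
#' derived local EFW centile, and maternal height (normal).
#'
#' @param n Number of subjects.
#' @return A tibble of covariates.
#' @export
default_covariate_law <- function(n) {
  r <- 2 * sin(pi * -0.2 / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  mca <- draw_from_law(z1, c(0.97, 0.22), "lognormal")
  ua <- draw_from_law(z2, c(1.10, 0.25), "lognormal")
  pct <- draw_from_law(stats::rnorm(n), c(97.0, 13.6), "lognormal")
  efw20_mom <- draw_from_law(stats::rnorm(n), c(0.97, 0.10), "lognormal")
  tibble::tibble(
    mca_pi_mom = mca,
    ua_pi_mom = ua,
    cpr_mom = mca / ua,
    pct_exfw3t = pct,
    efwc_local = 100 * stats::pnorm(log(pct / 100 * efw20_mom) / 0.18),
    maternal_height_cm = stats::rnorm(n, 162.7, 6.2)
  )
}

#' Simulate outcomes from a known logistic model
#'
#' Draws covariates from `covariate_law`, then the binary IFC outcome as
#' Bernoulli with probability `plogis(intercept + beta . x)`. Used for
#' parameter-recovery studies against published model coefficients.
#'
#' @param beta Named numeric vector of log-odds coefficients; names must be
#'   columns produced by `covariate_law`.
#' @param intercept Model intercept (log-odds).
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param covariate_law Function `n -> tibble`; default
#'   [default_covariate_law()].
#' @return A tibble of covariates plus the outcome column `ifc`; the
#'   attribute `"expected_prevalence"` carries the mean fitted probability.
#' @export
simulate_from_logistic <- function(beta, intercept, n, seed,
                                   covariate_law = default_covariate_law) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  run_seeded(seed, {
    x <- covariate_law(n)
    missing_cols <- setdiff(names(beta), names(x))
    if (length(missing_cols)) {
      stop("covariate_law does not produce: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    eta <- intercept + as.matrix(x[names(beta)]) %*% beta
    p <- stats::plogis(drop(eta))
    x$ifc <- stats::runif(n) < p
    attr(x, "expected_prevalence") <- mean(p)
    x
  })
}
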