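#' Hadlock four-parameter estimated fetal weight
#'
#' The standard four-parameter Hadlock regression of fetal weight on
#' ultrasound biometry:
#' `EFW = 10 ^ (1.3596 + 0.0064 HC + 0.0424 AC + 0.174 FL
#'              + 0.00061 BPD * AC - 0.00386 AC * FL)`
#' with all measurements in centimetres and the result in grams.
#'
#' @param bpd,hc,ac,fl Biparietal diameter, head circumference, abdominal
#'   circumference and femur length, in cm. Vectorised.
#' @return Estimated fetal weight in grams.
#' @examples
#' hadlock4_efw(bpd = 8.8, hc = 32, ac = 33, fl = 7)
#' @export
hadlock4_efw <- function(bpd, hc, ac, fl) {
  args <- list(bpd = bpd, hc = hc, ac = ac, fl = fl)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(is.na(v))) {
      stop(sprintf("biometry field '%s' is missing", nm), call. = FALSE)
    }
    if (any(v < 0 | v >= 60)) {
      stop(sprintf("biometry field '%s' must be in [0, 60) cm", nm),
           call. = FALSE)
    }
  }
  10^(1.3596 + 0.0064 * hc + 0.0424 * ac + 0.174 * fl +
        0.00061 * bpd * ac - 0.00386 * ac * fl)
}

#' EFW as a multiple of the gestational-age median
#'
#' @param efw Estimated fetal weight, grams.
#' @param ga Gestational age at measurement, decimal weeks.
#' @param efw_curve EFW [reference_curve()].
#' @return Dimensionless MoM, `efw / median(ga)`.
#' @export
efw_mom <- function(efw, ga, efw_curve) {
  if (any(efw <= 0)) stop("`efw` must be positive", call. = FALSE)
  efw / median_at(efw_curve, ga)
}

#' Expected fetal weight at the third trimester
#'
#' Carries the 20-week EFW MoM forward: the expected third-trimester weight
#' is `EFW MoM at 20 wk * EFW median at the third-trimester scan`. A fetus on
#' its mid-pregnancy track therefore has an expected weight equal to the
#' population median at the later scan, scaled by its own mid-pregnancy MoM.
#'
#' @param efw20 EFW at the mid-pregnancy scan, grams.
#' @param ga20 Gestational age at the mid-pregnancy scan; the protocol window
#'   is 20 +/- 1 weeks.
#' @param ga3t Gestational age at the third-trimester scan; the protocol
#'   window is 30+0 to 40+6 weeks.
#' @param efw_curve EFW [reference_curve()].
#' @param enforce_windows Validate the protocol GA windows (default `TRUE`);
#'   set `FALSE` for stress-testing outside them.
#' @return Expected third-trimester fetal weight, grams.
#' @export
expected_fw_3t <- function(efw20, ga20, ga3t, efw_curve,
                           enforce_windows = TRUE) {
  if (enforce_windows) {
    if (any(ga20 < 19 | ga20 > 21)) {
      stop("`ga20` outside the 20 +/- 1 week scan window", call. = FALSE)
    }
    if (any(ga3t < 30 | ga3t > 40 + 6 / 7)) {
      stop("`ga3t` outside the 30+0 to 40+6 week scan window", call. = FALSE)
    }
  }
  efw_mom(efw20, ga20, efw_curve) * median_at(efw_curve, ga3t)
}

#' Percentage of expected weight achieved
#'
#' The growth-potential statistic: `100 + 100 * (efw3t - exfw3t) / exfw3t`,
#' which simplifies algebraically to `100 * efw3t / exfw3t`. 125 means the
#' fetus grew 25% above its extrapolated expectation; 75 means 25% below.
#'
#' @param efw3t Actual third-trimester EFW, grams.
#' @param exfw3t Expected third-trimester EFW from [expected_fw_3t()], grams.
#' @return Percentage (e.g. 125 for a fetus 25% above expectation).
#' @export
pct_expected_fw <- function(efw3t, exfw3t) {
  if (any(exfw3t <= 0)) stop("`exfw3t` must be positive", call. = FALSE)
  100 * efw3t / exfw3t
}

#' Doppler indices as multiples of the median, plus the CPR
#'
#' Converts raw UA and MCA pulsatility indices to MoM against their
#' gestational-age medians and derives the cerebroplacental ratio
#' `CPR = MCA PI / UA PI` (and its MoM).
#'
#' @param ua_pi,mca_pi Raw pulsatility indices, dimensionless, in (0, 5).
#' @param ga Gestational age at the Doppler examination, decimal weeks.
#' @param refs Named list of curves as from [default_references()]; must
#'   contain `ua_pi`, `mca_pi` and `cpr`.
#' @return A tibble with columns `ua_pi_mom`, `mca_pi_mom`, `cpr`, `cpr_mom`.
#' @export
doppler_moms <- function(ua_pi, mca_pi, ga, refs = default_references()) {
  if (any(ua_pi <= 0 | ua_pi >= 5) || any(mca_pi <= 0 | mca_pi >= 5)) {
    stop("pulsatility indices must lie in (0, 5)", call. = FALSE)
  }
  cpr <- mca_pi / ua_pi
  tibble::tibble(
    ua_pi_mom = ua_pi / median_at(refs$ua_pi, ga),
    mca_pi_mom = mca_pi / median_at(refs$mca_pi, ga),
    cpr = cpr,
    cpr_mom = cpr / median_at(refs$cpr, ga)
  )
}

#' Per-pregnancy growth and Doppler assessment
#'
#' Takes a cohort (one row per pregnancy; see [read_cohort()] for the column
#' dictionary) and appends the derived quantities: 20-week EFW MoM, expected
#' third-trimester weight (`exfw3t_g`), percentage of expected weight
#' achieved (`pct_exfw3t`), EFW centiles against the local and
#' intergrowth-like references (`efwc_local`, `efwc_ig`), Doppler MoMs and
#' the CPR. If `efw20_g`/`efw3t_g` are absent but raw biometry columns
#' (`bpd20_cm` etc.) are present, EFW is computed with [hadlock4_efw()].
#'
#' @param cohort A data frame with columns `ga_scan20_wk`, `efw20_g`,
#'   `ga_scan3t_wk`, `efw3t_g`, `ua_pi`, `mca_pi` (or raw biometry, see
#'   above).
#' @param refs Reference curves, as from [default_references()].
#' @param enforce_windows Validate scan GA windows (see [expected_fw_3t()]).
#' @return The input tibble with assessment columns `efw20_mom`, `exfw3t_g`,
#'   `pct_exfw3t`, `ua_pi_mom`, `mca_pi_mom`, `cpr`, `cpr_mom`, `efwc_local`,
#'   `efwc_ig` appended.
#' @export
assess_growth <- function(cohort, refs = default_references(),
                          enforce_windows = TRUE) {
  cohort <- tibble::as_tibble(cohort)
  for (scan in c("20", "3t")) {
    efw_col <- paste0("efw", scan, "_g")
    bio <- paste0(c("bpd", "hc", "ac", "fl"), scan, "_cm")
    if (!efw_col %in% names(cohort)) {
      if (!all(bio %in% names(cohort))) {
        stop(sprintf("cohort needs either `%s` or biometry columns %s",
                     efw_col, paste(bio, collapse = ", ")), call. = FALSE)
      }
      cohort[[efw_col]] <- hadlock4_efw(cohort[[bio[1]]], cohort[[bio[2]]],
                                        cohort[[bio[3]]], cohort[[bio[4]]])
    }
  }
  needed <- c("ga_scan20_wk", "ga_scan3t_wk", "ua_pi", "mca_pi")
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    stop("cohort is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  exfw <- expected_fw_3t(cohort$efw20_g, cohort$ga_scan20_wk,
                         cohort$ga_scan3t_wk, refs$efw_local,
                         enforce_windows = enforce_windows)
  dop <- doppler_moms(cohort$ua_pi, cohort$mca_pi, cohort$ga_scan3t_wk, refs)
  dplyr::bind_cols(
    cohort,
    tibble::tibble(
      efw20_mom = efw_mom(cohort$efw20_g, cohort$ga_scan20_wk, refs$efw_local),
      exfw3t_g = exfw,
      pct_exfw3t = pct_expected_fw(cohort$efw3t_g, exfw),
      efwc_local = centile_from_value(cohort$efw3t_g, cohort$ga_scan3t_wk,
                                      refs$efw_local),
      efwc_ig = centile_from_value(cohort$efw3t_g, cohort$ga_scan3t_wk,
                                   refs$efw_intergrowth_like)
    ),
    dop
  )
}
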