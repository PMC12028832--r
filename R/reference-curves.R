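#' Gestational age in decimal weeks
#'
#' Builds gestational ages from completed weeks and days, the form in which
#' they are recorded clinically (e.g. "33 + 1" is 33 weeks plus 1 day). The
#' value is kept at full precision `weeks + days/7`; rounding to two decimals
#' is a display concern only, so multiples-of-the-median conversions do not
#' accumulate rounding error.
#'
#' @param weeks Completed weeks (integerish, one value or a vector).
#' @param days Additional days, 0--6. Recycled against `weeks`.
#' @return A numeric vector of decimal weeks.
#' @examples
#' gestational_age(33, 1) # 33.142857...
#' @export
gestational_age <- function(weeks, days = 0) {
  if (any(days < 0 | days > 6)) {
    stop("`days` must be between 0 and 6", call. = FALSE)
  }
  ga <- weeks + days / 7
  if (any(ga < 12 | ga > 43)) {
    stop("gestational age must lie in [12, 43] weeks", call. = FALSE)
  }
  ga
}

#' Gestational-age reference curve
#'
#' A reference curve maps gestational age to the population median of an
#' index (EFW in grams, or a dimensionless pulsatility index), together with
#' a multiplicative spread (standard deviation of log(value/median)) used for
#' centile conversion under a log-normal model.
#'
#' @param index_name One of `"EFW"`, `"UA_PI"`, `"MCA_PI"`, `"CPR"`.
#' @param median_fn Function of gestational age returning the median;
#'   must be strictly positive over `valid_range`.
#' @param log_sd Positive scalar, or a function of gestational age, giving
#'   the log-scale standard deviation.
#' @param valid_range Length-2 numeric, the gestational ages (weeks) over
#'   which the curve may be evaluated.
#' @param provenance Free-text label recorded in pipeline metadata.
#' @param monotone One of `"none"`, `"increasing"`, `"decreasing"`; the
#'   constructor verifies the median respects it on a fine grid.
#' @return An object of class `ref_curve`.
#' @export
reference_curve <- function(index_name, median_fn, log_sd, valid_range,
                            provenance = "user-supplied",
                            monotone = c("none", "increasing", "decreasing")) {
  index_name <- match.arg(index_name, c("EFW", "UA_PI", "MCA_PI", "CPR"))
  monotone <- match.arg(monotone)
  stopifnot(is.function(median_fn), length(valid_range) == 2,
            valid_range[1] < valid_range[2])
  spread_fn <- if (is.function(log_sd)) log_sd else function(ga) rep_len(log_sd, length(ga))
  grid <- seq(valid_range[1], valid_range[2], length.out = 201)
  m <- median_fn(grid)
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("median_fn must be finite and strictly positive over valid_range",
         call. = FALSE)
  }
  if (any(spread_fn(grid) <= 0)) {
    stop("log_sd must be strictly positive", call. = FALSE)
  }
  if (monotone == "increasing" && any(diff(m) <= 0)) {
    stop("median_fn is not strictly increasing over valid_range", call. = FALSE)
  }
  if (monotone == "decreasing" && any(diff(m) >= 0)) {
    stop("median_fn is not strictly decreasing over valid_range", call. = FALSE)
  }
  structure(
    list(index_name = index_name, median_fn = median_fn, spread_fn = spread_fn,
         valid_range = valid_range, provenance = provenance),
    class = "ref_curve"
  )
}

#' @export
print.ref_curve <- function(x, ...) {
  cat(sprintf("<ref_curve> %s over [%.1f, %.1f] wk  (%s)\n",
              x$index_name, x$valid_range[1], x$valid_range[2], x$provenance))
  invisible(x)
}

check_ga_range <- function(curve, ga) {
  bad <- ga < curve$valid_range[1] | ga > curve$valid_range[2]
  if (any(bad)) {
    stop(sprintf("gestational age %s outside the %s curve's valid range [%g, %g]",
                 paste(format(ga[bad]), collapse = ", "),
                 curve$index_name, curve$valid_range[1], curve$valid_range[2]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Median and spread of a reference curve at a gestational age
#'
#' @param curve A [reference_curve()].
#' @param ga Gestational age(s), decimal weeks, inside the curve's range.
#' @return `median_at()` the median (grams for EFW, dimensionless PI
#'   otherwise); `spread_at()` the log-scale SD.
#' @export
median_at <- function(curve, ga) {
  stopifnot(inherits(curve, "ref_curve"))
  check_ga_range(curve, ga)
  curve$median_fn(ga)
}

#' @rdname median_at
#' @export
spread_at <- function(curve, ga) {
  stopifnot(inherits(curve, "ref_curve"))
  check_ga_range(curve, ga)
  curve$spread_fn(ga)
}

#' Centile of a measurement against a reference curve
#'
#' Uses a log-normal model: `z = log(value / median) / log_sd`, centile
#' `100 * pnorm(z)`. A value exactly on the median maps to the 50th centile
#' for every gestational age.
#'
#' @param value Positive measurement(s) in the curve's units.
#' @param ga Gestational age(s), decimal weeks.
#' @param curve A [reference_curve()].
#' @return Centile(s) in (0, 100).
#' @export
centile_from_value <- function(value, ga, curve) {
  if (any(value <= 0)) stop("`value` must be positive", call. = FALSE)
  z <- log(value / median_at(curve, ga)) / spread_at(curve, ga)
  100 * stats::pnorm(z)
}

#' @rdname centile_from_value
#' @param centile Centile(s) strictly inside (0, 100).
#' @export
value_from_centile <- function(centile, ga, curve) {
  if (any(centile <= 0 | centile >= 100)) {
    stop("`centile` must lie strictly inside (0, 100)", call. = FALSE)
  }
  median_at(curve, ga) * exp(stats::qnorm(centile / 100) * spread_at(curve, ga))
}

#' The published EFW-median polynomial, as printed
#'
#' Evaluates the quadratic
#' `-3.266164164 + 0.368135209 * GA - 0.006318278 * GA^2`
#' exactly as published, with no rescaling. Note that over 20--41 weeks this
#' quadratic takes values of roughly 1.5--2.1 and peaks near 29 weeks, a
#' magnitude and shape inconsistent with fetal weight in grams (term median
#' around 3,200 g) but typical of a Doppler pulsatility index. It is kept
#' verbatim for reference and traceability; the pipeline's gram-scale EFW
#' median is the configurable curve in [default_references()].
#'
#' @param ga Gestational age(s), decimal weeks, in [20, 41].
#' @return The polynomial value.
#' @export
printed_efw_median <- function(ga) {
  if (any(ga < 20 | ga > 41)) {
    stop("`ga` must lie in [20, 41] weeks", call. = FALSE)
  }
  -3.266164164 + 0.368135209 * ga - 0.006318278 * ga^2
}

# Hard-coded default medians. The EFW log-quadratic is calibrated so the
# 20-week median is 373.5 g and the 39-week median 3250 g (mid-range of
# published gram-scale references); Doppler quadratics reproduce the
# canonical shapes: UA PI falling with gestation, MCA PI peaking near 29 wk.
.efw_local_coef <- c(1.464831639425010, 0.278820371594493, -0.002795802666855)
.ua_coef <- c(1.90, -0.0415, 0.00035)
.mca_coef <- c(-2.74060606060606116, 0.32654545454545458, -0.00557575757575758)

.quad <- function(coef) function(ga) coef[1] + coef[2] * ga + coef[3] * ga^2
.logquad <- function(coef) function(ga) exp(coef[1] + coef[2] * ga + coef[3] * ga^2)

#' Shipped default reference curves
#'
#' Returns the default set of gestational-age reference curves used for MoM
#' and centile conversion:
#' \describe{
#'   \item{efw_local}{gram-scale EFW median, log-quadratic, strictly
#'     increasing (373.5 g at 20 wk, 3250 g at 39 wk), log-SD 0.18.}
#'   \item{efw_intergrowth_like}{an alternative EFW standard for sensitivity
#'     comparison: the local median scaled by 0.985 with log-SD 0.19. A
#'     synthetic stand-in, not the published international standard, which is
#'     pluggable via [curves_from_json()].}
#'   \item{ua_pi}{UA pulsatility-index median, decreasing with gestation.}
#'   \item{mca_pi}{MCA pulsatility-index median, single interior maximum
#'     near 29 weeks.}
#'   \item{cpr}{cerebroplacental-ratio median, defined as the ratio of the
#'     MCA and UA medians, so CPR MoM equals MCA MoM / UA MoM.}
#' }
#' All curves are replaceable via [curves_from_json()].
#'
#' @return A named list of [reference_curve()] objects.
#' @export
default_references <- function() {
  efw_local <- reference_curve(
    "EFW", .logquad(.efw_local_coef), log_sd = 0.18, valid_range = c(16, 42),
    provenance = "ifcgrowth default: log-quadratic gram-scale EFW median",
    monotone = "increasing"
  )
  efw_ig <- reference_curve(
    "EFW", function(ga) 0.985 * .logquad(.efw_local_coef)(ga),
    log_sd = 0.19, valid_range = c(16, 42),
    provenance = "ifcgrowth default: synthetic intergrowth-like EFW standard",
    monotone = "increasing"
  )
  ua <- reference_curve(
    "UA_PI", .quad(.ua_coef), log_sd = 0.21, valid_range = c(16, 42),
    provenance = "ifcgrowth default: quadratic UA PI median",
    monotone = "decreasing"
  )
  mca <- reference_curve(
    "MCA_PI", .quad(.mca_coef), log_sd = 0.22, valid_range = c(16, 42),
    provenance = "ifcgrowth default: quadratic MCA PI median"
  )
  cpr <- reference_curve(
    "CPR", function(ga) .quad(.mca_coef)(ga) / .quad(.ua_coef)(ga),
    log_sd = 0.30, valid_range = c(16, 42),
    provenance = "ifcgrowth default: CPR median = MCA median / UA median"
  )
  list(efw_local = efw_local, efw_intergrowth_like = efw_ig,
       ua_pi = ua, mca_pi = mca, cpr = cpr)
}

#' Load reference curves from a JSON configuration
#'
#' Each entry is either a polynomial curve
#' `{"index": "EFW", "type": "polynomial", "coefficients": [...],
#'   "log_scale": true, "log_sd": 0.18, "range": [16, 42]}`
#' (coefficients in increasing powers of GA; `log_scale` applies `exp()` to
#' the polynomial) or a table curve
#' `{"type": "table", "knots": [[ga, median], ...], ...}` interpolated
#' monotonically in GA with `stats::splinefun(method = "hyman")`.
#'
#' @param path Path to a JSON file whose top level is a named object,
#'   names being curve labels (e.g. `"efw_local"`).
#' @return A named list of [reference_curve()] objects; entries absent from
#'   the file fall back to [default_references()].
#' @export
curves_from_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- default_references()
  for (label in names(spec)) {
    s <- spec[[label]]
    rng <- as.numeric(s$range)
    fn <- switch(
      s$type,
      polynomial = {
        coef <- as.numeric(s$coefficients)
        poly <- function(ga) {
          drop(outer(ga, seq_along(coef) - 1, `^`) %*% coef)
        }
        if (isTRUE(s$log_scale)) function(ga) exp(poly(ga)) else poly
      },
      table = {
        knots <- matrix(unlist(s$knots), ncol = 2, byrow = !is.matrix(s$knots))
        if (is.matrix(s$knots)) knots <- s$knots
        stats::splinefun(knots[, 1], knots[, 2], method = "hyman")
      },
      stop(sprintf("unknown curve type '%s' for '%s'", s$type, label),
           call. = FALSE)
    )
    curves[[label]] <- reference_curve(
      index_name = s$index, median_fn = fn, log_sd = as.numeric(s$log_sd),
      valid_range = rng,
      provenance = sprintf("loaded from %s (%s)", basename(path), label)
    )
  }
  curves
}
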