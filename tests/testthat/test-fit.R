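test_that("single binary predictor recovers the closed-form 2x2 log OR", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(16:30, 1)
    x <- runif(n) < 0.5
    y <- runif(n) < plogis(-0.5 + 1.5 * x)
    tab_ok <- all(table(factor(y, levels = c(F, T)),
                        factor(x, levels = c(F, T))) > 0)
    if (!tab_ok) next
    fit <- fit_ifc(tibble::tibble(ifc = y, exposed = x), "exposed")
    expect_equal(tidy(fit)$estimate[2], logor_2x2(y, x), tolerance = 1e-6)
    # intercept is the log odds of the event in the unexposed group
    expect_equal(tidy(fit)$estimate[1],
                 qlogis(sum(y & !x) / sum(!x)), tolerance = 1e-6)
  }
})

test_that("odds ratios are exp(beta) and round-trip exactly", {
  expect_identical(odds_ratio(0), 1)
  b <- c(-3.9666, 1.40944, -0.07083, -0.04431, 2.5)
  expect_equal(log(odds_ratio(b)), b, tolerance = 1e-12)
  expect_error(odds_ratio(Inf), "finite")
  # the Wald CI brackets the OR for every term of a real fit
  a <- assess_growth(simulate_cohort(seed = 15))
  f <- fit_ifc(a, c("mca_pi_mom", "pct_exfw3t"))
  tt <- tidy(f)
  expect_true(all(tt$or_low < tt$or & tt$or < tt$or_high))
  expect_equal(tt$or, exp(tt$estimate))
})

test_that("AIC identity holds and glance reports it", {
  a <- assess_growth(simulate_cohort(seed = 23))
  f <- fit_ifc(a, c("mca_pi_mom", "pct_exfw3t", "maternal_height_cm"))
  g <- glance(f)
  expect_equal(g$AIC, 2 * 4 - 2 * g$logLik, tolerance = 1e-12)
  expect_equal(g$AIC, stats::AIC(f$glm), tolerance = 1e-9)
  expect_equal(g$n, 777)
  expect_equal(g$n_events, 52)
})

test_that("affine predictor rescaling changes beta but not fit quality", {
  a <- assess_growth(simulate_cohort(seed = 31))
  f1 <- fit_ifc(a, "mca_pi_mom")
  a$mca_scaled <- 10 * a$mca_pi_mom + 3
  f2 <- fit_ifc(a, "mca_scaled")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-6)
  expect_equal(f1$roc$auc, f2$roc$auc, tolerance = 1e-12)
  expect_equal(tidy(f2)$estimate[2], tidy(f1)$estimate[2] / 10,
               tolerance = 1e-6)
})

test_that("perfect separation is flagged, never silent", {
  y <- rep(c(FALSE, TRUE), each = 20)
  co <- tibble::tibble(ifc = y, marker = as.numeric(y) + runif(40, 0, 0.5))
  f <- fit_ifc(co, "marker")
  expect_false(f$converged)
  expect_true(glance(f)$auc == 1)
})

test_that("degenerate inputs are rejected with named errors", {
  a <- assess_growth(simulate_cohort(cohort_spec(60, 6), seed = 2))
  a$flat <- 1
  expect_error(fit_ifc(a, "flat"), "constant")
  expect_error(fit_ifc(a, "nonexistent"), "nonexistent")
  b <- a; b$ifc <- FALSE
  expect_error(fit_ifc(b, "mca_pi_mom"), "event")
  expect_error(fit_ifc(a, c("mca_pi_mom", "mca_pi_mom")))
})

test_that("complete-case handling logs the dropped count", {
  a <- assess_growth(simulate_cohort(cohort_spec(100, 10), seed = 3))
  a$mca_pi_mom[c(4, 9, 44)] <- NA
  f <- fit_ifc(a, "mca_pi_mom")
  expect_equal(f$n, 97)
  expect_equal(f$n_dropped, 3)
})

test_that("univariable screen returns one row per candidate and survives failures", {
  a <- assess_growth(simulate_cohort(seed = 12))
  a$flat <- 5
  cands <- c("mca_pi_mom", "flat", "ua_pi_mom")
  scr <- univariable_screen(a, cands)
  expect_equal(nrow(scr), 3)
  expect_equal(scr$predictor, cands)
  expect_match(scr$error[2], "constant")
  expect_true(all(is.na(scr[2, c("estimate", "aic", "auc")])))
  expect_false(anyNA(scr$aic[c(1, 3)]))
  # the cerebral marker separates groups more strongly than the umbilical one
  expect_lt(scr$aic[1], scr$aic[3])
})

test_that("the predefined model battery matches the published structure", {
  pm <- predefined_models()
  expect_equal(sum(pm$type == "multivariable"), 8)
  expect_equal(sum(pm$type == "univariable"), 12)
  expect_equal(pm$predictors[pm$model ==
                 "Model 3: MCA PI MoM + EFWc (local) + maternal height"][[1]],
               c("mca_pi_mom", "efwc_local", "maternal_height_cm"))
  expect_equal(pm$predictors[pm$model ==
                 "Model 8: CPR MoM + %ExFW3t + maternal height"][[1]],
               c("cpr_mom", "pct_exfw3t", "maternal_height_cm"))
  multi <- pm$predictors[pm$type == "multivariable"]
  expect_true(all(vapply(multi, function(p)
    any(c("mca_pi_mom", "cpr_mom") %in% p), logical(1))))
})

test_that("AIC ranking sorts, flags the 2-unit rule and validates n", {
  a <- assess_growth(simulate_cohort(seed = 44))
  fits <- list(fit_ifc(a, "mca_pi_mom"), fit_ifc(a, "maternal_age"),
               fit_ifc(a, c("mca_pi_mom", "maternal_height_cm")))
  rk <- rank_models_by_aic(fits)
  expect_equal(rk$AIC, sort(rk$AIC))
  expect_equal(rk$distinguishable[-1], diff(rk$AIC) >= 2)
  expect_equal(rk$delta_aic, rk$AIC - rk$AIC[1])
  # a single fit ranks first trivially
  expect_equal(rank_models_by_aic(fits[1])$rank, 1)
  # fits on different n are not comparable
  b <- assess_growth(simulate_cohort(cohort_spec(300, 20), seed = 44))
  expect_error(rank_models_by_aic(list(fits[[1]], fit_ifc(b, "mca_pi_mom"))),
               "not comparable")
})

test_that("a pure-noise predictor costs about one AIC unit on average", {
  # E[delta AIC] = 2 - 2 E[delta loglik] with delta loglik ~ chi-sq(1)/2
  set.seed(60)
  n <- 250
  deltas <- replicate(400, {
    y <- runif(n) < 0.15
    x <- rnorm(n)
    noise <- rnorm(n)
    co <- tibble::tibble(ifc = y, x = x, noise = noise)
    fit_ifc(co, c("x", "noise"))$aic - fit_ifc(co, "x")$aic
  })
  # mean delta AIC 1 with MC standard error sqrt(2/400) ~ 0.07
  expect_equal(mean(deltas), 1, tolerance = 0.35)
})
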