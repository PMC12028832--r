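test_that("identical spec and seed give a byte-identical cohort", {
  a <- simulate_cohort(seed = 42)
  b <- simulate_cohort(seed = 42)
  expect_identical(a, b)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, pa); write_cohort(b, pb)
  expect_identical(readBin(pa, "raw", file.size(pa)),
                   readBin(pb, "raw", file.size(pb)))
  expect_false(identical(a, simulate_cohort(seed = 43)))
})

test_that("simulation does not disturb the global RNG stream", {
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(simulate_cohort(cohort_spec(50, 5), seed = 9))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("cohort has the spec'd sizes and fixed event count", {
  spec <- cohort_spec(n_total = 300, n_ifc = 30)
  co <- simulate_cohort(spec, seed = 8)
  expect_equal(nrow(co), 300)
  expect_equal(sum(co$ifc), 30)
  expect_false(any(is.na(co$ifc)))
  expect_error(cohort_spec(n_total = 100, n_ifc = 100), "n_ifc")
})

test_that("zero scales give degenerate group-constant covariates", {
  spec <- cohort_spec(
    n_total = 40, n_ifc = 8,
    mca_pi_mom = list(no_ifc = c(0.97, 0), ifc = c(0.81, 0)),
    ua_pi_mom = list(no_ifc = c(1.09, 0), ifc = c(1.19, 0)),
    maternal_height_cm = list(no_ifc = c(162.9, 0), ifc = c(160.2, 0)),
    pct_exfw3t = list(no_ifc = c(97.52, 0), ifc = c(89.9, 0)),
    efw20_mom = c(0.97, 0)
  )
  co <- simulate_cohort(spec, seed = 3)
  a <- assess_growth(co)
  # back-solve consistency: the assessment recovers the drawn values exactly
  expect_equal(a$mca_pi_mom, ifelse(a$ifc, 0.81, 0.97), tolerance = 1e-9)
  expect_equal(a$ua_pi_mom, ifelse(a$ifc, 1.19, 1.09), tolerance = 1e-9)
  expect_equal(a$cpr_mom, ifelse(a$ifc, 0.81 / 1.19, 0.97 / 1.09),
               tolerance = 1e-9)
  expect_equal(a$pct_exfw3t, ifelse(a$ifc, 89.9, 97.52), tolerance = 1e-9)
  expect_equal(a$efw20_mom, rep(0.97, 40), tolerance = 1e-9)
  expect_equal(a$maternal_height_cm, round(ifelse(a$ifc, 160.2, 162.9), 1))
})

test_that("group-conditional sample means sit near the spec locations", {
  spec <- cohort_spec()
  vars <- c(mca = "mca_pi_mom", ua = "ua_pi_mom", pct = "pct_exfw3t",
            height = "maternal_height_cm")
  # widely spaced seeds so replicate RNG streams are effectively independent
  reps <- lapply(1:20, function(s) {
    a <- assess_growth(simulate_cohort(spec, seed = 5000 + 97 * s))
    sapply(vars, function(v) tapply(a[[v]], a$ifc, mean))
  })
  pooled <- Reduce(`+`, reps) / length(reps) # rows: FALSE (no IFC), TRUE (IFC)
  # pooled over 20 replicates, means must sit within 3 SE of the targets
  n <- c(20 * 725, 20 * 52)
  check <- function(obs, target, sd) {
    expect_true(all(abs(obs - target) < 3 * sd / sqrt(n)),
                label = sprintf("means %s near %s", toString(round(obs, 3)),
                                toString(target)))
  }
  check(pooled[, "mca"], c(0.97, 0.81), c(0.22, 0.21))
  check(pooled[, "ua"], c(1.09, 1.19), c(0.24, 0.33))
  check(pooled[, "pct"], c(97.52, 89.9), c(13.5, 13))
  check(pooled[, "height"], c(162.9, 160.2), c(6.0, 7.8))
})

test_that("the MCA/UA copula hits the target rank correlation", {
  spec <- cohort_spec(n_total = 4000, n_ifc = 267)
  a <- assess_growth(simulate_cohort(spec, seed = 21))
  rho <- cor(a$mca_pi_mom[!a$ifc], a$ua_pi_mom[!a$ifc], method = "spearman")
  expect_lt(abs(rho - (-0.2)), 0.06)
})

test_that("the built-in group differences vanish under label permutation", {
  a <- assess_growth(simulate_cohort(seed = 17))
  vars <- c("mca_pi_mom", "ua_pi_mom", "pct_exfw3t", "maternal_height_cm")
  set.seed(99)
  p <- replicate(100, {
    perm <- a
    perm$ifc <- sample(perm$ifc)
    compare_groups(perm, vars)$p_value
  })
  expect_gt(median(p), 0.1)
})

test_that("logistic outcome simulation has the right prevalence", {
  d <- simulate_from_logistic(c(mca_pi_mom = 0), intercept = 0, n = 2000,
                              seed = 2)
  expect_equal(attr(d, "expected_prevalence"), 0.5)
  # observed prevalence within 3 SE of 0.5
  expect_lt(abs(mean(d$ifc) - 0.5), 3 * sqrt(0.25 / 2000))
  # intercept -10: event probability ~4.5e-5, so near-zero events at n = 777
  d2 <- simulate_from_logistic(c(mca_pi_mom = 0), intercept = -10, n = 777,
                               seed = 2)
  expect_equal(attr(d2, "expected_prevalence"), plogis(-10))
  expect_lte(sum(d2$ifc), 1)
  expect_error(
    simulate_from_logistic(c(nope = 1), intercept = 0, n = 10, seed = 1),
    "nope"
  )
})

test_that("logistic simulation prevalence matches its Monte-Carlo expectation", {
  beta <- c(mca_pi_mom = -3.533, pct_exfw3t = -0.02645,
            maternal_height_cm = -0.06240)
  prev <- vapply(1:30, function(s) {
    d <- simulate_from_logistic(beta, intercept = 13.32, n = 777,
                                seed = 400 + s)
    c(mean(d$ifc), attr(d, "expected_prevalence"))
  }, numeric(2))
  p_exp <- mean(prev[2, ])
  se <- sqrt(p_exp * (1 - p_exp) / (30 * 777))
  expect_lt(abs(mean(prev[1, ]) - p_exp), 3 * se)
})
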