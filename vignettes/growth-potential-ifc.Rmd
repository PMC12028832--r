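---
title: "Growth potential, Doppler MoM and the prediction of intrapartum fetal compromise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth potential, Doppler MoM and the prediction of intrapartum fetal compromise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifcgrowth)
library(dplyr)
```

## The problem and the model

Intrapartum fetal compromise (IFC) — loss of fetal well-being during labor,
operationalised here as an urgent cesarean section for an abnormal
cardiotocogram or fetal scalp pH — is the outcome every term-pregnancy
surveillance strategy tries to anticipate. Two families of ultrasound
markers compete for that job: *ponderal* ones (estimated fetal weight and
its centiles) and *haemodynamic* ones (umbilical and middle cerebral artery
pulsatility indices and their ratio, the cerebroplacental ratio, whose low
values signal "brain-sparing" blood-flow redistribution).

`ifcgrowth` implements a growth-potential variant of the ponderal family.
The idea: most growth-restricting influences are placental and act in the
second half of pregnancy, so the mid-pregnancy (20-week) estimated fetal
weight (EFW) is a usable proxy of the fetus's growth *potential*. Carrying
that potential forward with multiples of the median (MoM):

* `EFW MoM(20w) = EFW(20w) / median EFW(20w)`,
* expected third-trimester weight `ExFW3t = EFW MoM(20w) × median EFW(ga3t)`,
* percentage of expected weight achieved
  `%ExFW3t = 100 + 100 (EFW3t − ExFW3t)/ExFW3t = 100 · EFW3t / ExFW3t`.

A fetus that grew 25% beyond its extrapolated expectation has
`%ExFW3t = 125`; one that fell 25% short has `%ExFW3t = 75`. The package
then asks the comparative question: does `%ExFW3t` predict IFC better than
EFW centiles, better than cerebral Doppler? The machinery for answering is
the usual clinical-epidemiology stack, all included: univariable logistic
screens, eight predefined multivariable logistic models (every one anchored
on a cerebral Doppler term), odds ratios with Wald 95% intervals, AIC
ranking with the two-unit rule, and ROC analysis with DeLong intervals and
detection rates at 5% and 10% false-positive rates.

```{r worked}
refs <- default_references()
exfw <- expected_fw_3t(efw20 = 380, ga20 = 20, ga3t = 38, efw_curve = refs$efw_local)
round(exfw)
pct_expected_fw(efw3t = 1.25 * exfw, exfw3t = exfw)
pct_expected_fw(efw3t = 0.75 * exfw, exfw3t = exfw)
```

## Reference curves: what ships and why

Every MoM and centile needs a gestational-age reference. Four curves ship
as defaults, all replaceable through `curves_from_json()`:

| curve | default | role |
|---|---|---|
| `efw_local` | log-quadratic, 373.5 g at 20 wk, 3250 g at 39 wk, log-SD 0.18 | EFW MoM, `%ExFW3t`, local centiles |
| `efw_intergrowth_like` | local median × 0.985, log-SD 0.19 | alternative centile standard (synthetic stand-in, not the published international standard) |
| `ua_pi` | quadratic, decreasing 1.21 → 0.80 over 20–40 wk | UA PI MoM |
| `mca_pi` | quadratic, interior maximum ≈ 2.04 at 29.3 wk | MCA PI MoM |
| `cpr` | ratio of the MCA and UA medians | CPR MoM |

Two of these choices deserve comment.

**The published EFW-median quadratic is shipped verbatim but not used for
weights.** The originally printed coefficients
(−3.266164164 + 0.368135209·GA − 0.006318278·GA²) evaluate to ≈ 1.5–2.1
over 20–41 weeks with a peak near 29 weeks — a magnitude and shape that
cannot be fetal weight in grams (term median ≈ 3,200 g) but is typical of a
Doppler pulsatility index. `printed_efw_median()` keeps the formula exactly
as printed, for traceability; the pipeline's working EFW median is the
configurable gram-scale curve above. Its 20-week value (373.5 g) is
calibrated so that a cohort whose mean 20-week EFW is 362.3 g has a mean
EFW MoM of 0.97, keeping the descriptive statistics internally consistent.

**The CPR median is the ratio of the MCA and UA medians.** Whether the CPR
reference should be an independent curve or the ratio of its components is
genuinely open; the ratio convention is chosen because it makes
`CPR MoM = MCA MoM / UA MoM` hold exactly (a property the tests verify),
and an independent curve can be loaded when one is available.

Centiles use a log-normal model throughout: `z = log(value/median)/log_sd`,
centile `100·Φ(z)`. This is monotone in the value, maps the median to the
50th centile exactly, and inverts in closed form (`value_from_centile()`),
which the synthetic generator exploits. It does not reproduce any
particular published centile standard's skewness; for the model-comparison
purpose of this package only the monotone map and correct median behaviour
matter.

## The synthetic cohort: what it emulates, what it does not

`simulate_cohort()` generates a two-group screening population whose
defaults are a 777-pregnancy cohort with exactly 52 IFC events (prevalence
6.7%, fixed by count so descriptive tables replicate exactly). The
group-conditional laws mirror the study population the package is designed
around: IFC pregnancies have lower MCA PI MoM (0.81 vs 0.97, SD ≈ 0.21),
higher UA PI MoM (1.19 vs 1.09), shorter mothers (160.2 vs 162.9 cm) and a
lower `%ExFW3t` (89.9 vs 97.5), while the 20-week EFW MoM is drawn from the
*same* law in both groups — encoding the finding that both groups start
with the same growth potential and differ only in how much of it they
realise. Positive, mildly skewed quantities (MoMs, `%ExFW3t`, BMI) are
log-normal with parameters matched to the target mean/SD; height and age
are normal. MCA and UA MoMs are drawn through a Gaussian copula at rank
correlation −0.2 (mild haemodynamic redistribution; an assumption, not an
estimated value).

Raw scan values are then *back-solved* through the reference curves
(EFW in grams from the drawn MoM, raw PIs from the drawn Doppler MoMs), so
`assess_growth()` run on a generated cohort recovers the drawn quantities —
the whole pipeline is exercised end to end, not just the summary columns.
EFW centiles are consequently *derived*, not drawn: `%ExFW3t` and the
20-week MoM determine the third-trimester EFW MoM and hence the centile.
Drawing centiles independently would contradict the back-solve consistency
that the tests enforce.

What the generator deliberately does **not** emulate:

* **Cross-family covariate correlation.** In real pregnancies cerebral
  Doppler and weight metrics are positively correlated (brain-sparing
  accompanies restricted growth). Here only the MCA–UA pair is correlated;
  Doppler and weight covariates are independent given the outcome group.
  One consequence is quantified below.
* **Process dynamics.** Labor onset, interval to delivery, birthweight and
  neonatal columns are static draws at the study's margins, good enough for
  descriptive tables but not for modelling time-to-delivery.
* **Raw biometry.** The four-parameter Hadlock formula is not invertible to
  BPD/HC/AC/FL, so generated cohorts carry `efw_grams` directly (the cohort
  contract allows either); `hadlock4_efw()` is used when a real cohort
  carries raw biometry.

So a green test suite shows the *machinery* is correct under a faithful
null/alternative structure; it does not validate the clinical claim on real
data.

## What passes, and one thing that does not

All formula identities, oracle equivalences (trapezoidal AUC =
Mann–Whitney U/(n₁n₀) to 1e-12; logistic fits vs closed-form 2×2 log odds
ratios; DeLong intervals vs an independent reference implementation),
coverage and type-I-error simulations pass at their stated tolerances.

One qualitative replication target is *not* met, and we left it red rather
than tune anything: the requirement that, in ≥95% of seeds, cerebral
Doppler univariable models out-rank all weight-based ones by AIC *and* a
three-term model tops the multivariable ranking. Measured over 100 seeds
the joint rate is ≈ 0.81 (≈ 0.89 and ≈ 0.91 for the two parts). The reason
is power, not a defect: with 52 events, the expected AIC gap between the
MCA model (likelihood-ratio statistic ≈ 26) and the `%ExFW3t` model (≈ 15)
is ~11 units, while the between-seed standard deviation of that difference
for *independent* markers is ~13 (the variance of a noncentral χ²₁(λ) is
2 + 4λ). The missing cross-family correlation noted above would shrink that
variance in real data; under the generator's independence structure the
ordering simply cannot be stable in 95% of seeds. The observed single
cohort of the original analysis is one draw from exactly this kind of
distribution.

## Numerical and procedural choices

* **Logistic fits**: IRLS (`stats::glm`, binomial), convergence tolerance
  1e-10, max 100 iterations. Wald SEs from the observed information. Fits
  with a slope |β| > 15 or a non-converged IRLS loop are flagged
  `converged = FALSE` (quasi-separation), never silently returned. The
  intercept is excluded from the divergence check: with height in cm and
  `%ExFW3t` in percent, intercepts near 13 are legitimate.
* **Confidence intervals**: Wald on the log-odds scale
  (`exp(β ± 1.959964·se)`), the convention matching symmetric-on-log-scale
  clinical reporting. Profile-likelihood intervals are out of scope.
* **Missing data**: complete-case per model, with the dropped count kept in
  `glance()`. No multiple-testing correction in the univariable screen (a
  deliberate mirror of standard practice in this literature; stated in the
  report metadata).
* **ROC**: empirical curve over all unique thresholds; ties handled by
  grouping; AUC by the trapezoidal rule. Detection rate at a fixed FPR uses
  the step-function convention — the TPR at the most permissive threshold
  whose FPR does not exceed the target — because it never credits a model
  with sensitivity it cannot deliver at that budget; a linearly
  interpolated variant sits behind `interpolate = TRUE` for sensitivity
  analysis. AUC intervals are DeLong's; a degenerate AUC of 0 or 1
  collapses the interval with a warning.
* **Group comparisons**: Mann–Whitney via the tie-corrected normal
  approximation (no continuity correction) for continuous variables;
  Pearson chi-square without Yates correction for categorical ones (cell
  counts in the intended applications are ≥ 5); Fisher's exact test behind
  a flag for small cells.
* **AIC ranking**: ascending; adjacent models flagged distinguishable iff
  ΔAIC ≥ 2; ties broken by higher AUC, then fewer parameters. Fits on
  different n refuse to be ranked together.
* **Gestational age** is kept at full precision `weeks + days/7`; rounding
  to two decimals is display-only, so MoM conversions accumulate no
  rounding error.
* **Problem sizes in the test suite** were chosen to estimate each Monte
  Carlo quantity with adequate precision at interactive runtimes: 200
  replicate cohorts of n = 777 for coverage (binomial SE ≈ 1.5%), 1,000
  permutations for the type-I error (SE ≈ 0.7%), 1,000 random instances for
  the AUC/U identity, 100 seeds for the qualitative ranking rate.

## Known limitations

* The two shipped EFW references are pragmatic defaults, not published
  standards; real deployments should load their population's curves via
  `curves_from_json()`. Output metadata records the provenance of whatever
  curves were used.
* Wald intervals and p-values degrade with very few events; with fewer than
  ~20 events per model, profile or exact methods (not provided) would be
  preferable.
* The generator's independence structure makes model-ranking replication
  conservative, as quantified above.
* `%ExFW3t` inherits all the measurement error of two EFW estimates; the
  package quantifies its predictive value but cannot correct that error.

## Reproducing the analysis end to end

```{r pipeline}
report <- run_ifc_pipeline(seed = 20260919)
report$table5 %>% select(rank, model, AIC, delta_aic, auc) %>% head(8)
```

`run_ifc_pipeline(..., out_dir = "...")` writes the full bundle — five
analysis tables, per-model ROC curves and run metadata, every file stamped
with the seed and a configuration fingerprint — and identical seed + config
reproduce it byte for byte.
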