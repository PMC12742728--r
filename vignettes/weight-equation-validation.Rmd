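---
title: "Validating anthropometric weight-prediction equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating anthropometric weight-prediction equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthroweight)
```

## The problem

Safe drug dosing needs the patient's weight, but in emergencies and in many
low-resource clinics a working, calibrated scale is often unavailable, and
bedridden or obtunded patients cannot stand on one or report their own
weight. A long line of work therefore predicts weight from body measurements
that *can* be taken with a tape or caliper at the bedside: mid-arm
circumference (MAC), abdominal circumference (AC), calf circumference (CC),
hip circumference (HC), knee height (KH), subscapular skinfold thickness
(SST) and standing height (H).

`anthroweight` packages nine published linear prediction rules together with
the method-comparison machinery used to decide which of them is fit for
clinical use in a given population, and a synthetic cohort generator so the
whole pipeline can be exercised and stress-tested without access to any
participant-level data.

## The equations

Each rule is a linear combination of measurements, sometimes with separate
male/female coefficient sets (Chumlea, Crandall, Lorenz, Jung) and sometimes
with a numeric coded-sex regressor (male = 1, female = 2; Rabito 3). The full
registry is data, not code — inspect it with `equation_registry()` or audit
the bundled YAML copy in `inst/extdata/equations.yaml`. For example, Rabito
equation 3 is

$$\hat W = 0.5759\,\mathrm{MAC} + 0.5263\,\mathrm{AC} + 1.2452\,\mathrm{CC}
 - 4.8689\,S - 32.9241$$

with all circumferences in cm and $S$ the coded sex.

```{r}
predict_weight(list(mac_cm = 28.6, ac_cm = 81.8, cc_cm = 34.5, sex = "male"), "R3")
```

Units are fixed as published (cm for lengths and circumferences, mm for SST,
years for age); the ingest layer rejects out-of-range values rather than
converting or clamping, because silent unit slips are the dominant failure
mode for formulas like these. Predictions are never rounded internally —
rounding (2 decimals, half-up) happens only in report formatting. A
prediction can come out non-positive for extreme inputs (e.g. Cattermole's
$4\,\mathrm{MAC} - 50$ at a very small arm); such values are returned as-is
and flagged implausible in reports, because masking them would hide exactly
the pathology a validation study is meant to expose.

## The accuracy framework

For a set of prediction/measurement pairs the package computes the standard
criteria of this literature:

* **P10 / P20** — the percentage of predictions whose absolute relative
  error is within 10% (20%) of the measured weight, boundary inclusive.
  Clinical adequacy conventions are P10 > 70% and P20 > 95%.
* **MPE** — mean signed percentage error, under the convention
  $100(\hat W - W)/W$ (positive = overestimation). Published tables in this
  area are not always internally consistent about the sign; the convention
  here is fixed, documented in every run manifest, and P10/P20 — which are
  sign-symmetric — are unaffected by it.
* **Bland–Altman agreement** — differences $d_i = \hat W_i - W_i$ (estimate
  minus reference), bias $\bar d$, 95% limits of agreement
  $\bar d \pm 1.96\,s$ with $s$ the sample SD of the differences, and
  confidence intervals in the classical large-sample form: SE of the bias
  $s/\sqrt n$, SE of each limit $s\sqrt{3/n}$, both with Student-$t$
  critical values at $n-1$ df. The multiplier is the conventional 1.96, not
  a $t$ quantile. CIs require $n \ge 3$; zero-variance differences collapse
  the limits onto the bias and are flagged degenerate rather than erroring.

Subgroup analysis stratifies by sex and by WHO adult BMI category computed
from measured weight and height (underweight < 18.5, normal [18.5, 25),
overweight [25, 30), obese ≥ 30 kg/m²; lower boundaries inclusive). The WHO
cutoffs are the package's choice of operationalization for "nutritional
status", the default for adult cohorts. Non-evaluable predictions (missing
required measurements) are excluded pairwise per equation with
`n_evaluated` reported; nothing is imputed.

```{r}
cohort <- generate_cohort(synthetic_config(n_per_stratum = 10, seed = 1))
bundle <- run_validation(cohort)
bundle$overall[, c("equation", "n_evaluated", "p10", "p20", "mpe")]
```

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` reproduces the *design* of a quota-sampled validation
study: equal numbers of participants in each sex × nutrition stratum
(default 30 per stratum, 240 in total), so that the nutritional extremes
where these equations break down are well represented rather than sampled in
proportion to their population prevalence.

Within a stratum, height is drawn from a sex-specific normal distribution
(males 167 ± 8.4 cm, females 159.5 ± 6.4 cm, truncated to 100–250 cm), BMI
from a truncated normal confined to the stratum's WHO interval, and weight
is set to $\mathrm{BMI}\cdot(\mathrm{height}/100)^2$ — so every emitted
record's BMI lies in its stratum by construction. The remaining
measurements are linear functions of weight, height or BMI plus Gaussian
noise truncated above physiological floors (e.g. MAC ≈ 0.35·weight + 6 cm
± 1 cm). These derivation coefficients are package defaults calibrated so
that the default cohort's marginal medians land near a young-adult
outpatient population (weight ≈ 64.5 kg, height ≈ 162.5 cm, MAC ≈ 28.6 cm);
they are exposed in `synthetic_config()` rather than hard-coded, because a
real population is characterized by a joint distribution that marginal
summaries cannot pin down.

That is also the honest limitation: the generator emulates marginal
locations, quota structure and first-order physiological correlation, not
the true multivariate anthropometry of any population — no age trends, no
skewness beyond what truncation induces, no measurement-protocol error
structure. A pipeline that passes its tests on synthetic cohorts is shown to
be *computationally correct* (it recovers planted truths and satisfies the
metric identities); it is not thereby shown that any particular equation is
accurate in a real population. That question needs real measurements, which
is exactly what the ingest layer (`read_records()`) is for.

`plant_equation_truth()` supports the strongest such computational check:
it rewrites measured weight as a chosen equation's prediction plus
`Normal(0, sd)` noise, so the validation pipeline runs against a known
ground truth. With 2 kg noise on 240-record cohorts the planted equation
should — and in the test suite does — take the top P10 rank in at least
9 of 10 seeded replicates, and with zero noise it scores P10 = P20 = 100
exactly.

```{r}
planted <- plant_equation_truth(
  synthetic_config(seed = 42, planted_equation = "R3", planted_noise_sd = 2)
)
rep <- stratified_accuracy(planted, "all", axes = "overall")
rep[order(-rep$p10), c("equation", "p10", "p20")][1:3, ]
```

## Numerical and design choices

* **Quantiles.** Descriptive IQRs use linear interpolation between order
  statistics (`stats::quantile` type 7, the mainstream default). At a few
  hundred records the IQR endpoints are sensitive to this definition, so it
  is echoed in every run manifest.
* **Rounding.** Display values round half away from zero at 2 decimals
  (matching how results tables in this literature are printed); machine
  precision values are carried alongside in every report, and all internal
  comparisons use full precision.
* **P10 boundary.** "Within 10%" includes equality. At the 0.1 kg
  resolution of a clinical scale the choice is practically immaterial, but
  it is fixed and tested.
* **Truncated sampling.** Rejection sampling with an iteration cap;
  breaching the cap is a configuration error, never a silent relaxation of
  the bounds. Only out-of-bounds draws are redrawn, and strata are generated
  in a fixed order from one seeded stream, so cohorts are byte-identical
  given a config.
* **Ingest.** Whole rows are rejected (with row number and reason) when any
  field fails validation: unparseable numbers, non-positive measurements,
  implausible heights (outside 100–250 cm), unrecognizable sex labels.
  Missing fields are acceptable — the affected equations simply report the
  record non-evaluable. Duplicate participant ids abort the ingest, since
  they usually indicate a join or transcription accident upstream.
* **Determinism.** Manifests contain no timestamps; identical inputs
  produce byte-identical CSV/JSON/YAML reports, so report files can be
  diffed across runs and machines.

## Problem sizes in the test suite

The suite validates equations against an independent literal transcription
on 10,000 randomized records, checks Bland–Altman statistics against a
brute-force loop oracle at machine precision on small instances and against
the asymptotic $\mu \pm 1.96\sigma$ limits on 100,000 simulated Normal
differences (within 3 Monte-Carlo standard errors), and runs
ranking-recovery over ten 240-record planted cohorts — sizes chosen to make
the statistical assertions sharp while the whole suite stays comfortably
fast on a single CPU.

## Known limitations

* The registry covers linear tape-and-caliper rules; tape-lookup systems
  (e.g. length-band methods) and any re-fitting of coefficients are out of
  scope.
* BMI-based nutrition strata require measured weight and height; on cohorts
  where height is missing the nutrition axis is unavailable.
* MPE and the limits of agreement are reported under one documented sign
  convention; comparisons with tables published under a different (or
  mixed) convention should rely on the sign-symmetric P10/P20.
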