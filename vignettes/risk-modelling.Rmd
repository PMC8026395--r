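---
title: "Modelling gynecological cancer risk and surgery benefit in Lynch syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gynecological cancer risk and surgery benefit in Lynch syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchrrs)
```

## The estimation problem

Prospective registries of Lynch syndrome carriers observe each woman from a
planned inclusion examination until her last contact, recording
risk-reducing surgeries, incident endometrial (EC) and ovarian (OC) cancers,
and deaths. Penetrance — the probability that a carrier of a given
mismatch-repair gene develops cancer by a given age — must be estimated from
these staggered, censored observation windows. `lynchrrs` implements the
registry-style estimator: annual incidence rates in 5-year age bins,
converted to cumulative incidence by an annual recursion, combined with
pooled crude survival after cancer, and finally re-expressed as the cancers
and deaths a risk-reducing hysterectomy and/or bilateral
salpingo-oophorectomy (BSO) at a chosen age would prevent.

Assumptions worth stating explicitly:

* **Zero incidence before 25.** Prospective observation starts at 25; the
  cumulative incidence curve is anchored at Q(25) = 0.
* **Piecewise-constant hazards.** The annual rate estimated from a 5-year
  bin applies uniformly to each year in the bin; no smoothing.
* **Censoring at organ removal.** A woman leaves the EC risk set at
  hysterectomy and the OC risk set at BSO; for the combined endpoint she
  remains at risk while at least one organ is intact (configurable, see
  below).
* **Survival pooled over genes and ages.** Case numbers after cancer are too
  small for stratified survival; one EC and one OC 10-year crude survival is
  applied to every cell, and combined-endpoint survival is a risk-weighted
  interpolation between them.
* **Counterfactual benefit.** "Cancers prevented by surgery at age a" is the
  conditional risk the woman would otherwise carry over [a, b); no surgical
  morbidity, hormonal consequences or competing mortality enters the
  benefit measure.

## Person-years and censoring rules

For endpoint E, each record contributes the interval from
`max(age_inclusion, 25)` to the earliest of last observation, removal of the
organ(s) defining E, diagnosis of E, and 75, accumulated as exact fractional
overlaps with the bins \[25,30), ..., \[70,75). Three deliberate edge rules:

* A diagnosis at exactly the surgery age **counts as an event** and then
  censors: registries record occult cancers found at risk-reducing surgery
  as cancers.
* A diagnosis at or before inclusion marks a **previous cancer**: the record
  is kept (it still contributes to the other organ's risk set) but yields
  neither time nor events for that endpoint.
* Bins are half-open; an event at exactly 75 is out of range.

The combined EC-and/or-OC risk set is not defined in registry reports when a
woman has had one organ removed. The default here (`"both-organs"`) keeps
her at combined risk while either organ remains, which matches the
"endometrial and/or ovarian cancer" reading of the endpoint; the
`"any-surgery"` flag censors at the first surgery for sensitivity analysis.

Bins with fewer than `min_py = 10` person-years are flagged unreliable and
the flag propagates into the curve metadata rather than being imputed; a bin
with zero person-years contributes a zero rate with a warning.

## From rates to risks

The annual recursion

```
Q(age) = Q(age - 1) + (1 - Q(age - 1)) * AIR(age),  Q(25) = 0
```

is algebraically `1 - prod(1 - AIR(t))` and the implementation is tested to
agree with that closed form to 1e-12. Conditional interval risks
`(Q(b) - Q(a)) / (1 - Q(a))` compose exactly across a middle age
(`compose_interval_risks()`), which is also the internal-consistency check
applied to the tables. All table arithmetic uses unrounded probabilities;
whole-percent rounding (half away from zero) happens only at render time —
rounding earlier breaks the reproduction of several published cells.

## Crude survival and the combined endpoint

`kaplan_meier()` delegates the product-limit computation to
`survival::survfit` with all-cause death as the event ("crude" survival);
`cancer_deaths_only = TRUE` restricts events to deaths attributed to the
followed cancer. Deaths are processed before tied censorings. Because EC
survival exceeds OC survival by a constant difference, survival after the
combined endpoint is interpolated as

```
S_comb = S_OC + (S_EC - S_OC) * EC_risk / (EC_risk + OC_risk)
```

per age window, with the endometrial fraction computed from unrounded
interval risks. When both risks are zero in a window (e.g. PMS2 before 50)
the survival cell is undefined and the death risk is zero.

When no combined-endpoint incidence curve is available the combined risk
falls back to `1 - (1 - EC)(1 - OC)`; the fallback is flagged in the output.
It is conservative in the sense of lying between `max(EC, OC)` and
`EC + OC` — the combined risk is below the sum because treatment of the
first cancer removes the other organ from risk.

## The synthetic-cohort generator

The generator exists so that every stage can be validated against known
truth. Its design choices:

* **Discrete annual Bernoulli hazards**, not continuous-time exponentials:
  the simulator is then the *exact* inverse of the annual recursion, and
  `analytic_interval_risk()` (`1 - prod(1 - h(t))`) is an exact oracle
  rather than an approximation.
* **Calibration.** Default hazards per gene are solved from the published
  cumulative EC/OC risks at ages 40/50/60/70 (`printed_interval_risks()`):
  constant within 25–40 and within each decade after 40, with the 60–70
  level continued over 70–75. Every anchor is reproduced exactly; PMS2 gets
  zero hazard below 50.
* **Event timing.** Events and surgeries are stamped at the end of the
  at-risk year (`age + 0.99` at the 0.01-year resolution). The event year
  then contributes 0.99 person-years before truncation, so the
  events/person-years estimator recovers the generating annual hazard with
  bias factor `1/(1 - 0.01 h)` — negligible against sampling error at any
  realistic size.
* **Competing structure.** EC and OC processes are independent given the
  gene; the first cancer is treated by hysterectomy + BSO at the diagnosis
  age, removing the other organ (a same-year double hit is resolved by a
  fair coin). Prophylactic surgery is an annual uptake probability,
  1%/year from age 40 by default — surgery after completed childbearing,
  with a `hysterectomy_only` flag.
* **Observation process.** Inclusion ages are whole years drawn from bin
  weights that skew young (16% down to 3% across bins 25..70), reflecting
  predictive testing in early adulthood; follow-up is `1 + Poisson(9)` years
  truncated at 30, giving a mean around 10 years so that a decade of
  post-diagnosis observation is well represented.
* **Survival.** Death after diagnosis follows a mixture-cure model: with the
  cure probability the woman never dies of the cancer in the window,
  otherwise the death time is exponential with a 3-year scale — a few early
  deaths, then a flat curve, which is the shape reported for mismatch-repair
  deficient gynecological cancers. The cure fraction is solved so model
  10-year survival equals the 0.89/0.84 targets exactly. Background
  mortality is off by default (`background_mortality` turns on a constant
  annual rate); crude survival in real registries includes it.
* A death inside the first observation year is recorded at inclusion + 1,
  since registry inclusion requires a completed year of follow-up.

What the generator does **not** emulate: family ascertainment, secular
trends in surgery uptake, age-dependent case fatality, genotype
misclassification, and correlated EC/OC risk beyond the shared gene. Passing
recovery tests therefore shows the estimator chain is correct under the
stated model, not that the model captures every feature of registry data.

## Problem sizes and numerical checks

The validation suite simulates 100,000 MLH1 women (about a million
person-years) for parameter recovery: every bin's estimated rate within 3
binomial standard errors of the generating hazard, Q(50) within 0.01 of the
closed form, and Kaplan–Meier 10-year survival within 0.02 of the calibrated
targets using the cohort's own ~8,000 EC and ~2,300 OC cases. Unit tests use
cohorts of 300–30,000 and 2,500 dedicated post-diagnosis records. The
recursion/closed-form agreement is tested on 1,000 random rate vectors at
1e-12. Exact Poisson (Garwood) intervals for rates use gamma quantiles.

## Known limitations

* Confidence intervals on cumulative incidence and on the table cells are
  out of scope (the Poisson rate CI is plumbing only); a bootstrap over
  records would be the natural extension.
* No competing-risk (Aalen–Johansen) estimator: simple censoring mirrors the
  registry methodology, and overstates absolute risk slightly in the
  presence of competing death.
* Published whole-percent tables are not perfectly self-consistent under
  rounding; the calibration anchors the cumulative rows, so a few derived
  conditional cells differ from print by one percentage point.
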