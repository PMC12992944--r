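---
title: "Risk-scored thromboprophylaxis after cesarean section: model, simulation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-scored thromboprophylaxis after cesarean section}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtecs)
```

## The clinical problem

Venous thromboembolism (VTE) is a leading cause of maternal morbidity and
mortality, and cesarean section (CS) raises the risk several-fold over
vaginal delivery. The major guidelines disagree sharply on when to add
pharmacologic prophylaxis (low-molecular-weight heparin, LMWH) to mechanical
measures: RCOG-style criteria capture most cesarean patients, ACCP-style
criteria a substantial minority, and ACOG-style criteria almost none beyond
women with prior VTE or high-risk thrombophilia. Institutions in
populations with different baseline risk — lower observed VTE incidence,
different body habitus — therefore adapt their own scoring protocols to keep
LMWH use low without losing protection.

`vtecs` implements one such department protocol as a declarative rule set,
together with comparator rule sets for the three guideline styles, a
synthetic cohort generator that reproduces the statistical structure such an
audit assumes, and the evaluation pipeline (incidence comparison, screening
metrics with exact intervals, number needed to screen/treat).

## The scoring model

Each patient is scored before the cesarean. Every risk factor contributes
one point unless stated:

| factor | points |
|---|---|
| age ≥ 40 years | 1 |
| BMI ≥ 25 and < 30 kg/m² | 1 |
| BMI ≥ 30 kg/m² | 2 (replaces the overweight point) |
| parity ≥ 3 | 1 |
| pre-eclampsia; multiple pregnancy; preterm delivery (< 34 completed weeks); prolonged labor > 24 h; stillbirth; medical comorbidity; low-risk thrombophilia; current smoker; gross varicose veins; current systemic infection; immobility; family history of VTE | 1 each |
| postpartum hemorrhage ≥ 1000 mL or transfusion | +1 markup after delivery |

Decision thresholds: a **final score of 2** prescribes a pneumatic
compression cuff during and after the cesarean; a **final score ≥ 3** adds
at least 10 days of postnatal enoxaparin (40 mg daily below 100 kg booking
weight, 60 mg at or above). Women already on antenatal LMWH are not scored:
they continue LMWH and receive a cuff, and they are excluded from cohort
tier breakdowns.

Two attribution rules matter for audits. First, the intraoperative cuff
decision is made from the *pre-operative* score: a patient who reaches 2
only through the hemorrhage markup is not counted as having had mechanical
prophylaxis during the operation, although the markup can still push her
over the LMWH threshold. Second, the markup is a single point regardless of
how dramatic the hemorrhage.

All cutoffs are data, not code: `vte_protocol()` exposes them as arguments
and `write_protocol_config()`/`read_protocol_config()` serialize a rule set
to YAML, so guideline-style variants (age 35 instead of 40, preterm 37
instead of 34 weeks, a pharmacologic threshold of 2) are expressible as
alternative configurations.

### Ambiguities resolved

The protocol's source material states the preterm cutoff both as
"< 34 weeks" and "≤ 34 weeks", and the hemorrhage markup both as
"≥ 1000 mL" and "> 1000 mL". We default to **strictly < 34 completed
weeks** (consistent with worked cases delivered at 31 and 33 weeks scoring
the preterm point while cases at 38–39 weeks do not) and to an **inclusive
≥ 1000 mL** markup (consistent with a worked case whose 1.0 L loss scored
the point). Both are constructor arguments. "Medical comorbidities" is one
boolean: two comorbidities still contribute one point. Whether a systemic
infection diagnosed intraoperatively counts at scoring time is not
specified anywhere; the package treats the flag as a plain input.

### A known inconsistency in the bundled case series

The bundled worked-example series (`vte_example_cases()`) contains sixteen
postpartum VTE cases with reference scores. One protocol-period case prints
a reference total of 1 alongside a factor list of age 40 and BMI 28 kg/m² —
which scores 2 under the rule set (age 40 is on the inclusive side of the
cutoff, as another case in the same series confirms). The engine scores
from the factor list; the tests assert agreement with the reference total
for the other fifteen cases and document this single disagreement rather
than forcing it. Relatedly, whole-cohort screening arithmetic in the source
audit implies nine high-scoring event cases where the case series lists
eight; the package asserts the series' eight and does not reconcile the
two.

## Comparator guidelines

The three comparators share a recoding interface (`recode_guideline()`,
or `predict()` on a `vte_guideline`):

* **RCOG-style** — mechanical prophylaxis for every cesarean; LMWH for any
  emergency (intrapartum/urgent) cesarean, or an elective one with at least
  one risk factor from a configurable list (defaults: age ≥ 35, BMI ≥ 30,
  parity ≥ 3, preterm < 37 weeks, major hemorrhage, and the boolean
  factors).
* **ACCP-style** — LMWH for ≥ 1 major factor, ≥ 2 minor factors, or 1 minor
  factor with an emergency cesarean. Major/minor designations are
  configuration; the shipped default designates prior VTE/high-risk
  thrombophilia, immobility and pre-eclampsia as major.
* **ACOG-style** — universal pneumatic compression; LMWH only for prior
  VTE or high-risk thrombophilia, which a post-exclusion cohort never has.

No published machine-readable factor list exists for the first two; the
defaults are documented approximations meant for *orderings* (RCOG-style
rate ≥ ACCP-style rate ≥ department rate), not for reproducing any
specific audit's percentages. Institutions recoding their own data should
pin their lists via `write_guideline_config()`; presets ship under
`system.file("extdata", "guidelines", package = "vtecs")`.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the evaluation
assumes, not any real population:

* every factor is an **independent Bernoulli** draw at its audited marginal
  prevalence (two period presets are bundled; the protocol-period set puts,
  e.g., 11.2% at age ≥ 40, 13% overweight, 4.97% obese, 58.6% emergency
  cesareans);
* continuous covariates are sampled **uniformly within the band** implied
  by the drawn factor (age in [40, 50] vs [19, 40), BMI within its band,
  gestational age below/above 34 weeks, blood loss below/above 1000 mL),
  solely so that cutoff logic is exercised — within-band shapes are not
  identified by marginal prevalences and no realism is claimed. Band edges
  leave headroom so that rounding to one decimal cannot move a value across
  a scoring cutoff;
* the VTE outcome depends on the profile **only through the final-score
  stratum** (defaults 1/4064 below 2, 1/583 at 2, 3/156 at ≥ 3), times a
  relative-risk multiplier for pharmacologic-tier patients
  (`treatment_effect_rr`, default 1 = no effect);
* bleeding complications are drawn independently of the score (period
  presets 0.96%/0.76%); no causal LMWH–bleeding link is modelled;
* all randomness flows from one logged seed, with the global RNG stream
  left untouched.

Under the independence model the expected mean score with protocol-period
prevalences is about 0.62, close to the audited score distribution's mean,
which is why independence is adequate for testing the pipeline. What it
does **not** emulate: correlations between factors (obesity–pre-eclampsia,
urgency–hemorrhage), within-band covariate shapes, or secular trends. A
passing test suite therefore validates the *software* against its stated
model, not the protocol against real patients.

`exact_score_distribution()` complements the sampler with the exact pmf of
the score under the same model — a weighted Poisson-binomial (fourteen
weight-1 Bernoullis, one 0/1/2 BMI categorical, one weight-1 markup)
computed by sequential convolution, checked in the tests against exhaustive
enumeration on reduced rule sets and against Monte Carlo at n = 10⁶.
`expected_prophylaxis_rates()` derives the mechanical rate from the
pre-operative distribution (cuff attribution) and the pharmacologic rate
from the final distribution.

## Statistical choices

* **Clopper–Pearson** is the fixed default interval. It reproduces the
  conventional exact intervals reported for small screening numerators
  (e.g. 5/11 → 16.7%–76.6%), where Wilson does not; the bounds come from
  the beta-quantile closed form and the tests verify the defining tail
  equations to 1e-10.
* **Two-proportion comparison**: the continuity-corrected (Yates)
  chi-squared is the default for large 2×2 tables, with Fisher's exact
  test selected automatically when any expected cell is below 5. The
  two-sided Fisher p sums all tables with point probability at most the
  observed one (the common convention; doubling conventions exist and give
  different values). The method actually used is returned with the result.
* **Rounding**: printed percentages use round-half-up at the reported
  precision (45.45 → 45.5); machine output always carries unrounded
  values. Undefined ratios (zero denominators) are reported as `NA`,
  never as 0.
* **NNS/NNT**: `nns = 1/arr` and `nnt = nns × treated_fraction`; an
  absolute risk reduction ≤ 0 is an error (undefined), not a sentinel.

## Problem sizes used by the test suite

Distributional checks run at the sizes where their error bounds are sharp
but cheap: factor-prevalence recovery and stratum-risk recovery at
n = 10⁵–10⁶ with 3-standard-error bands; exhaustive enumeration oracles on
rule sets reduced to ≤ 12 factors and on 2×2 tables with N ≤ 30. The
null-uniformity check of the full pipeline (simulate → count → test) raises
the event risks to the 25–35% range on cohorts of 2000 so that the
two-proportion test leaves its discrete small-count regime; at the default
rare-event risks *every* 2×2 test is visibly conservative and no
implementation would show a uniform null, so that regime is exercised by
the recovery tests instead.

## Limitations

The comparator factor lists are approximations; exact reproduction of any
institution's recoded percentages requires that institution's lists and
patient-level data. The generator's independence assumption understates
tail clustering of risk factors, so simulated high-score fractions can
differ from audited ones even when every marginal matches. Event risks are
stratum-level; no patient-level heterogeneity within a stratum is
modelled. The package performs no time-to-event analysis, no covariate
adjustment, and no multiplicity correction — mirroring the single
pre-specified comparison design it implements.
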