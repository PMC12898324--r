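---
title: "Auditing SB-IPMN surveillance against a policy-driven rule engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing SB-IPMN surveillance against a policy-driven rule engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipmnaudit)
```

## The problem

Side-branch intraductal papillary mucinous neoplasms (SB-IPMN) are common,
mostly indolent pancreatic cysts with a small but real risk of progression
to pancreatic ductal adenocarcinoma (PDAC). Management is therefore
surveillance-based and guided by imaging and clinical risk features:
*high-risk stigmata* (HRS: main pancreatic duct ≥ 10 mm, obstructive
jaundice, enhancing mural nodule ≥ 5 mm) warrant referral for resection,
while *worrisome features* (WF: cyst ≥ 30 mm, small or non-enhancing mural
nodule, thickened wall, main duct 5–9 mm, abrupt duct-calibre change,
lymphadenopathy, elevated CA 19-9, growth > 5 mm per 2 years, and — in the
newer Kyoto framework — acute pancreatitis and new-onset diabetes) trigger
endoscopic-ultrasound-based evaluation, with the *cumulative count* of WFs
weighing on intensity. Everything below those tiers is scheduled by cyst
size.

In practice, adherence to this decision tree is variable. This package
implements the decision tree as a deterministic, policy-table-driven rule
engine, and then turns it around as an *audit instrument*: given what was
actually done for each patient, it classifies management as concordant,
over-surveillance, or under-surveillance, and quantifies the imaging
burden attributable to over-surveillance in scans per patient-year.

## The rule engine

`recommend()` applies the precedence **HRS > WF > size band** to the
feature state at an assessment date:

1. any HRS and a surgically fit patient without limited life expectancy →
   surgery referral; the same stigmata in an unfit patient → the policy's
   unfit rule (EUS-based surveillance);
2. otherwise, one or more WFs → the highest WF tier whose minimum count is
   met (the default policy has a single tier: EUS, 6 months);
3. otherwise the size band of the leading cyst.

All numeric content — thresholds, band edges, intervals — lives in a YAML
policy file (`inst/extdata/kyoto_policy.yaml`), not in code. The engine
records the policy version and file checksum in every recommendation's
rationale, so results are traceable to the exact policy that produced
them. The guideline text does not print a single canonical interval table;
the shipped default encodes the decision tree as: `<20 mm`: MRI/MRCP at
6 months, then every 18 months once stable; `20–29 mm`: 6 months, then
every 12; WF present: EUS every 6 months; HRS with unfit patient: EUS
every 6 months. Institutions that read the guideline differently can edit
the file without touching code.

Boundary conventions follow the printed feature definitions exactly:
`≥` for the size and duct cutoffs (a 10.0 mm duct *is* an HRS), a strict
`>` for growth (exactly 5 mm / 2 years is not a WF) and for CA 19-9
elevation above the configurable 37 U/mL cutoff. A mural nodule that does
not meet the enhancing-≥5 mm stigma definition (smaller, or not
enhancing) counts as the nodule WF, so the two nodule features are
mutually exclusive by construction. The two Kyoto-specific WFs (acute
pancreatitis, new-onset diabetes) are individually switchable in the
policy because guideline editions differ on their inclusion.

Two derived quantities need explicit conventions:

* **Growth** is first-vs-last cyst size within the trailing 24-month
  window ending at the latest scan, rescaled to mm per 24 months. This
  matches the "per 2 years" phrasing; a least-squares slope agrees with it
  on collinear series and is used as a cross-check in the tests. With
  fewer than two measurements in the window the rate is *undefined*
  (`NA`), never zero — an unknown rate must not silently clear the
  threshold. Dates are whole days, so the window edge admits half a day of
  rounding slack.
* **Stability.** A no-WF cyst uses its band's first interval until elapsed
  follow-up since the index scan reaches that interval, then the band's
  stable interval. The rationale: once the first-interval check has been
  passed without raising any WF, rapid growth would have been caught by
  the growth feature, so the lesion has demonstrated stability. This
  reproduces the canonical walk for a stable small cyst over 60 months:
  visits at months 6, 24, 42 and 60.

```{r}
p <- patient_record(
  "example", 71, "male",
  observations = rbind(
    cyst_observation("2016-03-10", 9, mpd_diameter = 2.4),
    cyst_observation("2016-09-12", 9.5, mpd_diameter = 2.5)
  ),
  radiological_followup_months = 48, clinical_followup_months = 60
)
recommend(p, at = "2016-09-12")
```

## The concordance audit

`audit_cohort()` compares, per patient, the first management decision
after the index MRI/MRCP with the recommendation computed at the index
scan. The intensity ordering is imaging < EUS < surgery. With recommended
interval $I$ and tolerance $\tau = \max(0.25\,I,\ 3\ \text{months})$:

* surveillance recommended — surgery instead is **over**; first imaging at
  $t < I - \tau$ is **over**; at $t > I + \tau$, stopping, or no imaging
  despite follow-up beyond $I + \tau$ is **under**; otherwise
  **concordant**;
* surgery recommended — surgery within a 6-month grace window is
  **concordant**; anything else (surveillance, stopping, delayed surgery)
  is **under**.

Patients with no post-index event and follow-up too short to judge are
*indeterminate*: excluded from the denominator but always counted and
reported. The tolerance is a knob, not a claim about any particular
institution's operational definition — the original operational definition
of "in accordance" is not published, so the auditor exposes
`audit_tolerance(pct, months, modality_strict, surgery_grace_months)` and
the tests verify that widening the tolerance can only move patients
*toward* concordance. By default MRI/MRCP and EUS at the recommended time
are treated as equivalent surveillance (`modality_strict = FALSE`),
because both are surveillance tools and the published analysis does not
state modality strictness.

The **imaging burden** uses the whole radiological follow-up window, not
just the first decision. A counterfactual scheduler
(`expected_imaging_count()`) walks the window: at each scheduled visit it
re-evaluates `recommend()` against the *observed* trajectory state at that
time, accrues one scan, and advances by the then-current interval. The
excess is pooled: total (observed − expected) MRI/MRCP scans divided by
total patient-years among classified patients. Counting MRI/MRCP only
matches the headline metric's definition; an all-modality variant is
available. A static alternative (schedule fixed at the index
recommendation) was rejected because a trajectory that develops a WF
mid-follow-up genuinely changes the guideline schedule; the re-evaluating
scheduler is this package's operational definition of "expected".

Incidence is reported in the conventional unit,
$100 \times \text{events} / \text{patient-years}$, rounded to two
decimals: one PDAC case over 1661 patient-years is 0.06% per patient-year.

## Cohort statistics

`describe_cohort()` reports continuous variables as median (IQR) — the
underlying clinical variables are skewed — and categorical ones as n (%).
`univariable_screen()` relates covariates to concordance class: chi-square
without continuity correction for categorical variables, switching to
Fisher's exact test whenever any expected cell count falls below 5 (the
published analysis lists both tests without stating its switching rule;
the expected-count rule is the standard one); Mann–Whitney for two-group
continuous comparisons (exact when combined n ≤ 20 and tie-free, normal
approximation with tie correction otherwise), Kruskal–Wallis beyond two
groups. `select_and_fit()` implements the stated selection rule: age and
sex are forced into the multivariable logistic model together with every
candidate whose univariable p is below 0.2; odds ratios are reported with
Wald 95% intervals (profile likelihood would also be defensible; Wald
matches the OR-with-CI reporting convention). The continuous cyst size
enters only through its >20 mm dichotomy, matching the multivariable
design. Complete separation aborts with an error naming the separating
variable rather than reporting a meaningless Wald interval. The
conservative-vs-liberal model runs within the non-concordant subgroup,
with age either continuous or dichotomized at 50 (both parameterizations
are exposed because the published subgroup model's choice is not stated).
No multiplicity correction is applied, as none is part of the analysis
battery being reproduced.

## The synthetic cohort generator

No patient-level data are deposited, so `generate_cohort()` creates
cohorts with the study's marginal structure; the generator's defaults
*are* the study conditions:

| quantity | target | family |
|---|---|---|
| n | 368 | — |
| age | median 69.5, IQR 63.2–75.2, ≥ 18 | normal matched to quartiles, truncated; 19/368 point mass under 50 |
| male fraction | 0.69 | Bernoulli |
| leading cyst size | median 10 mm, IQR 6–14 | log-normal matched to quartiles |
| multiple cysts | 0.105 | Bernoulli |
| radiological follow-up | median 48.5 mo, IQR 28–75 | log-normal |
| clinical follow-up | median 64 mo, IQR 46–88 | log-normal, ≥ radiological |
| comorbidities | per-condition prevalence | pooled from the published per-group percentages |
| PDAC hazard | 0.0006 / patient-year | exponential |

Log-normal parameters come from quantile matching: meanlog = log(median),
sdlog = (log q3 − log q1) / (2 Φ⁻¹(0.75)). Baseline WF/HRS prevalences are
not published; the defaults keep them low (0.5% per boolean finding, 2%
mural nodules, hazards of 0.005 and 0.001 per patient-year for new WFs
and HRS) so the simulated cohort is, like the real one, dominated by
stable low-risk cysts. That is calibration, not ground truth.

The **behavior model** draws a latent management class per patient
(defaults 0.158 / 0.603 / 0.239 for concordant / over / under, the
published partition), shifted on the log-odds scale by two covariate
modifiers taken from the published subgroup odds ratios: age < 50 toward
over (log 1.61) and cyst > 20 mm toward concordant (log 2.1). The realized
schedule multiplies each recommended interval by a class-specific factor —
0.95–1.05 for concordant (inside the audit tolerance), 0.25–0.45 for over
(below it even for the shortest 6-month interval), 1.6–2.6 for under, with
a 15% chance that an under-surveilled patient has no follow-up imaging at
all. Because the class manifests in the first post-index interval, the
latent class is recoverable by the auditor, which is exactly what the
end-to-end recovery tests score (`generate_cohort_with_truth()`).

Randomness uses one substream per patient keyed by (seed, patient index),
so cohorts are bitwise-reproducible and enlarging a cohort never perturbs
the patients already generated.

What the generator does *not* emulate: real lesion morphology dynamics
(growth is linear drift plus measurement noise), informative loss to
follow-up, inter-radiologist measurement variability, histology, cyst
fluid analysis, and any dependence of PDAC risk on features (the hazard is
constant). Passing tests therefore demonstrate the *internal* consistency
of engine, auditor and statistics under known truth — not that the
behavior model is a faithful portrait of any institution's practice.

## Numerical choices and problem sizes

* Intervals are months throughout; calendar arithmetic uses the mean
  Gregorian month (30.4375 days), making `months_between()` and
  `add_months()` mutually inverse to within rounding to whole days.
* Percentages are reported to one decimal, incidence to two — the
  reporting conventions of the audited quantities.
* The engine–oracle equivalence test sweeps a discretized feature grid of
  ~7700 states against an independently coded straight-line decision tree;
  the Fisher oracle sweep covers every 2×2 table with total n ≤ 40 (about
  17,000 after symmetry reduction); auditor recovery runs at n = 5000
  patients; distribution calibration at n = 10,000. These sizes give
  comfortable statistical resolution (multinomial standard errors well
  under the ±2-point recovery tolerance) while keeping the default suite
  quick to run.
* Ties in the classification windows resolve toward concordance: an event
  exactly at $I \pm \tau$ is on time.

## Known limitations

* The audit classifies on the first post-index decision only; a patient
  who starts on schedule and drifts later is still "concordant" (the
  burden metric, which integrates the whole window, is the complementary
  view).
* The engine models life expectancy and performance status as two
  booleans (`surgically_fit`, `limited_life_expectancy`); the original
  inputs are richer.
* The WF-count tiers support per-count escalation, but the shipped
  default maps every count ≥ 1 to one EUS rule because no printed
  per-count schedule exists to encode.
* Missing optional measurements (MPD, CA 19-9) are treated as "feature
  not demonstrated" with a note in the assessment — a pragmatic rule for
  retrospective charts, not a claim about how missingness was handled at
  data entry.
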