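---
title: "Measuring guideline-adherent breast cancer survivorship care from claims"
author: "survcare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring guideline-adherent breast cancer survivorship care from claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survcare)
```

## The measurement problem

After primary treatment for early-stage invasive breast cancer, guidelines
recommend a specific cadence of follow-up: regular physician visits, one
surveillance mammogram per year, *no* routine imaging for metastatic
disease in asymptomatic women, continued management of comorbid chronic
illness, and age-appropriate preventive screening. Whether survivors
actually receive this care can be measured at population scale from
linked administrative data — a cancer registry for diagnoses, staging,
treatment and vital status; fee-for-service billing claims for physician
encounters; and imaging/screening event records.

`survcare` implements that measurement as a pipeline:

1. **cohort** — eligibility screening, censoring, and anniversary-anchored
   follow-up windows;
2. **continuity** — the Usual Provider of Care (UPC) index;
3. **adherence** — per-patient-year classification against each indicator;
4. **report** — descriptive tabulation with disciplined denominators;
5. **synthetic data** — a claims generator with a truth table, standing in
   for the confidential provincial databases such studies run on.

## Cohort construction and censoring

The survivorship phase starts at **1 year post-diagnosis** (treatment-phase
utilization in Year 1 is never assessed) and is observed until the
earliest of:

* the administrative end of follow-up (`study_end`),
* **6 calendar months before death** — so end-of-life care is not misread
  as survivorship care,
* **90 days before a recurrence or new primary** — likewise for
  progression workup.

Patients are excluded when any of the following fail, evaluated in a fixed
order with *all* triggered reasons reported: alive at 30 months
post-diagnosis; curative surgery; no recurrence/new primary within 27
months; no metastasis within 1 year; unbroken health-insurance coverage
from diagnosis to the censored end date; at least one full year of
survivorship; no prior in situ breast or non-melanoma cancer; solid-tumour
histology.

Numerical choices, stated once and applied everywhere:

* "months" and "years" are **calendar arithmetic** (same day-of-month,
  clamped at month-end), not 182/365-day counts; anniversary years are then
  exact by construction. The 90-day recurrence offset is literal days.
* Year *k* (k = 2..5) is the **half-open window**
  `[diagnosis + (k-1) years, diagnosis + k years)`: an event on an
  anniversary belongs to the later year.
* A patient contributes to Year *k* only with **full follow-up** in that
  year (`end_date >=` window end); partial years are dropped, not
  prorated.
* Censoring ties break in the order `study_end` < death < recurrence.
* Coverage: any gap between diagnosis and the end date excludes; whether
  real linkage tolerated short administrative gaps is unknowable from
  published methods, so the strict reading is used (adjacent intervals,
  touching day-to-day, are merged first).

## The UPC index

For a window and specialty set, UPC is the largest single provider's share
of the patient's distinct **visit-days**. Same-day duplicate claims to one
provider collapse to one visit-day (fee-for-service data commonly
multi-bill one encounter); same-day claims to *different* providers count
separately. Three windows are assessed: baseline PCP care in
`[diagnosis - 30 months, diagnosis - 6 months)`, and survivorship PCP and
medical-oncology care from 1 year post-diagnosis to the censored end date.
The survivorship window ends at censoring rather than at a fixed Year-5
anniversary: continuity should be measured over time actually observed.

The four-level categorization is forced by its reporting shape — the
mutually exclusive rows `0 visit / 1-2 visits / Low / High` require the
index to be computed only at 3+ visits, with Low meaning UPC ≤ 0.75 and
High UPC > 0.75.

```{r upc}
v <- tibble::tibble(provider_id = c("A", "A", "A", "B"),
                    date = as.Date("2010-01-01") + c(0, 30, 60, 90))
compute_upc(v)   # 3/4 to the usual provider: exactly on the Low cutpoint
```

## Adherence indicators

**Physician visits**, three ways per follow-up year — any oncologist or
PCP; oncologist only; breast cancer-related (reason-coded) visits.
"Oncologist" means medical, radiation or surgical oncologists *plus any
surgeon with a breast-surgery claim during the follow-up period*; the
promotion is period-wide, so such a surgeon's earlier visits also count.
The adherent band is 3-4 visits in each of Years 2-3 and 2 visits in each
of Years 4-5. The Year 4-5 band is read as *exactly two* (under < 2,
over > 2): three-category reporting requires a bounded band, though "at
least 2" is an admissible alternative reading.

**Surveillance breast imaging** — mammogram, breast ultrasound or breast
MRI, one per follow-up year. In claims-only provinces a test counts as
surveillance iff it is **more than 330 days** after the previous
breast-imaging test *of any of the three modalities* (the gap is measured
against the test group as a whole, because the rule exists to exclude
symptom-triggered workup cascading from a recent test); a first-ever test
is surveillance, and pre-diagnosis tests count as history. Where a
provincial screening program flags its own tests, `program_flag` mode uses
those flags instead. Women with bilateral mastectomy are ineligible for
the whole indicator — with both breasts removed there is no surveillance
target; the published rule mentions mammograms only, so this wider reading
is a documented choice.

**Imaging for metastatic disease** — bone scans, chest X-ray/CT,
abdominal/pelvic ultrasound/CT, non-breast MRI. None is recommended for
asymptomatic survivors, so *any* such event in a year makes the year
non-adherent. Indications are not observable in claims, so symptomatic
imaging cannot be rescued; measured "overuse" is therefore an upper bound.

**Chronic-disease visits** — a patient has a condition (stable angina,
heart failure, COPD, TIA, diabetes) if its onset is on/before survivorship
start. Follow-up is partitioned into consecutive 6-calendar-month blocks
(12 months for TIA) anchored at survivorship start, discarding a trailing
partial block; adherent iff every block contains a visit reason-coded to
the condition. Anchoring at survivorship start (not calendar half-years)
matches "one visit every 6 months" without being stricter than stated — a
rolling no-183-day-gap rule was rejected as stricter. Reason-code matching
undercounts where comorbidity care is recorded under other reasons; that
is a data property, not a correctable artifact.

**Preventive care** — at least one cervical screen (age 20-69, no
hysterectomy or gynaecologic-cancer history), bone densitometry (65+),
colorectal screen (50-64) during the whole follow-up. Age eligibility is
evaluated once, at survivorship start; patients aging across a band
boundary mid-follow-up are not re-evaluated (one rule, stated once).
Chronic and preventive indicators are whole-follow-up binaries; visit and
imaging indicators are per-year three-category outcomes.

## The synthetic world

The generator emulates a large single-payer province with complete data
capture: diagnosis years 2007-2012, follow-up to end-2013, age about
median 60 (IQR-like spread 19 years), stage mix
(I/II/III/IV/Unknown = .423/.363/.112/.004/.098), lumpectomy .729,
mastectomy .350 (10% of mastectomies bilateral), chemotherapy .459,
radiotherapy .646, chronic prevalences (CSA .026, CHF .011, COPD .020,
TIA .006, DM .098) and preventive uptakes (cervical .670, bone
densitometry .387, colorectal .459) as tabulated for such cohorts.
Behavioural parameters are free: adherence mixes, oncologist visit
propensity, provider loyalty, metastatic-imaging rate.

Deliberate simplifications — and what a green test therefore does *not*
establish:

* Death and recurrence are independent geometric per-year hazards (2% and
  1.5%) with the event date uniform in its year; only the censoring logic
  consumes these dates, so no survival-curve realism is attempted (and
  none is tested).
* Provider choice: a visit goes to the patient's usual provider with
  probability `loyalty/(1+loyalty)`, else uniformly over a small pool.
  This spans the UPC category space and is monotone in `loyalty`, but is
  not a model of real referral networks.
* Each patient draws *one* visit-adherence category and realizes a count
  in that category's band in every full year — so classifier recovery of
  the mix is exact by construction, a test of the classifier, not a claim
  about real year-to-year stability.
* Utilization distributions for non-adherent categories are not published;
  the generator draws counts uniformly within bands (over = band maximum
  + 1..3) and exposes the mixes as configuration.
* Chronic-condition visits are emitted with specialty `other_specialist`
  (clinically plausible: internists and cardiologists manage these
  conditions) so they cannot perturb the PCP/oncologist visit counts that
  carry the visit truth labels.
* Fee codes, billing dialects and stage-specific survival are out of
  scope.

One structural fact is worth stating precisely: under the 330-day rule,
**two surveillance tests per year cannot be sustained** — three
consecutive gaps of 331+ days span more than two years. The generator
therefore guarantees the `over` surveillance label in Year 2 only (the
first assessed year, where recovery tests measure it), with roughly one
test per 331 days thereafter; `under` and `adherent` are realized in every
full year. Measured overuse being structurally rare under the interval
rule mirrors what the rule does to real claims data, and is one reason a
program-flag dialect reports more overuse than an interval dialect on the
same behaviour.

```{r recovery}
cfg <- sim_config(n_patients = 300, seed = 1,
                  visit_adherence_mix = c(under = .2, adherent = .5,
                                          over = .3))
tabs <- generate_dataset(cfg)
cohort <- build_cohort(tabs$registry, cfg$study_end)
ad <- assess_adherence(cohort, tabs$registry, tabs$visits, tabs$imaging,
                       tabs$screening)
y2 <- ad[ad$indicator == "visits_onc_or_pcp" & ad$year == "2" &
           ad$eligible, ]
round(prop.table(table(y2$category)), 3)
```

## Reporting

`summarize_results()` emits descriptive counts and proportions only — no
tests, no intervals: the intended inputs are a census of a jurisdiction,
not a sample. Denominators are strictly the eligible sets (full
follow-up, non-bilateral for breast surveillance, condition-prevalent for
chronic indicators, age/history-eligible for preventive ones), and within
each (indicator, year) the category proportions sum to 1. Rendered output
rounds to one decimal; CSVs keep full precision.

## Known limitations

* Exactly-two reading of the Year 4-5 visit band, group-wide 330-day gap,
  and indicator-wide bilateral-mastectomy exclusion are documented
  interpretations of under-specified rules; all are localized in
  `recommended_visit_schedule()`, `flag_surveillance()` and
  `classify_surveillance_adherence()` if a user needs the alternatives.
* Reason-coded chronic and breast-cancer-related visit measures inherit
  the coding completeness of the source claims.
* The generator's truth guarantees hold for the quantities the tests
  recover (Year-2 mixes, marginal frequencies, per-year visit counts);
  it makes no claim of joint realism across indicators.
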