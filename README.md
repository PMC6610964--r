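# survcare

Guideline-adherence quality indicators for breast cancer survivorship
care, computed from linked registry and health-claims event tables.

After curative treatment for invasive breast cancer, follow-up guidelines
specify a cadence of care: 3–4 physician visits per year in Years 2–3 and
2 per year in Years 4–5 post-diagnosis; one surveillance breast-imaging
test (mammogram, ultrasound or MRI) per year; *no* routine imaging for
metastatic disease in asymptomatic women; one condition-coded visit every
6 months for stable angina, heart failure, COPD and diabetes (yearly for
TIA); and age-appropriate cervical, colorectal and bone-density
screening. `survcare` measures population-level adherence to these
recommendations from administrative data, the way health-system
quality-of-care studies do — and ships a fully parameterized synthetic
claims generator (with a truth table) so every stage is testable without
access to confidential provincial databases.

The pipeline:

* **Cohort**: applies eligibility rules (alive at 30 months, curative
  surgery, no early recurrence/metastasis, unbroken insurance coverage,
  ≥1 survivorship year, no prior cancer history, solid histology) and
  censors follow-up at the earliest of study end, 6 months before death,
  or 90 days before recurrence. Adherence is assessed in
  anniversary-anchored half-open Years 2–5, each only under full
  follow-up.
* **Continuity**: the Usual Provider of Care index
  `UPC = max_provider(visit-days to that provider) / (total visit-days)`,
  categorized as `0 visits / 1–2 visits / Low (≤ 0.75) / High (> 0.75)`,
  over a pre-diagnosis baseline window and the survivorship period (PCP
  and medical oncology separately).
* **Adherence**: per patient-year classification (under / adherent /
  over, or adherent / not adherent) for visit frequency measured three
  ways, surveillance breast imaging (330-day interval rule or
  screening-program flags), metastatic-disease imaging, chronic-disease
  visits, and preventive care.
* **Report**: descriptive counts and proportions with strictly eligible
  denominators — no inferential statistics, by design.

## Worked example

```r
library(survcare)

cfg <- sim_config(n_patients = 500, seed = 2024)
res <- run_pipeline(config = cfg, out_dir = "out")

sum(res$cohort$included)
#> [1] 321
```

321 of 500 simulated women enter the survivorship cohort (the rest trip
an exclusion rule — mostly no curative surgery, or diagnosis too close to
the study end for a full survivorship year). Retention then decays with
censoring:

```r
dplyr::filter(res$summary$characteristics, variable == "full_followup")
#>   variable      level      n proportion
#> 1 full_followup year_2   321      1
#> 2 full_followup year_3   256      0.798
#> 3 full_followup year_4   175      0.545
#> 4 full_followup year_5   111      0.346
```

Visit adherence (any oncologist or PCP), per year — with the default
behavioural mix, most survivors see physicians *more* often than
recommended, the pattern such studies report:

```r
dplyr::filter(res$summary$per_year, indicator == "visits_onc_or_pcp")
#>   indicator         year category     n denominator proportion
#> 1 visits_onc_or_pcp 2    adherent   106         321      0.330
#> 2 visits_onc_or_pcp 2    over       176         321      0.548
#> 3 visits_onc_or_pcp 2    under       39         321      0.121
#> 4 visits_onc_or_pcp 3    adherent    81         256      0.316
#> ...
```

Each row's `n` counts eligible patient-years in that category;
`proportion` divides by the eligible denominator for that indicator-year
(ineligible or partially followed patient-years never enter it), so
proportions sum to 1 within each indicator-year.

The UPC index on four visit-days split 3:1 between two providers sits
exactly on the Low/High cutpoint:

```r
u <- compute_upc(tibble::tibble(
  provider_id = c("A", "A", "A", "B"),
  date = as.Date("2010-01-01") + c(0, 30, 60, 90)))
u$upc_value
#> [1] 0.75
upc_category(u$n_visits, u$upc_value)
#> [1] "low"
```

`run_pipeline()` writes every stage as CSV (`registry.csv` …
`adherence.csv`, `summary_*.csv`) plus a deterministic run log; re-running
with the same config reproduces the outputs byte for byte. A thin CLI
wrapper lives at `inst/cli/survcare.R`
(`survcare.R simulate|run --config cfg.txt --out dir --seed 1`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

simulates a cohort with the default configuration at the given seed, runs
the full pipeline (cohort screening, continuity, all adherence
indicators, summary tables), verifies the structural invariants of the
output, and writes the JSON report to `--out`.

## Vignette

`vignettes/survivorship-quality.Rmd` documents the measurement model:
censoring and window arithmetic, the reading of each guideline rule and
the choices made where published rules are under-specified, what the
synthetic generator does and does not emulate, and what a green test
establishes.
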