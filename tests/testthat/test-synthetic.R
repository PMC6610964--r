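test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_patients = 10), "'seed'")
  expect_error(sim_config(seed = 1, stage_probabilities =
                            c(I = .5, II = .5, III = .2, IV = 0,
                              Unknown = -.2)),
               "stage_probabilities")
  expect_error(sim_config(seed = 1, visit_adherence_mix =
                            c(under = .3, adherent = .3, over = .3)),
               "visit_adherence_mix")
  expect_error(sim_config(seed = 1, oncologist_visit_propensity = 1.4),
               "oncologist_visit_propensity")
  expect_error(sim_config(seed = 1, diagnosis_end = as.Date("2020-01-01")),
               "study_end")
  expect_error(sim_config(seed = 1, chronic_prevalence =
                            c(CSA = .1, CHF = .1, COPD = .1, TIA = .1)),
               "chronic_prevalence")
  expect_silent(validate_config(sim_config(seed = 1)))
})

test_that("n_patients = 0 yields the five empty tables with headers only", {
  tabs <- generate_dataset(sim_config(n_patients = 0, seed = 1))
  expect_named(tabs, c("registry", "visits", "imaging", "screening", "truth"))
  for (t in tabs) expect_equal(nrow(t), 0L)
  expect_true(all(c("patient_id", "diagnosis_date", "coverage_intervals")
                  %in% names(tabs$registry)))
})

test_that("identical config reproduces identical tables, on disk too", {
  cfg <- sim_config(n_patients = 40, seed = 99)
  t1 <- generate_dataset(cfg)
  t2 <- generate_dataset(cfg)
  expect_identical(t1, t2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_tables(t1, d1); write_tables(t2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("tables are mutually consistent and events stay in bounds", {
  cfg <- sim_config(n_patients = 150, seed = 3)
  tabs <- generate_dataset(cfg)
  reg <- tabs$registry
  expect_true(all(reg$birth_date < reg$diagnosis_date))
  expect_true(all(is.na(reg$death_date) |
                    reg$death_date >= reg$diagnosis_date))
  expect_true(all(!reg$bilateral_mastectomy | reg$mastectomy))
  for (tab in tabs[c("visits", "imaging", "screening")]) {
    expect_true(all(tab$patient_id %in% reg$patient_id))
    dx <- reg$diagnosis_date[match(tab$patient_id, reg$patient_id)]
    death <- reg$death_date[match(tab$patient_id, reg$patient_id)]
    expect_true(all(tab$date >= add_months(dx, -30)))
    expect_true(all(tab$date <= cfg$study_end))
    expect_true(all(is.na(death) | tab$date <= death))
  }
  # visits fall within coverage
  for (i in seq_len(nrow(reg))) {
    v <- tabs$visits[tabs$visits$patient_id == reg$patient_id[i], ]
    if (nrow(v) == 0) next
    cov <- survcare:::parse_coverage(reg$coverage_intervals[i])
    ok <- vapply(v$date, function(d)
      any(d >= cov$start & d <= cov$end), TRUE)
    expect_true(all(ok))
  }
})

test_that("re-deriving per-year visit counts from the tables reproduces the truth labels", {
  cfg <- sim_config(n_patients = 150, seed = 8)
  tabs <- generate_dataset(cfg)
  cohort <- build_cohort(tabs$registry, cfg$study_end)
  sch <- recommended_visit_schedule()
  inc <- cohort[cohort$included, ]
  for (i in seq_len(nrow(inc))) {
    pt <- inc[i, ]
    truth <- tabs$truth$visit_category[tabs$truth$patient_id ==
                                         pt$patient_id]
    pv <- tabs$visits[tabs$visits$patient_id == pt$patient_id, ]
    for (k in 2:5) {
      if (!pt[[paste0("full_y", k)]]) next
      cnt <- count_visits(pv, add_years(pt$diagnosis_date, k - 1),
                          add_years(pt$diagnosis_date, k), "onc_or_pcp")
      expect_equal(classify_visit_adherence(cnt, k, sch), truth)
    }
  }
})

test_that("a degenerate adherent-only mix forces every patient-year in band", {
  cfg <- sim_config(n_patients = 60, seed = 12,
                    visit_adherence_mix = c(under = 0, adherent = 1,
                                            over = 0))
  tabs <- generate_dataset(cfg)
  cohort <- build_cohort(tabs$registry, cfg$study_end)
  ad <- assess_adherence(cohort, tabs$registry, tabs$visits, tabs$imaging,
                         tabs$screening)
  v <- ad[ad$indicator == "visits_onc_or_pcp" & ad$eligible, ]
  expect_gt(nrow(v), 0)
  expect_true(all(v$category == "adherent"))
})

test_that("simulated marginals converge to configured probabilities (3 SE at n = 5000)", {
  cfg <- sim_config(n_patients = 5000, seed = 31)
  reg <- generate_dataset(cfg)$registry
  n <- nrow(reg)
  within3se <- function(obs_p, p) abs(obs_p - p) <= 3 * sqrt(p * (1 - p) / n)
  for (s in names(cfg$stage_probabilities))
    expect_true(within3se(mean(reg$stage == s),
                          cfg$stage_probabilities[[s]]))
  expect_true(within3se(mean(reg$lumpectomy), cfg$p_lumpectomy))
  expect_true(within3se(mean(reg$mastectomy), cfg$p_mastectomy))
  expect_true(within3se(mean(reg$radiotherapy), cfg$p_radio))
  expect_true(within3se(mean(reg$chemotherapy == "yes"), cfg$p_chemo))
  for (cond in c("CSA", "CHF", "COPD", "TIA", "DM"))
    expect_true(within3se(
      mean(!is.na(reg[[paste0("chronic_onset_", cond)]])),
      cfg$chronic_prevalence[[cond]]))
})

test_that("flat key-value config files round-trip", {
  path <- withr::local_tempfile(lines = c(
    "# demo configuration",
    "n_patients = 25",
    "seed = 7",
    "diagnosis_start = 2007-01-01",
    "diagnosis_end = 2010-12-31",
    "study_end = 2013-12-31",
    "visit_adherence_mix = under:0.2, adherent:0.5, over:0.3",
    "provider_loyalty = 4"))
  cfg <- read_config(path)
  expect_equal(cfg$n_patients, 25)
  expect_equal(cfg$seed, 7)
  expect_equal(unname(cfg$visit_adherence_mix), c(0.2, 0.5, 0.3))
  expect_equal(cfg$provider_loyalty, 4)
  expect_error(read_config(withr::local_tempfile(lines = "bogus_key = 3")),
               "unknown config key")
})
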