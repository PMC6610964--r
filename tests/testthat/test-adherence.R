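test_that("visit counts classify against the recommended schedule", {
  sch <- recommended_visit_schedule()
  # exhaustive check of counts 0..6 against each year's band
  for (k in 2:5) {
    lo <- sch$min_adherent[sch$year == k]
    hi <- sch$max_adherent[sch$year == k]
    for (cnt in 0:6) {
      want <- if (cnt < lo) "under" else if (cnt <= hi) "adherent" else "over"
      expect_equal(classify_visit_adherence(cnt, k), want)
    }
  }
  expect_equal(classify_visit_adherence(3, 2), "adherent")
  expect_equal(classify_visit_adherence(0, 4), "under")
  expect_equal(classify_visit_adherence(3, 5), "over")
  expect_error(classify_visit_adherence(-1, 2), "non-negative")
  expect_error(classify_visit_adherence(2, 6), "not in schedule")
})

test_that("count_visits filters by mode and promotes breast surgeons period-wide", {
  w0 <- as.Date("2009-06-15"); w1 <- as.Date("2010-06-15")
  v <- dplyr::bind_rows(
    visit_row("P", "2009-07-01", "A1", "PCP"),
    visit_row("P", "2009-08-01", "O1", "medical_oncologist"))
  expect_equal(count_visits(v, w0, w1, "onc_or_pcp"), 2L)
  expect_equal(count_visits(v, w0, w1, "onc_only"), 1L)
  expect_equal(count_visits(v, w0, w1, "breast_reason"), 0L)

  # surgeon with a breast-surgery claim in Year 3: Year 2 visits count
  v2 <- dplyr::bind_rows(
    visit_row("P", "2009-07-01", "S1", "surgeon"),
    visit_row("P", "2010-08-01", "S1", "surgeon", "breast_cancer"))
  ids <- breast_surgeons(v2, w0, as.Date("2013-06-15"))
  expect_equal(ids, "S1")
  expect_equal(count_visits(v2, w0, w1, "onc_only", oncologist_ids = ids), 1L)
  expect_equal(count_visits(v2, w0, w1, "onc_only"), 0L)

  # same-day duplicate claims collapse to one visit-day
  v3 <- dplyr::bind_rows(visit_row("P", "2009-07-01", "A1"),
                         visit_row("P", "2009-07-01", "A1"))
  expect_equal(count_visits(v3, w0, w1, "onc_or_pcp"), 1L)

  # other specialists never count
  v4 <- visit_row("P", "2009-07-01", "X1", "other_specialist", "DM")
  expect_equal(count_visits(v4, w0, w1, "onc_or_pcp"), 0L)
})

test_that("the 330-day interval rule separates surveillance from workup", {
  im <- function(dates, modality = "mammogram")
    tibble::tibble(patient_id = "P", date = as.Date(dates),
                   modality = modality, program_surveillance = NA)
  # 400 days apart: both surveillance
  expect_equal(flag_surveillance(im(c("2009-01-01", "2010-02-05"))),
               c(TRUE, TRUE))
  # ultrasound 60 days after a mammogram: diagnostic workup
  x <- dplyr::bind_rows(im("2009-01-01"),
                        im("2009-03-02", "breast_ultrasound"))
  expect_equal(flag_surveillance(x), c(TRUE, FALSE))
  # a single first-ever test is surveillance
  expect_equal(flag_surveillance(im("2009-01-01")), TRUE)
  # 330 is not "more than 330"; 331 is
  expect_equal(flag_surveillance(im(as.Date("2009-01-01") + c(0, 330))),
               c(TRUE, FALSE))
  expect_equal(flag_surveillance(im(as.Date("2009-01-01") + c(0, 331))),
               c(TRUE, TRUE))
  # unsorted input is rejected; non-breast modalities are rejected
  expect_error(flag_surveillance(im(c("2010-01-01", "2009-01-01"))),
               "sorted")
  expect_error(flag_surveillance(im("2009-01-01", "bone_scan")),
               "breast modalities")
  # program-flag mode reads the screening-program flag
  y <- im(c("2009-01-01", "2009-06-01"))
  y$program_surveillance <- c(FALSE, TRUE)
  expect_equal(flag_surveillance(y, "program_flag"), c(FALSE, TRUE))
})

test_that("surveillance and metastatic indicators classify per the guideline", {
  expect_equal(classify_surveillance_adherence(1, FALSE), "adherent")
  expect_equal(classify_surveillance_adherence(0, FALSE), "under")
  expect_equal(classify_surveillance_adherence(2, FALSE), "over")
  expect_equal(classify_surveillance_adherence(5, TRUE), "ineligible")

  w0 <- as.Date("2010-06-15"); w1 <- as.Date("2011-06-15")
  none <- tibble::tibble(patient_id = character(),
                         date = as.Date(character()),
                         modality = character(),
                         program_surveillance = logical())
  expect_equal(classify_metastatic_imaging(none, w0, w1), "adherent")
  bone <- imaging_row("P", "2011-01-10", "bone_scan")
  expect_equal(classify_metastatic_imaging(bone, w0, w1), "not_adherent")
  # outside the window it does not count
  expect_equal(classify_metastatic_imaging(bone, as.Date("2009-06-15"), w0),
               "adherent")
  # breast MRI is not a metastatic-disease investigation
  mri <- imaging_row("P", "2011-01-10", "breast_mri")
  expect_equal(classify_metastatic_imaging(mri, w0, w1), "adherent")
})

test_that("chronic-disease visit indicators scan 6-month (TIA: 12-month) blocks", {
  plan <- list(survivorship_start = as.Date("2009-06-15"),
               end_date = as.Date("2013-06-15"))
  # DM visits every 5 months cover every 6-month block
  dm_dates <- seq(as.Date("2009-07-01"), as.Date("2013-05-01"),
                  by = "5 months")
  dm <- dplyr::bind_rows(lapply(dm_dates, function(d)
    visit_row("P", d, "S", "other_specialist", "DM")))
  expect_equal(classify_chronic("DM", dm, plan, as.Date("2005-01-01")),
               "adherent")
  # one TIA visit per year suffices
  tia <- dplyr::bind_rows(lapply(seq(as.Date("2009-08-01"), by = "year",
                                     length.out = 4), function(d)
    visit_row("P", d, "S", "other_specialist", "TIA")))
  expect_equal(classify_chronic("TIA", tia, plan, as.Date("2005-01-01")),
               "adherent")
  # a missing block fails; reason codes for other conditions don't rescue it
  expect_equal(classify_chronic("CHF", dm, plan, as.Date("2005-01-01")),
               "not_adherent")
  # no condition, or onset after survivorship start -> ineligible
  expect_equal(classify_chronic("DM", dm, plan, as.Date(NA)), "ineligible")
  expect_equal(classify_chronic("DM", dm, plan, as.Date("2009-07-01")),
               "ineligible")
  # zero complete blocks -> ineligible
  short <- list(survivorship_start = as.Date("2009-06-15"),
                end_date = as.Date("2009-10-15"))
  expect_equal(classify_chronic("DM", dm, short, as.Date("2005-01-01")),
               "ineligible")
  expect_error(classify_chronic("GOUT", dm, plan, as.Date("2005-01-01")),
               "unknown chronic condition")
})

test_that("preventive eligibility follows age bands and history at survivorship start", {
  plan <- list(survivorship_start = as.Date("2009-06-15"),
               end_date = as.Date("2013-06-15"))
  scr <- screening_row("P", "2011-04-01", "colorectal_screen")
  p55 <- make_patient("P", birth_date = as.Date("1954-01-01"))
  res <- classify_preventive(p55, scr, plan)
  expect_equal(res[["colorectal"]], "adherent")
  expect_equal(res[["cervical"]], "not_adherent")
  expect_equal(res[["bone_density"]], "ineligible")

  p40 <- make_patient("P", birth_date = as.Date("1969-01-01"))
  expect_equal(classify_preventive(p40, scr, plan)[["bone_density"]],
               "ineligible")

  # hysterectomy history excludes from cervical screening despite screens
  p60 <- make_patient("P", birth_date = as.Date("1949-01-01"),
                      hysterectomy_or_gyn_cancer_history = TRUE)
  two <- dplyr::bind_rows(screening_row("P", "2010-01-01", "cervical_screen"),
                          screening_row("P", "2011-01-01", "cervical_screen"))
  expect_equal(classify_preventive(p60, two, plan)[["cervical"]],
               "ineligible")

  # age boundaries are evaluated at survivorship start
  p65 <- make_patient("P", birth_date = as.Date("1944-06-15"))
  expect_equal(classify_preventive(p65, scr, plan)[["bone_density"]],
               "not_adherent")
  p64 <- make_patient("P", birth_date = as.Date("1944-06-16"))
  expect_equal(classify_preventive(p64, scr, plan)[["bone_density"]],
               "ineligible")
})

test_that("every eligible patient-year gets exactly one category per indicator", {
  cfg <- sim_config(n_patients = 120, seed = 5)
  tabs <- generate_dataset(cfg)
  cohort <- build_cohort(tabs$registry, cfg$study_end)
  ad <- assess_adherence(cohort, tabs$registry, tabs$visits, tabs$imaging,
                         tabs$screening)
  expect_true(all(!is.na(ad$category[ad$eligible])))
  expect_true(all(is.na(ad$category[!ad$eligible])))
  expect_false(any(duplicated(ad[c("patient_id", "indicator", "year")])))
  three <- ad$indicator %in% c("visits_onc_or_pcp", "visits_onc_only",
                               "visits_breast_reason",
                               "surveillance_breast_imaging")
  expect_true(all(ad$category[ad$eligible & three] %in%
                    c("under", "adherent", "over")))
  expect_true(all(ad$category[ad$eligible & !three] %in%
                    c("adherent", "not_adherent")))
})
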