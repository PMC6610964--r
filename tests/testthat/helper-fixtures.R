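# Hand-built patient fixtures used across the suite.

GOLDEN_STUDY_END <- as.Date("2013-12-31")

# day-by-day membership oracle: a day is observed iff it precedes every
# censoring bound; used to cross-check the calendar-arithmetic plans
observed_day <- function(d, record, study_end) {
  d <= study_end &&
    (is.na(record$death_date) || d <= add_months(record$death_date, -6)) &&
    (is.na(record$recurrence_date) || d <= record$recurrence_date - 90)
}

make_patient <- function(patient_id,
                         birth_date = as.Date("1950-01-01"),
                         diagnosis_date = as.Date("2008-06-15"),
                         stage = "I",
                         lumpectomy = TRUE, mastectomy = FALSE,
                         bilateral_mastectomy = FALSE,
                         chemotherapy = "no", radiotherapy = FALSE,
                         curative_surgery = lumpectomy || mastectomy,
                         death_date = as.Date(NA),
                         recurrence_date = as.Date(NA),
                         metastasis_within_1yr = FALSE,
                         prior_cancer_history = FALSE,
                         non_solid_histology = FALSE,
                         hysterectomy_or_gyn_cancer_history = FALSE,
                         coverage_intervals = NULL,
                         chronic_onset_CSA = as.Date(NA),
                         chronic_onset_CHF = as.Date(NA),
                         chronic_onset_COPD = as.Date(NA),
                         chronic_onset_TIA = as.Date(NA),
                         chronic_onset_DM = as.Date(NA)) {
  if (is.null(coverage_intervals))
    coverage_intervals <- paste0(format(add_months(diagnosis_date, -36)),
                                 "..", format(GOLDEN_STUDY_END))
  tibble::tibble(
    patient_id = patient_id, birth_date = birth_date,
    diagnosis_date = diagnosis_date, stage = stage,
    lumpectomy = lumpectomy, mastectomy = mastectomy,
    bilateral_mastectomy = bilateral_mastectomy,
    chemotherapy = chemotherapy, radiotherapy = radiotherapy,
    curative_surgery = curative_surgery, death_date = death_date,
    recurrence_date = recurrence_date,
    metastasis_within_1yr = metastasis_within_1yr,
    prior_cancer_history = prior_cancer_history,
    non_solid_histology = non_solid_histology,
    hysterectomy_or_gyn_cancer_history = hysterectomy_or_gyn_cancer_history,
    coverage_intervals = coverage_intervals,
    chronic_onset_CSA = chronic_onset_CSA,
    chronic_onset_CHF = chronic_onset_CHF,
    chronic_onset_COPD = chronic_onset_COPD,
    chronic_onset_TIA = chronic_onset_TIA,
    chronic_onset_DM = chronic_onset_DM)
}

visit_row <- function(pid, date, provider, specialty = "PCP",
                      reason = "other") {
  tibble::tibble(patient_id = pid, date = as.Date(date),
                 provider_id = provider, specialty = specialty,
                 reason = reason)
}

imaging_row <- function(pid, date, modality, flag = NA) {
  tibble::tibble(patient_id = pid, date = as.Date(date), modality = modality,
                 program_surveillance = flag)
}

screening_row <- function(pid, date, kind) {
  tibble::tibble(patient_id = pid, date = as.Date(date), kind = kind)
}

# one condition-coded visit 10 days into each 6-month (or 12-month) block
chronic_visit_block <- function(pid, start, n_blocks, condition,
                                block_months = 6L, skip = integer()) {
  rows <- list()
  for (b in seq_len(n_blocks)) {
    if (b %in% skip) next
    d <- add_months(as.Date(start), (b - 1L) * block_months) + 10L
    rows[[length(rows) + 1L]] <- visit_row(pid, d, paste0(pid, "_SPEC"),
                                           "other_specialist", condition)
  }
  dplyr::bind_rows(rows)
}

# The golden fixture: 10 hand-constructed patients spanning every exclusion
# reason, every censoring cause, boundary visit counts, 329/330/331-day
# imaging gaps, bilateral mastectomy, each chronic condition and each
# preventive eligibility edge. Expected adherence.csv was hand-computed
# once (tests/testthat/golden_adherence.csv).
golden_tables <- function() {
  registry <- dplyr::bind_rows(
    make_patient("G01", birth_date = as.Date("1944-06-20")),
    make_patient("G02", diagnosis_date = as.Date("2008-01-15"),
                 death_date = as.Date("2009-09-15")),
    make_patient("G03", diagnosis_date = as.Date("2008-03-10"),
                 lumpectomy = FALSE,
                 recurrence_date = as.Date("2010-05-10")),
    make_patient("G04", birth_date = as.Date("1938-01-01"),
                 death_date = as.Date("2012-06-15"),
                 chronic_onset_TIA = as.Date("2000-01-01")),
    make_patient("G05", birth_date = as.Date("1962-03-01"),
                 diagnosis_date = as.Date("2008-02-01"),
                 recurrence_date = as.Date("2011-06-01"),
                 chronic_onset_CHF = as.Date("2007-01-01")),
    make_patient("G06", birth_date = as.Date("1985-07-01"),
                 lumpectomy = FALSE, mastectomy = TRUE,
                 bilateral_mastectomy = TRUE,
                 chronic_onset_COPD = as.Date("2008-01-01")),
    make_patient("G07", birth_date = as.Date("1957-01-01"),
                 hysterectomy_or_gyn_cancer_history = TRUE,
                 chronic_onset_DM = as.Date("2009-01-01")),
    make_patient("G08", metastasis_within_1yr = TRUE,
                 prior_cancer_history = TRUE),
    make_patient("G09", non_solid_histology = TRUE,
                 coverage_intervals =
                   "2005-06-15..2009-09-15;2009-11-15..2013-12-31"),
    make_patient("G10", birth_date = as.Date("1920-02-01"),
                 chronic_onset_CSA = as.Date("2005-06-01")))

  visits <- dplyr::bind_rows(
    # G01: onc_or_pcp 3,4,2,2; one med-onc breast visit each year
    visit_row("G01", "2009-07-01", "O1", "medical_oncologist",
              "breast_cancer"),
    visit_row("G01", "2009-09-01", "A1"),
    visit_row("G01", "2010-01-10", "A1"),
    visit_row("G01", "2010-07-01", "O1", "medical_oncologist",
              "breast_cancer"),
    visit_row("G01", "2010-09-01", "A1"),
    visit_row("G01", "2011-01-10", "A1"),
    visit_row("G01", "2011-03-01", "A1"),
    visit_row("G01", "2011-07-01", "O1", "medical_oncologist",
              "breast_cancer"),
    visit_row("G01", "2011-10-01", "A1"),
    visit_row("G01", "2012-07-01", "O1", "medical_oncologist",
              "breast_cancer"),
    visit_row("G01", "2012-10-01", "A1"),
    # G04: Year 2 five PCP days (over), Year 3 two (under); TIA visits
    visit_row("G04", "2009-07-01", "A1"),
    visit_row("G04", "2009-08-01", "A1"),
    visit_row("G04", "2009-09-01", "A1"),
    visit_row("G04", "2009-10-01", "A1"),
    visit_row("G04", "2009-11-01", "A1"),
    visit_row("G04", "2010-07-01", "A1"),
    visit_row("G04", "2010-08-01", "A1"),
    visit_row("G04", "2009-08-01", "G04_SPEC", "other_specialist", "TIA"),
    visit_row("G04", "2010-08-01", "G04_SPEC", "other_specialist", "TIA"),
    # G05: Year 2 four, Year 3 three; CHF visits in blocks 1-3 of 4
    visit_row("G05", "2009-03-05", "A1"),
    visit_row("G05", "2009-06-05", "A1"),
    visit_row("G05", "2009-09-05", "A1"),
    visit_row("G05", "2009-12-05", "A1"),
    visit_row("G05", "2010-03-05", "A1"),
    visit_row("G05", "2010-07-05", "A1"),
    visit_row("G05", "2010-11-05", "A1"),
    visit_row("G05", "2009-03-01", "G05_SPEC", "other_specialist", "CHF"),
    visit_row("G05", "2009-09-01", "G05_SPEC", "other_specialist", "CHF"),
    visit_row("G05", "2010-03-01", "G05_SPEC", "other_specialist", "CHF"),
    # G06: no physician visits at all; compliant COPD visits
    chronic_visit_block("G06", "2009-06-15", 9, "COPD"),
    # G07: surgeon promoted by a Year-3 breast-surgery claim
    visit_row("G07", "2009-08-01", "SURG1", "surgeon"),
    visit_row("G07", "2009-10-01", "SURG1", "surgeon"),
    visit_row("G07", "2009-12-01", "A1"),
    visit_row("G07", "2010-08-01", "SURG1", "surgeon", "breast_cancer"),
    visit_row("G07", "2010-09-01", "A1"),
    visit_row("G07", "2010-10-01", "A1"),
    visit_row("G07", "2010-11-01", "A1"),
    visit_row("G07", "2011-08-01", "A1"),
    visit_row("G07", "2011-09-01", "A1"),
    visit_row("G07", "2012-07-01", "A1"),
    visit_row("G07", "2012-08-01", "A1"),
    visit_row("G07", "2012-09-01", "A1"),
    # G07: DM visits, block 5 skipped
    chronic_visit_block("G07", "2009-06-15", 9, "DM", skip = 5L),
    # G10: 6,3,2,5 PCP days; compliant CSA visits
    visit_row("G10", "2009-07-05", "A1"),
    visit_row("G10", "2009-08-05", "A1"),
    visit_row("G10", "2009-09-05", "A1"),
    visit_row("G10", "2009-10-05", "A1"),
    visit_row("G10", "2009-11-05", "A1"),
    visit_row("G10", "2009-12-05", "A1"),
    visit_row("G10", "2010-07-05", "A1"),
    visit_row("G10", "2010-10-05", "A1"),
    visit_row("G10", "2011-01-05", "A1"),
    visit_row("G10", "2011-07-05", "A1"),
    visit_row("G10", "2011-10-05", "A1"),
    visit_row("G10", "2012-07-05", "A1"),
    visit_row("G10", "2012-08-05", "A1"),
    visit_row("G10", "2012-09-05", "A1"),
    visit_row("G10", "2012-10-05", "A1"),
    visit_row("G10", "2012-11-05", "A1"),
    # G10: compliant CSA visits in all 9 blocks
    chronic_visit_block("G10", "2009-06-15", 9, "CSA"))

  imaging <- dplyr::bind_rows(
    # G01: one mammogram per year, 365/366-day gaps, all surveillance
    imaging_row("G01", "2009-09-23", "mammogram"),
    imaging_row("G01", "2010-09-23", "mammogram"),
    imaging_row("G01", "2011-09-23", "mammogram"),
    imaging_row("G01", "2012-09-23", "mammogram"),
    # G04: one bone scan in Year 3
    imaging_row("G04", "2011-01-10", "bone_scan"),
    # G05: 330/331/329-day gap boundaries + a Year-2 chest CT
    imaging_row("G05", "2009-03-01", "mammogram"),
    imaging_row("G05", "2010-01-25", "mammogram"),
    imaging_row("G05", "2010-12-22", "mammogram"),
    imaging_row("G05", "2011-11-16", "breast_ultrasound"),
    imaging_row("G05", "2009-06-01", "chest_ct"),
    # G07: abdominal/pelvic CT in Year 4
    imaging_row("G07", "2012-01-10", "abdopelvic_ct"),
    # G10: pre-diagnosis mammogram, then two surveillance tests in Year 2
    imaging_row("G10", "2008-05-20", "mammogram"),
    imaging_row("G10", "2009-07-01", "mammogram"),
    imaging_row("G10", "2010-06-06", "mammogram"))
  # program flags replicate the interval rule (hand-checked gaps)
  imaging$program_surveillance <- c(TRUE, TRUE, TRUE, TRUE,
                                    NA,
                                    TRUE, FALSE, TRUE, FALSE, NA,
                                    NA,
                                    TRUE, TRUE, TRUE)

  screening <- dplyr::bind_rows(
    screening_row("G01", "2010-01-15", "colorectal_screen"),
    screening_row("G04", "2010-03-01", "bone_densitometry"),
    screening_row("G05", "2010-06-01", "cervical_screen"),
    screening_row("G07", "2012-05-01", "colorectal_screen"))

  list(registry = registry, visits = visits, imaging = imaging,
       screening = screening)
}
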