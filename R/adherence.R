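#' Guideline-adherence indicator classification
#'
#' Each eligible patient-year (visit and imaging indicators) or patient
#' (chronic-disease and preventive indicators) is classified against the
#' follow-up guidelines in effect for breast cancer survivors:
#' \itemize{
#'   \item physician visits, measured three ways (oncologist or PCP;
#'     oncologist only; breast cancer-related): adherent at 3-4 visits in
#'     each of Years 2-3 and 2 visits in each of Years 4-5;
#'   \item surveillance breast imaging (mammogram, breast ultrasound,
#'     breast MRI): one surveillance test per follow-up year, where a test
#'     is "surveillance" if it occurred more than 330 days after the last
#'     such test (or, in program-flag mode, carries a screening-program
#'     code); women with bilateral mastectomy are ineligible;
#'   \item imaging for metastatic disease (bone scan, chest X-ray/CT,
#'     abdominal/pelvic ultrasound/CT, non-breast MRI): adherent means NO
#'     such investigation, as none is recommended for asymptomatic
#'     patients;
#'   \item chronic-disease visits: one condition-coded visit every 6 months
#'     (every 12 months for TIA);
#'   \item preventive care: at least one cervical screen (age 20-69, no
#'     hysterectomy/gynaecologic-cancer history), bone densitometry
#'     (age >= 65), or colorectal screen (age 50-64) during follow-up.
#' }
#'
#' @name adherence
NULL

BREAST_MODALITIES <- c("mammogram", "breast_ultrasound", "breast_mri")
METASTATIC_MODALITIES <- c("bone_scan", "chest_xray", "chest_ct",
                           "abdopelvic_ultrasound", "abdopelvic_ct",
                           "nonbreast_mri")
ONCOLOGIST_SPECIALTIES <- c("medical_oncologist", "radiation_oncologist",
                            "surgical_oncologist")

#' Recommended visit schedule
#'
#' Adherent band of physician visits per follow-up year: 3-4 visits in each
#' of Years 2 and 3; 2 visits in each of Years 4 and 5.
#'
#' @return a tibble with columns `year`, `min_adherent`, `max_adherent`.
#' @export
recommended_visit_schedule <- function() {
  tibble::tibble(year = 2:5,
                 min_adherent = c(3L, 3L, 2L, 2L),
                 max_adherent = c(4L, 4L, 2L, 2L))
}

#' Classify a visit count against the recommended schedule
#'
#' @param visit_count number of qualifying visit-days in the year.
#' @param year follow-up year index, 2-5.
#' @param schedule a schedule tibble, by default
#'   [recommended_visit_schedule()].
#' @return `"under"`, `"adherent"` or `"over"`.
#' @export
classify_visit_adherence <- function(visit_count, year,
                                     schedule = recommended_visit_schedule()) {
  if (is.na(visit_count) || visit_count < 0)
    stop("visit_count must be a non-negative count", call. = FALSE)
  row <- schedule[schedule$year == year, ]
  if (nrow(row) != 1) stop("year ", year, " not in schedule", call. = FALSE)
  if (visit_count < row$min_adherent) "under"
  else if (visit_count <= row$max_adherent) "adherent"
  else "over"
}

#' Identify the oncologist provider set for one patient
#'
#' Oncologists are radiation, medical, or surgical oncologists, plus any
#' surgeon conducting a breast surgery during the follow-up period; the
#' promotion is period-wide, so a surgeon's Year 2 visits count even when
#' the breast-surgery claim falls in Year 3. A breast-surgery claim is a
#' claim with specialty `surgeon` and reason `breast_cancer`.
#'
#' @param visits one patient's visit claims.
#' @param followup_start,followup_end the survivorship period bounds.
#' @return character vector of promoted surgeon provider ids.
#' @export
breast_surgeons <- function(visits, followup_start, followup_end) {
  sel <- visits$specialty == "surgeon" & visits$reason == "breast_cancer" &
    visits$date >= followup_start & visits$date <= followup_end
  unique(visits$provider_id[sel])
}

#' Count qualifying visit-days in a window
#'
#' Counts distinct (provider, date) visit-days in the half-open window
#' `[start, end)` whose specialty passes the mode filter:
#' `onc_or_pcp` accepts PCPs plus oncologists; `onc_only` accepts
#' oncologists only; `breast_reason` accepts `onc_or_pcp` visits billed
#' with a breast-cancer reason code.
#'
#' @param visits one patient's visit claims.
#' @param start,end half-open window bounds.
#' @param mode `"onc_or_pcp"`, `"onc_only"` or `"breast_reason"`.
#' @param oncologist_ids extra provider ids treated as oncologists
#'   (promoted breast surgeons from [breast_surgeons()]).
#' @return integer count of visit-days.
#' @export
count_visits <- function(visits, start, end,
                         mode = c("onc_or_pcp", "onc_only", "breast_reason"),
                         oncologist_ids = character()) {
  mode <- match.arg(mode)
  is_onc <- visits$specialty %in% ONCOLOGIST_SPECIALTIES |
    (visits$specialty == "surgeon" & visits$provider_id %in% oncologist_ids)
  keep <- switch(mode,
    onc_or_pcp = visits$specialty == "PCP" | is_onc,
    onc_only = is_onc,
    breast_reason = (visits$specialty == "PCP" | is_onc) &
      visits$reason == "breast_cancer")
  keep <- keep & in_window(visits$date, start, end)
  length(unique(paste(visits$provider_id[keep], format(visits$date[keep]))))
}

#' Flag breast-imaging events as surveillance
#'
#' In `interval_rule` mode, scans chronologically over ALL breast-imaging
#' events of the three modalities (pre-diagnosis history included): an
#' event is surveillance iff more than 330 days separate it from the
#' immediately preceding breast-imaging event of any of the three
#' modalities, or no prior event exists. The gap is measured against the
#' test group as a whole, since the rule's purpose is to exclude
#' symptom-triggered workup after a recent test. In `program_flag` mode
#' (screening-program dialect), an event is surveillance iff its
#' `program_surveillance` flag is set.
#'
#' @param imaging one patient's breast-imaging events, sorted by date;
#'   columns `date`, `modality`, and (for program mode)
#'   `program_surveillance`.
#' @param mode `"interval_rule"` or `"program_flag"`.
#' @return logical vector, one flag per event.
#' @export
flag_surveillance <- function(imaging, mode = c("interval_rule",
                                                "program_flag")) {
  mode <- match.arg(mode)
  if (nrow(imaging) == 0) return(logical())
  if (!all(imaging$modality %in% BREAST_MODALITIES))
    stop("flag_surveillance expects breast modalities only", call. = FALSE)
  if (is.unsorted(imaging$date))
    stop("imaging events must be sorted by date", call. = FALSE)
  if (mode == "program_flag") return(imaging$program_surveillance %in% TRUE)
  gaps <- c(Inf, diff(as.numeric(imaging$date)))
  gaps > 330
}

#' Classify surveillance breast-imaging adherence for one year
#'
#' @param surveillance_count number of surveillance-flagged tests within
#'   one full-follow-up year window.
#' @param bilateral_mastectomy flag; such women have no intact breast to
#'   image and are ineligible for the indicator.
#' @return `"ineligible"`, `"under"` (0 tests), `"adherent"` (1) or
#'   `"over"` (>= 2).
#' @export
classify_surveillance_adherence <- function(surveillance_count,
                                            bilateral_mastectomy) {
  if (isTRUE(bilateral_mastectomy)) return("ineligible")
  if (surveillance_count == 0) "under"
  else if (surveillance_count == 1) "adherent"
  else "over"
}

#' Classify imaging for metastatic disease in a window
#'
#' Adherent iff the window contains no bone scan, chest X-ray or CT,
#' abdominal/pelvic ultrasound or CT, or non-breast MRI; breast modalities
#' are excluded from this indicator.
#'
#' @param imaging one patient's imaging events (any modality).
#' @param start,end half-open window bounds.
#' @return `"adherent"` or `"not_adherent"`.
#' @export
classify_metastatic_imaging <- function(imaging, start, end) {
  hit <- imaging$modality %in% METASTATIC_MODALITIES &
    in_window(imaging$date, start, end)
  if (any(hit)) "not_adherent" else "adherent"
}

#' Classify chronic-disease visit adherence
#'
#' A patient has the condition if its onset is on/before survivorship
#' start. Follow-up `[survivorship_start, end_date)` is partitioned into
#' consecutive 6-calendar-month blocks (12 months for TIA), the trailing
#' partial block discarded; adherent iff every complete block contains at
#' least one physician visit billed with that condition as the reason.
#' A patient with zero complete blocks is ineligible.
#'
#' @param condition one of `"CSA"`, `"CHF"`, `"COPD"`, `"TIA"`, `"DM"`.
#' @param visits one patient's visit claims.
#' @param plan follow-up plan (needs `survivorship_start`, `end_date`).
#' @param onset the condition's onset date, `NA` if never diagnosed.
#' @return `"ineligible"`, `"adherent"` or `"not_adherent"`.
#' @export
classify_chronic <- function(condition, visits, plan, onset) {
  if (!condition %in% CHRONIC_CONDITIONS)
    stop("unknown chronic condition code: ", condition, call. = FALSE)
  if (is.na(onset) || onset > plan$survivorship_start) return("ineligible")
  block_months <- if (condition == "TIA") 12L else 6L
  blocks <- chronic_blocks(plan$survivorship_start, plan$end_date,
                           block_months)
  if (nrow(blocks) == 0) return("ineligible")
  vd <- visits$date[visits$reason == condition]
  for (i in seq_len(nrow(blocks))) {
    if (!any(in_window(vd, blocks$start[i], blocks$end[i])))
      return("not_adherent")
  }
  "adherent"
}

# complete consecutive calendar blocks of block_months within [start, end)
chronic_blocks <- function(start, end, block_months) {
  starts <- ends <- as.Date(character())
  k <- 0L
  repeat {
    bs <- add_months(start, k * block_months)
    be <- add_months(start, (k + 1L) * block_months)
    if (be > end) break
    starts <- c(starts, bs)
    ends <- c(ends, be)
    k <- k + 1L
  }
  tibble::tibble(start = starts, end = ends)
}

#' Classify preventive-care adherence
#'
#' Age eligibility is evaluated once, at survivorship start: cervical
#' screening for ages 20-69 without hysterectomy or gynaecologic-cancer
#' history, bone densitometry at age >= 65, colorectal screening at ages
#' 50-64. Adherent iff at least one event of the matching kind falls in
#' `[survivorship_start, end_date)`.
#'
#' @param record patient registry record (needs `birth_date`,
#'   `hysterectomy_or_gyn_cancer_history`).
#' @param screening one patient's screening events (`date`, `kind` in
#'   `cervical_screen`, `bone_densitometry`, `colorectal_screen`).
#' @param plan follow-up plan.
#' @return named character vector over `cervical`, `bone_density`,
#'   `colorectal`, each `"ineligible"`, `"adherent"` or `"not_adherent"`.
#' @export
classify_preventive <- function(record, screening, plan) {
  record <- as.list(record)
  age <- age_at(record$birth_date, plan$survivorship_start)
  kinds <- c(cervical = "cervical_screen", bone_density = "bone_densitometry",
             colorectal = "colorectal_screen")
  eligible <- c(
    cervical = age >= 20 && age <= 69 &&
      !isTRUE(record$hysterectomy_or_gyn_cancer_history),
    bone_density = age >= 65,
    colorectal = age >= 50 && age <= 64)
  out <- character(3)
  names(out) <- names(kinds)
  for (k in names(kinds)) {
    if (!eligible[[k]]) { out[[k]] <- "ineligible"; next }
    hit <- screening$kind == kinds[[k]] &
      in_window(screening$date, plan$survivorship_start, plan$end_date)
    out[[k]] <- if (any(hit)) "adherent" else "not_adherent"
  }
  out
}

# completed years of age at a reference date (calendar anniversaries)
age_at <- function(birth_date, at) {
  yrs <- as.POSIXlt(at)$year - as.POSIXlt(birth_date)$year
  if (add_years(birth_date, yrs) > at) yrs <- yrs - 1L
  yrs
}

#' Assess every adherence indicator for a cohort
#'
#' Runs all indicator classifiers over the included patients. Visit and
#' imaging indicators are per full-follow-up year (Years 2-5); chronic and
#' preventive indicators are whole-follow-up binaries (year `"all"`).
#' Patient-years without full follow-up are reported ineligible with
#' reason `partial_year`.
#'
#' @param cohort cohort tibble from [build_cohort()].
#' @param registry registry tibble (for treatment flags, birth dates,
#'   chronic onsets).
#' @param visits,imaging,screening event tibbles for the whole cohort.
#' @param surveillance_mode `"interval_rule"` or `"program_flag"` (the
#'   screening-program dialect).
#' @return a long tibble: `patient_id`, `indicator`, `year` (2-5 or
#'   `"all"`), `eligible`, `reason` (ineligibility reason or empty),
#'   `category`.
#' @export
assess_adherence <- function(cohort, registry, visits, imaging, screening,
                             surveillance_mode = c("interval_rule",
                                                   "program_flag")) {
  surveillance_mode <- match.arg(surveillance_mode)
  inc <- cohort[cohort$included %in% TRUE, ]
  schedule <- recommended_visit_schedule()
  vis_idx <- split(seq_len(nrow(visits)), visits$patient_id)
  img_idx <- split(seq_len(nrow(imaging)), imaging$patient_id)
  scr_idx <- split(seq_len(nrow(screening)), screening$patient_id)
  out <- vector("list", nrow(inc))
  for (i in seq_len(nrow(inc))) {
    pt <- as.list(inc[i, ])
    reg <- as.list(registry[match(pt$patient_id, registry$patient_id), ])
    pv <- visits[vis_idx[[pt$patient_id]] %||% integer(), ]
    pim <- imaging[img_idx[[pt$patient_id]] %||% integer(), ]
    psc <- screening[scr_idx[[pt$patient_id]] %||% integer(), ]
    plan <- list(survivorship_start = pt$survivorship_start,
                 end_date = pt$end_date)
    onc_ids <- breast_surgeons(pv, pt$survivorship_start, pt$end_date)

    # breast imaging flagged over the whole history (pre-diagnosis included)
    bim <- pim[pim$modality %in% BREAST_MODALITIES, ]
    bim <- bim[order(bim$date), ]
    surv_flag <- flag_surveillance(bim, surveillance_mode)
    surv_dates <- bim$date[surv_flag]

    full <- c(`2` = pt$full_y2, `3` = pt$full_y3,
              `4` = pt$full_y4, `5` = pt$full_y5)
    rows <- list()
    for (k in 2:5) {
      ws <- add_years(pt$diagnosis_date, k - 1L)
      we <- add_years(pt$diagnosis_date, k)
      if (!isTRUE(full[[as.character(k)]])) {
        for (ind in c("visits_onc_or_pcp", "visits_onc_only",
                      "visits_breast_reason", "surveillance_breast_imaging",
                      "metastatic_imaging"))
          rows[[length(rows) + 1L]] <- adh_row(pt$patient_id, ind, k,
                                               FALSE, "partial_year", NA)
        next
      }
      for (mode in c(visits_onc_or_pcp = "onc_or_pcp",
                     visits_onc_only = "onc_only",
                     visits_breast_reason = "breast_reason")) {
        ind <- names(which(c(visits_onc_or_pcp = "onc_or_pcp",
                             visits_onc_only = "onc_only",
                             visits_breast_reason = "breast_reason") == mode))
        cnt <- count_visits(pv, ws, we, mode, onc_ids)
        rows[[length(rows) + 1L]] <- adh_row(
          pt$patient_id, ind, k, TRUE, "",
          classify_visit_adherence(cnt, k, schedule))
      }
      if (isTRUE(reg$bilateral_mastectomy)) {
        rows[[length(rows) + 1L]] <- adh_row(
          pt$patient_id, "surveillance_breast_imaging", k, FALSE,
          "bilateral_mastectomy", NA)
      } else {
        n_surv <- sum(in_window(surv_dates, ws, we))
        rows[[length(rows) + 1L]] <- adh_row(
          pt$patient_id, "surveillance_breast_imaging", k, TRUE, "",
          classify_surveillance_adherence(n_surv, FALSE))
      }
      rows[[length(rows) + 1L]] <- adh_row(
        pt$patient_id, "metastatic_imaging", k, TRUE, "",
        classify_metastatic_imaging(pim, ws, we))
    }
    for (cond in CHRONIC_CONDITIONS) {
      onset <- reg[[paste0("chronic_onset_", cond)]] %||% as.Date(NA)
      cat <- classify_chronic(cond, pv, plan, onset)
      rows[[length(rows) + 1L]] <- adh_row(
        pt$patient_id, paste0("chronic_", cond), "all",
        cat != "ineligible",
        if (cat == "ineligible") "no_condition_or_no_complete_block" else "",
        if (cat == "ineligible") NA else cat)
    }
    prev <- classify_preventive(reg, psc, plan)
    for (k in names(prev)) {
      rows[[length(rows) + 1L]] <- adh_row(
        pt$patient_id, paste0("prev_", k), "all",
        prev[[k]] != "ineligible",
        if (prev[[k]] == "ineligible") "age_or_history" else "",
        if (prev[[k]] == "ineligible") NA else prev[[k]])
    }
    out[[i]] <- dplyr::bind_rows(rows)
  }
  if (length(out) == 0) return(empty_adherence())
  dplyr::bind_rows(out)
}

adh_row <- function(patient_id, indicator, year, eligible, reason, category) {
  tibble::tibble(patient_id = patient_id, indicator = indicator,
                 year = as.character(year), eligible = eligible,
                 reason = reason,
                 category = if (is.na(category[1])) NA_character_
                            else as.character(category))
}

empty_adherence <- function() {
  tibble::tibble(patient_id = character(), indicator = character(),
                 year = character(), eligible = logical(),
                 reason = character(), category = character())
}
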