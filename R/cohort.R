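#' Cohort eligibility, censoring and follow-up windows
#'
#' The survivorship phase starts 1 year post-diagnosis and runs to the
#' earliest of the administrative end of follow-up, 6 calendar months before
#' death, or 90 days before a recurrence/new primary. Adherence is assessed
#' in anniversary-anchored Years 2-5, each a half-open window
#' `[diagnosis + (k-1) years, diagnosis + k years)`, and a patient
#' contributes to Year k only with full follow-up in that year.
#'
#' @name cohort
NULL

EXCLUSION_CODES <- c("not_alive_30mo", "no_curative_surgery",
                     "early_recurrence", "early_metastasis",
                     "coverage_gap", "insufficient_followup",
                     "prior_cancer_history", "non_solid_histology")

# candidate censored end date + which bound binds.
# Tie-break order: study_end < death < recurrence.
censor_end <- function(record, study_end) {
  bounds <- c(study_end = as.numeric(study_end),
              death_minus_6mo = if (!is.na(record$death_date))
                as.numeric(add_months(record$death_date, -6)) else Inf,
              recurrence_minus_90d = if (!is.na(record$recurrence_date))
                as.numeric(record$recurrence_date - 90) else Inf)
  end <- min(bounds)
  cause <- names(bounds)[which(bounds == end)[1]]
  list(end_date = as.Date(end, origin = "1970-01-01"), censor_cause = cause)
}

#' Screen one registry record against the cohort eligibility rules
#'
#' Rules are evaluated in a documented fixed order and every triggered
#' reason is reported, not just the first:
#' (1) alive at diagnosis + 30 months; (2) curative surgery;
#' (3) no recurrence/new primary within 27 months of diagnosis;
#' (4) no metastasis within 1 year; (5) uninterrupted health-insurance
#' coverage from diagnosis to the censored end date; (6) at least 1 year of
#' survivorship follow-up (censored end >= diagnosis + 2 years);
#' (7) no prior in situ breast / non-melanoma cancer history;
#' (8) solid-tumour histology.
#'
#' @param record a patient registry record (one-row data frame or list with
#'   the registry columns).
#' @param study_end administrative end-of-follow-up `Date`.
#' @return a list with `patient_id`, `decision` (`"included"`/`"excluded"`)
#'   and `reasons` (character vector of triggered exclusion codes, in rule
#'   order).
#' @export
apply_eligibility <- function(record, study_end) {
  record <- as.list(record)
  if (is.null(record$diagnosis_date) || is.na(record$diagnosis_date))
    stop("missing diagnosis_date for patient ",
         record$patient_id %||% "<unknown>", call. = FALSE)
  dx <- record$diagnosis_date
  ce <- censor_end(record, study_end)
  reasons <- character()
  if (!is.na(record$death_date) && record$death_date < add_months(dx, 30))
    reasons <- c(reasons, "not_alive_30mo")
  if (!isTRUE(record$curative_surgery))
    reasons <- c(reasons, "no_curative_surgery")
  if (!is.na(record$recurrence_date) &&
      record$recurrence_date < add_months(dx, 27))
    reasons <- c(reasons, "early_recurrence")
  if (isTRUE(record$metastasis_within_1yr))
    reasons <- c(reasons, "early_metastasis")
  if (!coverage_spans(record$coverage_intervals, dx, ce$end_date))
    reasons <- c(reasons, "coverage_gap")
  if (ce$end_date < add_years(dx, 2))
    reasons <- c(reasons, "insufficient_followup")
  if (isTRUE(record$prior_cancer_history))
    reasons <- c(reasons, "prior_cancer_history")
  if (isTRUE(record$non_solid_histology))
    reasons <- c(reasons, "non_solid_histology")
  list(patient_id = record$patient_id,
       decision = if (length(reasons) > 0) "excluded" else "included",
       reasons = reasons)
}

#' Build the survivorship follow-up plan for an eligible patient
#'
#' @inheritParams apply_eligibility
#' @return a list with `patient_id`, `survivorship_start`
#'   (diagnosis + 1 year), `end_date`, `censor_cause` (one of `study_end`,
#'   `death_minus_6mo`, `recurrence_minus_90d`), and `year_windows`, a
#'   tibble with one row per Year 2-5: half-open `[start, end)` bounds and a
#'   `full_followup` flag true iff `end_date >=` the window's end.
#' @export
build_followup <- function(record, study_end) {
  record <- as.list(record)
  dx <- record$diagnosis_date
  ce <- censor_end(record, study_end)
  start <- add_years(dx, 1)
  if (ce$end_date < start)
    stop("patient ", record$patient_id,
         " has no survivorship follow-up; should have been excluded",
         call. = FALSE)
  years <- 2:5
  ws <- add_years(dx, years - 1L)
  we <- add_years(dx, years)
  tibble::tibble(
    year = years, start = ws, end = we,
    full_followup = ce$end_date >= we
  ) -> yw
  list(patient_id = record$patient_id,
       survivorship_start = start,
       end_date = ce$end_date,
       censor_cause = ce$censor_cause,
       year_windows = yw)
}

#' Screen a whole registry and build follow-up plans
#'
#' Applies [apply_eligibility()] to every registry row and
#' [build_followup()] to the included patients.
#'
#' @param registry registry tibble (see [read_tables()] for the schema).
#' @param study_end administrative end-of-follow-up `Date`.
#' @return a tibble with one row per patient: `patient_id`, `included`,
#'   `reasons` (`;`-joined exclusion codes, empty when included),
#'   `survivorship_start`, `end_date`, `censor_cause`, and
#'   `full_y2` .. `full_y5` flags (all `NA` for excluded patients).
#' @export
build_cohort <- function(registry, study_end) {
  n <- nrow(registry)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- as.list(registry[i, ])
    rep <- apply_eligibility(rec, study_end)
    if (rep$decision == "included") {
      plan <- build_followup(rec, study_end)
      ff <- plan$year_windows$full_followup
      out[[i]] <- tibble::tibble(
        patient_id = rec$patient_id, included = TRUE, reasons = "",
        diagnosis_date = rec$diagnosis_date,
        survivorship_start = plan$survivorship_start,
        end_date = plan$end_date, censor_cause = plan$censor_cause,
        full_y2 = ff[1], full_y3 = ff[2], full_y4 = ff[3], full_y5 = ff[4])
    } else {
      out[[i]] <- tibble::tibble(
        patient_id = rec$patient_id, included = FALSE,
        reasons = paste(rep$reasons, collapse = ";"),
        diagnosis_date = rec$diagnosis_date,
        survivorship_start = as.Date(NA), end_date = as.Date(NA),
        censor_cause = NA_character_,
        full_y2 = NA, full_y3 = NA, full_y4 = NA, full_y5 = NA)
    }
  }
  dplyr::bind_rows(out)
}

# does the union of coverage intervals contain every day of [from, to]?
coverage_spans <- function(intervals, from, to) {
  iv <- parse_coverage(intervals)
  if (nrow(iv) == 0) return(FALSE)
  iv <- iv[order(iv$start), , drop = FALSE]
  cur_start <- iv$start[1]
  cur_end <- iv$end[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= cur_end + 1) {
      cur_end <- max(cur_end, iv$end[i])
    } else {
      if (cur_start <= from && cur_end >= to) return(TRUE)
      cur_start <- iv$start[i]
      cur_end <- iv$end[i]
    }
  }
  cur_start <= from && cur_end >= to
}

# coverage serialization: "YYYY-MM-DD..YYYY-MM-DD;..." (closed intervals)
parse_coverage <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.na(x) || !nzchar(x))
    return(data.frame(start = as.Date(character()),
                      end = as.Date(character())))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  se <- strsplit(parts, "..", fixed = TRUE)
  data.frame(start = as.Date(vapply(se, `[`, "", 1)),
             end = as.Date(vapply(se, `[`, "", 2)))
}

format_coverage <- function(start, end) {
  paste(paste0(format(start), "..", format(end)), collapse = ";")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
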