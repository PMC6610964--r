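#' Usual Provider of Care (UPC) continuity index
#'
#' The UPC index is the fraction of a patient's visit-days made to the
#' single most-visited provider. Same-day duplicate claims to one provider
#' collapse to one visit-day (fee-for-service data commonly multi-bill one
#' encounter); same-day claims to different providers count separately.
#' The index is computed only when a patient has at least 3 visit-days;
#' fewer visits fall into the count buckets of the four-level
#' categorization: `0 visit`, `1-2 visits`, `Low` (UPC <= 0.75),
#' `High` (UPC > 0.75).
#'
#' @param visits a tibble of visit claims for ONE patient, pre-filtered to
#'   the intended window and specialty set; needs columns `provider_id` and
#'   `date`.
#' @return a list with `n_visits` (distinct visit-days) and `upc_value`
#'   (`NA` when `n_visits < 3`).
#' @examples
#' v <- tibble::tibble(provider_id = c("A", "A", "A", "B"),
#'                     date = as.Date("2010-01-01") + c(0, 30, 60, 90))
#' compute_upc(v)  # n_visits 4, upc 0.75
#' @export
compute_upc <- function(visits) {
  if (is.null(visits) || nrow(visits) == 0)
    return(list(n_visits = 0L, upc_value = NA_real_))
  days <- unique(paste(visits$provider_id, format(visits$date)))
  n <- length(days)
  if (n < 3) return(list(n_visits = n, upc_value = NA_real_))
  prov <- sub(" .*$", "", days)
  list(n_visits = n, upc_value = max(table(prov)) / n)
}

#' Four-level continuity category
#'
#' @param n_visits distinct visit-days in the window.
#' @param upc_value UPC index, `NA` when `n_visits < 3`.
#' @return one of `"zero_visits"`, `"one_two_visits"`, `"low"` (UPC <=
#'   0.75), `"high"` (UPC > 0.75).
#' @export
upc_category <- function(n_visits, upc_value) {
  if (n_visits == 0) return("zero_visits")
  if (n_visits <= 2) return("one_two_visits")
  if (upc_value <= 0.75) "low" else "high"
}

#' Continuity assessment windows
#'
#' Three (window, interval, specialty) triples per patient: `baseline` is
#' PCP care in the 6-to-30-month pre-diagnosis period,
#' `[diagnosis - 30 months, diagnosis - 6 months)`; `survivorship_pcp` and
#' `survivorship_medonc` are PCP and medical-oncology care from 1 year
#' post-diagnosis to the censored end date (closed on the right).
#'
#' @param record patient registry record (needs `diagnosis_date`).
#' @param plan the patient's follow-up plan from [build_followup()].
#' @return a tibble with columns `window`, `start`, `end`,
#'   `right_closed`, `specialty`.
#' @export
continuity_windows <- function(record, plan) {
  record <- as.list(record)
  dx <- record$diagnosis_date
  tibble::tibble(
    window = c("baseline", "survivorship_pcp", "survivorship_medonc"),
    start = c(add_months(dx, -30), plan$survivorship_start,
              plan$survivorship_start),
    end = c(add_months(dx, -6), plan$end_date, plan$end_date),
    right_closed = c(FALSE, TRUE, TRUE),
    specialty = c("PCP", "PCP", "medical_oncologist")
  )
}

#' Continuity of care for a whole cohort
#'
#' Computes the UPC index and four-level category for every included
#' patient in each of the three continuity windows.
#'
#' @param cohort cohort tibble from [build_cohort()].
#' @param visits visit-claims tibble for the whole cohort.
#' @return a tibble: `patient_id`, `window`, `n_visits`, `upc_value`,
#'   `category`.
#' @export
assess_continuity <- function(cohort, visits) {
  inc <- cohort[cohort$included %in% TRUE, ]
  vis_idx <- split(seq_len(nrow(visits)), visits$patient_id)
  out <- vector("list", nrow(inc))
  for (i in seq_len(nrow(inc))) {
    pt <- as.list(inc[i, ])
    plan <- list(survivorship_start = pt$survivorship_start,
                 end_date = pt$end_date)
    wins <- continuity_windows(list(diagnosis_date = pt$diagnosis_date), plan)
    pv <- visits[vis_idx[[pt$patient_id]] %||% integer(), ]
    res <- vector("list", nrow(wins))
    for (j in seq_len(nrow(wins))) {
      w <- wins[j, ]
      keep <- pv$specialty == w$specialty & pv$date >= w$start &
        (if (w$right_closed) pv$date <= w$end else pv$date < w$end)
      u <- compute_upc(pv[keep, ])
      res[[j]] <- tibble::tibble(
        patient_id = pt$patient_id, window = w$window,
        n_visits = u$n_visits, upc_value = u$upc_value,
        category = upc_category(u$n_visits, u$upc_value))
    }
    out[[i]] <- dplyr::bind_rows(res)
  }
  if (length(out) == 0)
    return(tibble::tibble(patient_id = character(), window = character(),
                          n_visits = integer(), upc_value = double(),
                          category = character()))
  dplyr::bind_rows(out)
}
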