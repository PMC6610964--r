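#' Descriptive summary tables
#'
#' Tabulates the pipeline outputs into the study's reporting surfaces:
#' a cohort-characteristics table (retention, stage, treatment, continuity
#' categories), per-year three-category tables for the visit and imaging
#' indicators, and whole-follow-up tables for chronic-disease and
#' preventive indicators. Descriptive counts and proportions only — no
#' tests or confidence intervals are computed, as the inputs represent a
#' census, not a sample.
#'
#' Denominator discipline: every proportion uses only eligible
#' patient-years (full follow-up, indicator-specific eligibility); within
#' each (indicator, year) the category proportions sum to 1.
#'
#' @param adherence long adherence tibble from [assess_adherence()].
#' @param cohort cohort tibble from [build_cohort()].
#' @param continuity continuity tibble from [assess_continuity()].
#' @param registry optional registry tibble; adds stage and treatment
#'   rows to the characteristics table.
#' @return a named list of tibbles: `characteristics`, `per_year`,
#'   `whole_followup`.
#' @export
summarize_results <- function(adherence, cohort, continuity,
                              registry = NULL) {
  inc <- cohort[cohort$included %in% TRUE, ]
  ids <- inc$patient_id
  if (!all(adherence$patient_id %in% ids) ||
      !all(continuity$patient_id %in% ids))
    stop("mixed-run inputs: adherence/continuity contain patients not in ",
         "the cohort", call. = FALSE)
  n_inc <- nrow(inc)

  char_rows <- list(tibble::tibble(
    variable = "cohort", level = "included", n = n_inc, proportion = 1))
  for (k in 2:5) {
    cnt <- sum(inc[[paste0("full_y", k)]])
    char_rows[[length(char_rows) + 1L]] <- tibble::tibble(
      variable = "full_followup", level = paste0("year_", k),
      n = cnt, proportion = if (n_inc > 0) cnt / n_inc else NA_real_)
  }
  if (!is.null(registry)) {
    reg_inc <- registry[registry$patient_id %in% ids, ]
    char_rows[[length(char_rows) + 1L]] <-
      count_levels(reg_inc$stage, "stage")
    for (v in c("lumpectomy", "mastectomy", "radiotherapy"))
      char_rows[[length(char_rows) + 1L]] <-
        count_levels(ifelse(reg_inc[[v]], "yes", "no"), v)
    char_rows[[length(char_rows) + 1L]] <-
      count_levels(reg_inc$chemotherapy, "chemotherapy")
  }
  for (w in unique(continuity$window)) {
    cw <- continuity[continuity$window == w, ]
    char_rows[[length(char_rows) + 1L]] <-
      count_levels(cw$category, paste0("continuity_", w))
  }
  characteristics <- dplyr::bind_rows(char_rows)

  yearly <- adherence[adherence$year != "all" & adherence$eligible, ]
  per_year <- if (nrow(yearly) > 0) {
    yearly |>
      dplyr::count(.data$indicator, .data$year, .data$category,
                   name = "n") |>
      dplyr::group_by(.data$indicator, .data$year) |>
      dplyr::mutate(denominator = sum(.data$n),
                    proportion = .data$n / .data$denominator) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$indicator, .data$year, .data$category)
  } else {
    tibble::tibble(indicator = character(), year = character(),
                   category = character(), n = integer(),
                   denominator = integer(), proportion = double())
  }

  whole <- adherence[adherence$year == "all", ]
  whole_followup <- if (nrow(whole) > 0) {
    el <- whole |>
      dplyr::group_by(.data$indicator) |>
      dplyr::summarise(n_eligible = sum(.data$eligible),
                       prevalence = sum(.data$eligible) / n_inc,
                       n_adherent = sum(.data$category %in% "adherent"),
                       .groups = "drop") |>
      dplyr::mutate(adherence_proportion = ifelse(
        .data$n_eligible > 0, .data$n_adherent / .data$n_eligible,
        NA_real_))
    el
  } else {
    tibble::tibble(indicator = character(), n_eligible = integer(),
                   prevalence = double(), n_adherent = integer(),
                   adherence_proportion = double())
  }

  list(characteristics = characteristics, per_year = per_year,
       whole_followup = whole_followup)
}

count_levels <- function(x, variable) {
  tb <- table(x)
  tibble::tibble(variable = variable, level = names(tb),
                 n = as.integer(tb),
                 proportion = as.integer(tb) / max(1L, length(x)))
}

#' Render a summary table with proportions to one decimal place
#'
#' CSV outputs keep full precision; this is the human-readable rendering.
#'
#' @param tab a tibble with a `proportion` column.
#' @return the tibble with `proportion` formatted as a percentage string.
#' @export
format_proportions <- function(tab) {
  tab$proportion <- sprintf("%.1f%%", 100 * tab$proportion)
  tab
}
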