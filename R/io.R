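#' Read and write the pipeline's CSV tables
#'
#' All tables are UTF-8 CSV with a mandatory header row and ISO-8601
#' dates. Missing columns and unparseable dates are reported as
#' named-column errors with a row number.
#'
#' @name io
NULL

TABLE_SCHEMAS <- list(
  registry = c(patient_id = "chr", birth_date = "date",
               diagnosis_date = "date", stage = "chr", lumpectomy = "lgl",
               mastectomy = "lgl", bilateral_mastectomy = "lgl",
               chemotherapy = "chr", radiotherapy = "lgl",
               curative_surgery = "lgl", death_date = "date",
               recurrence_date = "date", metastasis_within_1yr = "lgl",
               prior_cancer_history = "lgl", non_solid_histology = "lgl",
               hysterectomy_or_gyn_cancer_history = "lgl",
               coverage_intervals = "chr", chronic_onset_CSA = "date",
               chronic_onset_CHF = "date", chronic_onset_COPD = "date",
               chronic_onset_TIA = "date", chronic_onset_DM = "date"),
  visits = c(patient_id = "chr", date = "date", provider_id = "chr",
             specialty = "chr", reason = "chr"),
  imaging = c(patient_id = "chr", date = "date", modality = "chr",
              program_surveillance = "lgl"),
  screening = c(patient_id = "chr", date = "date", kind = "chr")
)

#' Write simulated or pipeline tables to a directory
#'
#' @param tables named list of tibbles (e.g. from [generate_dataset()]);
#'   each element `x` is written as `x.csv`.
#' @param dir output directory, created if needed.
#' @return the paths written, invisibly.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(tables))
  for (i in seq_along(tables)) {
    paths[i] <- file.path(dir, paste0(names(tables)[i], ".csv"))
    readr::write_csv(tables[[i]], paths[i], na = "")
  }
  invisible(paths)
}

#' Read the four event tables from a directory
#'
#' @param dir directory containing `registry.csv`, `visits.csv`,
#'   `imaging.csv`, `screening.csv`.
#' @return named list of validated tibbles.
#' @export
read_tables <- function(dir) {
  out <- list()
  for (nm in names(TABLE_SCHEMAS)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path))
      stop("missing input table: ", path, call. = FALSE)
    out[[nm]] <- read_events(path, TABLE_SCHEMAS[[nm]])
  }
  out
}

# read one CSV against a schema; all coercion errors name the column
read_events <- function(path, schema) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(names(schema), names(raw))
  if (length(missing) > 0)
    stop(sprintf("file '%s': missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  out <- raw[names(schema)]
  for (col in names(schema)) {
    out[[col]] <- switch(schema[[col]],
      chr = out[[col]],
      date = parse_date_col(out[[col]], col),
      lgl = parse_logical_col(out[[col]], col))
  }
  tibble::as_tibble(out)
}

parse_logical_col <- function(x, col) {
  up <- toupper(trimws(ifelse(is.na(x), "", x)))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1")] <- TRUE
  out[up %in% c("FALSE", "F", "0")] <- FALSE
  bad <- which(!(up %in% c("TRUE", "T", "1", "FALSE", "F", "0", "", "NA")))
  if (length(bad) > 0)
    stop(sprintf("column '%s': unparseable logical at row %d ('%s')",
                 col, bad[1], x[bad[1]]), call. = FALSE)
  out
}
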