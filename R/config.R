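#' Simulation configuration
#'
#' Parameterizes the synthetic-claims generator. Defaults describe a large
#' single-payer provincial cohort with complete data capture (diagnosis years
#' 2007-2012, follow-up complete to end of 2013): stage mix, treatment
#' probabilities, and chronic-condition prevalences follow the published
#' descriptive characteristics of such a cohort; behavioural parameters
#' (adherence mixes, provider loyalty, imaging rates) are exposed so tests
#' can sweep them.
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer RNG seed; mandatory (reproducibility is part of the
#'   generator contract).
#' @param diagnosis_start,diagnosis_end bounds of the diagnosis window.
#' @param study_end administrative end of follow-up.
#' @param age_median,age_spread median age at diagnosis (years) and an
#'   IQR-like spread; ages are drawn normal(median, spread/1.349), truncated
#'   to 18-95.
#' @param stage_probabilities length-5 probability vector over stages
#'   I, II, III, IV, Unknown (must sum to 1).
#' @param p_lumpectomy,p_mastectomy,p_bilateral_given_mastectomy,p_chemo,p_radio
#'   per-modality treatment probabilities; lumpectomy and mastectomy are
#'   drawn independently and `curative_surgery` is their union.
#' @param annual_death_hazard,annual_recurrence_hazard per-year geometric
#'   hazards for death and recurrence/new primary.
#' @param visit_adherence_mix length-3 probability vector over
#'   (under, adherent, over) for the physician-visit indicator.
#' @param oncologist_visit_propensity probability a follow-up visit is to a
#'   medical oncologist rather than a PCP.
#' @param provider_loyalty concentration parameter >= 0 governing how a
#'   patient's visits spread over providers: a visit goes to the patient's
#'   usual provider with probability loyalty/(1+loyalty), else uniformly
#'   over the pool. loyalty -> Inf gives UPC = 1; loyalty = 0 gives a
#'   uniform spread.
#' @param surveillance_adherence_mix length-3 probability vector over
#'   (under, adherent, over) for surveillance breast imaging.
#' @param metastatic_imaging_rate per-year probability of receiving a
#'   not-recommended metastatic-disease investigation.
#' @param chronic_prevalence named probabilities for CSA, CHF, COPD, TIA, DM.
#' @param chronic_visit_compliance named per-condition probability of a
#'   compliant visit pattern.
#' @param preventive_uptake named probabilities for cervical, bone_density,
#'   colorectal screening uptake among the eligible.
#' @param breast_reason_fraction fraction of follow-up visits billed with a
#'   breast-cancer reason code.
#' @param baseline_visit_rate expected number of PCP visits in the 24-month
#'   pre-diagnosis baseline window (Poisson).
#' @param p_prior_history,p_non_solid,p_hysterectomy,p_metastasis_1yr,p_coverage_gap
#'   probabilities of record features that trigger cohort exclusions (and,
#'   for hysterectomy, preventive ineligibility). Patients with neither
#'   lumpectomy nor mastectomy have no curative surgery; that exclusion
#'   needs no separate knob.
#' @param n_pcp_pool,n_onc_pool provider pool sizes per patient neighbourhood.
#' @return a validated `survcare_config` list.
#' @export
sim_config <- function(n_patients = 1000,
                       seed = NULL,
                       diagnosis_start = as.Date("2007-01-01"),
                       diagnosis_end = as.Date("2012-12-31"),
                       study_end = as.Date("2013-12-31"),
                       age_median = 60,
                       age_spread = 19,
                       stage_probabilities = c(I = 0.423, II = 0.363,
                                               III = 0.112, IV = 0.004,
                                               Unknown = 0.098),
                       p_lumpectomy = 0.729,
                       p_mastectomy = 0.350,
                       p_bilateral_given_mastectomy = 0.10,
                       p_chemo = 0.459,
                       p_radio = 0.646,
                       annual_death_hazard = 0.02,
                       annual_recurrence_hazard = 0.015,
                       visit_adherence_mix = c(under = 0.10, adherent = 0.30,
                                               over = 0.60),
                       oncologist_visit_propensity = 0.5,
                       provider_loyalty = 3,
                       surveillance_adherence_mix = c(under = 0.15,
                                                      adherent = 0.75,
                                                      over = 0.10),
                       metastatic_imaging_rate = 0.30,
                       chronic_prevalence = c(CSA = 0.026, CHF = 0.011,
                                              COPD = 0.020, TIA = 0.006,
                                              DM = 0.098),
                       chronic_visit_compliance = c(CSA = 0.95, CHF = 0.93,
                                                    COPD = 0.93, TIA = 0.99,
                                                    DM = 0.96),
                       preventive_uptake = c(cervical = 0.670,
                                             bone_density = 0.387,
                                             colorectal = 0.459),
                       breast_reason_fraction = 0.30,
                       baseline_visit_rate = 8,
                       p_prior_history = 0.02,
                       p_non_solid = 0.01,
                       p_hysterectomy = 0.20,
                       p_metastasis_1yr = 0.01,
                       p_coverage_gap = 0.01,
                       n_pcp_pool = 5,
                       n_onc_pool = 3) {
  cfg <- list(
    n_patients = n_patients, seed = seed,
    diagnosis_start = diagnosis_start, diagnosis_end = diagnosis_end,
    study_end = study_end,
    age_median = age_median, age_spread = age_spread,
    stage_probabilities = stage_probabilities,
    p_lumpectomy = p_lumpectomy, p_mastectomy = p_mastectomy,
    p_bilateral_given_mastectomy = p_bilateral_given_mastectomy,
    p_chemo = p_chemo, p_radio = p_radio,
    annual_death_hazard = annual_death_hazard,
    annual_recurrence_hazard = annual_recurrence_hazard,
    visit_adherence_mix = visit_adherence_mix,
    oncologist_visit_propensity = oncologist_visit_propensity,
    provider_loyalty = provider_loyalty,
    surveillance_adherence_mix = surveillance_adherence_mix,
    metastatic_imaging_rate = metastatic_imaging_rate,
    chronic_prevalence = chronic_prevalence,
    chronic_visit_compliance = chronic_visit_compliance,
    preventive_uptake = preventive_uptake,
    breast_reason_fraction = breast_reason_fraction,
    baseline_visit_rate = baseline_visit_rate,
    p_prior_history = p_prior_history,
    p_non_solid = p_non_solid,
    p_hysterectomy = p_hysterectomy,
    p_metastasis_1yr = p_metastasis_1yr,
    p_coverage_gap = p_coverage_gap,
    n_pcp_pool = n_pcp_pool, n_onc_pool = n_onc_pool
  )
  class(cfg) <- "survcare_config"
  validate_config(cfg)
  cfg
}

CHRONIC_CONDITIONS <- c("CSA", "CHF", "COPD", "TIA", "DM")
PREVENTIVE_KINDS <- c("cervical", "bone_density", "colorectal")

#' Validate a simulation configuration
#'
#' Rejects invalid configurations with an error naming the offending field.
#' A seed is mandatory: reproducibility is part of the generator contract.
#'
#' @param cfg a `survcare_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid config field '%s': %s", field, why), call. = FALSE)
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      fail(field, "must be a single probability in [0,1]")
  }
  chk_simplex <- function(field, len, names_expected = NULL) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != len || anyNA(v) || any(v < 0))
      fail(field, sprintf("must be %d non-negative numbers", len))
    if (abs(sum(v) - 1) > 1e-9)
      fail(field, sprintf("must sum to 1 (got %.12f)", sum(v)))
    if (!is.null(names_expected) && !is.null(names(v)) &&
        !identical(names(v), names_expected))
      fail(field, paste("names must be", paste(names_expected, collapse = ", ")))
  }
  chk_prob_vec <- function(field, names_expected) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != length(names_expected) || anyNA(v) ||
        any(v < 0 | v > 1))
      fail(field, "must be probabilities in [0,1]")
    if (is.null(names(v)) || !setequal(names(v), names_expected))
      fail(field, paste("must be named", paste(names_expected, collapse = ", ")))
  }

  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != floor(cfg$n_patients))
    fail("n_patients", "must be a non-negative integer")
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      is.na(cfg$seed))
    fail("seed", "a single integer seed is mandatory")
  for (f in c("diagnosis_start", "diagnosis_end", "study_end"))
    if (!inherits(cfg[[f]], "Date") || length(cfg[[f]]) != 1)
      fail(f, "must be a single Date")
  if (cfg$diagnosis_start > cfg$diagnosis_end)
    fail("diagnosis_end", "diagnosis window is empty")
  if (cfg$diagnosis_end >= cfg$study_end)
    fail("study_end", "diagnosis window must end before study_end")
  if (!is.numeric(cfg$age_median) || cfg$age_median <= 18)
    fail("age_median", "must exceed 18")
  if (!is.numeric(cfg$age_spread) || cfg$age_spread <= 0)
    fail("age_spread", "must be positive")
  chk_simplex("stage_probabilities", 5,
              c("I", "II", "III", "IV", "Unknown"))
  chk_simplex("visit_adherence_mix", 3, c("under", "adherent", "over"))
  chk_simplex("surveillance_adherence_mix", 3, c("under", "adherent", "over"))
  for (f in c("p_lumpectomy", "p_mastectomy", "p_bilateral_given_mastectomy",
              "p_chemo", "p_radio", "annual_death_hazard",
              "annual_recurrence_hazard", "oncologist_visit_propensity",
              "metastatic_imaging_rate", "breast_reason_fraction",
              "p_prior_history", "p_non_solid",
              "p_hysterectomy", "p_metastasis_1yr", "p_coverage_gap"))
    chk_prob(f)
  chk_prob_vec("chronic_prevalence", CHRONIC_CONDITIONS)
  chk_prob_vec("chronic_visit_compliance", CHRONIC_CONDITIONS)
  chk_prob_vec("preventive_uptake", PREVENTIVE_KINDS)
  if (!is.numeric(cfg$provider_loyalty) || cfg$provider_loyalty < 0)
    fail("provider_loyalty", "must be >= 0")
  if (!is.numeric(cfg$baseline_visit_rate) || cfg$baseline_visit_rate < 0)
    fail("baseline_visit_rate", "must be >= 0")
  for (f in c("n_pcp_pool", "n_onc_pool"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1)
      fail(f, "must be >= 1")
  invisible(cfg)
}

#' @export
print.survcare_config <- function(x, ...) {
  cat("<survcare_config>\n")
  cat(sprintf("  patients: %d   seed: %s\n", x$n_patients,
              format(x$seed)))
  cat(sprintf("  diagnosis window: %s .. %s   study end: %s\n",
              x$diagnosis_start, x$diagnosis_end, x$study_end))
  cat(sprintf("  visit mix (u/a/o): %s   surveillance mix: %s\n",
              paste(x$visit_adherence_mix, collapse = "/"),
              paste(x$surveillance_adherence_mix, collapse = "/")))
  cat(sprintf("  loyalty: %g   oncologist propensity: %g\n",
              x$provider_loyalty, x$oncologist_visit_propensity))
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' Each non-blank, non-comment line is `key = value`; vector-valued fields
#' (probability mixes) are comma-separated and may carry `name:value` pairs.
#' Unknown keys are rejected.
#'
#' @param path path to the config file.
#' @param seed optional seed overriding any `seed` line in the file.
#' @return a validated `survcare_config`.
#' @export
read_config <- function(path, seed = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  defaults <- formals(sim_config)
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(defaults))
      stop("unknown config key: ", key, call. = FALSE)
    args[[key]] <- parse_config_value(key, val)
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(sim_config, args)
}

parse_config_value <- function(key, val) {
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", val)) return(as.Date(val))
  parts <- strsplit(val, ",", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (all(grepl(":", parts, fixed = TRUE))) {
    nm <- vapply(strsplit(parts, ":", fixed = TRUE), `[`, "", 1)
    vv <- as.numeric(vapply(strsplit(parts, ":", fixed = TRUE), `[`, "", 2))
    return(stats::setNames(vv, trimws(nm)))
  }
  out <- suppressWarnings(as.numeric(parts))
  if (anyNA(out)) stop("unparseable value for config key ", key, call. = FALSE)
  out
}
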