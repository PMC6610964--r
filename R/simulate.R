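#' Simulate linked registry and claims tables with a known truth table
#'
#' Generates the four event tables the pipeline consumes (registry,
#' physician visit claims, imaging events, screening events) plus a truth
#' table recording, per patient, the adherence behaviour each patient was
#' simulated to follow — so downstream classifiers can be tested by
#' parameter recovery without any access to real administrative data.
#'
#' The generator is deterministic given the config (which carries a
#' mandatory seed): two runs with the same config produce byte-identical
#' tables.
#'
#' Key behavioural mechanics:
#' \itemize{
#'   \item Each patient draws one visit-adherence category from
#'     `visit_adherence_mix`; in every full follow-up year the number of
#'     distinct PCP/oncologist visit-days is then drawn uniformly from
#'     that category's count range for the year (so the truth label is
#'     recoverable with probability 1).
#'   \item Each follow-up visit is to a medical oncologist with probability
#'     `oncologist_visit_propensity`, else a PCP; the provider is the
#'     patient's usual provider with probability
#'     `loyalty/(1+loyalty)`, else uniform over the patient's pool, which
#'     spans the whole UPC category space.
#'   \item Surveillance breast imaging follows the drawn category:
#'     `under` = no tests; `adherent` = one mammogram per full year at a
#'     fixed per-patient day offset (successive tests are 365/366 days
#'     apart, so every test passes the 330-day rule); `over` = two tests
#'     more than 330 days apart in Year 2, then one roughly every 331 days.
#'     Sustaining two 330-day-spaced tests per year beyond the first
#'     assessed year is arithmetically impossible, so the `over` label is
#'     guaranteed in Year 2 only (where recovery tests measure it).
#'     A pre-diagnosis diagnostic mammogram (and, for some patients, a
#'     workup ultrasound a week later) is emitted as imaging history.
#'     `program_surveillance` flags are set by applying the same 330-day
#'     rule at generation time, so interval and program modes agree.
#'   \item Chronic-condition visits are billed with the condition as
#'     reason and specialty `other_specialist`, one per 6-month block
#'     (12 for TIA); non-compliant patients skip one randomly chosen
#'     block. Using a non-PCP specialty keeps these visits out of the
#'     visit-adherence counts, preserving the visit truth labels.
#' }
#'
#' @param config a validated [sim_config()].
#' @return a named list of five tibbles: `registry`, `visits`, `imaging`,
#'   `screening`, `truth`.
#' @export
generate_dataset <- function(config) {
  validate_config(config)
  set.seed(as.integer(config$seed))
  n <- config$n_patients
  reg_rows <- truth_rows <- vector("list", n)
  visit_rows <- imaging_rows <- screening_rows <- vector("list", n)
  idw <- max(5L, nchar(as.character(max(n, 1L))))

  for (i in seq_len(n)) {
    p <- simulate_patient(sprintf("P%0*d", idw, i), config)
    reg_rows[[i]] <- p$registry
    truth_rows[[i]] <- p$truth
    visit_rows[[i]] <- p$visits
    imaging_rows[[i]] <- p$imaging
    screening_rows[[i]] <- p$screening
  }
  list(registry = bind_or_empty(reg_rows, empty_registry()),
       visits = bind_or_empty(visit_rows, empty_visits()),
       imaging = bind_or_empty(imaging_rows, empty_imaging()),
       screening = bind_or_empty(screening_rows, empty_screening()),
       truth = bind_or_empty(truth_rows, empty_truth()))
}

bind_or_empty <- function(rows, empty) {
  rows <- rows[!vapply(rows, is.null, TRUE)]
  rows <- rows[vapply(rows, nrow, 0L) > 0]
  if (length(rows) == 0) empty else dplyr::bind_rows(rows)
}

simulate_patient <- function(pid, cfg) {
  dx <- cfg$diagnosis_start +
    sample.int(as.integer(cfg$diagnosis_end - cfg$diagnosis_start) + 1L, 1L) - 1L
  age <- min(95, max(18, stats::rnorm(1, cfg$age_median,
                                      cfg$age_spread / 1.349)))
  birth <- add_years(dx, -floor(age)) - sample.int(365L, 1L) + 1L
  stage <- sample(names(cfg$stage_probabilities), 1L,
                  prob = cfg$stage_probabilities)
  lump <- stats::runif(1) < cfg$p_lumpectomy
  mast <- stats::runif(1) < cfg$p_mastectomy
  bilat <- mast && stats::runif(1) < cfg$p_bilateral_given_mastectomy
  chemo <- if (stats::runif(1) < cfg$p_chemo) "yes" else "no"
  radio <- stats::runif(1) < cfg$p_radio

  death <- hazard_date(dx, cfg$annual_death_hazard)
  recur <- hazard_date(dx, cfg$annual_recurrence_hazard)
  mets1 <- stats::runif(1) < cfg$p_metastasis_1yr
  prior <- stats::runif(1) < cfg$p_prior_history
  nonsolid <- stats::runif(1) < cfg$p_non_solid
  hyst <- stats::runif(1) < cfg$p_hysterectomy

  cov_start <- add_months(dx, -36)
  cov_end <- cfg$study_end
  has_gap <- stats::runif(1) < cfg$p_coverage_gap
  coverage <- if (has_gap) {
    format_coverage(c(cov_start, add_months(dx, 17)),
                    c(add_months(dx, 15), cov_end))
  } else {
    format_coverage(cov_start, cov_end)
  }

  # chronic conditions: onset uniform in the 5 pre-diagnosis years
  onsets <- stats::setNames(rep(as.Date(NA), 5), CHRONIC_CONDITIONS)
  chron_present <- stats::runif(5) < cfg$chronic_prevalence
  onsets[chron_present] <- dx - sample.int(5L * 365L, sum(chron_present))
  chron_compliant <- stats::runif(5) < cfg$chronic_visit_compliance

  registry <- tibble::tibble(
    patient_id = pid, birth_date = birth, diagnosis_date = dx,
    stage = stage, lumpectomy = lump, mastectomy = mast,
    bilateral_mastectomy = bilat, chemotherapy = chemo,
    radiotherapy = radio, curative_surgery = lump || mast,
    death_date = death, recurrence_date = recur,
    metastasis_within_1yr = mets1, prior_cancer_history = prior,
    non_solid_histology = nonsolid,
    hysterectomy_or_gyn_cancer_history = hyst,
    coverage_intervals = coverage,
    chronic_onset_CSA = onsets[["CSA"]], chronic_onset_CHF = onsets[["CHF"]],
    chronic_onset_COPD = onsets[["COPD"]], chronic_onset_TIA = onsets[["TIA"]],
    chronic_onset_DM = onsets[["DM"]])

  elig <- apply_eligibility(registry, cfg$study_end)
  included <- elig$decision == "included"

  # provider pools are per-patient (opaque ids); first is the usual provider
  pcp_pool <- paste0(pid, "_PCP", seq_len(cfg$n_pcp_pool))
  onc_pool <- paste0(pid, "_ONC", seq_len(cfg$n_onc_pool))

  # baseline PCP visits in [dx-30m, dx-6m), distinct days
  b_start <- add_months(dx, -30)
  b_end <- add_months(dx, -6)
  nb <- stats::rpois(1, cfg$baseline_visit_rate)
  nb <- min(nb, as.integer(b_end - b_start))
  visits <- list()
  if (nb > 0) {
    bdays <- b_start + sample.int(as.integer(b_end - b_start), nb) - 1L
    visits[[length(visits) + 1L]] <- tibble::tibble(
      patient_id = pid, date = sort(bdays),
      provider_id = pick_providers(nb, pcp_pool, cfg$provider_loyalty),
      specialty = "PCP", reason = "other")
  }

  imaging <- list()
  screening <- list()
  truth <- tibble::tibble(
    patient_id = pid, included = included,
    reasons = paste(elig$reasons, collapse = ";"),
    visit_category = NA_character_, surveillance_category = NA_character_,
    chronic_CSA = NA_character_, chronic_CHF = NA_character_,
    chronic_COPD = NA_character_, chronic_TIA = NA_character_,
    chronic_DM = NA_character_,
    prev_cervical = NA_character_, prev_bone_density = NA_character_,
    prev_colorectal = NA_character_,
    met_y2 = NA_character_, met_y3 = NA_character_,
    met_y4 = NA_character_, met_y5 = NA_character_)

  if (included) {
    plan <- build_followup(registry, cfg$study_end)
    fu <- simulate_followup(pid, cfg, registry, plan, pcp_pool, onc_pool)
    visits <- c(visits, fu$visits)
    imaging <- fu$imaging
    screening <- fu$screening
    truth[names(fu$truth)] <- fu$truth
  } else {
    # imaging history still exists for excluded patients (diagnostic workup)
    imaging[[1L]] <- tibble::tibble(
      patient_id = pid, date = dx - 14L, modality = "mammogram",
      program_surveillance = NA)
  }

  im <- bind_or_empty(imaging, empty_imaging())
  if (nrow(im) > 0) {
    im <- im[order(im$date, im$modality), ]
    # program flags replicate the 330-day interval rule on breast modalities
    is_breast <- im$modality %in% BREAST_MODALITIES
    flags <- rep(NA, nrow(im))
    bi <- im[is_breast, ]
    flags[is_breast] <- flag_surveillance(bi, "interval_rule")
    im$program_surveillance <- flags
  }

  list(registry = registry, truth = truth,
       visits = bind_or_empty(visits, empty_visits()),
       imaging = im,
       screening = bind_or_empty(screening, empty_screening()))
}

simulate_followup <- function(pid, cfg, registry, plan, pcp_pool, onc_pool) {
  reg <- as.list(registry)
  dx <- reg$diagnosis_date
  schedule <- recommended_visit_schedule()
  yw <- plan$year_windows
  visits <- list()
  imaging <- list()
  screening <- list()

  ## --- physician visits -------------------------------------------------
  vcat <- sample(c("under", "adherent", "over"), 1L,
                 prob = cfg$visit_adherence_mix)
  for (k in 2:5) {
    w <- yw[yw$year == k, ]
    sch <- schedule[schedule$year == k, ]
    if (w$full_followup) {
      cnt <- switch(vcat,
        under = sample.int(sch$min_adherent, 1L) - 1L,
        adherent = sch$min_adherent +
          sample.int(sch$max_adherent - sch$min_adherent + 1L, 1L) - 1L,
        over = sch$max_adherent + sample.int(3L, 1L))
      win_end <- w$end
    } else {
      # partial trailing year: a little realistic utilization, unassessed
      win_end <- plan$end_date
      if (as.integer(win_end - w$start) < 60) next
      cnt <- stats::rpois(1, 1)
      if (cnt == 0) next
    }
    ndays <- as.integer(win_end - w$start)
    cnt <- min(cnt, ndays)
    if (cnt == 0) next
    days <- sort(w$start + sample.int(ndays, cnt) - 1L)
    is_onc <- stats::runif(cnt) < cfg$oncologist_visit_propensity
    prov <- character(cnt)
    prov[is_onc] <- pick_providers(sum(is_onc), onc_pool,
                                   cfg$provider_loyalty)
    prov[!is_onc] <- pick_providers(sum(!is_onc), pcp_pool,
                                    cfg$provider_loyalty)
    reason <- ifelse(stats::runif(cnt) < cfg$breast_reason_fraction,
                     "breast_cancer", "other")
    visits[[length(visits) + 1L]] <- tibble::tibble(
      patient_id = pid, date = days, provider_id = prov,
      specialty = ifelse(is_onc, "medical_oncologist", "PCP"),
      reason = reason)
  }

  ## --- chronic-condition visits (specialty other_specialist) ------------
  truth_chronic <- stats::setNames(rep(NA_character_, 5),
                                   paste0("chronic_", CHRONIC_CONDITIONS))
  for (ci in seq_along(CHRONIC_CONDITIONS)) {
    cond <- CHRONIC_CONDITIONS[ci]
    onset <- reg[[paste0("chronic_onset_", cond)]]
    if (is.na(onset) || onset > plan$survivorship_start) {
      truth_chronic[[paste0("chronic_", cond)]] <- "ineligible"
      next
    }
    bm <- if (cond == "TIA") 12L else 6L
    blocks <- chronic_blocks(plan$survivorship_start, plan$end_date, bm)
    if (nrow(blocks) == 0) {
      truth_chronic[[paste0("chronic_", cond)]] <- "ineligible"
      next
    }
    compliant <- stats::runif(1) < cfg$chronic_visit_compliance[[cond]]
    skip <- if (compliant) 0L else sample.int(nrow(blocks), 1L)
    truth_chronic[[paste0("chronic_", cond)]] <- if (compliant) "adherent" else "not_adherent"
    for (b in seq_len(nrow(blocks))) {
      if (b == skip) next
      d <- blocks$start[b] +
        sample.int(as.integer(blocks$end[b] - blocks$start[b]), 1L) - 1L
      visits[[length(visits) + 1L]] <- tibble::tibble(
        patient_id = pid, date = d, provider_id = paste0(pid, "_SPEC1"),
        specialty = "other_specialist", reason = cond)
    }
  }

  ## --- breast imaging ----------------------------------------------------
  scat <- sample(c("under", "adherent", "over"), 1L,
                 prob = cfg$surveillance_adherence_mix)
  imaging[[length(imaging) + 1L]] <- tibble::tibble(
    patient_id = pid, date = dx - 14L, modality = "mammogram",
    program_surveillance = NA)
  if (stats::runif(1) < 0.3) {
    imaging[[length(imaging) + 1L]] <- tibble::tibble(
      patient_id = pid, date = dx - 7L, modality = "breast_ultrasound",
      program_surveillance = NA)
  }
  if (scat == "adherent") {
    off <- sample(40:300, 1L)
    for (k in 2:5) {
      w <- yw[yw$year == k, ]
      if (!w$full_followup) next
      imaging[[length(imaging) + 1L]] <- tibble::tibble(
        patient_id = pid, date = w$start + off, modality = "mammogram",
        program_surveillance = NA)
    }
  } else if (scat == "over") {
    w2 <- yw[yw$year == 2, ]
    t1 <- w2$start + sample(5:14, 1L)
    t2 <- t1 + 331L + sample.int(10L, 1L) - 1L
    last <- t2
    dates <- c(t1, t2)
    repeat {
      nxt <- last + 331L + sample.int(20L, 1L) - 1L
      if (nxt >= plan$end_date) break
      dates <- c(dates, nxt)
      last <- nxt
    }
    # dates landing outside full-followup years are simply unassessed
    imaging[[length(imaging) + 1L]] <- tibble::tibble(
      patient_id = pid, date = dates, modality = "mammogram",
      program_surveillance = NA)
  }

  ## --- metastatic-disease imaging ----------------------------------------
  truth_met <- stats::setNames(rep(NA_character_, 4), paste0("met_y", 2:5))
  for (k in 2:5) {
    w <- yw[yw$year == k, ]
    if (!w$full_followup) next
    hit <- stats::runif(1) < cfg$metastatic_imaging_rate
    truth_met[[paste0("met_y", k)]] <-
      if (hit) "not_adherent" else "adherent"
    if (hit) {
      imaging[[length(imaging) + 1L]] <- tibble::tibble(
        patient_id = pid,
        date = w$start + sample.int(as.integer(w$end - w$start), 1L) - 1L,
        modality = sample(METASTATIC_MODALITIES, 1L),
        program_surveillance = NA)
    }
  }

  ## --- preventive screening ----------------------------------------------
  age <- age_at(reg$birth_date, plan$survivorship_start)
  eligible <- c(
    cervical = age >= 20 && age <= 69 &&
      !isTRUE(reg$hysterectomy_or_gyn_cancer_history),
    bone_density = age >= 65,
    colorectal = age >= 50 && age <= 64)
  kinds <- c(cervical = "cervical_screen", bone_density = "bone_densitometry",
             colorectal = "colorectal_screen")
  truth_prev <- stats::setNames(rep(NA_character_, 3),
                                paste0("prev_", names(kinds)))
  fdays <- as.integer(plan$end_date - plan$survivorship_start)
  for (k in names(kinds)) {
    nm <- paste0("prev_", k)
    if (!eligible[[k]]) { truth_prev[[nm]] <- "ineligible"; next }
    uptake <- stats::runif(1) < cfg$preventive_uptake[[k]]
    truth_prev[[nm]] <- if (uptake) "adherent" else "not_adherent"
    if (uptake && fdays > 0) {
      screening[[length(screening) + 1L]] <- tibble::tibble(
        patient_id = pid,
        date = plan$survivorship_start + sample.int(fdays, 1L) - 1L,
        kind = kinds[[k]])
    }
  }

  list(visits = visits, imaging = imaging, screening = screening,
       truth = c(list(visit_category = vcat, surveillance_category = scat),
                 as.list(truth_chronic), as.list(truth_prev),
                 as.list(truth_met)))
}

# geometric per-year hazard -> date uniform within the fatal year; NA if the
# event never fires within 60 years (effectively never, given study spans)
hazard_date <- function(dx, hazard) {
  if (hazard <= 0) return(as.Date(NA))
  g <- stats::rgeom(1, hazard)
  if (g >= 60) return(as.Date(NA))
  ys <- add_years(dx, g)
  ye <- add_years(dx, g + 1L)
  ys + sample.int(as.integer(ye - ys), 1L) - 1L
}

# usual provider w.p. loyalty/(1+loyalty), else uniform over the pool
pick_providers <- function(n, pool, loyalty) {
  if (n == 0) return(character())
  theta <- if (is.infinite(loyalty)) 1 else loyalty / (1 + loyalty)
  loyal <- stats::runif(n) < theta
  out <- pool[sample.int(length(pool), n, replace = TRUE)]
  out[loyal] <- pool[1]
  out
}

empty_registry <- function() {
  tibble::tibble(patient_id = character(), birth_date = as.Date(character()),
                 diagnosis_date = as.Date(character()), stage = character(),
                 lumpectomy = logical(), mastectomy = logical(),
                 bilateral_mastectomy = logical(), chemotherapy = character(),
                 radiotherapy = logical(), curative_surgery = logical(),
                 death_date = as.Date(character()),
                 recurrence_date = as.Date(character()),
                 metastasis_within_1yr = logical(),
                 prior_cancer_history = logical(),
                 non_solid_histology = logical(),
                 hysterectomy_or_gyn_cancer_history = logical(),
                 coverage_intervals = character(),
                 chronic_onset_CSA = as.Date(character()),
                 chronic_onset_CHF = as.Date(character()),
                 chronic_onset_COPD = as.Date(character()),
                 chronic_onset_TIA = as.Date(character()),
                 chronic_onset_DM = as.Date(character()))
}

empty_visits <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 provider_id = character(), specialty = character(),
                 reason = character())
}

empty_imaging <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 modality = character(), program_surveillance = logical())
}

empty_screening <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 kind = character())
}

empty_truth <- function() {
  tibble::tibble(patient_id = character(), included = logical(),
                 reasons = character(), visit_category = character(),
                 surveillance_category = character(),
                 chronic_CSA = character(), chronic_CHF = character(),
                 chronic_COPD = character(), chronic_TIA = character(),
                 chronic_DM = character(), prev_cervical = character(),
                 prev_bone_density = character(),
                 prev_colorectal = character(), met_y2 = character(),
                 met_y3 = character(), met_y4 = character(),
                 met_y5 = character())
}
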