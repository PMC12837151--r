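#' Construct a cohort configuration
#'
#' Bundles every knob of the synthetic cohort generator. All per-stratum
#' parameters are 3 x 2 matrices with rows `mixed`, `small_lt4500`,
#' `small_ge4500` and columns `cat`, `dog`.
#'
#' @param n_practices_per_type Named integer vector (names = strata): number
#'   of practices generated per intended stratum.
#' @param years Integer vector of calendar years covered.
#' @param median_consultations Matrix of target median annual consultations
#'   per practice, by stratum and species.
#' @param treatment_prob Matrix of per-consultation probabilities that the
#'   animal receives an antibiotic treatment.
#' @param critical_frac Matrix of probabilities that a treatment uses a
#'   critical antibiotic.
#' @param practice_effect_sdlog Log-scale standard deviation of a
#'   per-practice use multiplier applied to `treatment_prob` (shared by both
#'   species of a practice, median 1). This is the between-practice
#'   heterogeneity in prescribing behaviour that benchmarking exists to
#'   expose; 0 turns it off.
#' @param therapy_days_mean Mean administered treatment duration in days;
#'   durations are drawn as 1 + Poisson(mean - 1).
#' @param consult_sdlog Log-scale standard deviation of practice size
#'   (between-practice spread of the log-normal consultation counts).
#' @param consult_year_sdlog Log-scale standard deviation of the
#'   year-to-year jitter around a practice's size; practice volume is
#'   stable, so this is small.
#' @param missing_nbconsult_prob Probability that a (practice, year)
#'   consultation declaration is withheld (both species).
#' @param zero_use_frac Probability that a practice prescribes no antibiotics
#'   at all for one species (a non-user).
#' @param sub100_frac Probability that a practice is a marginal reporter with
#'   fewer than 100 annual consultations (excluded from benchmarking).
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return A list of class `abu_cohort_config`.
#' @seealso [default_swiss_like_config()] for the calibrated defaults,
#'   [generate_cohort()] for the generator itself.
#' @export
cohort_config <- function(n_practices_per_type,
                          years,
                          median_consultations,
                          treatment_prob,
                          critical_frac,
                          therapy_days_mean = 5,
                          practice_effect_sdlog = 0.4,
                          consult_sdlog = 0.8,
                          consult_year_sdlog = 0.1,
                          missing_nbconsult_prob = 0.10,
                          zero_use_frac = 0.03,
                          sub100_frac = 0.05,
                          seed = 1L) {
  stopifnot(length(years) >= 1)
  if (!all(abu_strata %in% names(n_practices_per_type))) {
    abort("n_practices_per_type must be named by the three strata")
  }
  n_practices_per_type <- n_practices_per_type[abu_strata]
  if (any(n_practices_per_type < 0)) abort("practice counts must be >= 0")
  if (sum(n_practices_per_type) == 0) abort("at least one practice required")
  check_mat <- function(m, what, upper = Inf) {
    if (!all(abu_strata %in% rownames(m)) || !all(abu_species %in% colnames(m))) {
      abort(paste0(what, " must have strata rows and species columns"))
    }
    if (any(m < 0) || any(m > upper)) {
      abort(paste0(what, " out of range"))
    }
    m[abu_strata, abu_species]
  }
  probs_ok <- function(p) {
    if (p < 0 || p > 1) abort("probabilities must lie in [0, 1]")
    p
  }
  structure(list(
    n_practices_per_type = n_practices_per_type,
    years = as.integer(sort(years)),
    median_consultations = check_mat(median_consultations, "median_consultations"),
    treatment_prob = check_mat(treatment_prob, "treatment_prob", upper = 1),
    critical_frac = check_mat(critical_frac, "critical_frac", upper = 1),
    therapy_days_mean = therapy_days_mean,
    practice_effect_sdlog = practice_effect_sdlog,
    consult_sdlog = consult_sdlog,
    consult_year_sdlog = consult_year_sdlog,
    missing_nbconsult_prob = probs_ok(missing_nbconsult_prob),
    zero_use_frac = probs_ok(zero_use_frac),
    sub100_frac = probs_ok(sub100_frac),
    seed = as.integer(seed)
  ), class = "abu_cohort_config")
}

#' Swiss-like default cohort configuration
#'
#' Returns the generator configuration calibrated to the published national
#' cohort: 202 mixed practices, 414 smaller and 70 larger companion-animal
#' practices or clinics over 2022-2024; stratum- and species-specific median
#' consultation counts (e.g. 1481 for dogs in mixed practices, 5812 in large
#' companion clinics), treatment percentages (e.g. 12.0% of dog consultations
#' in mixed practices lead to an antibiotic treatment, 21.1% for cats) and
#' critical-antibiotic shares (5.2-6.8% of dog treatments, 20.0-27.5% of cat
#' treatments).
#'
#' @param seed Integer seed stored in the config.
#' @return An `abu_cohort_config` object.
#' @export
#' @examples
#' cfg <- default_swiss_like_config()
#' cfg$median_consultations
default_swiss_like_config <- function(seed = 1L) {
  mk <- function(mixed_cat, mixed_dog, lt_cat, lt_dog, ge_cat, ge_dog) {
    matrix(c(mixed_cat, lt_cat, ge_cat, mixed_dog, lt_dog, ge_dog),
           nrow = 3, dimnames = list(abu_strata, abu_species))
  }
  cohort_config(
    n_practices_per_type = c(mixed = 202L, small_lt4500 = 414L,
                             small_ge4500 = 70L),
    years = 2022:2024,
    median_consultations = mk(1602, 1481, 1671, 1612, 5545, 5812),
    treatment_prob = mk(0.211, 0.120, 0.150, 0.098, 0.136, 0.098),
    critical_frac = mk(0.200, 0.052, 0.275, 0.068, 0.223, 0.068),
    therapy_days_mean = 5,
    practice_effect_sdlog = 0.4,
    consult_sdlog = 0.8,
    consult_year_sdlog = 0.1,
    missing_nbconsult_prob = 0.10,
    zero_use_frac = 0.03,
    sub100_frac = 0.05,
    seed = seed
  )
}

# Synthetic product formulary: which VMPs the generator prescribes, their
# substances (semicolon-joined) and a standard dose. Substance codes must
# exist in the bundled catalog; cefovecin is the long-acting injectable.
#' @noRd
synthetic_formulary <- function() {
  tibble(
    vmp_id = c("AMOX-250", "AMC-SYN-375", "TMS-240", "DOXY-100", "CLIND-150",
               "CEFA-500", "ENRO-50", "MARBO-20", "AZITH-250", "CONV-80"),
    substances = c("amoxicillin", "amoxicillin;ampicillin",
                   "trimethoprim;sulfadiazine", "doxycycline", "clindamycin",
                   "cefalexin", "enrofloxacin", "marbofloxacin",
                   "azithromycin", "cefovecin"),
    critical = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, TRUE, TRUE, TRUE),
    dose = c(12.5, 15, 30, 10, 11, 22.5, 5, 2, 10, 8)
  )
}

#' @noRd
synthetic_indications <- c("skin", "urinary", "respiratory",
                           "gastrointestinal", "dental", "other")

#' Generate a synthetic IS-ABV-like cohort
#'
#' Simulates the three input tables of the pipeline. For every practice,
#' species and year, annual consultations are drawn from a log-normal with
#' the configured stratum median; the number of treated animals is
#' Binomial(NbConsult, treatment_prob); each treatment becomes one
#' prescription of a single animal, with an administered duration of
#' 1 + Poisson(therapy_days_mean - 1) days and a critical-antibiotic product
#' with probability critical_frac. A configured share of practices are
#' non-users for a species, a share report fewer than 100 consultations, and
#' a share of (practice, year) consultation declarations are withheld —
#' treatments still occur at those practices, only the declaration is
#' missing, which downstream triggers the max-of-registered-years imputation.
#'
#' @param config An `abu_cohort_config`, e.g. [default_swiss_like_config()].
#' @return A list of class `abu_cohort` with tibbles `practices`
#'   (including the generator's intended stratum as `sim_stratum`, simulation
#'   ground truth not available for real data), `consultations` and
#'   `prescriptions`.
#' @export
#' @examples
#' cfg <- default_swiss_like_config()
#' cfg$n_practices_per_type <- c(mixed = 5L, small_lt4500 = 5L,
#'                               small_ge4500 = 2L)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$practices)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "abu_cohort_config"))
  set.seed(config$seed)
  n_per <- config$n_practices_per_type
  n_tot <- sum(n_per)
  years <- config$years

  sim_stratum <- rep(names(n_per), n_per)
  practices <- tibble(
    practice_id = sprintf("P%04d", seq_len(n_tot)),
    sim_stratum = sim_stratum,
    declared_type = dplyr::case_match(sim_stratum,
                                      "mixed" ~ "mixed_practice",
                                      "small_lt4500" ~ "companion_practice",
                                      "small_ge4500" ~ "companion_clinic"),
    canton = sample_cantons(n_tot)
  )

  # a practice's size is drawn once per species; years jitter around it
  sizes <- tidyr::crossing(practices[, c("practice_id", "sim_stratum")],
                           species = abu_species)
  med <- config$median_consultations[cbind(sizes$sim_stratum, sizes$species)]
  sizes$base_consult <- rlnorm(nrow(sizes), meanlog = log(med),
                               sdlog = config$consult_sdlog)
  cells <- tidyr::crossing(sizes, year = years)
  cells$n_consultations <- pmax(1L, as.integer(round(
    cells$base_consult * rlnorm(nrow(cells), 0, config$consult_year_sdlog))))
  cells$base_consult <- NULL

  # marginal reporters: all their declarations fall below 100
  sub100 <- practices$practice_id[
    runif(n_tot) < config$sub100_frac]
  is_sub <- cells$practice_id %in% sub100
  cells$n_consultations[is_sub] <-
    sample(10:99, sum(is_sub), replace = TRUE)

  # per-species non-users
  zero_keys <- tidyr::crossing(practice_id = practices$practice_id,
                               species = abu_species)
  zero_keys <- zero_keys[runif(nrow(zero_keys)) < config$zero_use_frac, ]
  cells$zero_use <- paste(cells$practice_id, cells$species) %in%
    paste(zero_keys$practice_id, zero_keys$species)

  # practice-level prescribing propensity, shared across species and years
  use_mult <- setNames(rlnorm(n_tot, 0, config$practice_effect_sdlog),
                       practices$practice_id)
  p_treat <- pmin(0.95, config$treatment_prob[
    cbind(cells$sim_stratum, cells$species)] * use_mult[cells$practice_id])
  cells$n_treated <- ifelse(
    cells$zero_use, 0L,
    rbinom(nrow(cells), cells$n_consultations, p_treat))

  # withheld declarations: the practice still treats, it just fails to report
  py <- tidyr::crossing(practice_id = practices$practice_id, year = years)
  withheld <- py[runif(nrow(py)) < config$missing_nbconsult_prob, ]
  keep <- !(paste(cells$practice_id, cells$year) %in%
              paste(withheld$practice_id, withheld$year))
  consultations <- cells[keep, c("practice_id", "species", "year",
                                 "n_consultations")]
  consultations <- dplyr::arrange(consultations, .data$practice_id,
                                  .data$species, .data$year)

  prescriptions <- draw_prescriptions(cells, config)

  structure(list(practices = practices,
                 consultations = consultations,
                 prescriptions = prescriptions),
            class = "abu_cohort")
}

#' @noRd
sample_cantons <- function(n) {
  big <- c(BE = 0.15, ZH = 0.15, AG = 0.09, VD = 0.09)
  rest <- c("GE", "BS", "BL", "LU", "SG", "TI", "VS", "FR", "NE", "SO",
            "TG", "GR", "SZ", "ZG", "SH", "AR", "AI", "GL", "JU", "NW",
            "OW", "UR")
  codes <- c(names(big), rest)
  w <- c(unname(big), rep((1 - sum(big)) / length(rest), length(rest)))
  sample(codes, n, replace = TRUE, prob = w)
}

#' @noRd
draw_prescriptions <- function(cells, config) {
  total <- sum(cells$n_treated)
  if (total == 0) {
    return(tibble(practice_id = character(), date = as.Date(character()),
                  year = integer(), species = character(),
                  vmp_id = character(), substances = character(),
                  therapy_days = numeric(), animals_treated = integer(),
                  indication = character(), dosage_mg_per_kg = numeric()))
  }
  idx <- rep(seq_len(nrow(cells)), cells$n_treated)
  cf <- config$critical_frac[cbind(cells$sim_stratum, cells$species)][idx]
  is_crit <- runif(total) < cf
  form <- synthetic_formulary()
  crit_rows <- which(form$critical)
  ncrit_rows <- which(!form$critical)
  pick <- integer(total)
  pick[is_crit] <- sample(crit_rows, sum(is_crit), replace = TRUE)
  pick[!is_crit] <- sample(ncrit_rows, sum(!is_crit), replace = TRUE)
  td <- 1 + rpois(total, max(config$therapy_days_mean - 1, 0))
  dose <- form$dose[pick] * ifelse(runif(total) < 0.2, 1.5, 1)
  out <- tibble(
    practice_id = cells$practice_id[idx],
    date = as.Date(sprintf("%d-01-01", cells$year[idx])) +
      sample(0:364, total, replace = TRUE),
    year = cells$year[idx],
    species = cells$species[idx],
    vmp_id = form$vmp_id[pick],
    substances = form$substances[pick],
    therapy_days = as.numeric(td),
    animals_treated = 1L,
    indication = sample(synthetic_indications, total, replace = TRUE,
                        prob = c(0.30, 0.20, 0.15, 0.15, 0.10, 0.10)),
    dosage_mg_per_kg = dose
  )
  dplyr::arrange(out, .data$practice_id, .data$species, .data$year,
                 .data$date, .data$vmp_id)
}

#' Write a synthetic cohort to a directory of CSV files
#'
#' @param cohort An `abu_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed); writes
#'   `practices.csv`, `consultations.csv`, `prescriptions.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "abu_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_practices(cohort$practices, file.path(dir, "practices.csv"))
  write_consultations(cohort$consultations,
                      file.path(dir, "consultations.csv"))
  write_prescriptions(cohort$prescriptions,
                      file.path(dir, "prescriptions.csv"))
  invisible(dir)
}
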