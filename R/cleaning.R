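#' Collapse exact duplicate prescription rows
#'
#' Registry exports can contain the same prescription entered twice. Rows
#' identical in every field collapse to a single row; rows differing in any
#' field (e.g. therapy days) are both kept.
#'
#' @param prescriptions Prescription tibble.
#' @return List with `records` (deduplicated tibble) and `n_dropped`.
#' @export
deduplicate_prescriptions <- function(prescriptions) {
  out <- dplyr::distinct(prescriptions)
  list(records = out, n_dropped = nrow(prescriptions) - nrow(out))
}

#' Remove implausible prescription rows
#'
#' Concretizes the "obvious errors" rule: therapy days must lie in
#' (0, `max_therapy_days`] (boundary inclusive) and animals treated in
#' [1, `max_animals_treated`]. Both bounds are configurable.
#'
#' @param prescriptions Prescription tibble.
#' @param max_therapy_days Upper bound on administered therapy days.
#' @param max_animals_treated Upper bound on animals treated per row.
#' @return List with `records` and `n_dropped`.
#' @export
filter_outliers <- function(prescriptions, max_therapy_days = 365,
                            max_animals_treated = 10000) {
  ok <- prescriptions$therapy_days > 0 &
    prescriptions$therapy_days <= max_therapy_days &
    prescriptions$animals_treated >= 1 &
    prescriptions$animals_treated <= max_animals_treated
  ok[is.na(ok)] <- FALSE
  list(records = prescriptions[ok, , drop = FALSE],
       n_dropped = sum(!ok))
}

#' Impute missing consultation counts and derive benchmark eligibility
#'
#' For every practice, species and year in the benchmark window, determines
#' the consultation count used downstream (`nbconsult_used`) and whether a
#' pATI can be computed:
#' \itemize{
#'   \item a practice-species with no declared count in any year is
#'     ineligible for all years (`no_nbconsult_any_year`);
#'   \item a missing year among partially declared years is imputed as the
#'     maximum over the registered years and flagged `corrected` — a
#'     deliberately conservative fill that can only lower the indicator,
#'     never inflate it;
#'   \item years with fewer than 100 consultations are ineligible
#'     (`under_100`): such practices are unlikely to reflect typical use.
#' }
#'
#' @param consultations Consultation tibble from [read_consultations()].
#' @param practices Practice registry tibble.
#' @param years Integer vector: the full benchmark window.
#' @return Eligibility tibble with one row per practice x species x year:
#'   `nbconsult_raw`, `nbconsult_used`, `corrected`, `eligible`,
#'   `exclusion_reason`.
#' @export
impute_consultations <- function(consultations, practices, years) {
  if (length(years) == 0) abort("years must be a non-empty vector")
  grid <- tidyr::crossing(practice_id = practices$practice_id,
                          species = abu_species,
                          year = as.integer(years))
  elig <- dplyr::left_join(
    grid,
    consultations[, c("practice_id", "species", "year", "n_consultations")],
    by = c("practice_id", "species", "year"))
  elig <- dplyr::rename(elig, nbconsult_raw = "n_consultations")
  elig <- elig |>
    dplyr::group_by(.data$practice_id, .data$species) |>
    dplyr::mutate(
      max_registered = if (all(is.na(.data$nbconsult_raw))) NA_integer_
                       else max(.data$nbconsult_raw, na.rm = TRUE)) |>
    dplyr::ungroup()
  elig <- elig |>
    dplyr::mutate(
      corrected = is.na(.data$nbconsult_raw) & !is.na(.data$max_registered),
      nbconsult_used = dplyr::coalesce(.data$nbconsult_raw,
                                       .data$max_registered),
      exclusion_reason = dplyr::case_when(
        is.na(.data$nbconsult_used) ~ "no_nbconsult_any_year",
        .data$nbconsult_used < abu_min_consultations ~ "under_100",
        TRUE ~ NA_character_),
      eligible = is.na(.data$exclusion_reason)) |>
    dplyr::select(!"max_registered")
  elig[, c("practice_id", "species", "year", "nbconsult_raw",
           "nbconsult_used", "corrected", "eligible", "exclusion_reason")]
}

#' Assign each practice-species to a benchmarking stratum
#'
#' Practices declared as mixed are their own stratum regardless of volume.
#' Companion-animal practices and clinics are split per species on the
#' benchmark year's consultation count: strictly more than 4500
#' consultations places the practice-species in `small_ge4500`, otherwise
#' `small_lt4500`. The split is per species because a clinic can be large
#' for cats and small for dogs.
#'
#' @param practices Practice registry tibble.
#' @param eligibility Eligibility tibble from [impute_consultations()].
#' @param benchmark_year Year whose consultation count drives the split.
#' @return Tibble with `practice_id`, `species`, `practice_type`.
#' @export
assign_stratum <- function(practices, eligibility, benchmark_year) {
  ref <- eligibility[eligibility$year == benchmark_year,
                     c("practice_id", "species", "nbconsult_used")]
  out <- tidyr::crossing(practices[, c("practice_id", "declared_type")],
                         species = abu_species)
  out <- dplyr::left_join(out, ref, by = c("practice_id", "species"))
  out$practice_type <- dplyr::case_when(
    out$declared_type == "mixed_practice" ~ "mixed",
    !is.na(out$nbconsult_used) &
      out$nbconsult_used > abu_volume_split ~ "small_ge4500",
    TRUE ~ "small_lt4500")
  out[, c("practice_id", "species", "practice_type")]
}
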