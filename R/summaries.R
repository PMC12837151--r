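#' Percentage ratio rounded like the published tables
#'
#' `100 * numerator / denominator`, rounded half away from zero to one
#' decimal — the convention behind every printed share (e.g. 9/32 prints as
#' 28.1). Base `round()` rounds half to even and would disagree on exact
#' halves.
#'
#' @param numerator,denominator Numeric vectors (recycled).
#' @return Percentages rounded to one decimal.
#' @export
#' @examples
#' ratio_pct(686, 989)  # 69.4
#' ratio_pct(9, 32)     # 28.1
ratio_pct <- function(numerator, denominator) {
  if (any(denominator == 0)) abort("denominator must be non-zero")
  x <- 100 * numerator / denominator
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Summarise antibiotic use of one practice, species and year
#'
#' The per-practice half of the benchmark report: total treatments (animals
#' treated summed over prescriptions), critical treatments, the percentage
#' of consultations leading to an antibiotic treatment, the percentage of
#' critical treatments among all treatments, treatment counts by antibiotic
#' class and by indication, therapy days per treated animal, and the ten
#' most prescribed products with their modal dosage.
#'
#' A multi-substance product whose substances span several antibiotic
#' classes is counted once under `"combination"` so that class counts always
#' sum to the number of treatments.
#'
#' @param prescriptions Prescriptions of one practice x species x year.
#' @param nbconsult Consultation count for that practice-species-year.
#' @param catalog Substance catalog.
#' @return A list of class `abu_practice_summary`.
#' @export
summarize_practice <- function(prescriptions, nbconsult, catalog) {
  n_rx <- nrow(prescriptions)
  if (n_rx == 0) {
    return(structure(list(
      n_treatments = 0L, n_critical_treatments = 0L,
      pct_ab_treatments = 0, pct_critical = 0,
      treatments_by_class = integer(0), treatments_by_indication = integer(0),
      top_vmps = tibble(vmp_id = character(), n = integer(),
                        modal_dosage = numeric()),
      therapy_days_per_animal = 0), class = "abu_practice_summary"))
  }
  info <- substance_info(prescriptions$substances, catalog)
  at <- prescriptions$animals_treated
  n_treat <- sum(at)
  n_crit <- sum(at[info$n_critical > 0])
  td <- prescriptions$therapy_days + info$max_carryover

  classes <- vapply(split_substances(prescriptions$substances), function(s) {
    cls <- unique(catalog$ab_class[match(s, catalog$substance_code)])
    if (length(cls) == 1) cls else "combination"
  }, character(1))
  by_class <- tapply(at, classes, sum)
  by_class <- setNames(as.integer(by_class), names(by_class))
  by_ind <- tapply(at, prescriptions$indication, sum)
  by_ind <- setNames(as.integer(by_ind), names(by_ind))

  top <- top_vmps(prescriptions)

  structure(list(
    n_treatments = as.integer(n_treat),
    n_critical_treatments = as.integer(n_crit),
    pct_ab_treatments = 100 * n_treat / nbconsult,
    pct_critical = if (n_treat == 0) 0 else 100 * n_crit / n_treat,
    treatments_by_class = by_class[order(names(by_class))],
    treatments_by_indication = by_ind[order(names(by_ind))],
    top_vmps = top,
    therapy_days_per_animal = sum(td * at) / n_treat
  ), class = "abu_practice_summary")
}

# Ten most prescribed products by animals treated; ties broken by vmp_id
# lexicographically; modal dosage = most frequent, ties -> smallest.
#' @noRd
top_vmps <- function(prescriptions) {
  counts <- prescriptions |>
    dplyr::group_by(.data$vmp_id) |>
    dplyr::summarise(n = sum(.data$animals_treated),
                     modal_dosage = modal_value(.data$dosage_mg_per_kg),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$vmp_id)
  head(counts, 10)
}

#' @noRd
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])  # which.max takes the first =
}                                         # smallest value on ties

#' Cohort-level summary per stratum and species
#'
#' One row per practice type x species over the benchmark year: number of
#' practices with a computable pATI, median/mean/max consultations,
#' median/mean/max animal treatments (with the critical-only counterparts),
#' median percentage of consultations leading to a treatment, median
#' percentage of critical treatments among treatments, and median pATI for
#' both scopes. Practices eligible but without prescriptions count with zero
#' treatments.
#'
#' @param prescriptions Cleaned prescription tibble.
#' @param eligibility Eligibility tibble.
#' @param strata Stratum assignment from [assign_stratum()].
#' @param pati_table Output of [compute_pati_table()].
#' @param catalog Substance catalog.
#' @param year Benchmark year summarised.
#' @return Tibble, one row per populated practice type x species.
#' @export
summarize_cohort <- function(prescriptions, eligibility, strata, pati_table,
                             catalog, year) {
  elig <- eligibility[eligibility$eligible & eligibility$year == year, ]
  elig <- dplyr::left_join(elig, strata, by = c("practice_id", "species"))

  rx <- prescriptions[prescriptions$year == year, ]
  info <- substance_info(rx$substances, catalog)
  rx$is_critical_rx <- info$n_critical > 0
  per_practice <- rx |>
    dplyr::group_by(.data$practice_id, .data$species) |>
    dplyr::summarise(
      n_treatments = sum(.data$animals_treated),
      n_critical = sum(.data$animals_treated[.data$is_critical_rx]),
      .groups = "drop")
  base <- dplyr::left_join(elig, per_practice,
                           by = c("practice_id", "species"))
  base <- tidyr::replace_na(base, list(n_treatments = 0, n_critical = 0))
  base$pct_ab <- 100 * base$n_treatments / base$nbconsult_used
  base$pct_crit <- ifelse(base$n_treatments == 0, 0,
                          100 * base$n_critical / base$n_treatments)

  pati_wide <- pati_table[pati_table$year == year, ] |>
    tidyr::pivot_wider(id_cols = c("practice_id", "species"),
                       names_from = "scope", values_from = "pati",
                       names_prefix = "pati_")
  base <- dplyr::left_join(base, pati_wide, by = c("practice_id", "species"))

  base |>
    dplyr::group_by(.data$practice_type, .data$species) |>
    dplyr::summarise(
      n_practices = dplyr::n(),
      consult_median = median(.data$nbconsult_used),
      consult_mean = mean(.data$nbconsult_used),
      consult_max = max(.data$nbconsult_used),
      treat_median = median(.data$n_treatments),
      treat_mean = mean(.data$n_treatments),
      treat_max = max(.data$n_treatments),
      crit_treat_median = median(.data$n_critical),
      crit_treat_mean = mean(.data$n_critical),
      crit_treat_max = max(.data$n_critical),
      pct_ab_median = median(.data$pct_ab),
      pct_crit_median = median(.data$pct_crit),
      pati_median = median(.data$pati_all),
      crit_pati_median = median(.data$pati_critical),
      .groups = "drop")
}

#' Canton-level counts and shares
#'
#' Counts benchmarked practices and animal treatments per canton for the
#' benchmark year, with shares of the national total as printed percentages
#' ([ratio_pct()]).
#'
#' @param practices Practice registry tibble (with `canton`).
#' @param classified Output of [classify_cohort()]; its practices define the
#'   benchmarked set.
#' @param prescriptions Cleaned prescription tibble.
#' @param year Benchmark year.
#' @return Tibble with `canton`, `n_practices`, `share_practices`,
#'   `n_treatments`, `share_treatments`, sorted by descending practice count.
#' @export
canton_summary <- function(practices, classified, prescriptions, year) {
  bench_ids <- unique(classified$practice_id)
  bench <- practices[practices$practice_id %in% bench_ids, ]
  rx <- prescriptions[prescriptions$year == year &
                        prescriptions$practice_id %in% bench_ids, ]
  rx <- dplyr::left_join(rx[, c("practice_id", "animals_treated")],
                         practices[, c("practice_id", "canton")],
                         by = "practice_id")
  pr_counts <- bench |> dplyr::count(.data$canton, name = "n_practices")
  tr_counts <- rx |>
    dplyr::group_by(.data$canton) |>
    dplyr::summarise(n_treatments = sum(.data$animals_treated),
                     .groups = "drop")
  out <- dplyr::full_join(pr_counts, tr_counts, by = "canton")
  out <- tidyr::replace_na(out, list(n_practices = 0L, n_treatments = 0))
  out$share_practices <- ratio_pct(out$n_practices, sum(out$n_practices))
  out$share_treatments <- ratio_pct(out$n_treatments, sum(out$n_treatments))
  dplyr::arrange(out, dplyr::desc(.data$n_practices), .data$canton)
}
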