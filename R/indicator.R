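# Per-prescription substance bookkeeping, computed once per distinct
# substance combination (there are few combinations even in large cohorts).
#' @noRd
substance_info <- function(substances, catalog) {
  u <- unique(substances)
  codes <- split_substances(u)
  unknown <- setdiff(unique(unlist(codes)), catalog$substance_code)
  if (length(unknown) > 0) {
    abort(paste0("substances not in catalog: ",
                 paste(unknown, collapse = ", ")))
  }
  info <- tibble(
    substances = u,
    n_substances = lengths(codes),
    n_critical = vapply(codes, function(s) {
      sum(catalog$is_critical[match(s, catalog$substance_code)])
    }, integer(1)),
    max_carryover = vapply(codes, function(s) {
      max(catalog$carryover_days[match(s, catalog$substance_code)])
    }, numeric(1))
  )
  info[match(substances, info$substances), ]
}

#' Therapy days of each prescription, including carry-over
#'
#' A therapy day is a day on which an active substance is administered or
#' remains effective. For long-acting formulations the catalog supplies a
#' carry-over time; the therapy days of a prescription are the administered
#' days plus the largest carry-over among the product's substances
#' (default 0, so TD reduces to administered days for ordinary products).
#'
#' @param prescriptions Prescription tibble.
#' @param catalog Substance catalog.
#' @return Numeric vector of therapy days (TD), one per row.
#' @export
#' @examples
#' catalog <- default_catalog()
#' rx <- tibble::tibble(substances = c("amoxicillin", "cefovecin"),
#'                      therapy_days = c(7, 1))
#' therapy_days(rx, catalog)  # 7 and 1 + 13
therapy_days <- function(prescriptions, catalog) {
  info <- substance_info(prescriptions$substances, catalog)
  prescriptions$therapy_days + info$max_carryover
}

#' Compute the pATI for one practice, species and year
#'
#' The practice-level antibiotic treatment indicator is
#' \deqn{pATI = \frac{\sum_i TD_i \times NbAS_i \times AT_i}{NbConsult}}
#' summed over the prescriptions \eqn{i} of the practice-species-year:
#' therapy days (administered days plus carry-over) times the number of
#' active substances in the product times the number of animals treated,
#' normalised by the annual consultations for that species. Under
#' `scope = "critical"`, \eqn{NbAS_i} counts only the product's critical
#' substances, so products without critical substances contribute zero.
#'
#' @param prescriptions Prescriptions of a single practice, species and year
#'   (may be empty: the pATI of a non-user is 0).
#' @param nbconsult Consultation count used as denominator; must be at least
#'   100 (smaller denominators are filtered out upstream by eligibility).
#' @param catalog Substance catalog.
#' @param scope `"all"` or `"critical"`.
#' @return A single non-negative number.
#' @export
#' @examples
#' catalog <- default_catalog()
#' rx <- tibble::tibble(substances = c("trimethoprim;sulfadiazine",
#'                                     "amoxicillin"),
#'                      therapy_days = c(5, 7), animals_treated = c(3, 1))
#' compute_pati(rx, nbconsult = 100, catalog)  # (5*2*3 + 7*1*1)/100
compute_pati <- function(prescriptions, nbconsult, catalog,
                         scope = c("all", "critical")) {
  scope <- match.arg(scope)
  if (length(nbconsult) != 1 || is.na(nbconsult) ||
      nbconsult < abu_min_consultations) {
    abort("nbconsult must be a single value >= 100 (filter upstream)")
  }
  if (nrow(prescriptions) == 0) return(0)
  info <- substance_info(prescriptions$substances, catalog)
  td <- prescriptions$therapy_days + info$max_carryover
  nbas <- if (scope == "critical") info$n_critical else info$n_substances
  sum(td * nbas * prescriptions$animals_treated) / nbconsult
}

#' Compute the full pATI table of a cohort
#'
#' One row per eligible practice x species x year x scope. Eligible
#' combinations without prescriptions get a pATI of 0 (non-users); ineligible
#' combinations are absent. The `corrected` flag (imputed denominator) is
#' carried along because corrected values are classified but excluded from
#' threshold construction.
#'
#' @param prescriptions Cleaned prescription tibble.
#' @param eligibility Eligibility tibble from [impute_consultations()].
#' @param strata Stratum assignment from [assign_stratum()].
#' @param catalog Substance catalog.
#' @return Tibble with `practice_id`, `species`, `year`, `scope`, `pati`,
#'   `corrected`, `practice_type`.
#' @export
compute_pati_table <- function(prescriptions, eligibility, strata, catalog) {
  info <- substance_info(prescriptions$substances, catalog)
  rx <- prescriptions
  rx$td <- rx$therapy_days + info$max_carryover
  rx$num_all <- rx$td * info$n_substances * rx$animals_treated
  rx$num_critical <- rx$td * info$n_critical * rx$animals_treated
  num <- rx |>
    dplyr::group_by(.data$practice_id, .data$species, .data$year) |>
    dplyr::summarise(num_all = sum(.data$num_all),
                     num_critical = sum(.data$num_critical),
                     .groups = "drop")
  out <- eligibility[eligibility$eligible,
                     c("practice_id", "species", "year", "nbconsult_used",
                       "corrected")]
  out <- dplyr::left_join(out, num, by = c("practice_id", "species", "year"))
  out <- tidyr::replace_na(out, list(num_all = 0, num_critical = 0))
  out <- dplyr::left_join(out, strata, by = c("practice_id", "species"))
  out <- tidyr::pivot_longer(out, c("num_all", "num_critical"),
                             names_to = "scope", names_prefix = "num_",
                             values_to = "numerator")
  out$pati <- out$numerator / out$nbconsult_used
  out <- dplyr::arrange(out, .data$practice_id, .data$species, .data$year,
                        .data$scope)
  out[, c("practice_id", "species", "year", "scope", "pati", "corrected",
          "practice_type")]
}
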