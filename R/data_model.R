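#' Read the active-substance catalog
#'
#' The catalog maps each active-substance code to its antibiotic class, a
#' criticality flag and a carry-over time in days (the time a long-acting
#' formulation remains effective beyond the administered days; 0 for ordinary
#' formulations). Accepts a CSV file (columns `substance_code`, `ab_class`,
#' and optionally `is_critical`, `carryover_days`) or a YAML file holding a
#' list of entries with the same fields.
#'
#' `is_critical` is derived from `ab_class` when absent; when present it must
#' agree with [critical_classes()], otherwise the file is rejected: silently
#' miscounting critical antibiotics is the worst failure mode of the pipeline.
#'
#' @param path Path to a `.csv`, `.yml` or `.yaml` catalog file.
#' @return A tibble with columns `substance_code`, `ab_class`, `is_critical`,
#'   `carryover_days`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("catalog file not found: ", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
    cat_df <- dplyr::bind_rows(lapply(entries, as_tibble))
  } else {
    cat_df <- readr::read_csv(path, show_col_types = FALSE,
                              progress = FALSE)
  }
  required <- c("substance_code", "ab_class")
  missing <- setdiff(required, names(cat_df))
  if (length(missing) > 0) {
    abort(paste0("catalog schema error: missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  if (!"carryover_days" %in% names(cat_df)) cat_df$carryover_days <- 0
  cat_df$carryover_days[is.na(cat_df$carryover_days)] <- 0
  derived <- cat_df$ab_class %in% critical_classes()
  if ("is_critical" %in% names(cat_df)) {
    stated <- as.logical(cat_df$is_critical)
    bad <- which(stated != derived)
    if (length(bad) > 0) {
      abort(paste0("catalog inconsistency: is_critical disagrees with ",
                   "ab_class for ", paste(cat_df$substance_code[bad],
                                          collapse = ", ")))
    }
  }
  cat_df$is_critical <- derived
  if (anyDuplicated(cat_df$substance_code)) {
    abort("catalog contains duplicated substance codes")
  }
  if (any(cat_df$carryover_days < 0)) {
    abort("carryover_days must be non-negative")
  }
  as_tibble(cat_df[, c("substance_code", "ab_class", "is_critical",
                       "carryover_days")])
}

#' @noRd
prescription_columns <- c("practice_id", "date", "year", "species", "vmp_id",
                          "substances", "therapy_days", "animals_treated",
                          "indication", "dosage_mg_per_kg")

#' Split semicolon-joined substance cells into code vectors
#'
#' Prescriptions carry their active substances as one semicolon-joined cell
#' (one row per prescription). This helper recovers the list of codes.
#'
#' @param substances Character vector of semicolon-joined substance codes.
#' @return List of character vectors.
#' @export
#' @examples
#' split_substances(c("amoxicillin", "trimethoprim;sulfadiazine"))
split_substances <- function(substances) {
  strsplit(as.character(substances), ";", fixed = TRUE)
}

#' Validate a raw prescription table
#'
#' Applies the row-level invariants: positive therapy days, at least one
#' animal treated, a known species, at least one substance, every substance
#' code present in the catalog, and (optionally) a year inside the benchmark
#' window. Rows violating any invariant are rejected with a per-row reason
#' rather than silently coerced.
#'
#' @param df Data frame with the prescription schema (see
#'   [read_prescriptions()]).
#' @param catalog Substance catalog from [read_catalog()].
#' @param years Optional integer vector; when given, rows outside it are
#'   rejected.
#' @return List with `records` (tibble of valid rows) and `rejects` (tibble
#'   with `row`, `reason`).
#' @export
validate_prescriptions <- function(df, catalog, years = NULL) {
  df <- as_tibble(df)
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- why
  }
  flag(!(df$species %in% abu_species), "unknown species")
  if ("date" %in% names(df)) {
    flag(is.na(df$date), "missing date")
    flag(as.integer(format(df$date, "%Y")) != df$year,
         "date outside stated year")
  }
  flag(!is.finite(df$therapy_days) | df$therapy_days <= 0,
       "therapy_days must be > 0")
  flag(!is.finite(df$animals_treated) | df$animals_treated < 1 |
         df$animals_treated != round(df$animals_treated),
       "animals_treated must be a positive integer")
  subs <- split_substances(df$substances)
  n_subs <- lengths(subs)
  flag(is.na(df$substances) | n_subs < 1 | !nzchar(df$substances),
       "no active substance")
  known <- vapply(subs, function(s) all(s %in% catalog$substance_code),
                  logical(1))
  flag(!known, "unknown substance code")
  if (!is.null(years)) flag(!(df$year %in% years), "year outside window")
  bad <- !is.na(reason)
  rejects <- tibble(row = which(bad), reason = reason[bad])
  list(records = df[!bad, , drop = FALSE], rejects = rejects)
}

#' Read a prescription table
#'
#' One row per antibiotic prescription or application: the practice, the
#' prescription date and year, the species, the veterinary medicinal product
#' (VMP), its active substances
#' (semicolon-joined in one cell), the administered therapy days, the number
#' of animals treated, the indication, and optionally the dosage in mg/kg
#' (display only). Invalid rows are rejected with a diagnostic (see
#' [validate_prescriptions()]); the rejects are attached as the `"rejects"`
#' attribute and a warning reports their count.
#'
#' @inheritParams validate_prescriptions
#' @param path Path to a CSV file with a header row.
#' @return Tibble of valid prescription records, with attribute `rejects`.
#' @export
read_prescriptions <- function(path, catalog, years = NULL) {
  if (!file.exists(path)) abort(paste0("prescriptions file not found: ", path))
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  missing <- setdiff(prescription_columns, header)
  if (length(missing) > 0) {
    abort(paste0("prescriptions schema error: missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          practice_id = readr::col_character(),
                          date = readr::col_date(),
                          year = readr::col_integer(),
                          species = readr::col_character(),
                          vmp_id = readr::col_character(),
                          substances = readr::col_character(),
                          therapy_days = readr::col_double(),
                          animals_treated = readr::col_integer(),
                          indication = readr::col_character(),
                          dosage_mg_per_kg = readr::col_double()
                        ))
  out <- validate_prescriptions(df, catalog, years)
  if (nrow(out$rejects) > 0) {
    warn(paste0(nrow(out$rejects), " prescription row(s) rejected; ",
                "see attr(x, 'rejects')"))
  }
  res <- out$records
  attr(res, "rejects") <- out$rejects
  res
}

#' Write a prescription table
#'
#' Inverse of [read_prescriptions()]: writes the documented CSV schema so
#' that a write/read round trip is the identity on all fields.
#'
#' @param records Tibble of prescription records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prescriptions <- function(records, path) {
  readr::write_csv(records[, prescription_columns], path, progress = FALSE)
  invisible(path)
}

#' Read annual consultation counts
#'
#' One row per practice, species and year with the total number of
#' consultations (NbConsult) — the population at risk and the denominator of
#' the pATI. At most one row per (practice, species, year) is allowed.
#'
#' @param path Path to a CSV with columns `practice_id`, `species`, `year`,
#'   `n_consultations`.
#' @return Tibble of consultation records.
#' @export
read_consultations <- function(path) {
  if (!file.exists(path)) abort(paste0("consultations file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          practice_id = readr::col_character(),
                          species = readr::col_character(),
                          year = readr::col_integer(),
                          n_consultations = readr::col_integer()
                        ))
  required <- c("practice_id", "species", "year", "n_consultations")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("consultations schema error: missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  if (any(bad <- !(df$species %in% abu_species))) {
    abort(paste0("unknown species in consultations: ",
                 paste(unique(df$species[bad]), collapse = ", ")))
  }
  if (any(df$n_consultations < 0, na.rm = TRUE)) {
    abort("n_consultations must be non-negative")
  }
  key <- paste(df$practice_id, df$species, df$year)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("duplicate consultation record for (practice, species, ",
                 "year) = (", dup, ")"))
  }
  as_tibble(df)
}

#' @rdname read_consultations
#' @param records Tibble of consultation records.
#' @export
write_consultations <- function(records, path) {
  cols <- c("practice_id", "species", "year", "n_consultations")
  readr::write_csv(records[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read the practice registry
#'
#' One row per practice with its self-declared type (companion-animal
#' practice, companion-animal clinic, or mixed practice treating both
#' livestock and companion animals) and its two-letter canton code.
#'
#' @param path Path to a CSV with columns `practice_id`, `declared_type`,
#'   `canton`.
#' @return Tibble of practice records.
#' @export
read_practices <- function(path) {
  if (!file.exists(path)) abort(paste0("practices file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  required <- c("practice_id", "declared_type", "canton")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("practices schema error: missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  bad <- !(df$declared_type %in% abu_declared_types)
  if (any(bad)) {
    abort(paste0("unknown practice type: ",
                 paste(unique(df$declared_type[bad]), collapse = ", ")))
  }
  if (anyDuplicated(df$practice_id)) abort("duplicated practice_id in registry")
  as_tibble(df[, required])
}

#' @rdname read_practices
#' @param records Tibble of practice records.
#' @export
write_practices <- function(records, path) {
  readr::write_csv(records[, c("practice_id", "declared_type", "canton")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname read_catalog
#' @param catalog Catalog tibble.
#' @export
write_catalog <- function(catalog, path) {
  cols <- c("substance_code", "ab_class", "is_critical", "carryover_days")
  readr::write_csv(catalog[, cols], path, progress = FALSE)
  invisible(path)
}

#' Bundled synthetic substance catalog
#'
#' Convenience accessor for the synthetic catalog shipped with the package
#' (`inst/extdata/substance_catalog.csv`): a small but representative set of
#' companion-animal antibiotics covering the critical classes and one
#' long-acting injectable with a 13-day carry-over.
#'
#' @return Catalog tibble as from [read_catalog()].
#' @export
default_catalog <- function() {
  read_catalog(system.file("extdata", "substance_catalog.csv",
                           package = "abubench", mustWork = TRUE))
}
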