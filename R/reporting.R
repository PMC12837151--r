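#' Run the full benchmarking analysis on one cohort
#'
#' Chains the pipeline stages — deduplication, outlier removal, consultation
#' imputation and eligibility, stratum assignment, pATI computation,
#' threshold construction, classification, cohort and canton summaries — and
#' returns every intermediate table plus stage counts.
#'
#' @param prescriptions,consultations,practices The three input tibbles (see
#'   [read_prescriptions()], [read_consultations()], [read_practices()]).
#' @param catalog Substance catalog.
#' @param years Benchmark window (defaults to the years present in the
#'   consultation table).
#' @param benchmark_year Year used for classification and summaries
#'   (defaults to the last year of the window).
#' @param max_therapy_days Outlier bound passed to [filter_outliers()].
#' @return A list of class `abu_benchmark` with elements `prescriptions`
#'   (cleaned), `eligibility`, `strata`, `pati`, `contributions`,
#'   `thresholds`, `classified`, `cohort_summary`, `canton_summary`,
#'   `counts`, `benchmark_year`, `years`.
#' @export
benchmark_cohort <- function(prescriptions, consultations, practices,
                             catalog, years = NULL,
                             benchmark_year = NULL,
                             max_therapy_days = 365) {
  if (is.null(years)) years <- sort(unique(consultations$year))
  if (is.null(benchmark_year)) benchmark_year <- max(years)
  n_raw <- nrow(prescriptions)

  dd <- deduplicate_prescriptions(prescriptions)
  fo <- filter_outliers(dd$records, max_therapy_days = max_therapy_days)
  rx <- fo$records

  eligibility <- impute_consultations(consultations, practices, years)
  strata <- assign_stratum(practices, eligibility, benchmark_year)
  pati <- compute_pati_table(rx, eligibility, strata, catalog)
  contributions <- mean_pati_contributions(pati)
  thresholds <- suppressWarnings(compute_thresholds(contributions))
  classified <- classify_cohort(pati, thresholds, benchmark_year)
  cohort_summary <- summarize_cohort(rx, eligibility, strata, pati,
                                     catalog, benchmark_year)
  cantons <- canton_summary(practices, classified, rx, benchmark_year)

  counts <- list(
    prescriptions_raw = n_raw,
    duplicates_dropped = dd$n_dropped,
    outliers_dropped = fo$n_dropped,
    prescriptions_clean = nrow(rx),
    practices_total = nrow(practices),
    practice_species_eligible = nrow(unique(
      pati[, c("practice_id", "species")])),
    practices_benchmarked = length(unique(classified$practice_id)),
    threshold_contributors = length(unique(contributions$practice_id))
  )
  structure(list(prescriptions = rx, eligibility = eligibility,
                 strata = strata, pati = pati,
                 contributions = contributions, thresholds = thresholds,
                 classified = classified, cohort_summary = cohort_summary,
                 canton_summary = cantons, counts = counts,
                 benchmark_year = benchmark_year, years = years),
            class = "abu_benchmark")
}

#' @export
print.abu_benchmark <- function(x, ...) {
  cat("Antibiotic-use benchmark,", min(x$years), "-", max(x$years),
      "(benchmark year", paste0(x$benchmark_year, ")\n"))
  cat("  practices:", x$counts$practices_total,
      "| benchmarked:", x$counts$practices_benchmarked,
      "| threshold contributors:", x$counts$threshold_contributors, "\n")
  cat("  clean prescriptions:", x$counts$prescriptions_clean,
      "(", x$counts$duplicates_dropped, "duplicates,",
      x$counts$outliers_dropped, "outliers dropped )\n")
  invisible(x)
}

#' Assemble the benchmark report of one practice
#'
#' Gathers everything the per-practice report shows: for each species and
#' scope, the category, the practice's pATI per year, the stratum thresholds,
#' and the anonymized comparison series (the pATI values of all comparable
#' practices per year with only the practice's own value flagged); plus the
#' practice's own use summary and the stratum medians for comparison.
#' Practices without a pATI still receive the anonymized cohort distribution
#' — their own point is simply absent.
#'
#' @param run An `abu_benchmark` from [benchmark_cohort()].
#' @param practice_id Practice to report on.
#' @param catalog Substance catalog (for the use summary).
#' @return A list of class `abu_practice_report`. No identifier of any other
#'   practice appears anywhere in it.
#' @export
build_report <- function(run, practice_id, catalog = default_catalog()) {
  stopifnot(inherits(run, "abu_benchmark"))
  if (!practice_id %in% run$eligibility$practice_id) {
    abort(paste0("unknown practice: ", practice_id))
  }
  pati <- run$pati
  species_blocks <- lapply(abu_species, function(sp) {
    stratum <- run$strata$practice_type[
      run$strata$practice_id == practice_id & run$strata$species == sp]
    scopes <- lapply(abu_scopes, function(sc) {
      pool <- pati[pati$species == sp & pati$scope == sc &
                     pati$practice_type == stratum, ]
      own <- pool[pool$practice_id == practice_id, ]
      thr <- run$thresholds[run$thresholds$practice_type == stratum &
                              run$thresholds$species == sp &
                              run$thresholds$scope == sc, ]
      cls <- run$classified[run$classified$practice_id == practice_id &
                              run$classified$species == sp &
                              run$classified$scope == sc, ]
      pos <- pool$pati[pool$pati > 0]
      series <- lapply(run$years, function(yr) {
        others <- pool$pati[pool$year == yr &
                              pool$practice_id != practice_id]
        own_y <- own$pati[own$year == yr]
        list(year = yr, values = unname(sort(others)),
             own = if (length(own_y) == 1) own_y else NULL)
      })
      list(
        category = if (nrow(cls) == 1) as.character(cls$category) else NULL,
        pati_by_year = setNames(as.list(own$pati), as.character(own$year)),
        signal = if (nrow(thr) == 1) thr$signal else NULL,
        action = if (nrow(thr) == 1) thr$action else NULL,
        n_comparable = length(unique(pool$practice_id)),
        fig1 = list(axis = "log10",
                    zero_floor = if (length(pos)) min(pos) / 2 else NULL,
                    years = series)
      )
    })
    elig_sp <- run$eligibility[
      run$eligibility$practice_id == practice_id &
        run$eligibility$species == sp &
        run$eligibility$year == run$benchmark_year, ]
    own_rx <- run$prescriptions[
      run$prescriptions$practice_id == practice_id &
        run$prescriptions$species == sp &
        run$prescriptions$year == run$benchmark_year, ]
    summ <- if (nrow(elig_sp) == 1 && elig_sp$eligible) {
      unclass(summarize_practice(own_rx, elig_sp$nbconsult_used, catalog))
    } else NULL
    if (!is.null(summ)) {
      summ$treatments_by_class <- as.list(summ$treatments_by_class)
      summ$treatments_by_indication <- as.list(summ$treatments_by_indication)
    }
    med <- run$cohort_summary[run$cohort_summary$practice_type == stratum &
                                run$cohort_summary$species == sp, ]
    list(species = sp, practice_type = stratum,
         eligible = nrow(elig_sp) == 1 && elig_sp$eligible,
         scopes = setNames(scopes, abu_scopes),
         summary = summ,
         stratum_medians = if (nrow(med) == 1) as.list(med[, c(
           "consult_median", "treat_median", "pct_ab_median",
           "pct_crit_median", "pati_median", "crit_pati_median")]) else NULL)
  })
  structure(list(practice_id = practice_id,
                 benchmark_year = run$benchmark_year,
                 years = run$years,
                 species = setNames(species_blocks, abu_species)),
            class = "abu_practice_report")
}

#' Render a practice report
#'
#' Serialises an assembled report deterministically. `"json"` is the
#' canonical machine format; `"text"` a human-readable summary; `"html"` a
#' minimal page embedding the canonical JSON payload in a
#' `<script type="application/json">` block, so numbers can be extracted
#' unchanged from the rendered page. pATI series carry log-scale metadata
#' (`axis = "log10"`), and null pATI values are drawn at a floor of half the
#' smallest positive comparable value.
#'
#' @param report An `abu_practice_report` from [build_report()].
#' @param format One of `"json"`, `"text"`, `"html"`.
#' @return A single string (the document).
#' @export
render_report <- function(report, format = c("json", "text", "html")) {
  format <- match.arg(format)
  payload <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                              digits = NA, null = "null", pretty = TRUE)
  if (format == "json") return(as.character(payload))
  lines <- c(
    paste0("Antibiotic-use benchmark report - practice ", report$practice_id),
    paste0("Benchmark year: ", report$benchmark_year))
  for (sp in names(report$species)) {
    blk <- report$species[[sp]]
    lines <- c(lines, "", paste0(toupper(sp), " (stratum: ",
                                 blk$practice_type, ")"))
    for (sc in names(blk$scopes)) {
      s <- blk$scopes[[sc]]
      cat_lab <- if (is.null(s$category)) "not classified" else s$category
      thr_lab <- if (is.null(s$signal)) "no thresholds" else
        sprintf("signal %.4g / action %.4g", s$signal, s$action)
      pati_lab <- if (length(s$pati_by_year) == 0) "no pATI" else
        paste(sprintf("%s=%.4g", names(s$pati_by_year),
                      unlist(s$pati_by_year)), collapse = ", ")
      lines <- c(lines, sprintf("  [%s] category: %s | %s | pATI: %s",
                                sc, cat_lab, thr_lab, pati_lab))
    }
    if (!is.null(blk$summary)) {
      lines <- c(lines, sprintf(
        "  treatments: %d (critical: %d) | %% of consultations: %.1f | therapy days/animal: %.2f",
        blk$summary$n_treatments, blk$summary$n_critical_treatments,
        blk$summary$pct_ab_treatments, blk$summary$therapy_days_per_animal))
    }
  }
  text <- paste(lines, collapse = "\n")
  if (format == "text") return(text)
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
         "<title>Benchmark report ", report$practice_id, "</title></head>\n",
         "<body>\n<pre>\n", gsub("<", "&lt;", text), "\n</pre>\n",
         "<script type=\"application/json\" id=\"report-data\">\n",
         payload, "\n</script>\n</body></html>\n")
}

#' Run the whole pipeline end to end on a synthetic cohort
#'
#' Simulates a cohort, writes the three input CSVs, reads them back through
#' the package readers, runs [benchmark_cohort()], writes every output table
#' and the per-practice reports, and records a manifest (seed, full
#' configuration, stage counts) so that two runs with the same seed are
#' byte-identical.
#'
#' @param config An `abu_cohort_config`;
#'   [default_swiss_like_config()] by default.
#' @param out_dir Output directory.
#' @param seed Optional seed overriding `config$seed`.
#' @param report_format Format(s) of rendered reports, subset of
#'   `c("json", "text", "html")`.
#' @param max_reports Cap on the number of per-practice reports written
#'   (`Inf` = all benchmarked practices); reports are written in practice-id
#'   order.
#' @return The `abu_benchmark` run, invisibly.
#' @export
run_pipeline <- function(config = default_swiss_like_config(),
                         out_dir, seed = NULL,
                         report_format = "json",
                         max_reports = Inf) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  input_dir <- file.path(out_dir, "input")
  cohort <- generate_cohort(config)
  write_cohort(cohort, input_dir)

  catalog <- default_catalog()
  practices <- read_practices(file.path(input_dir, "practices.csv"))
  consultations <- read_consultations(file.path(input_dir,
                                                "consultations.csv"))
  prescriptions <- read_prescriptions(file.path(input_dir,
                                                "prescriptions.csv"),
                                      catalog, years = config$years)

  run <- benchmark_cohort(prescriptions, consultations, practices, catalog,
                          years = config$years)

  readr::write_csv(run$pati, file.path(out_dir, "pati.csv"),
                   progress = FALSE)
  readr::write_csv(run$thresholds, file.path(out_dir, "thresholds.csv"),
                   progress = FALSE)
  cls <- run$classified
  cls$category <- as.character(cls$category)
  readr::write_csv(cls, file.path(out_dir, "categories.csv"),
                   progress = FALSE)
  readr::write_csv(run$cohort_summary,
                   file.path(out_dir, "cohort_summary.csv"),
                   progress = FALSE)
  readr::write_csv(run$canton_summary,
                   file.path(out_dir, "canton_summary.csv"),
                   progress = FALSE)

  report_dir <- file.path(out_dir, "reports")
  dir.create(report_dir, showWarnings = FALSE)
  ids <- sort(unique(run$classified$practice_id))
  ids <- head(ids, max_reports)
  ext <- c(json = "json", text = "txt", html = "html")
  for (id in ids) {
    rep <- build_report(run, id, catalog)
    for (fmt in report_format) {
      writeLines(render_report(rep, fmt),
                 file.path(report_dir, paste0(id, ".", ext[[fmt]])))
    }
  }

  manifest <- list(
    seed = config$seed,
    years = config$years,
    benchmark_year = run$benchmark_year,
    config = config_as_list(config),
    counts = run$counts,
    n_reports = length(ids)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}

# canonical, JSON-friendly view of a config (matrices -> named lists)
#' @noRd
config_as_list <- function(config) {
  mat_list <- function(m) {
    lapply(setNames(rownames(m), rownames(m)), function(r) {
      as.list(setNames(m[r, ], colnames(m)))
    })
  }
  list(
    n_practices_per_type = as.list(config$n_practices_per_type),
    years = config$years,
    median_consultations = mat_list(config$median_consultations),
    treatment_prob = mat_list(config$treatment_prob),
    critical_frac = mat_list(config$critical_frac),
    therapy_days_mean = config$therapy_days_mean,
    practice_effect_sdlog = config$practice_effect_sdlog,
    consult_sdlog = config$consult_sdlog,
    consult_year_sdlog = config$consult_year_sdlog,
    missing_nbconsult_prob = config$missing_nbconsult_prob,
    zero_use_frac = config$zero_use_frac,
    sub100_frac = config$sub100_frac,
    seed = config$seed
  )
}
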