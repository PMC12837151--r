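catalog <- default_catalog()

run_small <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cohort <- generate_cohort(small_config(seed = 19L))
      memo <<- list(
        cohort = cohort,
        run = benchmark_cohort(cohort$prescriptions, cohort$consultations,
                               cohort$practices, catalog,
                               years = 2022:2024))
    }
    memo
  }
})

test_that("an eligible practice's report carries its own point per year", {
  env <- run_small()
  run <- env$run
  elig_ids <- run$pati |>
    dplyr::filter(!is.na(pati)) |>
    dplyr::count(practice_id) |>
    dplyr::filter(n == 12)  # both species, 3 years, 2 scopes
  id <- elig_ids$practice_id[1]
  rep <- build_report(run, id, catalog)
  expect_equal(rep$practice_id, id)
  blk <- rep$species$dog$scopes$all
  expect_equal(length(blk$pati_by_year), 3)
  own_flags <- vapply(blk$fig1$years, function(y) !is.null(y$own), logical(1))
  expect_true(all(own_flags))
  expect_equal(blk$fig1$axis, "log10")
  expect_equal(rep$species$dog$scopes$all$category,
               as.character(run$classified$category[
                 run$classified$practice_id == id &
                   run$classified$species == "dog" &
                   run$classified$scope == "all"]))
})

test_that("an ineligible practice still sees the anonymized distribution", {
  env <- run_small()
  run <- env$run
  ineligible <- setdiff(env$cohort$practices$practice_id,
                        unique(run$pati$practice_id))
  expect_gt(length(ineligible), 0)  # the draw keeps some non-reporters
  rep <- build_report(run, ineligible[1], catalog)
  blk <- rep$species$cat$scopes$all
  expect_equal(length(blk$pati_by_year), 0)
  expect_false(rep$species$cat$eligible)
  total_vals <- sum(vapply(blk$fig1$years, function(y) length(y$values),
                           integer(1)))
  expect_gt(total_vals, 0)
})

test_that("no foreign practice identifier leaks into a rendered report", {
  env <- run_small()
  run <- env$run
  id <- sort(unique(run$classified$practice_id))[1]
  rep <- build_report(run, id, catalog)
  other_ids <- setdiff(env$cohort$practices$practice_id, id)
  for (fmt in c("json", "text", "html")) {
    doc <- render_report(rep, fmt)
    expect_false(any(vapply(other_ids, grepl, logical(1), x = doc,
                            fixed = TRUE)),
                 info = fmt)
    expect_true(grepl(id, doc, fixed = TRUE), info = fmt)
  }
})

test_that("rendering is deterministic and the html embeds the json payload", {
  env <- run_small()
  run <- env$run
  id <- sort(unique(run$classified$practice_id))[2]
  rep <- build_report(run, id, catalog)
  expect_identical(render_report(rep, "json"), render_report(rep, "json"))
  expect_identical(render_report(rep, "html"), render_report(rep, "html"))
  html <- render_report(rep, "html")
  payload <- sub(".*<script type=\"application/json\" id=\"report-data\">\\n",
                 "", html)
  payload <- sub("\\n</script>.*", "", payload)
  expect_equal(jsonlite::fromJSON(payload, simplifyVector = FALSE),
               jsonlite::fromJSON(render_report(rep, "json"),
                                  simplifyVector = FALSE))
})

test_that("reports flag very high users against the action threshold", {
  env <- run_small()
  run <- env$run
  vh <- run$classified[run$classified$category == "very_high" &
                         run$classified$scope == "all", ]
  expect_gt(nrow(vh), 0)  # a 58-practice cohort always has some
  rep <- build_report(run, vh$practice_id[1], catalog)
  blk <- rep$species[[vh$species[1]]]$scopes$all
  expect_equal(blk$category, "very_high")
  expect_gt(blk$pati_by_year[[as.character(run$benchmark_year)]],
            blk$action)
})

test_that("the end-to-end pipeline writes consistent counts and stays deterministic", {
  cfg <- small_config(seed = 29L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run <- suppressWarnings(run_pipeline(cfg, d1, report_format = c("json", "html"),
                                       max_reports = 5))
  suppressWarnings(run_pipeline(cfg, d2, report_format = c("json", "html"),
                                max_reports = 5))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$counts$prescriptions_raw,
               man$counts$prescriptions_clean +
                 man$counts$duplicates_dropped +
                 man$counts$outliers_dropped)
  expect_equal(man$seed, 29)
  expect_true(file.exists(file.path(d1, "thresholds.csv")))

  files1 <- sort(list.files(d1, recursive = TRUE))
  files2 <- sort(list.files(d2, recursive = TRUE))
  expect_equal(files1, files2)
  for (f in files1) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     info = f)
  }
})

test_that("missing input files fail with a diagnostic naming the file", {
  expect_error(read_prescriptions("no/such/prescriptions.csv", catalog),
               "prescriptions.csv")
  expect_error(read_consultations("no/such/consultations.csv"),
               "consultations.csv")
})
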