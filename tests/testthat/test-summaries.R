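catalog <- default_catalog()

test_that("printed shares round half away from zero to one decimal", {
  expect_equal(ratio_pct(686, 989), 69.4)
  expect_equal(ratio_pct(9, 32), 28.1)
  expect_equal(ratio_pct(15, 32), 46.9)
  expect_equal(ratio_pct(0, 7), 0)
  expect_equal(ratio_pct(1, 16), 6.3)   # 6.25 rounds away from zero
  expect_equal(ratio_pct(-1, 16), -6.3)
  expect_equal(ratio_pct(c(1, 3), c(2, 4)), c(50, 75))
  expect_error(ratio_pct(1, 0), "non-zero")
})

test_that("a practice summary reports treatments, shares and breakdowns", {
  set.seed(6)
  rx <- dplyr::bind_rows(
    make_rx("P0001", substances = "amoxicillin", n = 80),
    make_rx("P0001", substances = "enrofloxacin", vmp_id = "ENRO-50",
            dosage_mg_per_kg = 5, indication = "urinary", n = 30),
    make_rx("P0001", substances = "trimethoprim;sulfadiazine",
            vmp_id = "TMS-240", indication = "dental", n = 10))
  rx$date <- rx$date + seq_len(nrow(rx))
  s <- summarize_practice(rx, 1000, catalog)
  expect_equal(s$n_treatments, 120L)
  expect_equal(s$pct_ab_treatments, 12.0)
  expect_equal(s$n_critical_treatments, 30L)
  expect_equal(s$pct_critical, 25)
  expect_equal(sum(s$treatments_by_class), s$n_treatments)
  expect_equal(sum(s$treatments_by_indication), s$n_treatments)
  expect_equal(unname(s$treatments_by_class[c("penicillin",
                                              "fluoroquinolone")]),
               c(80L, 30L))
  # a multi-class combination product is counted once, as "combination"
  expect_equal(unname(s$treatments_by_class["combination"]), 10L)
  expect_equal(s$therapy_days_per_animal, 7)
})

test_that("an antibiotic-free practice summarises to zeroes", {
  s <- summarize_practice(make_rx()[0, ], 500, catalog)
  expect_equal(s$n_treatments, 0L)
  expect_equal(s$pct_critical, 0)
  expect_equal(nrow(s$top_vmps), 0)
})

test_that("top products are the ten most frequent, ties by product id", {
  set.seed(30)
  counts <- c(30, 25, 25, 20, 15, 12, 10, 8, 6, 5, 5, 2)
  vmps <- sprintf("VMP-%02d", 1:12)
  rx <- dplyr::bind_rows(lapply(1:12, function(i) {
    make_rx("P0001", vmp_id = vmps[i], substances = "amoxicillin",
            dosage_mg_per_kg = 10 + (i %% 3), n = counts[i])
  }))
  rx$date <- rx$date + seq_len(nrow(rx))
  top <- summarize_practice(rx, 1000, catalog)$top_vmps
  expect_equal(nrow(top), 10)
  # brute-force check of membership and ordering
  want <- tibble::tibble(vmp_id = vmps, n = counts) |>
    dplyr::arrange(dplyr::desc(n), vmp_id) |> head(10)
  expect_equal(top$vmp_id, want$vmp_id)
  expect_equal(top$n, as.integer(want$n))
})

test_that("modal dosage takes the most frequent value, smallest on ties", {
  rx <- make_rx("P0001", n = 4)
  rx$date <- rx$date + 1:4
  rx$dosage_mg_per_kg <- c(10, 20, 20, 10)
  top <- summarize_practice(rx, 1000, catalog)$top_vmps
  expect_equal(top$modal_dosage, 10)
  rx$dosage_mg_per_kg <- c(10, 20, 20, 5)
  top <- summarize_practice(rx, 1000, catalog)$top_vmps
  expect_equal(top$modal_dosage, 20)
})

test_that("cohort summaries degenerate correctly and ignore row order", {
  practices <- make_practices("P0001", "mixed_practice")
  consult <- make_consultations("P0001", c("cat", "dog"), 2024, 1500L)
  rx <- make_rx("P0001", year = 2024, species = "cat", n = 60)
  rx$date <- rx$date + seq_len(nrow(rx))
  run <- benchmark_cohort(rx, consult, practices, catalog, years = 2024)
  cs <- run$cohort_summary
  cat_row <- cs[cs$species == "cat", ]
  expect_equal(cat_row$consult_median, 1500)
  expect_equal(cat_row$consult_mean, 1500)
  expect_equal(cat_row$consult_max, 1500)
  expect_equal(cat_row$treat_median, 60)
  expect_equal(cat_row$pct_ab_median, 4)
  expect_equal(cat_row$pati_median, 60 * 7 / 1500)

  cohort <- generate_cohort(small_config(seed = 31L))
  runA <- benchmark_cohort(cohort$prescriptions, cohort$consultations,
                           cohort$practices, catalog, years = 2022:2024)
  perm <- cohort$prescriptions[sample(nrow(cohort$prescriptions)), ]
  runB <- benchmark_cohort(perm, cohort$consultations,
                           cohort$practices, catalog, years = 2022:2024)
  expect_equal(runA$cohort_summary, runB$cohort_summary)
  expect_equal(runA$thresholds, runB$thresholds)
})

test_that("canton shares are computed on benchmarked practices", {
  practices <- dplyr::bind_rows(
    make_practices(sprintf("B%03d", 1:3), canton = "BE"),
    make_practices(sprintf("Z%03d", 1:2), canton = "ZH"),
    make_practices("X001", canton = "AI"))  # never registers -> excluded
  ids <- practices$practice_id[1:5]
  consult <- make_consultations(ids, "dog", 2024, 1000L)
  rx <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    out <- make_rx(ids[i], year = 2024, n = 10 * i)
    out$date <- out$date + seq_len(nrow(out))
    out
  }))
  run <- benchmark_cohort(rx, consult, practices, catalog, years = 2024)
  cant <- run$canton_summary
  expect_setequal(cant$canton, c("BE", "ZH"))
  expect_equal(cant$n_practices[cant$canton == "BE"], 3L)
  expect_equal(sum(cant$n_practices), 5L)
  expect_equal(sum(cant$n_treatments), sum(10 * (1:5)))
  # unrounded shares sum to 100
  expect_equal(sum(100 * cant$n_practices / sum(cant$n_practices)), 100)
  be_share <- ratio_pct(cant$n_practices[cant$canton == "BE"], 5)
  expect_equal(cant$share_practices[cant$canton == "BE"], be_share)
  # single-canton cohort -> 100%
  solo <- run$canton_summary[run$canton_summary$canton == "BE", ]
  practices_be <- practices[practices$canton == "BE", ]
  run_be <- benchmark_cohort(rx[rx$practice_id %in% practices_be$practice_id, ],
                             consult[consult$practice_id %in%
                                       practices_be$practice_id, ],
                             practices_be, catalog, years = 2024)
  expect_equal(run_be$canton_summary$share_practices, 100)
  expect_equal(run_be$canton_summary$share_treatments, 100)
})
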