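catalog <- default_catalog()

test_that("percentile follows the 1 + q(n-1) interpolation convention", {
  expect_equal(percentile(1:100, 0.95), 95.05)
  expect_equal(percentile(1:100, 0.75), 75.25)
  expect_equal(percentile(42, 0.31), 42)
  expect_equal(percentile(rep(3.2, 17), 0.95), 3.2)
  expect_error(percentile(numeric(0), 0.5), "empty")
  expect_error(percentile(c(1, NA), 0.5), "NA")
  expect_error(percentile(1:5, 1.2), "0, 1")
  set.seed(33)
  for (i in 1:50) {
    x <- rlnorm(sample(1:80, 1))
    q <- runif(1)
    expect_equal(percentile(x, q), quantile_oracle(x, q))
  }
})

test_that("threshold contributions drop corrected years and non-users", {
  pt <- tibble::tibble(
    practice_id = "P0001", species = "dog", year = 2022:2024, scope = "all",
    pati = c(0.5, 0.7, 9.9), corrected = c(FALSE, FALSE, TRUE),
    practice_type = "mixed")
  contrib <- mean_pati_contributions(pt)
  expect_equal(contrib$mean_pati, 0.6)
  expect_equal(contrib$n_years, 2)

  nonuser <- dplyr::mutate(pt, pati = 0, corrected = FALSE)
  expect_equal(nrow(mean_pati_contributions(nonuser)), 0)
})

test_that("contributions equal a brute-force filter-and-mean oracle", {
  cohort <- generate_cohort(small_config(seed = 23L))
  run <- benchmark_cohort(cohort$prescriptions, cohort$consultations,
                          cohort$practices, catalog, years = 2022:2024)
  contrib <- run$contributions
  raw <- run$pati
  idx <- sample(nrow(contrib), 25)
  for (i in idx) {
    r <- contrib[i, ]
    vals <- raw$pati[raw$practice_id == r$practice_id &
                       raw$species == r$species & raw$scope == r$scope &
                       !raw$corrected & raw$pati > 0]
    expect_equal(r$mean_pati, mean(vals))
  }
})

test_that("thresholds are ordered, per-stratum, and order-preserving", {
  set.seed(8)
  contrib <- tidyr::crossing(practice_id = sprintf("P%03d", 1:30),
                             practice_type = c("mixed", "small_lt4500",
                                               "small_ge4500"),
                             species = c("cat", "dog"),
                             scope = c("all", "critical"))
  contrib$mean_pati <- rlnorm(nrow(contrib))
  # make every cat value larger than every dog value
  contrib$mean_pati[contrib$species == "cat"] <-
    contrib$mean_pati[contrib$species == "cat"] + 20
  thr <- compute_thresholds(contrib)
  expect_equal(nrow(thr), 12)
  expect_true(all(thr$signal <= thr$action))
  expect_true(all(thr$signal > 0))
  wide <- tidyr::pivot_wider(thr, id_cols = c("practice_type", "scope"),
                             names_from = "species",
                             values_from = c("signal", "action"))
  expect_true(all(wide$signal_cat > wide$signal_dog))
  expect_true(all(wide$action_cat > wide$action_dog))

  # 20-value fixture against the interpolation oracle
  vals <- rlnorm(20)
  one <- tibble::tibble(practice_id = sprintf("P%02d", 1:20),
                        practice_type = "mixed", species = "dog",
                        scope = "all", mean_pati = vals)
  got <- suppressWarnings(compute_thresholds(one))
  expect_equal(got$signal, quantile_oracle(vals, 0.75))
  expect_equal(got$action, quantile_oracle(vals, 0.95))
  expect_equal(got$n_contributing, 20)
})

test_that("thresholds are invariant to permutation and duplication", {
  set.seed(12)
  one <- tibble::tibble(practice_id = sprintf("P%02d", 1:25),
                        practice_type = "mixed", species = "dog",
                        scope = "all", mean_pati = rlnorm(25))
  base <- suppressWarnings(compute_thresholds(one))
  perm <- suppressWarnings(compute_thresholds(one[sample(25), ]))
  expect_equal(perm$signal, base$signal)
  expect_equal(perm$action, base$action)
  # duplicating the whole contributor set moves the interpolation position
  # by less than one rank, so thresholds shift by at most one gap between
  # adjacent order statistics
  dup <- one[rep(1:25, 2), ]
  dup$practice_id <- sprintf("P%02d", 1:50)
  both <- suppressWarnings(compute_thresholds(dup))
  gap <- max(diff(sort(one$mean_pati)))
  expect_lt(abs(both$signal - base$signal), gap)
  expect_lt(abs(both$action - base$action), gap)
})

test_that("categorization boundaries follow the strict-above convention", {
  expect_equal(as.character(categorize(0, 0.5, 1.5)), "none")
  expect_equal(as.character(categorize(0.5, 0.5, 1.5)), "acceptable")
  expect_equal(as.character(categorize(1.5, 0.5, 1.5)), "high")
  expect_equal(as.character(categorize(1.5 + 1e-9, 0.5, 1.5)), "very_high")
  # monotone in pati
  grid <- categorize(seq(0, 3, by = 0.01), 0.5, 1.5)
  expect_true(all(diff(as.integer(grid)) >= 0))
  expect_error(categorize(-1, 0.5, 1.5), "non-negative")
  expect_error(categorize(1, 2, 1), "cannot exceed")
})

test_that("classification respects eligibility and stratum thresholds", {
  practices <- make_practices(sprintf("P%03d", 1:60))
  consult <- make_consultations(practices$practice_id, "cat", 2022:2024,
                                2000L)
  set.seed(5)
  rx <- dplyr::bind_rows(lapply(practices$practice_id, function(id) {
    make_rx(id, year = 2024, species = "cat", substances = "amoxicillin",
            therapy_days = sample(1:30, 1), n = sample(3:20, 1))
  }))
  rx$date <- rx$date + seq_len(nrow(rx))  # keep rows distinct
  run <- benchmark_cohort(rx, consult, practices, catalog,
                          years = 2022:2024)
  cls <- run$classified
  # nothing ever prescribed for dogs, but dogs registered -> dogs classified
  # as non-users; cats carry the real signal
  expect_true(all(cls$category[cls$species == "dog"] == "none"))
  cat_all <- cls[cls$species == "cat" & cls$scope == "all", ]
  thr <- run$thresholds[run$thresholds$species == "cat" &
                          run$thresholds$scope == "all", ]
  n <- thr$n_contributing
  share_very_high <- mean(cat_all$category == "very_high")
  share_high_up <- mean(cat_all$category >= "high")
  expect_lte(share_very_high, 0.05 + 1 / n)
  expect_lte(share_high_up, 0.25 + 1 / n)
})
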