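# Shared in-code fixtures: a prescription-row factory, small table builders
# and a scaled-down cohort config. No fixture files on disk.

make_rx <- function(practice_id = "P0001", year = 2024L, species = "dog",
                    vmp_id = "AMOX-250", substances = "amoxicillin",
                    therapy_days = 7, animals_treated = 1L,
                    indication = "skin", dosage_mg_per_kg = 12.5,
                    date = NULL, n = 1) {
  if (is.null(date)) date <- as.Date(sprintf("%d-06-15", year))
  out <- tibble::tibble(
    practice_id = practice_id, date = date, year = as.integer(year),
    species = species, vmp_id = vmp_id, substances = substances,
    therapy_days = therapy_days, animals_treated = as.integer(animals_treated),
    indication = indication, dosage_mg_per_kg = dosage_mg_per_kg
  )
  out[rep(seq_len(nrow(out)), each = n), ]
}

make_practices <- function(ids, declared_type = "companion_practice",
                           canton = "BE") {
  tibble::tibble(practice_id = ids, declared_type = declared_type,
                 canton = canton)
}

make_consultations <- function(ids, species = "dog", years = 2022:2024,
                               n = 1000L) {
  tidyr::crossing(practice_id = ids, species = species,
                  year = as.integer(years)) |>
    dplyr::mutate(n_consultations = as.integer(n))
}

# small but fully populated config for fast end-to-end tests
small_config <- function(seed = 1L) {
  cfg <- default_swiss_like_config(seed = seed)
  cfg$n_practices_per_type <- c(mixed = 20L, small_lt4500 = 30L,
                                small_ge4500 = 8L)
  cfg
}

# independent sort-and-interpolate quantile oracle (position 1 + q(n-1))
quantile_oracle <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- 1 + q * (n - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# independent per-row pATI oracle working directly off raw fields
pati_oracle <- function(rx, nbconsult, catalog, scope = "all") {
  total <- 0
  for (i in seq_len(nrow(rx))) {
    codes <- strsplit(rx$substances[i], ";", fixed = TRUE)[[1]]
    j <- match(codes, catalog$substance_code)
    td <- rx$therapy_days[i] + max(catalog$carryover_days[j])
    nbas <- if (scope == "critical") sum(catalog$is_critical[j])
            else length(codes)
    total <- total + td * nbas * rx$animals_treated[i]
  }
  total / nbconsult
}
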