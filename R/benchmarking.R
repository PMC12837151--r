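#' Linear-interpolation percentile
#'
#' The quantile convention used throughout the benchmarking: linear
#' interpolation between order statistics at position \eqn{1 + q(n - 1)}
#' (the default convention of R, `type = 7`). Exposed as its own operation
#' because the signal and action thresholds are defined directly in terms of
#' it.
#'
#' @param values Numeric vector, at least one finite value, no NAs.
#' @param q Quantile fraction in [0, 1] (0.75 = signal, 0.95 = action).
#' @return The interpolated percentile, a single number.
#' @export
#' @examples
#' percentile(1:100, 0.95)  # 95.05
percentile <- function(values, q) {
  if (length(values) == 0) abort("percentile of an empty vector")
  if (anyNA(values)) abort("values must not contain NA")
  if (any(q < 0 | q > 1)) abort("q must lie in [0, 1]")
  unname(quantile(values, probs = q, type = 7, names = FALSE))
}

#' Mean pATI contributions to threshold construction
#'
#' Thresholds are computed from per-practice means of the yearly pATI values
#' within each stratum, after two exclusions: years whose denominator was
#' imputed (`corrected`) are dropped, and null pATI values (non-users) are
#' dropped. A practice with no surviving year contributes nothing to the
#' thresholds of that stratum — it will still be classified against them.
#'
#' @param pati_table Output of [compute_pati_table()].
#' @return Tibble with `practice_id`, `practice_type`, `species`, `scope`,
#'   `mean_pati`, `n_years`.
#' @export
mean_pati_contributions <- function(pati_table) {
  pati_table |>
    dplyr::filter(!.data$corrected, .data$pati > 0) |>
    dplyr::group_by(.data$practice_id, .data$practice_type, .data$species,
                    .data$scope) |>
    dplyr::summarise(mean_pati = mean(.data$pati),
                     n_years = dplyr::n(), .groups = "drop")
}

#' Signal and action thresholds per stratum
#'
#' For every populated stratum (practice type x species x scope), the signal
#' threshold is the 75th and the action threshold the 95th percentile of the
#' contributing practices' mean pATI values.
#'
#' @param contributions Output of [mean_pati_contributions()].
#' @return Tibble with `practice_type`, `species`, `scope`, `signal`,
#'   `action`, `n_contributing`.
#' @export
compute_thresholds <- function(contributions) {
  out <- contributions |>
    dplyr::group_by(.data$practice_type, .data$species, .data$scope) |>
    dplyr::summarise(signal = percentile(.data$mean_pati, 0.75),
                     action = percentile(.data$mean_pati, 0.95),
                     n_contributing = dplyr::n(), .groups = "drop")
  if (nrow(out) < 12) {
    warn(paste0("thresholds computed for ", nrow(out),
                " of 12 possible strata; empty strata have no pair"))
  }
  out
}

#' Classify a pATI value against its stratum thresholds
#'
#' The four use categories, from low to high: `none` (null pATI, a
#' non-user), `acceptable` (positive, at or below the signal threshold),
#' `high` (above signal, at or below action), `very_high` (strictly above the
#' action threshold). "Above" is strict at both boundaries: a value exactly
#' at the signal threshold is acceptable, exactly at the action threshold is
#' high.
#'
#' @param pati Numeric vector of pATI values.
#' @param signal,action Thresholds (recycled along `pati`).
#' @return Ordered factor with levels `none < acceptable < high < very_high`.
#' @export
#' @examples
#' categorize(c(0, 0.2, 0.9, 2), signal = 0.5, action = 1.5)
categorize <- function(pati, signal, action) {
  if (any(pati < 0, na.rm = TRUE)) abort("pati must be non-negative")
  if (any(signal > action, na.rm = TRUE)) {
    abort("signal threshold cannot exceed action threshold")
  }
  lab <- dplyr::case_when(
    pati == 0 ~ "none",
    pati <= signal ~ "acceptable",
    pati <= action ~ "high",
    TRUE ~ "very_high")
  factor(lab, levels = abu_category_levels, ordered = TRUE)
}

#' Classify every benchmarked practice for one year
#'
#' Looks up each practice-species-scope pATI of the given year against its
#' stratum's thresholds. Practices with a corrected (imputed) denominator are
#' classified like any other — they are only excluded from threshold
#' construction. Passing an earlier year classifies it retrospectively
#' against the same threshold set.
#'
#' @param pati_table Output of [compute_pati_table()].
#' @param thresholds Output of [compute_thresholds()].
#' @param benchmark_year Year whose pATI values are classified.
#' @return Tibble with `practice_id`, `species`, `scope`, `practice_type`,
#'   `pati`, `corrected`, `category`. Rows whose stratum has no thresholds
#'   get `NA` category.
#' @export
classify_cohort <- function(pati_table, thresholds, benchmark_year) {
  yr <- pati_table[pati_table$year == benchmark_year, ]
  out <- dplyr::left_join(yr, thresholds,
                          by = c("practice_type", "species", "scope"))
  out$category <- factor(NA_character_, levels = abu_category_levels,
                         ordered = TRUE)[rep(1, nrow(out))]
  has <- !is.na(out$signal)
  out$category[has] <- categorize(out$pati[has], out$signal[has],
                                  out$action[has])
  out[, c("practice_id", "species", "scope", "practice_type", "pati",
          "corrected", "category")]
}
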