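#' Cluster-bootstrap comparison of a group quantile
#'
#' Compares the `q`-quantile of two groups of practice-level values (e.g.
#' cat vs dog pATI) while respecting that values are clustered within
#' practices — most practices contribute values to both groups. Practice ids
#' are resampled with replacement; each draw keeps all values of the drawn
#' practice in both groups, preserving the within-practice dependence that a
#' random practice effect models. The estimate is
#' `percentile(values_a, q) - percentile(values_b, q)`; the two-sided
#' p-value is the fraction of the bootstrap distribution of the difference
#' on the opposite side of zero, doubled and capped at 1.
#'
#' @param values_a,values_b Numeric value vectors of the two groups.
#' @param q Quantile fraction compared (0.5 = median).
#' @param clusters_a,clusters_b Cluster (practice) ids parallel to the value
#'   vectors; ids shared across groups are resampled jointly.
#' @param n_boot Number of bootstrap replicates (>= 200).
#' @param seed Optional integer seed for reproducibility.
#' @param conf_level Confidence level of the percentile interval.
#' @return List with `estimate`, `ci` (length-2), `p_value`, `n_boot`, `q`.
#' @export
#' @examples
#' set.seed(42)
#' a <- rlnorm(60); b <- rlnorm(60) * 2
#' ids <- sprintf("P%02d", 1:60)
#' bootstrap_quantile_diff(a, b, q = 0.5, ids, ids, n_boot = 500, seed = 7)
bootstrap_quantile_diff <- function(values_a, values_b, q,
                                    clusters_a, clusters_b,
                                    n_boot = 1000, seed = NULL,
                                    conf_level = 0.95) {
  if (length(values_a) != length(clusters_a) ||
      length(values_b) != length(clusters_b)) {
    abort("values and cluster ids must have equal lengths")
  }
  if (length(values_a) < 10 || length(values_b) < 10) {
    abort("each group needs at least 10 values for a stable quantile")
  }
  if (n_boot < 200) abort("n_boot must be at least 200")
  if (!is.null(seed)) set.seed(seed)

  split_a <- split(values_a, as.character(clusters_a))
  split_b <- split(values_b, as.character(clusters_b))
  ids <- union(names(split_a), names(split_b))
  n_cl <- length(ids)

  estimate <- percentile(values_a, q) - percentile(values_b, q)

  boot <- vapply(seq_len(n_boot), function(i) {
    draw <- sample(ids, n_cl, replace = TRUE)
    a <- unlist(split_a[draw], use.names = FALSE)
    b <- unlist(split_b[draw], use.names = FALSE)
    if (length(a) == 0 || length(b) == 0) return(NA_real_)
    percentile(a, q) - percentile(b, q)
  }, numeric(1))
  boot <- boot[!is.na(boot)]

  alpha <- 1 - conf_level
  ci <- unname(quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 7))
  p <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  list(estimate = estimate, ci = ci, p_value = p,
       n_boot = length(boot), q = q)
}
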