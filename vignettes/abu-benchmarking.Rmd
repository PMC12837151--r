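---
title: "Benchmarking antibiotic use in companion-animal practices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking antibiotic use in companion-animal practices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

National surveillance registries collect every antibiotic prescription that
veterinarians issue for cats and dogs, together with each practice's annual
number of consultations per species. Benchmarking turns this stream into a
per-practice signal: how much antibiotic pressure does a practice exert per
consultation, how does that compare to similar practices, and which
practices warrant attention? `abubench` implements such a pipeline
end-to-end, exercised on a synthetic cohort because real registry extracts
contain personal data of practices and are not public.

## The indicator

The core quantity is the practice-level antibiotic treatment indicator
(pATI), computed per practice, species and calendar year:

$$\mathrm{pATI} \;=\; \frac{\sum_{i=1}^{\mathrm{totVMP}} TD_i \times NbAS_i \times AT_i}{NbConsult}$$

where, for each prescription $i$ of a veterinary medicinal product (VMP),
$TD_i$ is the number of therapy days (administered days plus the
*carry-over* — the time a long-acting formulation remains effective, a
catalog property defaulting to 0), $NbAS_i$ the number of active substances
in the product, $AT_i$ the number of animals treated, and $NbConsult$ the
annual number of consultations for that species — the population at risk.
The same computation restricted to critical antibiotics (macrolides,
fluoroquinolones, 3rd/4th-generation cephalosporins), counting only the
critical substances of each product, yields the *critical pATI*. The
indicator is deliberately count-based rather than dose-based (no
DDDvet/DCDvet): it reads directly as "therapy days per consultation".

Two conventions are open in the formula and fixed here: carry-over is added
to the administered days *before* multiplying by the substance count, and
for combination products under the critical scope $NbAS_i$ counts critical
substances only.

## Eligibility, imputation, stratification

A pATI requires a trustworthy denominator. Per practice and species:

* no declared consultation count in *any* year of the window → no pATI at
  all (`no_nbconsult_any_year`);
* a missing year among declared years is imputed as the **maximum** of the
  declared years and flagged `corrected`. The maximum is deliberately
  conservative — it can only shrink the indicator, never inflate it, so a
  practice cannot look like a high user because of an imputation;
* fewer than 100 consultations in a year → ineligible for that year
  (`under_100`); such marginal reporters (emergency-only case loads,
  specialities) do not reflect typical use. The boundary is strict:
  exactly 100 is eligible.

Practices are compared within strata: self-declared mixed practices form
their own stratum regardless of volume; companion-animal practices and
clinics are split at **more than 4500 consultations per year** (strict),
evaluated per species on the benchmark year's count — a clinic can be
large for cats and small for dogs. When a practice crosses the 4500 line
between years, the benchmark-year stratum is used throughout, including for
its earlier years' values in threshold construction.

## Thresholds and categories

Within each stratum × species × scope, each practice contributes the mean
of its yearly pATI values after dropping corrected years and null (zero)
values. The **signal threshold** is the 75th percentile of these
contributions and the **action threshold** the 95th, with the quantile
convention of linear interpolation at position $1 + q(n-1)$ (R's default,
`type = 7`). Categories follow, with "above" strict at both boundaries:

| category | rule |
|---|---|
| `none` | pATI = 0 (non-user) |
| `acceptable` | 0 < pATI ≤ signal |
| `high` | signal < pATI ≤ action |
| `very_high` | pATI > action |

Classification uses the benchmark year's pATI; practices with corrected
denominators *are* classified (they are only excluded from threshold
construction). This asymmetry is the mechanism by which more than 5% of
practices can land above the 95th-percentile action value: the bound
"share above action ≤ 5% + 1/n" is a property of the percentile over its
own input values, and corrected practices are not among them. Earlier years
can be classified retrospectively against the same single threshold set.

Note one subtlety the test suite encodes: the ≤ 5% + 1/n bound transfers
from the contribution means to the benchmark-year values only insofar as a
practice's yearly value tracks its multi-year mean; strong year-over-year
swings can push the single-year share above the bound even without any
corrected denominator.

Under the type-7 convention, thresholds are exactly invariant to permuting
the contributors but only approximately invariant to duplicating the whole
contributor set: duplication shifts the interpolation position by less than
one rank, i.e. the threshold by at most one gap between adjacent order
statistics.

## Quantile comparisons with a cluster bootstrap

Species and practice-type contrasts (e.g. "the median cat pATI exceeds the
median dog pATI") compare group quantiles of values that are clustered
within practices — most practices contribute both a cat and a dog value.
`bootstrap_quantile_diff()` resamples *practice ids* with replacement,
keeping all of a drawn practice's values in both groups, which preserves
the within-practice dependence that a random practice effect would model.
The estimate is the difference of type-7 group quantiles; the two-sided
p-value is twice the smaller tail of the bootstrap distribution around
zero, capped at 1. We chose this design over fitting a linear quantile
mixed model: the scientific content of the comparison is the quantile
contrast itself, not the estimator's machinery, and the bootstrap makes the
clustering assumption explicit and testable. Its calibration is verified by
simulation in the test suite: under a null with a shared practice effect
(200 clusters, 500 replicates, 200 simulation runs) the rejection rate at
$\alpha = 0.05$ stays within 5% ± 2 points. Defaults: 1000 replicates, 95%
percentile interval; groups below 10 values are refused because extreme
quantiles of tiny groups are unstable.

## The synthetic cohort generator

`generate_cohort()` emulates a three-year national registry extract so the
whole pipeline is testable without confidential data. Per practice, species
and year:

* **practice size**: annual consultations are log-normal around the
  stratum- and species-specific median (defaults: 1481/1602 for dogs/cats
  in mixed practices, 1612/1671 in smaller companion practices, 5812/5545
  in large ones), with between-practice `sdlog = 0.8` — only medians,
  means and maxima of the real distributions are published, and 0.8 puts
  the max/median ratio on the published order. A practice's size is drawn
  once and jittered year to year with `sdlog = 0.1`: practice volume is
  stable, and this stability is what makes multi-year mean contributions
  representative of single benchmark years.
* **prescribing propensity**: the probability that a consultation yields an
  antibiotic treatment is the configured stratum median (12.0%/21.1% for
  dogs/cats in mixed practices, 9.8%/15.0% and 9.8%/13.6% in the two
  companion strata) times a per-practice log-normal multiplier
  (`sdlog = 0.4`, median 1, shared across species). Between-practice
  heterogeneity is essential: without it the contributor distribution is
  pure counting noise and "high users" do not exist as a phenomenon. With
  0.4, the action threshold sits roughly twice the median, matching the
  published observation that thresholds can run about twice as high
  between comparable groups. The multiplier's median of 1 keeps every
  configured median recoverable.
* **treatments**: treated animals per cell are
  $\mathrm{Binomial}(NbConsult, p)$; each treatment becomes one
  single-animal prescription (companion animals are treated individually;
  multi-animal rows exist only in unit fixtures), dated uniformly within
  the year, with administered days $1 + \mathrm{Poisson}(\mu - 1)$
  (positive integers, one tunable parameter; default mean 5 d puts the
  median pATI on the published scale of roughly 0.6 for dogs and 1.0–1.3
  for cats), and a critical product with the configured stratum probability
  (5.2–6.8% for dogs, 20.0–27.5% for cats). Products come from a small
  synthetic formulary resolved against the bundled substance catalog; one
  long-acting injectable (cefovecin, carry-over 13 d) exercises the
  therapy-day carry-over path.
* **messiness**: 10% of practice-years withhold their consultation
  declaration (treatments still occur — downstream this triggers
  imputation), 3% of practice-species are non-users, and 5% of practices
  are sub-100-consultation reporters destined for exclusion.

What the generator does **not** emulate: seasonality, indication-specific
prescribing, dose heterogeneity beyond a bimodal per-product dosage,
shelter-medicine effects that inflate cat treatments, correlations between
practice size and prescribing style, and reporting errors other than exact
duplicates. Green pipeline tests on this cohort therefore demonstrate the
*mechanics* (eligibility, imputation, thresholds, classification,
reporting) and the statistical calibration of the generator itself — not
that real Swiss distributions are reproduced, which is impossible without
the confidential data.

## Numerical and degenerate-input choices

* Quantiles: `type = 7` everywhere (thresholds, bootstrap, summaries).
* Printed shares: half-away-from-zero rounding to one decimal
  (`ratio_pct()`), the convention consistent with published ratios such as
  9/32 → 28.1 and 15/32 → 46.9; base `round()` would give 28.2.
* Empty prescription sets: pATI 0, summaries of zeroes, empty top-10.
* Strata with no contributors get no threshold pair (warning); their
  practices remain unclassified (`NA`) rather than silently compared to
  another stratum.
* Modal dosage per product: most frequent value, smallest on ties.
* Log-scale display: a null pATI cannot be drawn on a log axis; report
  series carry a documented floor of half the smallest positive comparable
  value, tagged as metadata rather than baked into the numbers.
* Exact duplicate rows (all fields equal, including the prescription date)
  are collapsed; rows differing in any field are kept.

## Problem sizes used by the shipped checks

The package's own verification runs on deliberately scaled cohorts: unit
fixtures of 1–300 practices, generator-calibration checks at 200 practices
per stratum (one seeded draw), bootstrap calibration at 200 clusters × 500
replicates × 200 runs, and full-pipeline determinism on a 58-practice
cohort. The full Swiss-scale default (686 practices, ~1M prescriptions)
runs in seconds and is what `scripts/acceptance.R` executes.

## Known limitations

* The outlier rule is a bounded concretization (therapy days in (0, 365],
  animals treated in [1, 10000]); registry-grade error feedback loops are
  out of scope.
* Whether the 4500-consultation split should use one year, the mean or the
  maximum across years is unspecified upstream; this implementation
  documents and uses the benchmark year.
* The acceptance of a practice's mean contribution under a stratum uses the
  benchmark-year stratum even for earlier years.
* p-values from the cluster bootstrap are granular at 1/`n_boot` and the
  percentile interval can be slightly anticonservative for extreme
  quantiles in small strata.
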