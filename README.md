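# abubench

Practice-level benchmarking of antibiotic use (ABU) in cats and dogs.

National registries of veterinary antibiotic prescriptions make it possible
to tell every practice how its antibiotic pressure compares with that of
similar practices — the backbone of antimicrobial-stewardship programmes
for companion animals. `abubench` implements such a benchmarking pipeline
for epidemiologists and veterinary public-health analysts: from raw
prescription, consultation and practice-registry tables to per-practice
benchmark reports, cohort summaries and statistical group comparisons. A
seeded synthetic cohort generator stands in for the confidential registry
data, so everything here runs out of the box.

## The indicator

The central statistic is the practice-level antibiotic treatment indicator
(pATI), computed per practice, species and year:

```
         sum over prescriptions i of  TD_i × NbAS_i × AT_i
pATI  =  ---------------------------------------------------
                           NbConsult
```

with `TD_i` the therapy days of prescription *i* (administered days plus
the carry-over of long-acting formulations), `NbAS_i` the number of active
substances in the product, `AT_i` the animals treated, and `NbConsult` the
practice's annual consultations for that species (the population at risk).
A parallel *critical pATI* counts only critical antibiotics (macrolides,
fluoroquinolones, 3rd/4th-generation cephalosporins).

Practices are compared within strata (mixed practices; companion-animal
practices/clinics at most 4500 consultations per year; above 4500 — split
per species). Within each stratum × species × scope, the **signal**
threshold is the 75th percentile and the **action** threshold the 95th
percentile of the contributing practices' multi-year mean pATI (corrected
denominators and non-users excluded). Every benchmarked practice is then
classified: `none`, `acceptable`, `high` (above signal), or `very_high`
(above action).

## Worked example

```r
library(abubench)

cfg <- default_swiss_like_config(seed = 42)
cfg$n_practices_per_type <- c(mixed = 60L, small_lt4500 = 120L,
                              small_ge4500 = 20L)
cohort  <- generate_cohort(cfg)
catalog <- default_catalog()
run <- benchmark_cohort(cohort$prescriptions, cohort$consultations,
                        cohort$practices, catalog, years = 2022:2024)
run
#> Antibiotic-use benchmark, 2022 - 2024 (benchmark year 2024)
#>   practices: 200 | benchmarked: 189 | threshold contributors: 189
#>   clean prescriptions: 408390 ( 1223 duplicates, 0 outliers dropped )

subset(run$thresholds, scope == "all")
#> # A tibble: 6 × 6
#>   practice_type species scope signal action n_contributing
#>   <chr>         <chr>   <chr>  <dbl>  <dbl>          <int>
#> 1 mixed         cat     all    2.02    2.42             57
#> 2 mixed         dog     all    1.09    1.39             57
#> 3 small_ge4500  cat     all    1.31    2.00             29
#> 4 small_ge4500  dog     all    0.723   1.20             19
#> 5 small_lt4500  cat     all    1.45    2.21             98
#> 6 small_lt4500  dog     all    0.877   1.39            110

table(subset(run$classified, scope == "all")$category)
#>       none acceptable       high  very_high
#>          8        275         74         21
```

The thresholds read directly in therapy-days-per-consultation: a dog
consultation in a mixed practice of this cohort carries a median antibiotic
pressure well below the 1.09 signal value, and a practice above 1.39 for
dogs would be flagged `very_high`. Cat thresholds run roughly twice the dog
thresholds, matching the species difference the indicator is designed to
expose. The classification table counts practice × species pairs in the
2024 benchmark year, including non-users (`none`).

Is the cat–dog difference systematic? Compare group medians with the
cluster bootstrap (practices contribute both a cat and a dog value, so ids
are resampled jointly):

```r
contrib <- subset(run$contributions, scope == "all")
cats <- subset(contrib, species == "cat")
dogs <- subset(contrib, species == "dog")
bootstrap_quantile_diff(cats$mean_pati, dogs$mean_pati, q = 0.5,
                        cats$practice_id, dogs$practice_id,
                        n_boot = 500, seed = 7)
#> $estimate
#> [1] 0.4233...   # median cat pATI minus median dog pATI
#> $ci
#> [1] 0.388 0.494
#> $p_value
#> [1] 0
```

Per-practice reports (the practice's own pATI trajectory against the
anonymized distribution of comparable practices, plus a summary of its own
use) come from `build_report()` / `render_report()`, and
`run_pipeline(cfg, out_dir)` executes the whole chain — simulate, read,
clean, compute, benchmark, summarise, report — deterministically for a
given seed. A thin command-line wrapper is installed as `exec/abu-bench`
(`abu-bench run-all --seed 42 --out DIR`).

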