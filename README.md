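# circsleep

Multimodal circadian sleep-health analysis for adolescent cohorts, as a
tidyverse-native R package. `circsleep` turns three raw data streams —
epoch-level wrist-actigraphy counts, sleep diaries, and timed salivary
melatonin concentrations — plus a self-report survey into per-subject
circadian health measures and covariate-adjusted group comparisons of
mental-health outcomes. It is written for sleep and circadian researchers who
want the full chain (device counts → sleep timing → circadian phase →
dichotomous risk groups → effect sizes) to be scripted, inspectable, and
reproducible, and it ships a seeded synthetic cohort generator so the entire
pipeline runs and is testable with no participant data.

## What it computes

**Sleep/wake scoring (Sadeh).** One-minute activity counts are scored with the
Sadeh discriminant

PS = 7.601 − 0.065·MW5 − 1.08·NAT − 0.056·SD6 − 0.703·LG

where MW5 is the mean count in the 11-minute window centred on the scored
minute, NAT the number of minutes in that window with counts in [50, 100),
SD6 the population SD of the scored minute and its 5 predecessors, and LG =
ln(count + 1); a minute is sleep when PS ≥ 0. Nightly sleep onset is the
first run of ≥ 10 consecutive sleep minutes after diary in-bed time, offset
the end of the last such run; midsleep is their midpoint. All clock
arithmetic lives on a noon-to-noon axis (minutes since 12:00), so times that
straddle midnight subtract and average without wrap-around.

**Circadian phase (DLMO).** Dim-light melatonin onset is the clock time at
which the piecewise-linear interpolant of the 30-min saliva samples first
crosses 4 pg/mL in a sustained rise (the next sample must stay above
threshold, rejecting contamination spikes). Sessions that never reach the
threshold, start above it, or retain fewer than 8 samples get explicit
validity statuses instead of estimates.

**Circadian metrics and groups.** Phase angle of entrainment = mean sleep
onset − DLMO; social jetlag = |mean free-night onset − mean school-night
onset|. Four dichotomies follow printed cut points: circadian phase (DLMO
before vs at/after 22:00), alignment (phase angle within [2 h, 4 h] vs
outside), social jetlag (≤ 1 h vs > 1 h), chronotype (MEQ total ≤ 41
eveningness vs ≥ 42).

**Group comparisons.** For each grouping × outcome (depression, anxiety,
stress, cognitive reappraisal, expressive suppression), an OLS general linear
model adjusts for sex, pubertal development, and income band; the group
effect is the partial (type-III) F, reported with the two-tailed p and
partial eta squared, η²ₚ = F·df₁ / (F·df₁ + df_error), labelled against the
0.01 / 0.06 / 0.14 benchmarks.

## Worked example

```r
library(circsleep)

# a fully synthetic 52-subject cohort with a planted phase->depression effect
cohort <- generate_cohort(cohort_config(seed = 42))
res <- analyze_cohort(cohort)

res$ns
#> # A tibble: 4 × 4
#>   grouping             n n_reference n_risk
#>   <chr>            <int>       <int>  <int>
#> 1 phase_group         47          29     18
#> 2 alignment_group     38          22     16
#> 3 sjl_group           43          36      7
#> 4 chronotype_group    52          42     10

dplyr::filter(tibble::as_tibble(res$comparisons),
              grouping == "phase_group", outcome == "depression") |>
  dplyr::select(n1, m1, n2, m2, F, df_error, p, eta_p2)
#> # A tibble: 1 × 8
#>      n1    m1    n2    m2     F df_error      p eta_p2
#>   <int> <dbl> <int> <dbl> <dbl>    <int>  <dbl>  <dbl>
#> 1    23  9.83    18  14.4  6.91       36 0.0125  0.161
```

Read: of the 52 simulated adolescents, 47 had a valid DLMO estimate and 43
valid actigraphy. Among the 41 complete cases for the phase analysis, the 18
late-phase adolescents (DLMO at/after 22:00) report a raw mean depression
score of 14.4 against 9.8 for early phase; adjusting for sex, pubertal
status, and income, the group effect is F(1, 36) = 6.91, p = 0.013, η²ₚ =
0.16 — one seeded draw around the generator's planted effect of 0.13.
`autoplot(res$comparisons)` shows all 20 effect sizes against the benchmarks,
and `tidy()` / `glance()` work on any single fit from `fit_group_model()`.

`run_pipeline()` wraps the same chain (from raw CSVs or a simulate block) and
writes a diff-friendly bundle: nightly TSV, DLMO JSON, profile TSV, the
Table-style results TSV/JSON, cohort descriptives, and the serialized run
configuration.

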