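---
title: "Methods: from wrist counts and saliva to circadian effect sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wrist counts and saliva to circadian effect sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circsleep)
```

`circsleep` implements a complete multimodal circadian sleep-health analysis
for adolescent cohorts: actigraphy-based sleep timing, salivary-melatonin
circadian phase, derived alignment metrics, dichotomous risk groupings, and
covariate-adjusted group contrasts on mental-health outcomes. This vignette
explains each model, the parameters that matter, the synthetic-data design,
and the numerical choices — in enough detail that a reader can audit or
re-derive every number the package produces.

## The noon-to-noon clock axis

Every clock time in the package is represented as minutes since 12:00 of the
night's reference date (`clock_to_noon()` / `noon_to_clock()`). Bedtimes,
sleep onsets, DLMO, and melatonin sampling sessions all straddle midnight;
on the noon axis 23:00 (660) precedes 00:30 (750), so differences, means,
and midpoints are ordinary arithmetic. There is no wrap-around case anywhere
downstream, which removes an entire class of sign errors from phase-angle
and social-jetlag computations.

## Sleep/wake scoring and nightly summaries

Minute-level counts (30-s device epochs are summed in pairs first; the
discriminant below was developed on 1-min epochs) are scored with the Sadeh
linear discriminant

$$PS = 7.601 - 0.065\,MW5 - 1.08\,NAT - 0.056\,SD6 - 0.703\,LG,$$

sleep iff $PS \ge 0$, with MW5 the mean count over the 11-minute window
centred on the scored minute, NAT the count of window minutes with activity
in $[50, 100)$, SD6 the population SD of the scored minute and its five
predecessors, and $LG = \ln(\text{count}+1)$. Two numerical conventions are
fixed deliberately:

* **Boundary padding.** Windows that extend beyond the series are padded
  with zero counts, so the first and last five minutes have deterministic
  labels rather than depending on partial-window conventions.
* **No count ceiling by default.** Published variants disagree about
  clipping extreme counts; the default is the bare formula, with a
  configurable `cap` (e.g. 300) for sensitivity analysis.

Nightly onset is the start of the first run of at least `onset_run = 10`
consecutive sleep minutes at/after diary in-bed time; offset is the minute
after the last such run before out-of-bed time. The 10-minute run rule is a
declared default matching common device-software behaviour — the source
device's rule is not public — and is exposed as a parameter. Midsleep is the
onset/offset midpoint, and duration their difference; both follow exactly
from the run rule.

Diaries take precedence over inference. A night falls back to
`infer_bed_times()` only when the diary entry is missing or measurably
contradicts the trace: mean activity above `wake_threshold = 40` counts/min
in the 30 min after reported in-bed, or every minute below it in the 30 min
before reported rise. The inference itself anchors on the longest
low-activity block of the night (trailing 10-min mean below the threshold,
at least 3 h long), takes in-bed as the start of the last strictly
decreasing run of 10-min mean activity entering that block, and out-of-bed
as the first subsequent minute whose forward 30-min mean exceeds the
threshold. This replaces a joint-manual-review step with a reproducible
rule; the threshold (40 counts/min) is the conventional low-activity bound
for wrist counts and is configurable.

Nights with under 80% of expected epochs in the in-bed window are excluded
with an explicit status (`min_coverage`, configurable), mirroring
non-compliance exclusions in field studies. Excluded nights remain in the
nightly table — counts always reconcile.

## DLMO estimation

A melatonin session is planned to start 5 h before and end 1 h after the
participant's typical bedtime, sampled every 30 min. The inclusive grid has
13 points while protocols commonly count 12 samples; the reader accepts
either and the session-planning helper reports the 13 nominal times.

DLMO is the first *sustained* crossing of the 4 pg/mL threshold by the
piecewise-linear interpolant of the samples: the crossing pair $(c_i <
4 \le c_{i+1})$ qualifies only if the following sample (when one exists) is
also at/above threshold. The sustained rule rejects single-sample
contamination spikes and can be disabled. Linear interpolation within the
bracketing pair gives minute-level resolution — needed because DLMO enters
phase-angle arithmetic — and a `step` mode (first supra-threshold sample
time) exists for sensitivity analysis. Whether the original analysis
interpolated or stepped is unknowable from the published description; linear
is the default because the downstream phase-angle cut points are in minutes.

Sessions get exactly one of four statuses: `ok`, `never_above_threshold`
(no sustained rise), `never_below_threshold` (already at/above threshold at
the first sample), or `insufficient_samples` (fewer than 8 retained samples,
preserving at least 3.5 h of coverage; the protocol publishes no minimum, so
8 is a declared choice). On a 30-min grid the interpolation error for a
convex baseline-then-rise profile is bounded by half the sampling interval;
the test suite verifies ≤ 15 min against the closed-form crossing and
1-second agreement with a dense-grid search of the interpolant.

## Circadian metrics and dichotomies

Per subject: mean sleep onset is the noon-axis mean over all valid nights;
phase angle of entrainment is mean onset minus DLMO; social jetlag is the
absolute difference between mean free-night and mean school-night onsets. A
night is *free* when its morning falls on Saturday or Sunday. The three
fixed-bedtime stabilization nights (8–10 of the monitoring period) are
included in mean onset — the phase-angle definition averages over the whole
period — but excluded from social jetlag by default, because
schedule-constrained nights carry no naturalistic weekday/weekend contrast
(`include_stabilization` reverses this).

The four groupings follow the printed cut points exactly, with boundary
conventions as printed: DLMO before 22:00 = early, at/after = late; phase
angle within $[120, 240]$ min = aligned, below 2 h or above 4 h =
misaligned; social jetlag ≤ 60 min = minimal, > 60 = present; MEQ ≤ 41 =
eveningness, ≥ 42 = intermediate-to-morningness. Missing inputs yield
missing labels, never defaults. Each analysis then uses every subject whose
modalities support it (phase needs DLMO; social jetlag needs actigraphy;
alignment needs both; chronotype needs neither), so per-analysis Ns differ
by design and are reported, not hidden.

## Group models and effect sizes

Each grouping × outcome cell is an OLS fit of
`outcome ~ group + sex + pds_total + income_band` on complete cases
(listwise deletion; income "declined to report" is missing). The group
effect is the partial (type-III) F from comparing the full model against the
model without the group column — identical to the squared t of the group
coefficient for a single-df effect — with
$\eta_p^2 = F \cdot df_1 / (F \cdot df_1 + df_{error})$ and labels at the
0.01/0.06/0.14 benchmarks. Group descriptives are raw means/SDs, not
adjusted means, matching how such tables are conventionally printed. The
default three-covariate set is chosen because the published error dfs (33 at
n = 38; 36 at n = 41) are consistent with five design columns; a
two-covariate variant (`covariates = c("sex", "pds_total")`) is one argument
away, and the error df is always reported so either convention is auditable.
No multiplicity correction is applied; the result table records the number
of tests, and the `interpret` flag marks cells at or above the medium
(0.06) benchmark — the reporting rule appropriate to small samples.

Degenerate designs (constant or aliased covariates, one-level groups, empty
cells) raise errors naming the offending column; the grid runner converts
them to missing-statistics rows with warnings so one broken cell cannot
abort a report.

## The synthetic cohort generator

The generator's defaults are the study conditions: 52 subjects, 10
monitoring nights starting midweek, DLMO 21:30 ± 71 min, phase angle
105 ± 74 min truncated to the observed 9–232 min range, social jetlag mean
40 SD 79 min, MEQ 47.15 ± 6.48 correlated −0.4 with DLMO, sleep duration
444 ± 48 min, outcome means/SDs at their observed values, 9/52 subjects
with no usable actigraphy and 5/52 with invalid melatonin sessions (3
never-above, 2 never-below, sampled disjointly), and a single planted
effect: phase group on depression with target $\eta_p^2 = 0.13$.

Design choices worth knowing:

* **The latent DLMO is the crossing time.** Each subject's drawn DLMO *is*
  the 4 pg/mL crossing; the melatonin profile (flat baseline $b \sim
  U(0.5, 2.5)$ pg/mL, then a linear rise $r \sim U(3, 8)$ pg/mL/h, with
  multiplicative lognormal noise) places its rise start at
  $\text{DLMO} - 60(4-b)/r$ min. The estimator's ground truth is therefore
  closed-form, and a linear (not sigmoid) rise keeps it so; profile shape is
  a declared convention, not an estimate from any assay.
* **Social jetlag is generated as the quantity the pipeline computes.** A
  per-subject free-night delay shifts free-night onsets; school-night onsets
  are counter-shifted so the 10-night mean onset equals DLMO + phase angle
  exactly. The delay is gamma-distributed with the configured mean/SD —
  the observed SJL marginal (mean 40, SD 79 min, support ≥ 0) has a
  coefficient of variation near 2, which no zero-truncated normal can
  attain — and capped at the observed 3:34 maximum to keep night windows
  physical, with the gamma mean re-solved so the capped mean still equals
  the configured one. Likewise the phase-angle truncation would shift its
  mean by ~7 min, so the latent location is re-solved to make the truncated
  mean equal the configured 1:45.
* **Activity traces.** Wake epochs draw Gamma(shape 2, mean 180) counts;
  sleep epochs are 0 with probability 0.9, else Gamma(shape 1, mean 20).
  Between diary in-bed and sleep onset (a 4–7 min gap) counts taper to zero
  by a quartic ramp, and symmetrically after offset. The taper is steeper
  than a linear ramp on purpose: the diary-discrepancy trigger averages the
  30 min after in-bed against the 40 counts/min threshold, and a linear
  ramp from wake-level counts would trip it on essentially every generated
  night, contradicting the premise that generated diaries are consistent
  with their traces.
* **Outcome calibration.** Outcomes are
  $\mu + \beta\,\text{risk} + \gamma_{sex}\,\text{sex} +
  \gamma_{pds}\,\text{PDS} + \varepsilon$ with centred regressors. For a
  planted effect, the estimated $\eta_p^2$ of a 1-df effect is noncentral
  Beta$(\tfrac12, \tfrac{m}{2}, \lambda)$ distributed, so the generator
  solves $\lambda$ from $E[\hat\eta_p^2] = \text{target}$ via the
  Poisson-mixture series for the noncentral Beta mean, then sets $\beta =
  \sigma\sqrt{\lambda / \tilde n}$ with $\tilde n$ the sum of squares of the
  group indicator *residualized on the realized covariates* (naive
  $n_1 n_2 / n$ ignores chance group–covariate correlation and attenuates
  the planted effect). $\sigma$ is then chosen so the marginal outcome SD
  matches its configured value. Calibration is against true group labels;
  end-to-end recovery through the measured pipeline carries a small
  attenuation from ~2% phase-group misclassification near the 22:00
  boundary, which is left in as honest measurement behaviour.
* **Determinism.** All truncated/capped draws go through inverse-CDF
  transforms of `runif`, so the RNG stream length never depends on
  parameter values; one seed yields byte-identical emitted files.

What the generator does *not* emulate: melatonin pharmacokinetics or light
exposure, naps and daytime wear, device-specific count transduction,
within-questionnaire item structure, or correlated missingness (dropout is
subject-level and random). Passing recovery tests therefore demonstrates the
pipeline's correctness and calibration under the declared data model, not
robustness to every artefact of field recordings.

## Problem sizes and verification layout

The test suite checks each estimator against an independent oracle:
brute-force per-window recomputation of the Sadeh discriminant on random
200-minute traces; dense 1-second grid search of the melatonin interpolant
(500 noise-free profiles in the acceptance suite); explicit normal-equations
OLS and textbook one-way-ANOVA sums of squares on 100 random small designs;
and closed-form crossing times for generated profiles. End-to-end recovery
runs 50 replicate 52-subject cohorts in the test suite and 100 in
`scripts/acceptance.R` — at 50 replicates the Monte Carlo SE of the mean
recovered $\eta_p^2$ is about 0.012, comfortably inside the ±0.02
calibration band being verified. Published p-values and effect sizes are
reproduced analytically from their printed F statistics and the realized
design dfs, to within the precision those rounded inputs support.

## Known limitations

* The Sadeh run-rule onset/offset and all activity thresholds are declared
  defaults, not recovered device settings; conclusions about a specific
  device's output require matching its configuration.
* DLMO sessions whose concentrations start near the threshold can be
  "rescued" by assay noise into marginally valid estimates; the validity
  taxonomy flags designed exclusion cases but cannot detect a noisy
  borderline baseline.
* The planted-effect machinery calibrates one effect per outcome cleanly;
  several simultaneous effects on one outcome share a residual-variance
  budget and are solved independently, which is approximate when their
  groups are correlated.
* Group comparisons are cross-sectional OLS contrasts; no causal or
  longitudinal interpretation is implied by the package's outputs.
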