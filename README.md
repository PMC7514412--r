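# esin

Severity and complexity classification of emergency department (ED) visits,
in the style of the five-level Emergency Severity Index (ESI), computed
retrospectively from chart-abstraction survey variables (ESI-N).

## The problem

US emergency departments have no mandated triage standard. National
ED survey data (NHAMCS-ED style visit records) carry a recorded
"immediacy" item, but it is frequently unknown or not performed, and many
hospitals use triage scales with fewer than five levels, biasing national
acuity estimates. `esin` derives an objective, reproducible five-level
severity/complexity index for each visit from items with low nonresponse:
the coded presenting complaint (up to three reason-for-visit codes), a
small set of resuscitation flags, vital-sign extremes, the pain score, and
a count of diagnostic/therapeutic resources actually used.

The index is assigned by a stepwise rule set:

1. **Level 1 — Immediate**: an arrest/unconscious/dead-on-arrival
   complaint code or checkbox, endotracheal intubation, CPR, or an adult
   vital extreme (pulse ≤ 50 or systolic BP ≤ 80, with age > 25);
2. **Level 2 — Emergent** (if not level 1): one of fifteen emergent
   complaint conditions (some age-gated, e.g. abdominal pain in patients
   65+), or a danger-zone vital sign for the patient's age band;
3. **Level 3 — Urgent** (if not level 1–2): more than one resource used,
   severe pain, pediatric fever, or a motor-vehicle accident;
4. **Level 4 — Semi-urgent**: exactly one resource used;
5. **Level 5 — Nonurgent**: no resources used.

Missing fields never fire a criterion (a visit with missing vitals keeps
its level rather than becoming missing), so the index is total. Resources
are counted the ESI way — all blood tests one resource, each imaging
modality its own, ECG, IV fluids, parenteral medications, procedures
(complex ones count double) — and the whole rule content (code sets,
thresholds, age bands, resource groups) lives in an editable YAML/JSON
configuration, not in code.

Estimation is design-based: weighted shares, group means and
outcome-by-level tables carry Taylor-linearized 95% CIs over the masked
stratum/PSU design variables (with an explicit SRS fallback), and every
estimate from fewer than 30 unweighted records is flagged unreliable.

The package is aimed at health-services researchers who need a case-mix /
acuity adjuster for ED survey data, and ships a synthetic-record generator
with planted ground-truth levels so the full pipeline runs and is testable
without any data download.

## Worked example

```r
library(esin)

cfg <- load_criteria()                      # shipped rule configuration
gen <- generate_records(mixture_spec(n = 5000, seed = 2026), cfg)
classified <- classify_table(gen$records, cfg)
#> classified 5000 visits; unweighted level tallies 1-5: 56, 1281, 2119, 755, 789

weighted_share_by_level(classified)
#> # A tibble: 5 × 8
#>   level statistic  value ci_low ci_high    se unweighted_n reliable
#>   <int> <chr>      <dbl>  <dbl>   <dbl> <dbl>        <int> <lgl>
#> 1     1 proportion  1.09  0.636    1.54 0.230           56 TRUE
#> 2     2 proportion 26.2  24.7    27.8   0.789         1281 TRUE
#> 3     3 proportion 41.6  40.3    42.9   0.665         2119 TRUE
#> 4     4 proportion 15.4  14.3    16.5   0.553          755 TRUE
#> 5     5 proportion 15.7  14.6    16.7   0.547          789 TRUE
```

The `value` column is the survey-weighted percent of visits at each level
with its 95% CI: under the default study mixture most visits are urgent
(level 3), and only about 1% are immediate. The weighted mean level:

```r
mean_level_by_group(classified)
#> 1 all   mean       3.18   3.16    3.21 0.0141         5000 TRUE
```

Admission rates rise steeply with acuity (level 1 ≈ 47%, level 5 ≈ 3%
in this cohort):

```r
outcome_by_level(classified, "admitted")   # statistic == "rate" rows
#>  level statistic value ci_low ci_high    se unweighted_n reliable
#>      1      rate 46.68  34.15   59.22 6.395           56     TRUE
#>      2      rate 16.70  14.25   19.16 1.254         1281     TRUE
#>      3      rate 12.65  10.90   14.39 0.891         2119     TRUE
#>      4      rate  2.65   1.13    4.17 0.774          755     TRUE
#>      5      rate  2.75   1.54    3.95 0.613          789     TRUE
```

Classifying a single hand-built record, with its audit trail of every
criterion that fired:

```r
rec <- coerce_records_public(tibble::tibble(
  visit_id = "example", age_years = 30L, pulse_bpm = 45L,
  services = "CBC|XRAY", visit_weight = 1
))
out <- assign_level(rec, cfg)
out$esin_level
#> [1] 1
out$matched_criteria
#> [1] "1:Pulse ≤50 and age >25|3:More than 1 resource used"
```

Raw survey-style files are read with `read_puf(path, year)` (fixed-width
ASCII with per-year dialect files handling sentinel codes, implied
decimals and variable renames), and a command-line front-end is installed
as `exec/esin` with `classify`, `summarize` and `simulate` subcommands.

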