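---
title: "ESI-N: a retrospective severity and complexity index for ED visits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ESI-N: a retrospective severity and complexity index for ED visits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esin)
```

## The index and its assumptions

`esin` assigns each emergency-department visit one of five ordinal
severity/complexity levels (1 = Immediate … 5 = Nonurgent) from variables
routinely abstracted into national ED survey records. Because it is
computed after the visit, it differs from prospective triage in two
deliberate ways: it keys on the *coded presenting complaint* (up to three
reason-for-visit codes) rather than the final diagnosis, and it counts
resources *actually used* rather than predicted. The assignment is a
stepwise minimum: level-1 criteria (arrest/unconscious/dead-on-arrival
complaints, the DOA checkbox, endotracheal intubation, CPR, adult pulse
≤ 50 or systolic BP ≤ 80 with age > 25) are checked first; failing those,
level-2 criteria (fifteen emergent complaint conditions, some age-gated,
plus age-banded danger-zone vitals); failing those, level-3 floors (more
than one resource, severe pain, pediatric fever, motor-vehicle accident);
otherwise the resource count alone separates levels 3/4/5 as > 1 / 1 / 0.

Two structural assumptions follow. First, *missingness is conservative*: a
missing field never fires a criterion, so blanking vitals can only move a
visit toward a less acute level, and every record — even one that is
entirely missing apart from its weight — receives a level (it falls
through to level 5 with zero resources). This is the package's answer to
the item nonresponse that afflicts the recorded "immediacy" variable: the
index is total by construction. Second, *all rule content is data*: code
sets, thresholds, age bands and resource groups live in a YAML/JSON
configuration validated at load time, because survey variable names and
code schemes drift across years and the published description of the
procedure names conditions and variables, not numeric code lists.

## Parameters that matter

* **Adult level-1 vital thresholds** — pulse ≤ 50 beats/min and systolic
  BP ≤ 80 mmHg, both gated to age > 25 completed years, inclusive
  comparisons as printed in the source procedure. These are shipped
  verbatim and the loader treats them as canonical.
* **Danger-zone vital bands** (level 2) — the published procedure states
  which variables enter (age in days/years, pulse, temperature) but not
  the numeric ceilings. The shipped defaults follow the ESI danger-zone
  convention: pulse > 180 under 90 days (with fever ≥ 100.4 °F in that
  band), > 160 to age 3, > 140 to age 8, > 100 above; strict exceedance,
  because the criterion is framed as *exceeding* a threshold. These are
  documented reconstructions, editable in `criteria.yaml`.
* **Age gates** — "(elderly)" ≥ 65 years, "(youth)" < 2 years,
  "(infants)" < 1 year; the source names the categories but not the
  cutoffs, so these sit in configuration. Ages are completed years at
  visit; under one year the day count (`age_days`) is authoritative, and
  band lookup converts years at 365.25 days.
* **Severe pain** — the top category (4) of the five-level 0–4 pain
  scale. A five-level scale is coarser than the 10-point clinical one;
  taking only the top category is the conservative reading.
* **Pediatric fever** — age < 2 years with temperature ≥ 100.4 °F
  (38 °C), the standard fever threshold.
* **Resource groups** — ESI convention: all blood tests one resource;
  each imaging modality separately; ECG; IV fluids; parenteral
  medications; simple procedures count 1, complex procedures 2; oral
  medications and point-of-care glucose never count. The exact service
  variables counted by any given survey year are part of the per-year
  dialect, so a group with no observable member in a year simply cannot
  trigger.
* **Reason-for-visit code sets** — keyed by the verbatim condition labels
  the completeness check enforces. The shipped five-digit codes are
  plausible placeholders for the public reason-for-visit classification
  scheme and are expected to be reviewed/extended by users who work with
  real files; the classifier depends only on the configuration, so code
  revisions never touch code. The "Abdominal pain, vomiting and diarrhea"
  row is implemented as *all-of* — three distinct code families must all
  appear among the visit's three codes — which is the strict reading of a
  conjunctive label.

## Survey-weighted estimation

All national-style estimates are ratio estimators weighted by the
per-visit inflation weight. Variance is Taylor-linearized over the masked
stratum/PSU identifiers using the with-replacement first-stage
approximation standard for public-use survey files: for a domain ratio
\(\hat R = \sum_d w_i x_i / \sum_d w_i\), the linearized scores
\(u_i = d_i\, w_i (x_i - \hat R)/\hat W_d\) are totaled per PSU and their
stratum-level dispersion summed. Domain (subgroup) estimates keep the full
design, so PSUs without domain members still contribute. When any stratum
has a single PSU, or design variables are absent, estimation degrades
explicitly (with a warning) to an SRS fallback that treats each record as
its own PSU — under equal weights this reproduces classical unweighted
statistics exactly, which the tests assert. Confidence intervals are
symmetric normal-approximation 95% intervals on the natural scale,
matching the symmetric parenthetical intervals such tables conventionally
print, and any estimate based on fewer than 30 unweighted records is
flagged unreliable rather than suppressed.

Duration outcomes (waiting time, length of stay) are summarized both ways
deliberately: weighted means with linearized CIs *and* weighted medians
with Woodruff CIs (inverting the CI of the estimated distribution function
at 0.5). Published tables of this kind are ambiguous about which is meant;
the package labels both and asserts neither as "the" value. Durations use
the visit weight alone, with missing durations excluded and the exclusion
count logged.

## What the generator emulates — and what it does not

`generate_records()` draws a planted level for each record from a mixture
(default: the weighted level shares the index produces on pooled national
data, 1.4/24.5/42.5/15.1/16.4 percent) and constructs the record to fire
*exactly one criterion of that level and nothing more acute*: complaint
codes come only from the planted condition's configured set (otherwise
from a benign pool outside every set), vitals are clamped into the safe
region of all non-planted rules, and resource counts are planted
consistently (≥ 2 / exactly 1 / 0 for resource-driven levels 3/4/5). That
makes the ground truth exact rather than probabilistic, which is what lets
the tests demand 100% label fidelity. Missingness is then applied only to
fields that are not load-bearing for the planted criterion, so the planted
label survives by construction.

Around the label the generator fills in: log-normal visit weights
(meanlog = log 250, sdlog = 0.6 — a right-skew choice mimicking inflation
weights, not an assertion about any agency's weighting); a small
stratum/PSU design (8 strata × 4 PSUs); per-level Bernoulli outcomes with
admission rates 37.9/18.0/12.3/2.5/1.5 percent (critical-care admissions
nested inside admissions so both marginals hold), ambulance and
left-without-being-seen rates back-derived from published
outcome-by-level compositions; log-normal durations with per-level means
(waiting 13.5–24.9 min, stay 201.4–82.9 min, sdlog 0.7); and a recorded
immediacy that equals the planted level with probability 0.7 (otherwise
one level off), and is unknown or marked "no triage" for 15 percent of
visits.

What it does *not* emulate: joint distributions of demographics with
acuity, correlation between outcomes beyond the ICU⊂admission nesting,
hospital-level clustering of practice style, or real reason-for-visit
coding behavior. Passing tests therefore demonstrate the correctness of
the classification algebra, the estimators and the I/O — not calibration
against real survey files, which additionally requires a reviewed code
map (see above).

## Numerical and degenerate-input choices

* Mixture probability vectors must sum to 1; vectors within 0.005
  (e.g. printed rounded shares summing to 0.999) are renormalized, anything
  further off is an error.
* Sentinel handling is uniform: every negative placeholder and blank-fill
  maps to a single missing state per field; "not taken" and "unknown" are
  not distinguished because the classifier treats both identically.
  Recorded immediacy keeps `0` ("no triage") as a value and maps unknown
  codes to missing; the nonresponse share counts both.
* Service items are stored pipe-delimited in a canonical sorted order, so
  resource counting is order-invariant and raw/CSV round trips are exact.
* Rows violating hard invariants (non-positive weight, day-count age with
  nonzero years, out-of-range pain) are rejected into a per-row report,
  never silently dropped; visits with missing weights are rejected and
  counted rather than imputed.
* The classifier is evaluated twice in this package: the vectorized
  stepwise production path, and a deliberately independent scalar oracle
  that evaluates every criterion with no early exit and takes the minimum
  fired level. The two share no evaluation code and are required to agree
  exactly on 10^5 mixed generated-plus-adversarial records.

## Problem sizes

The shipped test suite uses 10^4-record sweeps for the structural
invariants and mixture recovery, 10^5 records for oracle agreement, and
smaller engineered cohorts for exact arithmetic checks. The
`scripts/acceptance.R` reproduction runs the full pipeline at 10^5
records, a size chosen to keep Monte-Carlo error on small cells (the 1.4%
level-1 share and its outcome rates) comfortably below the precision being
reported.

## Known limitations

The index inherits the coarseness of its inputs: a five-level pain scale,
a short list of abstracted services, and complaint codes assigned by
coders rather than triage nurses, so it will misclassify some visits
relative to prospective bedside triage. The shipped reason-for-visit code
map and the level-2 vital thresholds are reconstructions that must be
reviewed before use on real files; year dialects cover 2010–2015-style
layouts and later years will need new dialect files. Inter-rater
reliability is out of scope by design, and no significance testing across
groups is provided — confidence intervals only.
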