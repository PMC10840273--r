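---
title: "Rule-based CVC-BSI surveillance: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based CVC-BSI surveillance: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvcbsi)
```

This vignette is the package's own account of the science it
implements: the surveillance model and its assumptions, the parameters
that matter and their defaults, what the synthetic cohort generator does
and does not emulate, the numerical conventions, and the design choices
made where the design was genuinely open.

## The surveillance problem

Central venous catheter-related bloodstream infection (CVC-BSI) is a
key indicator of infection prevention in hospitals, traditionally
ascertained by manual chart review against the ECDC definition of
microbiologically confirmed catheter-related bloodstream infection.
Automating that review requires recasting the clinical definition as
deterministic rules over structured EHR data: microbiology results
(blood cultures with time to positivity, quantitative catheter-tip
cultures), vital signs, and admission history.

The unit of analysis is the **potential episode**: one per blood-culture
draw, plus one per admission in which no culture was drawn. Counting
culture-free admissions keeps denominators meaningful for a whole
hospital population rather than only for tested patients, and it defines
the three strata used in evaluation: admissions with a positive culture,
with only negative cultures, and without cultures.

## Detection model

For an episode anchored on a positive draw, the label is the conjunction
of a *bloodstream-infection confirmation* and a *catheter attribution*:

* **Confirmation.** Organisms are split into recognised pathogens and
  common commensals purely by membership in the commensal list (exact
  species-level match after trimming and case-folding; no taxonomy
  expansion). One culture confirms a pathogen. A commensal needs a
  second distinct draw with the same species within the pairing window,
  plus — under the symptom-using variant — at least one qualifying vital
  sign in the symptom window.
* **Attribution.** Either a quantitative tip culture at or above the
  CFU threshold with a confirming species, collected inside the window
  *after* the draw (tips collected before the draw never match), or a
  central/peripheral draw pair within the pairing gap whose peripheral
  time to positivity exceeds the central one by at least the
  differential threshold. If both criteria hold, both evidence tags are
  recorded and the episode counts once.

The two algorithm variants differ only in the symptom conjunct of the
commensal pathway. This placement mirrors the structure of the ECDC
bloodstream-infection case definition (pathogens: one culture;
commensals: two cultures *and* clinical signs), and it is the reading
consistent with discrepancy patterns in which "no symptoms present
(contaminant culture)" false positives arise only for the
microbiology-only variant. Because the alternative reading — symptoms
required for every episode — is defensible, it is available as the
`require_symptoms_for_pathogens` toggle, default `FALSE`. A direct
consequence of the default is a monotonicity invariant the tests
exercise: every episode positive under the symptom-using variant is
positive under the microbiology-only variant.

Episodes are deduplicated with the 14-day repeat infection timeframe:
scanning positives per admission in anchor order (ties broken by draw
id), the first positive opens an episode whose timeframe covers the
index anchor date plus the following 13 calendar days; positives inside
it are suppressed and linked to the index, and the window is anchored on
index episodes only, never rolling. Negative episodes inside a
timeframe remain negative rather than suppressed, so suppression never
hides a disagreement with reference labels. Suppressed positives do not
re-anchor or extend the index episode's healthcare-associated
classification.

Healthcare-associated (HA) classification uses calendar-day arithmetic
(admission day = day 1): day ≥ 3 is HA, and day 1–2 is HA when the same
patient's previous admission ended within the 48-hour look-back,
compared on clock times.

## Parameters

| parameter | unit | default | meaning |
|---|---|---|---|
| `fever_threshold` | °C | 38.0 | fever if strictly greater |
| `sbp_threshold` | mmHg | 90 | hypotension if strictly less |
| `dbp_threshold` | mmHg | 60 | hypotension if less or equal |
| `symptom_window_days` | days | 3 | closed window before and after the anchor |
| `contaminant_pair_window_hours` | h | 48 | max gap between commensal draws |
| `tip_window_hours` | h | 48 | tip window after the draw, inclusive |
| `tip_cfu_threshold` | CFU/ml | 1000 | quantitative tip cut-off, inclusive |
| `paired_draw_max_minutes` | min | 15 | max gap within a central/peripheral pair |
| `dtp_min_hours` | h | 2 | min peripheral-minus-central positivity gap |
| `rit_days` | days | 14 | repeat infection timeframe, index day = day 1 |
| `ha_min_day` | day | 3 | first unconditionally HA admission day |
| `ha_readmission_window_hours` | h | 48 | look-back to the previous discharge |
| `bootstrap_reps` | — | 10000 | bootstrap replicates |
| `ci_level` | — | 0.95 | confidence level |

The symptom window is implemented as clock arithmetic (± 3 × 24 h around
the anchor) rather than calendar days: vitals carry clock times, the
anchoring draw does too, and no rounding convention for a calendar-day
reading is established for this rule, so the symmetric closed interval
is the least surprising choice. Timestamps are timezone-naive local
clock times at minute resolution, held internally as UTC so that
duration arithmetic can never be shifted by daylight-saving transitions.

Missing data policy: a differential-time pair requires both times to
positivity recorded; a missing value fails the criterion, with no
imputation. Draws with unspecified site can anchor and confirm an
episode but never participate in a pair. "Two different blood cultures"
means two distinct draw events; multiple bottles from one draw collapse
to a single draw at ingestion.

## Evaluation statistics

Point estimates are the usual 2×2 ratios. Confidence intervals in the
sampled validation set use the Wilson score interval (asymptotic
variance, no continuity correction), with the boundary cases pinned
exactly (an interval for 0/n starts at 0; for n/n it ends at 1). The
AUROC of a fixed binary rule is the area under its two-segment ROC
polygon, i.e. balanced accuracy (sensitivity + specificity)/2 — one
number per 2×2 table, which is what single-threshold rules admit. Kappa
is the chance-corrected agreement; since no analytic method is
established here for a kappa interval on extrapolated counts, kappa
intervals are bootstrap percentile like the other extrapolated metrics.

Extrapolation to a full surveillance population scales each stratum's
confusion-matrix cells by that stratum's target/sampled episode ratio
and sums; cells stay real-valued, and metrics are computed on the scaled
cells without rounding. Uncertainty is assessed by bootstrapping
*before* extrapolating: each replicate resamples episodes with
replacement within each stratum at the stratum's sampled size, rebuilds
and rescales the cells, and recomputes the metric; the interval is the
empirical 2.5th/97.5th percentile band. Because episodes within a
stratum are exchangeable given their (predicted, reference) cell, the
within-stratum resample is drawn as a multinomial over the four cells —
identical in distribution to resampling episode labels one by one, and
fast enough that 10,000 replicates take well under a second. Replicates
in which a metric is undefined (zero marginal) are dropped from the
percentiles and their fraction is reported, rather than imputed as 0 or
1. Zero marginals in point estimates likewise yield `NA` with a
warning, never a silent 0.

Reporting rounds half away from zero (`round_half_up`) at the printed
precision — 3 decimals for metrics, 2 for rates — because half-to-even
rounding turns e.g. 26/32 = 0.8125 into 0.812 where the conventional
presentation is 0.813. Internal computation is always at full precision.

Incidence uses in-patient hospital-days: discharge date minus admission
date in whole days, minimum one day per admission. The monthly series
assigns each stay day to its calendar month, so per-bin denominators sum
to the cohort total and the series conserves the case count; cases are
binned by the anchor date of the detected episode. Whether admission and
discharge days should be counted inclusively is not pinned down by any
convention available here; the whole-day difference reproduces the
familiar order of magnitude and is stated explicitly so it can be
audited.

For extrapolation of a validation sample shaped like the published
design, the culture-free stratum's target size is its admission count
(one episode each), and the remaining draw-anchored episodes are split
between the positive and negative strata by the admission sampling
proportion. The extrapolated sensitivity, PPV and kappa are insensitive
to that split (their informative cells live in the positive stratum,
scaled by a common factor); only the bulk true-negative mass moves, and
with it nothing beyond the third decimal of specificity and NPV.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical shape of a hospital-wide
surveillance cohort: about five of six admissions have at least one
blood culture; draws grow an organism with probability 0.36; length of
stay is log-normal with median ≈ 8 days; admission dates spread over a
two-year window; vitals are recorded 6-hourly in 90% of admissions;
CVC-BSI affects ≈ 1.2% of draw-anchored episodes in culture-positive
admissions, ≈ 63% of cases are healthcare-associated, ≈ 30% run through
the commensal pathway, and attribution is split evenly between tip
cultures and differential time to positivity. These calibration
defaults are illustrative of a tertiary-care cohort, chosen once, and
are configuration — not fitted quantities.

Every true case is implanted by an explicit recipe that satisfies the
rules by construction (pathogen or commensal pathway; tip or
differential-time attribution; day-3 or readmission HA route, with the
prior admission planted when needed). Every background episode violates
at least one conjunct by construction: background organisms never match
implant organisms, background tip cultures grow organisms absent from
blood cultures, background draws sit on an hourly grid that keeps them
more than the pairing gap apart, and background vitals never cross a
symptom threshold. Truth recovery on such cohorts is therefore *exact*,
and any discrepancy is a detector bug — this is the property the
acceptance checks exploit at a scale of ≈ 20,000 episodes (5,800
admissions, chosen so a full dual-variant run completes in about a
minute on one CPU).

What the generator deliberately does not model: real organism
epidemiology and antibiograms, ICU documentation gaps, free-text notes,
near-miss configurations (a draw pair at 47.9 h, a tip at 999 CFU/ml),
or correlated vital-sign trajectories. Passing the truth-recovery tests
therefore demonstrates that the rule engine implements the rules
exactly — not that the rules themselves capture every messy clinical
situation; boundary behaviour is pinned separately by
`implant_edge_cases()`, which appends fixtures sitting exactly on each
decision boundary (48 h pair gap, 2 h positivity differential, 15 min
pair window, +48 h tip, 38.0 °C, 60 mmHg, day-13/day-14 repeats, 48 h
readmission) with their intended labels per variant.

The shipped commensal list is a representative subset of the CDC
common-commensal list, one code per line, and is user-replaceable
configuration: the exact institutional list version matters for
production use but not for the package's logic, which only consumes
membership.

## Numerical and degenerate-input conventions

* All window comparisons are closed (inclusive) unless the source rule
  is strict ("> 38 °C", "< 90 mmHg"); each boundary has a dedicated
  fixture.
* Ties between two positive draws at one timestamp are ordered by draw
  id for the repeat-infection scan, making suppression deterministic.
* `confirm_bsi` on a negative draw is a contract violation (error), not
  `FALSE` — negative episodes are handled by the caller.
* Empty cohorts enumerate zero episodes and produce empty label sets;
  an admission with no satellites is valid (its episode is the
  admission itself).
* All randomness — generator, bootstrap — flows through explicit seeds;
  repeated runs are byte-identical, which the round-trip and checksum
  tests assert.

## Known limitations

* The detection rules cover microbiologically confirmed CVC-BSI only:
  no local/general catheter infection, no peripheral-venous-catheter
  BSI, no insertion-site pus cultures, and no explicit check that a
  catheter was present — the culture criteria act as a proxy.
* Vital-sign symptoms are limited to structured temperature and blood
  pressure; chills and other free-text symptoms are out of scope.
* The AUROC of a binary rule compresses one operating point into one
  number; it is reported for comparability, not as a discrimination
  analysis.
* Hospital-days, not catheter-days, denominate the incidence rates, so
  rates are not directly comparable to catheter-day-based figures.
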