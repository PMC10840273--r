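# cvcbsi

Fully-automated, rule-based surveillance of central venous
catheter-related bloodstream infection (CVC-BSI) from tabular electronic
health record extracts, with the diagnostic-accuracy statistics needed to
validate such surveillance against manual record review.

Continuous surveillance of healthcare-associated infections is usually
done by manual chart review — slow, expensive and prone to reviewer bias.
This package implements two deterministic detection algorithms that
operate on four routine EHR tables (admissions, blood-culture draws,
CVC-tip cultures, vital signs) plus the CDC common-commensal organism
list, and everything needed to evaluate them: Wilson score intervals,
Cohen's kappa, stratified extrapolation with bootstrap percentile
confidence intervals, incidence rate tables and time series, and a
calibrated synthetic cohort generator so the whole pipeline is testable
without patient data. It is aimed at infection-control epidemiologists
and clinical data scientists building or validating automated HAI
surveillance.

## The detection rules

The unit of surveillance is the *potential CVC-BSI episode*: every
blood-culture draw during an admission is one potential episode, and an
admission without any draw counts as one potential episode.

An episode anchored on a positive draw is CVC-BSI when both hold:

1. **Bloodstream infection confirmed.** A recognised pathogen needs one
   positive culture. A common commensal (contaminant) needs a second,
   distinct draw growing the same species within 48 h — and, under
   algorithm 1 (*with_symptoms*), BSI symptoms within ±3 days of the
   draw: temperature > 38 °C, systolic pressure < 90 mmHg, or diastolic
   pressure ≤ 60 mmHg. Algorithm 2 (*microbiology_only*) drops the
   symptom conjunct.
2. **Catheter attribution.** Either a quantitative CVC-tip culture
   ≥ 10³ CFU/ml growing the same species within 48 h *after* the draw, or
   a central/peripheral pair drawn ≤ 15 min apart with the same species
   and a differential time to positivity ≥ 2 h (central flags first).

Repeat positives within the 14-day repeat infection timeframe (RIT,
counted from the index episode's anchor date, index day = day 1) are
suppressed. A detected episode is healthcare-associated (HA) when
anchored on admission day ≥ 3 (admission day = day 1) or on day 1–2 with
a previous admission discharged ≤ 48 h before.

Performance against reference labels is summarised as sensitivity,
specificity, PPV, NPV, the single-threshold AUROC
((sensitivity + specificity)/2) and Cohen's kappa, with Wilson score
intervals in the sampled validation set; estimates for a full
surveillance population are obtained by scaling per-stratum confusion
matrices by their episode sampling fractions, with percentile intervals
from bootstrap resampling *before* extrapolation.

## Worked example

```r
library(cvcbsi)

# a synthetic cohort with implanted, recipe-verified infections
sim <- generate_cohort(cohort_sim_config(n_admissions = 300, seed = 42))
sim$bundle
#> cohort_bundle: 300 admissions, 971 blood-culture draws ( 370 positive ),
#>   31 tip cultures, 26961 vital observations
#>   reference labels: 1023 episodes, 9 CVC-BSI

labels <- run_surveillance(sim$bundle, "microbiology_only")
table(labels$cvc_bsi)
#> FALSE  TRUE
#>  1014     9

cm <- build_confusion(labels, sim$truth$reference_labels)
print(cm)
#>          reference
#> predicted  pos  neg
#>       pos    9    0
#>       neg    0 1014

binary_metrics(cm)$sensitivity
#> sensitivity: 1.000 (0.701-1.000, wilson)
```

The nine detected episodes are exactly the nine implanted infections:
each satisfied the confirmation and attribution rules by construction,
and every background culture violates at least one conjunct. The Wilson
interval (0.701–1.000) reflects that only nine positives inform the
sensitivity estimate.

On published validation counts the same functions reproduce the familiar
panel:

```r
cm <- confusion_matrix(tp = 45, fp = 4, fn = 6, tn = 4271)
round_half_up(c(sens = binary_metrics(cm, ci = FALSE)$sensitivity$point,
                kappa = cohens_kappa(cm), auroc = auroc_binary(cm)), 3)
#>  sens kappa auroc
#> 0.882 0.899 0.941
```

A command-line wrapper (`inst/cli/cvcbsi.R`) exposes `simulate`,
`detect`, `evaluate` and `incidence` subcommands over the same functions
and writes a run manifest next to every output.

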