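# lateq

Hippocampal-volume quartile enrichment for suspected LATE co-pathology on
the Alzheimer's disease continuum.

## The problem

Limbic-predominant age-related TDP-43 encephalopathy (LATE) frequently
coexists with Alzheimer's disease (AD), accelerates decline, and has no
clinically available in-vivo biomarker. Autopsy work shows that among
amyloid-positive patients, those in the lowest range of hippocampal volume
(HV) are disproportionately enriched for concomitant LATE neuropathologic
change (LATE-NC). `lateq` implements, as a tested and fully synthetic-data
reproducible pipeline, the quartile-based stratification framework built on
that observation, for biostatisticians and imaging researchers who want to
study, extend, or stress-test the approach without access to restricted
cohort data.

## The method

For each subject the working measure is the total hippocampal volume
(anterior + posterior) of the **more atrophic hemisphere** — LATE-NC is
frequently asymmetric — adjusted to the cognitively unimpaired (CU)
reference via ordinary least squares:

```
HV_adj = HV_min − β_age (age − mean_age_CU) − β_ICV (ICV − mean_ICV_CU)
```

with `β_age`, `β_ICV` estimated in amyloid-negative CU subjects only.
Quartile cut-offs `q25`, `q50` are the 25th/50th percentiles of `HV_adj`
among amyloid-positive cognitively impaired (CI) subjects. Labels:

| amyloid | cognition | HV_adj            | label       |
|---------|-----------|-------------------|-------------|
| Aβ+     | CI        | `< q25`           | AD+sLATE+   |
| Aβ+     | CI        | `> q50`           | AD+sLATE−   |
| Aβ+     | CI        | `[q25, q50]`      | EXCLUDED_Q2 |
| Aβ−     | CI        | `< q25`           | AD−sLATE+   |
| Aβ−     | CU        | —                 | Aβ−CU       |

Around this core the package provides: LATE-suggestive imaging features
(asymmetry index `|L−R|/(L+R)·200`, ERC/PHC thickness ratio,
Gaussian-mixture Tau-MaX from tau-PET SUVRs, tracer-specific amyloid
positivity); graph-generic mass-univariate inference (per-vertex GLM +
TFCE + max-statistic permutation FWER, per-vertex linear mixed models +
FDR); cognitive-domain mixed models with pairwise slope contrasts; SILA
trajectory modelling (rate sampling → robust LOESS → Euler integration)
with tau-onset anchoring and impairment-onset estimation; and autopsy
validation (exact conditional odds ratios, enrichment frequencies,
ROC/Youden). A seeded synthetic cohort generator reproduces the group
structure the method assumes, so every stage is testable end to end.

## Worked example

```r
library(lateq)
cfg    <- cohort_config()                      # defaults mirror the published cohort structure
cohort <- generate_cohort(cfg, seed = 42)
strat  <- stratify_cohort(cohort$subjects)
strat$cutoffs
#> <quartile_cutoffs> q25=2461.0 mm^3  q50=3041.8 mm^3  (n_ref=173)
table(strat$subjects$group_assigned)
#>    AD+sLATE-    AD+sLATE+    AD-sLATE+     Abeta-CU  EXCLUDED_Q2 UNCLASSIFIED
#>           86           43           18          193           44            2
```

The cut-offs are the quartiles of adjusted HV among the 173 amyloid-positive
CI subjects; the middle band (44 subjects here) is excluded by design, and
amyloid-negative CI subjects below `q25` become the suspected-LATE-only
reference group.

```r
aut  <- generate_autopsy_cohort(cfg, n = 2000, seed = 7)
cuts <- compute_quartile_cutoffs(aut$hv_adjusted)
tab  <- contingency_from_groups(aut, cuts)
as.matrix(tab)
#>         late
#> quartile LATE+ LATE-
#>    Q1      406    94
#>    Q3-Q4   265   735
fe <- fisher_exact(tab)
sprintf("OR = %.2f, p = %.3g", fe$or, fe$p)
#> "OR = 11.96, p = 1.12e-93"
round(enrichment_frequencies(tab), 1)
#>   q1 q3q4
#> 81.2 26.5
```

The lowest-HV quartile is strongly enriched for LATE-NC (81% vs 27% here;
the conditional-MLE odds ratio fluctuates around the configured value of
13.8 across seeds). `run_pipeline(run_config(...))` chains all stages —
simulation, stratification, features, TFCE/LME maps, trajectory models,
autopsy validation — into one seeded, byte-reproducible report.

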