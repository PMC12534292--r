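# pspsubtype

Early clinical subtyping and progression analysis for progressive
supranuclear palsy (PSP).

PSP is a four-repeat tauopathy whose early clinical face varies widely:
besides the classic Richardson's syndrome (early falls with vertical gaze
palsy), patients present with parkinsonism, isolated postural instability,
speech/language disorder, frontal behavioral change, or ocular motor
dysfunction — and these presentations differ in how fast the disease runs.
Because earlier criteria permit multiple simultaneous diagnoses, a mutually
exclusive rule over what is observable within three years of onset is what a
clinician (or a trial screener) actually needs. This package is for
researchers who want to apply such a rule, reproduce the discovery pipeline
that generates one, or stress-test either on simulated cohorts.

## What the package implements

**The subtyping rule.** Each of 12 key symptom families is reduced to a
tri-state early status (present / absent / not evaluated), composites are
formed (frontal presentation F, postural instability PI, speech/language SL,
ocular motor OM, and parkinsonism = bradykinesia ∨ rigidity ∨ rest tremor),
and a fixed decision tree assigns exactly one of eight labels, treating
not-evaluated as absent:

```
PI:   F -> PSP-PF;   ¬F ∧ OM -> PSP-RS;   else -> PSP-PI
¬PI:  F -> PSP-F;    SL -> PSP-SL;   OM -> PSP-OM;
      parkinsonism -> PSP-P;   else -> Misc
```

`enumerate_rule_table()` proves totality and mutual exclusivity by
enumerating all 2⁵ combinations (label counts 8/8/4/4/4/2/1/1).

**The discovery pipeline.** `distill_subtypes()` reproduces how such a rule
is distilled from data: a 2-D fuzzy-neighbor embedding of the binary
patient × symptom matrix (Euclidean, 15 neighbors, min dist 0.1),
density-peak cluster detection (min cluster size 15), a depth-≤4 Gini
decision tree fit to the cluster labels with ten-fold cross-validated
accuracy and macro one-vs-rest AUC, leave-one-feature-out ablation, refit on
the surviving features, and an appended parkinsonism leaf that splits the
all-absent node into PSP-P vs Misc (a split the depth budget provably cannot
learn).

**Progression and prognosis.** Milestone quantiles t25/t50/t75 (time until
25/50/75% of evaluated patients develop a symptom), early vs lifelong
frequency tables, Cox proportional-hazards fits (Breslow ties, PSP-PF
reference), model survival curves, Harrell's concordance index and ΔC for
with/without-subtype model comparison, Kruskal–Wallis with Steel–Dwass
all-pairs post hoc, and pairwise chi-square with Holm correction.

**A calibrated simulator.** `generate_cohort()` draws longitudinal cohorts
from per-subtype archetypes (log-normal durations and symptom onsets,
Poisson visit schedules with incomplete documentation) calibrated to a
588-patient autopsy cohort: subtype prevalences 188/68/204/36/29/31/13/19,
duration medians 6, 7, 8, 10, 8, 9, 8, 9 years, and published symptom-onset
medians (e.g. PSP-PF: PI at 0.3 y, frontal at 1.6 y).

## Worked example

```r
library(pspsubtype)

co <- generate_cohort(588, seed = 42)
labels <- classify_cohort(co)           # inclusion rule + early features + tree
table(labels$subtype[labels$included])
#> PSP-PF PSP-RS PSP-PI  PSP-P PSP-SL  PSP-F PSP-OM   Misc
#>    143     82    222     32     31     35     19     24

rec <- survival_records(co, labels)
fit_cox(rec, c("age_at_onset", "sex", "subtype"))
#> Cox proportional-hazards fit (Breslow ties) on age_at_onset + sex + subtype
#>           term   coef    hr    se     z       p
#>   age_at_onset  0.006 1.006 0.005  1.03 3.0e-01
#>      sexfemale -0.118 0.888 0.087 -1.36 1.7e-01
#>    subtypeMisc -1.101 0.332 0.223 -4.94 8.0e-07
#>   subtypePSP-F -0.904 0.405 0.191 -4.72 2.3e-06
#>  subtypePSP-OM -0.983 0.374 0.246 -3.99 6.7e-05
#>   subtypePSP-P -1.496 0.224 0.202 -7.41 1.3e-13
#>  subtypePSP-PI -0.721 0.486 0.109 -6.60 4.0e-11
#>  subtypePSP-RS -0.274 0.760 0.139 -1.97 4.9e-02
#>  subtypePSP-SL -0.885 0.413 0.203 -4.37 1.3e-05
#> in-sample concordance: 0.637

milestone_quantiles(co, labels, "pi")[c(1, 3, 4), ]
#>   subtype symptom n_evaluated n_developed   t25   t50   t75
#> 1  PSP-PF      pi         143         143 0.247 0.314 0.455
#> 3  PSP-PI      pi         222         222 0.245 0.330 0.502
#> 4   PSP-P      pi          32          20 4.278 6.836    NA
```

Read it as the model says you should: every subtype's hazard ratio against
PSP-PF is below 1 — PSP-PF is the aggressive phenotype with the shortest
course, and PSP-P (hazard ratio 0.22 here, the 10-year-median archetype)
the slowest; postural instability arrives in the first four months for the
PI-bearing subtypes but after four years, and in only 20 of 32 evaluated
patients, in PSP-P, where `NA` means fewer than 75% ever developed it. The
in-sample concordance of 0.637 against an age+sex-only baseline near 0.5 is
the gain `delta_c()` quantifies.

The full pipeline (simulate → classify → distill → progression → stats)
runs as one reproducible unit with a manifest of hashed artifacts:

```r
run_pipeline(list(seed = 7, n_patients = 588, output_dir = "psp_run"))
```

or from a shell via `inst/scripts/psp-pipeline.R`. The methods vignette
(`vignettes/psp-early-subtyping.Rmd`) documents the model, the simulator's
assumptions and calibration, and every numerical convention.

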