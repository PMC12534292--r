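---
title: "Early PSP subtyping: models, simulator, and statistical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early PSP subtyping: models, simulator, and statistical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pspsubtype)
```

## The scientific problem

Progressive supranuclear palsy (PSP) is a four-repeat tauopathy defined
neuropathologically, but its clinical face is heterogeneous: the classic
Richardson's syndrome (early falls plus vertical gaze palsy) coexists with
parkinsonism-predominant, speech/language, frontal-behavioral, ocular motor,
and pure postural-instability presentations. Because prior criteria allow
multiple simultaneous diagnoses, and because the presentations differ in
prognosis, a *mutually exclusive* subtyping rule based on what is observable
*early* (within three years of clinical onset) is clinically valuable: it
lets a bedside clinician estimate progression speed and stratify patients
for trials at a point where intervention is still meaningful.

This package implements such a rule — a five-feature decision tree over
tri-state early manifestations — together with the discovery pipeline that
produces this kind of rule from data (embedding, density clustering,
decision-tree distillation, ablation), the progression and prognosis
statistics used to characterize the resulting subtypes, and a calibrated
synthetic-cohort generator so that every stage is testable without access to
patient-level records, which are not publicly deposited for the autopsy
cohort that motivates the defaults.

## The subtyping rule

Twelve key symptom families are tracked (`psp_symptoms()`). Five composite
manifestations drive the classifier: frontal presentation (one behavioral or
dysexecutive feature suffices — a deliberately permissive threshold, since
early behavioral change is often documented with a single phrase like
"personality change"), postural instability (PI), speech/language disorder
(SL), ocular motor dysfunction (OM), and parkinsonism (any of bradykinesia,
rigidity, rest tremor). Each symptom in the early window is in one of three
states: present, absent, or not evaluated; a not-evaluated composite is
treated as absent during tree traversal, because a rule intended for bedside
use cannot demand complete documentation.

```
PI present:  frontal present            -> PSP-PF
             frontal absent, OM present -> PSP-RS
             otherwise                  -> PSP-PI
PI absent:   frontal present            -> PSP-F
             SL present                 -> PSP-SL
             OM present                 -> PSP-OM
             parkinsonism present       -> PSP-P
             otherwise                  -> Misc
```

`enumerate_rule_table()` verifies by exhaustion that the rule is total and
mutually exclusive over all 32 present/absent combinations, yielding 7 named
subtypes plus the miscellaneous class with per-label combination counts
8 (PF), 8 (F), 4 (RS), 4 (PI), 4 (SL), 2 (OM), 1 (P), 1 (Misc).

Two genuinely open choices are worth recording. First, on the PI-absent
branch we check frontal presentation before speech/language, so a patient
with both (and no PI) is PSP-F; the published subtype definitions exclude SL
explicitly from PSP-OM and PSP-P but are silent for PSP-F, and a depth-4
tree with the parkinsonism leaf appended afterwards forces frontal to sit at
depth 2. The priority is exposed as `sl_before_frontal` so the opposite
convention is one flag away. Second, the early window treats `t = 3` years
as inside the window (closed bound); "within three years" is ambiguous at
the boundary and the closed reading is documented here once and used
everywhere.

## Tri-state feature extraction

A patient enters analysis only with at least one key-symptom record at
`t <= 3` and one at `t > 3` (`meets_inclusion()`), so both the early window
and the later course are documented. Within a window, a symptom is *present*
if any present record falls inside; *absent* if the symptom was evaluated
inside the window but never present; *not evaluated* if there is no
in-window record at all. A present record *after* the window never
retroactively marks the early state: the early status of such a patient is
not-evaluated, which matches the evaluated-denominator logic of the
frequency tables. For clustering input the tri-state collapses to binary
with both absent and not-evaluated mapping to 0 — the same imputation the
discovery analysis uses, and a known limitation (missingness and absence are
conflated at that stage only).

## The synthetic cohort generator

`default_archetypes()` encodes eight generating processes, one per subtype,
calibrated to the 588-patient autopsy cohort behind the defaults:
prevalences proportional to the subtype sizes (188, 68, 204, 36, 29, 31, 13,
19 of 588), median disease durations of 6, 7, 8, 10, 8, 9, 8, 9 years, male
fractions and onset-age medians per subtype, and symptom-onset medians
matching the published milestone times (PSP-PF: PI 0.3 y, frontal 1.6 y,
bradykinesia 2.1 y, rigidity 2.5 y, OM 2.6 y; PSP-RS: PI 0.6, OM 1.8,
bradykinesia 2.3, rigidity 3.0; PSP-PI: PI 0.3 with bradykinesia, rigidity
and OM only at 4.4-4.7 y; PSP-P: tremor 1.6; PSP-SL: SL 0.6; PSP-F: frontal
0.3; PSP-OM: OM 1.5).

Modelling choices, made once and frozen:

* **Log-normal durations and onsets**, parameterized by the median (directly
  calibrated to the published medians) and a log-scale spread. Spreads of
  0.22-0.30 for durations reproduce the published interquartile ranges
  (e.g. 6 [5, 7] for PSP-PF); symptom onsets use spread 0.4.
* **Symptom models not pinned by a printed number** encode the qualitative
  course descriptions: PSP-F develops parkinsonian and motor neuron signs
  four to five years after onset; PSP-PI transitions late toward the
  Richardson picture; the Misc archetype shows none of the five composites
  early, with occasional ataxia, motor neuron, cortical or akinetic signs
  (mirroring the composition 4/2/1/1 plus 11 with nothing, of 19).
* **Observation schedule**: Poisson visits at 1.5/year plus a guaranteed
  baseline visit at onset and a terminal (autopsy) visit at death; each
  symptom is documented at a visit with probability 0.6; a developed
  symptom's onset date itself is documented with probability 0.9, otherwise
  its onset is taken from the first later visit where it is noted — the
  same convention the abstracted records use.
* **Everyone dies**: it is an autopsy cohort, so durations are fully
  observed; `censor_frac` exists for generality and defaults to 0.
* Pre-onset visits emit *absent* records, which is what gives the tri-state
  logic something to chew on.

What the generator deliberately does **not** emulate: correlated
documentation gaps (real records miss symptoms in bursts, e.g. whole visits
without an eye-movement exam), drift in documentation standards over a
25-year collection window, levodopa response, and neuropathology. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline's logic
is correct under the stated statistical structure, not that the published
cohort's numbers are reproduced; the published fidelity and concordance
values depend on the real records and are treated as qualitative targets
only.

`noiseless_archetypes()` rounds presence probabilities to 0/1 and zeroes all
spreads; with a dense schedule the pipeline then recovers every latent label
exactly, which is the main correctness trace for the generator-classifier
loop.

## The distillation pipeline

`distill_subtypes()` reproduces the discovery procedure on a binary
patient-by-symptom matrix:

1. **Embedding** (`umap_embed()`): the standard fuzzy-neighbor manifold
   projection with the published settings — Euclidean metric, 15 neighbors,
   minimum distance 0.1, 2 components. No pre-installed R package provides
   this embedding, so it is implemented here: per-point bandwidths calibrated
   to `log2(k)` effective neighbors, probabilistic t-conorm symmetrization,
   and layout by sampled attractive/repulsive gradient epochs on the
   rational kernel fitted to the minimum-distance target. Two aspects
   deserve note for binary data. With 12 binary features a cohort of
   hundreds of patients contains many *identical* rows; the connectivity
   radius is therefore set to the nearest *distinct* neighbor distance, so
   low-multiplicity patterns remain firmly attached to their neighborhoods
   instead of floating free. And when the fuzzy graph splits into
   disconnected components, components are laid out separately and placed
   apart, the standard treatment.
2. **Cluster detection** (`detect_clusters()`): density-peak clustering with
   `min_cluster_size = 15`. A center is a point with at least 15 neighbors
   within three bandwidths that is farther than both three bandwidths and 5%
   of the embedding diameter from any denser point; everyone else drains to
   their nearest higher-density neighbor. We initially used a single-radius
   core-connectivity method, but on the lattice geometry binary data
   produces (coincident-point stacks surrounded by sparse satellites) no
   single radius is reliable — counts flapped with the seed — whereas
   density peaks are stable because sparse satellites can never found a
   cluster. This is the package's stand-in for the visual cluster
   identification of the original analysis, and it is the one stage where a
   method had to be chosen without published guidance.
3. **Tree fidelity** (`fit_subtype_tree()`, `cross_validate_tree()`): an
   rpart classification tree with the published hyperparameters (Gini, best
   splitter, depth <= 4, minsplit 2, minbucket 1), assessed by stratified
   tenfold cross-validation with accuracy and macro one-vs-rest AUC from
   leaf class probabilities. AUC definition is a documented choice: only
   "AUC" is specified upstream, and macro-averaged one-vs-rest is the
   conventional multiclass reading. Classes smaller than the fold count
   trigger a logged fall-back to unstratified folds.
4. **Ablation and simplification** (`ablate_features()`,
   `simplify_tree()`): each feature is dropped in turn and the
   cross-validated metrics recomputed; features whose accuracy delta exceeds
   0.02 (a package choice — no threshold is published) are kept, the tree is
   refit on them, and the all-absent leaf is split by the parkinsonism
   composite into PSP-P versus Misc. That last step cannot be learned by the
   tree itself: at the all-absent point every one of the five features is
   relevant, so separating PSP-P from Misc requires a fifth consecutive
   split, one more than the depth budget — which is exactly why the
   parkinsonism leaf has to be appended by domain knowledge rather than
   found by the fitter.

On six well-separated archetypes (`separated_archetypes()`; minimal modal
patterns with 2% feature flips, designed so that discrimination flows
through the tree's own features rather than redundant auxiliary markers) at
the study size of 588 patients, the pipeline recovers six clusters, selects
exactly the four load-bearing features (frontal, PI, SL, OM), and the
exported rule table agrees with the hard-coded tree on well over 95% of
patients across seeds. The test suite asserts this end to end.

## Progression summaries

`milestone_quantiles()` computes, per subtype, the time by which 25/50/75%
of patients *evaluated* for a symptom have developed it; the quantile is the
corresponding order statistic of observed onsets with non-developers counted
in the denominator, and is undefined whenever the developed fraction never
reaches the level. No censoring correction is applied — the cohort is fully
observed to death, and the plain-proportion reading matches how the
milestone figures are defined; a Kaplan-Meier variant is out of scope.
`frequency_table()` reports early (within-window) and lifelong presence
percentages over the evaluated denominator, so early <= lifelong by
construction. Both report their denominators explicitly, because
evaluated-ever versus evaluated-at-death is the one genuinely ambiguous
denominator choice; with the simulator's terminal visit the two nearly
coincide.

## Survival and group-comparison statistics

`fit_cox()` wraps a proportional-hazards partial-likelihood fit with
**Breslow** tie handling (the tie method is not published; Breslow is the
convention of the Python survival stack the original analysis used), subtype
one-hot coded against **PSP-PF** as reference, with rank-deficiency and
separation checks that name the offending term. `survival_curve()`
evaluates S(t) = exp(-H0(t) exp(x'b)) for a covariate profile (the
representative profile being mean onset age, male sex). Harrell's C
(`concordance_index()`) is implemented directly — comparable pairs are
those with distinct durations and an observed event for the shorter
survivor; risk ties count one half — and is verified in the tests against
both a brute-force pair enumeration and the survival package's
implementation. `delta_c()` compares in-sample C with and without the
subtype indicators over an age+sex base model, mirroring the with/without
comparison used to quantify the prognostic value of subtyping; on default
synthetic cohorts the gain is positive and the age+sex base sits near 0.5
because neither covariate carries survival signal in the generator.

`kruskal_wallis()` delegates to the tie-corrected H test; `steel_dwass()`
implements the all-pairs post hoc: for each pair the tie-corrected
standardized rank-sum statistic is referred to the studentized range
distribution (k groups, infinite df, statistic scaled by sqrt(2)), and for
small groups a seeded single-step max-T permutation reference replaces the
asymptotics (and doubles as its validation oracle in the tests).
`pairwise_chisq_holm()` runs pairwise chi-square tests **without continuity
correction** — with Yates' correction the published TDP-43 contrast between
PSP-F (5/26) and PSP-PF (5/157) could not reach significance after Holm
adjustment across the 28-pair family, while the uncorrected test reproduces
it — followed by Holm's step-down with enforced monotonicity.

## Numerical conventions and problem sizes

All simulation-facing functions take an explicit seed and restore the
caller's RNG state. The pipeline driver derives per-stage seeds from one
top-level seed (`seed * 13421 + 7907 * stage`, kept within integer range) so
stages can be re-run in isolation; identical configurations produce
byte-identical artifacts. The test suite runs its heaviest checks at the
sizes the analyses are defined at — 588 patients for distillation, 2000 per
archetype for calibration recovery, 200 replicates of n = 2000 for Cox bias,
2000 null simulations for the Kruskal-Wallis type-I rate — chosen as the
smallest sizes at which the quantities under test are stable.

## Known limitations

* The embedding is a faithful but compact reimplementation; its layouts are
  not numerically identical to any reference implementation, only
  structurally equivalent (the package never relies on exact coordinates).
* Cluster delineation on real, noisier cohorts may need the bandwidth or
  `min_cluster_size` adjusted; both are exposed.
* The tri-state-to-binary collapse at the clustering stage conflates
  absence with missingness, exactly as the upstream analysis does.
* Milestone quantiles ignore the (absent, by design) censoring; applying
  them to a living cohort would bias times downward.
* The generator's missingness is independent per visit and symptom; real
  documentation gaps are correlated, so real-data fidelity metrics will be
  lower than synthetic ones.
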