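---
title: "Harmonizing child behavioral instruments: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing child behavioral instruments: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rosettabank` fuses eight standardized child behavioral instruments into a
minimal bank of harmonized questions and runs a machine-learning
assessment pipeline on the fused data. This vignette documents the data
model, the statistical procedures, the parameters that matter, and the
design decisions taken where the published material leaves the design
open.

## The semantic hierarchy

Clinical domains form a rooted tree: three top-level domains (Cognitive,
Motor, Somatic) subdivide into subgroups and finally into 57 leaf
categories (Adaptability, Attention, Sleep, ...). Every harmonized
question hangs on exactly one leaf. Node ids are full slash-delimited
paths, because leaf labels repeat: several subgroups have a catch-all
leaf named after themselves (e.g. `Cognitive/Behavioral/Social/Social`).

Two documented readings of the tree coexist in the source material: the
narrative counts 57 leaves, while the per-leaf fusion table lists 60
distinct leaf rows (adding subgroup-level catch-all rows for Emotional,
Sensory, Executive Functioning and Somatic). `build_default_hierarchy()`
returns the 57-leaf narrative tree; the flag `include_catch_alls = TRUE`
adds the four extra leaves so that every row of the fusion table — and
therefore every entry of the packaged 209-question manifest — has a leaf
to hang on. The two gross-motor sub-leaves are unnamed in the source;
their labels (`Locomotion`, `Coordination`) are fixture metadata.

## The crosswalk and answer consolidation

A crosswalk holds four tables: the instrument-version registry, the item
bank, the harmonized question bank, and the many-to-one item-to-question
mappings, each with a per-item answer map.

The consolidated answer-code count of a question is the **minimum** source
scale size among its mapped items (`answer_code_count()`): a child
assessed only with the coarsest instrument must be able to produce every
code, and it cannot be inferred how a respondent would have answered a
finer scale. The default answer map (`default_answer_map(k, m)`) is the
identity on the `m − 1` least severe choices and collapses all remaining
most-severe choices onto the top code. Maps are validated to be monotone
non-decreasing in severity and surjective onto `1..m` whenever `k ≥ m`.
When a source scale is *coarser* than the target (`k < m`) no default is
generated — the collapse rule only works downward — and an explicit map
must be supplied.

Quality-described scales (ADI-R, ADOS-2) are treated as ordinal with the
printed order taken as least-to-most severe; frequency (Likert) scales
are ordinal by construction.

**Aggregation policy.** Nothing in the source specifies how several mapped
item responses from one child collapse into a single question cell.
`translate()` exposes three deterministic policies — `max` (most severe
code, the default), `mean` (rounded mean, half up), `first` (canonical
(instrument, version, item) order) — all invariant to response row order.
`max` is the default because it preserves clinical signal and never
fabricates fractional codes.

**Counting granularity.** Overlap and fusion statistics
(`overlap_matrix()`, `fusion_summary()`) count *instruments* (8), while
translation and simulation operate at *version* level (15 versions in the
case-study registry). The overlap matrix's diagonal counts questions
exclusive to one instrument; the totals column counts questions an
instrument touches at all.

## The cohort simulator

`simulate_cohort()` is a generative stand-in for the unavailable clinical
cohort. It emulates the *structure* of that data — three diagnostic
classes in proportions 588 : 69 : 89 at desk scale (one fifth of the
source cohort's 2,941 : 343 : 447), 15 instrument versions, each child
completing only 1–2 of them — not its distributions, norms, or
prevalence. Per child and leaf, a latent severity is drawn,

θ(i, leaf) = shift(condition(i), leaf) + Normal(0, `noise_sd`²),

and each item of an assigned version is answered on its native `k`-point
scale by thresholding θ + Normal(0, `item_noise_sd`²) at `k − 1` equally
spaced cut-points between 0.5 and 2.0. This thresholded-latent-Gaussian
(graded-response style) model is the simplest fully specified monotone
ordinal response model; monotonicity of the expected answer in θ is
tested against a Monte-Carlo oracle. Baseline severities are zero, so the
neither class sits mostly at the least severe codes.

Default effect shifts (latent standard-normal units, set once and
documented in `default_effects()`): autism +2.5 on Social,
Language & Communication and Sensory leaves and +0.5 on Attention; ADHD
+2.5 on Attention, Hyperactivity, Impulsivity and Inhibitory Control and
+1.5 on Memory; neither all zero. These are strong, clearly separated
profiles — the simulator is a test harness for the pipeline's mechanics,
not a claim about real effect sizes.

Three disjoint seed streams drive latent draws, version assignment and
response noise, so changing the assignment range does not perturb the
latent severities; cohorts are bit-identical given (config, seed).
Version assignment is weighted sampling without replacement (uniform by
default), which reproduces the little-overlap regime without claiming the
real assignment mechanism.

What passing tests on this simulator do **not** show: robustness to real
instruments' norms and T-scores, informative (non-random) instrument
assignment, rater effects, comorbidity, or realistic class balance. The
published full-scale classification results are not reproducible from
synthetic data, and the package does not attempt it.

## Ensemble imputation

`impute_ensemble()` implements the constraint-based ensemble: per feature,
random candidate subsets of *other* features; only rows with 100%
coverage of the candidate subset (by the *original* observation mask)
train and receive predictions; draws with fewer than `min_class_samples`
training rows in any labelled class are discarded; predictions accumulate
until every target cell has `min_predictions`, and cells are the clamped
mean. Key consequences, asserted as invariants: observed cells are
conserved exactly; imputed values never feed back as predictors (no
cascading); cells that never reach the floor stay missing, flagged
`failed`.

Numerical and design choices:

* **Forest mode**: regression on the ordinal codes, final mean clamped to
  `[1, m]` and not rounded by default — averaging implies continuous
  aggregation; `mode = "classification"` and `round = TRUE` are exposed.
* **Subset size**: uniform in `[3, min(20, p − 1)]` by default, bounded so
  the fully covered training pool stays non-empty under block
  missingness.
* **Draw cap**: `max_draws_per_feature = 200` operationalizes the
  admission that some cells are unimputable; the loop otherwise has no
  stated termination.
* **Guard scaling**: the full-scale guard is 50 rows per class. At desk
  scale that is unattainable (69 ADHD children in the whole cohort), so
  the pipeline profile scales it with the cohort: 10 = 50 × (746/3731).
* **Degenerate inputs**: a matrix with no observed values anywhere is
  rejected as unusable rather than silently producing an all-failed
  result.

Labels enter only through the class-size guard, never as predictors.

## Two-stage assessment and pruning

Stage 1 (gate) learns condition-present vs neither on all rows; stage 2
learns autism vs ADHD on the *truly* positive rows (gate filtering
applies only at prediction time, where the discriminator is consulted
exactly for rows at or above `gate_threshold`, default 0.5). Stratified
`k`-fold cross-validation (default `k = 20`; the desk-scale profile uses
`k = 5`) pools out-of-fold scores: stage-1 AUC over all rows, stage-2 AUC
over the truly positive rows.

`iterative_prune()` removes one element per iteration: the candidate
feature with the lowest normalized-importance × post-imputation-coverage
product, or the candidate row with the highest failed-cell fraction —
whichever is worse on a common badness scale (one minus the feature
product vs the row fraction). The source names both ingredients but not
their combination; the product rule is the simplest combination using
exactly the two stated signals. Ties on feature badness break toward
lower coverage, then lower importance, keeping the trace deterministic.
Which cross-validated quantity "hits a maximum" is also unstated; the
pruning objective is configurable (`mean` of both stages' pooled AUC by
default, or either stage alone). Pruning stops after `prune_patience`
iterations without improvement, never prunes a stage below trainability,
and returns the best-scoring state seen.

Boosting hyperparameters (depth 3, 200 rounds, learning rate 0.1) are
unstated in the source and exposed in `classifier_config()`; the
desk-scale profile uses 100 rounds. All boosting and forest fits run
single-threaded with derived seeds, so runs are exactly reproducible.

## Desk-scale study profile and problem sizes

`pipeline_config()` encodes the desk-scale profile used throughout the
test suite: the synthetic 30-question crosswalk over all 15 registry
versions, the 746-child cohort, imputation with guard 10 / floor 10 /
subsets of size 3–5 / 50 trees / 150 draws per feature, and 5-fold CV
with 100 rounds. The test suite exercises smaller instances (matrices of
10–18 questions, cohorts of 90–800 rows, 20-seed Monte-Carlo loops for
the null-AUC, imputation-vs-baseline and pruning-retention properties);
these sizes are chosen to make the statistical checks sharp at desk
scale. A single global seed fans out to per-stage seeds through a fixed
integer recurrence, so every stage is independently reproducible.

## Known limitations

* Question phrasing and the published 30-question case-study selection
  are expert artifacts; the package ships them as fixtures but cannot
  regenerate them.
* Fixtures reconstruct published tables; where the tables disagree (57 vs
  60 leaves; 207 vs 209 questions) the reconciliation is documented in
  `inst/extdata/README.md` rather than silently resolved, and
  synthetic stand-in entries are labelled `[synthetic]`.
* The imputer's class-size guard makes imputability depend strongly on
  cohort size and class balance; under heavy block missingness many cells
  legitimately fail, and downstream models must tolerate missing values
  (the boosted trees do).
* No calibration, external validation, or clinical-use thresholds are
  provided; cross-validated AUC on synthetic cohorts demonstrates the
  pipeline's mechanics, nothing more.
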