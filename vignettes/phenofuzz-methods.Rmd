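---
title: "Digital phenotyping of adolescent depression: models, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital phenotyping of adolescent depression: models, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofuzz)
```

## The problem

Passive smartphone sensing turns a phone into a behavioural monitor:
location fixes, gyroscope bursts, call and text-message records, screen
on/off events and the daily count of newly stored images together describe
how much a person moves, communicates and engages with the device. In
adolescent depression such digital phenotypes are candidate objective
markers for two clinical questions: does a subject belong to the depressed
(MDD) or the healthy-control group, and — among treated patients — will the
subject respond to an antidepressant? `phenofuzz` implements the full
analysis pipeline for a two-group design of this kind: 24 cases and 10
controls monitored for five weeks (one baseline week, then treatment for
the cases), with the clinician-rated CDRS-R defining treatment response as
a decrease of at least 40% from baseline to treatment week 8.

Because data of this kind are private clinical records, the package ships a
synthetic-cohort generator as a first-class, tested module. Every
downstream stage — feature extraction, fuzzy feature selection,
classification, cross-validation, clinical statistics — is exercised
against cohorts whose group structure is planted and therefore known.

## Raw streams and daily features

One subject-day is reduced to 14 base features: screen-usage minutes; the
counts, total durations and distinct-contact counts of sent/received calls;
the counts, total character lengths and distinct-contact counts of
sent/received text messages; total GPS movement distance; gyroscope
momentum; and the number of image files added that day.

Two features deserve their formulas:

* **Movement distance** is the sum of great-circle distances between
  consecutive 15-minute GPS fixes, using the haversine formula with an
  Earth radius of 6371 km. One degree of longitude on the equator is
  therefore 6371·π/180 = 111.195 km, which doubles as a test fixture.
* **Momentum** summarizes a 5-second gyroscope burst sampled at 0.1 s
  (50 triaxial samples): the Euclidean norms of the 49 consecutive sample
  differences are averaged after discarding the single largest and single
  smallest norm, i.e. a trimmed mean over 47 values. (A 50-sample burst
  yields 49 differences; a description of this trimming as 48 averaged
  quantities does not add up and we implement the arithmetic that does.)
  A constant burst has momentum exactly 0, and a linear ramp with slope
  0.1 per sample on one axis has momentum exactly 0.1.

Each base feature is carried in three representations, stored as the three
assays of a `PhenotypeExperiment` (a `SummarizedExperiment` whose rows are
features and whose columns are subject-days): the raw daily value, the
absolute deviation from the subject-week mean, and the subject-week
standard deviation. Weeks are subject-anchored 7-day blocks counted from
each subject's monitoring start, not calendar weeks, so the baseline week
is always week 0. The weekly SD uses the population (divide-by-*n*)
convention by default — the week is the entire population of interest, not
a sample from a longer window — with the sample convention available via
`sdType = "sample"`. "Distance from the mean" is taken as the absolute
deviation, keeping the feature sign-free; the signed deviations sum to zero
within each week, which the tests assert. Missing stream-days contribute 0
and are flagged in a `complete` column rather than dropped, since the
learning matrix must be dense.

The diagnosis task uses the baseline week of all 34 subjects (14 × 3 = 42
columns); the response task uses the treatment-period days of the 24 cases
plus two dose features (daily dose and the subject's maximum prescribed
dose; 44 columns), labelled responder vs nonresponder.

## NEWFM: weighted fuzzy membership functions

Feature selection uses a neural network with weighted fuzzy membership
functions. For every feature and each of the two classes the model holds
`m = 3` triangular membership functions. A function is a triangle with apex
`v` and feet at the neighbouring apexes (the outermost feet extend one
spacing beyond); its weight `w ∈ [0, 1]` says how much the class relies on
it. Features are min-max scaled to [0, 1] on the training data; apexes are
initialized evenly over the range with all weights 0.5.

Training is online: for each sample and feature, the maximally responding
function of the sample's own class moves its apex toward the value,
`v ← v + α (x − v)`, and is reinforced, `w ← min(1, w + β (1 − w) μ)`,
while the winner of the opposite class is weakened,
`w ← max(0, w − β w μ)`, where `μ` is the membership before the update.
Feet are re-derived from the sorted apexes after each epoch. Defaults are
`α = 0.05`, `β = 0.01`, 100 epochs; all are exposed in `newfmConfig()`.
If a value falls outside every triangle of a class (possible after apexes
migrate inward), the nearest-apex function is treated as the winner with
zero membership: its apex still moves toward the sample, so coverage can
recover, but no weight changes. Degenerate constant features are flagged
and score zero rather than erroring.

The class-conditional curve of a feature is the **bounded sum** of its
weighted triangles, `min(1, Σ wᵢ μᵢ(x))`. A feature is scored by how little
its two class curves overlap: on a uniform 256-point grid, with `O` the
trapezoid integral of the pointwise minimum of the curves and `T` that of
the maximum, the score is `(T − O)/T` (0 when the curves coincide or `T`
is 0, 1 when their supports are disjoint). Ranks are descending in score
with ties broken by ascending feature index for reproducibility. The tests
hold the implementation to a brute-force oracle evaluated at 10× grid
resolution (maximum absolute error below 10⁻⁶).

**Backward elimination** wraps the scorer: train on the active set, rank,
measure accuracy of the NEWFM classifier itself (class score = mean
bounded-sum membership across active features, argmax with ties to the
first class level) on a stratified 20% held-out split drawn once per call,
then delete the lowest-ranked feature. When a deletion lowers the held-out
accuracy the feature is restored and the search stops; at least 2 features
always survive. A held-out split rather than training fit drives the
stopping rule so that selection does not reward memorization. The full
path — active set, ranks and accuracy at every accepted step — is kept,
because feature importance is defined over it. An alternative reading of
the source algorithm re-ranks every training epoch rather than every
elimination step; the per-step reading is implemented.

## Classifiers

The primary classifier is a feed-forward network with 2 hidden layers of
20 nodes trained for exactly 300 epochs. The remaining choices are not
dictated by the protocol and are ours: ReLU activations, softmax output
with cross-entropy loss, He-normal initialization, and full-batch Adam at
learning rate 10⁻³ — sample sizes of a few hundred rows make full-batch
training both stable and fast, and the network is written directly in R
matrix code. Training is deterministic given the configuration seed. The
sensitivity baseline is an RBF-kernel SVM (via `e1071`) with cost 1 and
kernel width `1/(p · mean feature variance)` by default; both
hyperparameters are exposed.

## Validation protocol

Cross-validation is **subject-level**: subjects (never rows) are shuffled
and dealt to 3 folds, stratified by class, so fold subject counts differ by
at most one (34 subjects → 12/11/11) and no subject's days ever straddle a
fold boundary — the leakage that row-level splitting would cause is ruled
out by construction. Within each fold pass, NEWFM elimination runs on the
two training folds only, the classifier is trained on the selected columns
(min-max scaled on training data), and accuracy is measured on the held-out
fold at the subject-day row level; a per-subject majority-vote accuracy is
available alongside. The 3-fold pass is repeated 10 times with fresh fold
assignments; the report carries the 10 repeat means with their maximum and
minimum. A repeat that happens to draw a single-class test fold is redrawn
with the next sub-seed and logged, never silently accepted.

**Averaged-rank importance**: every elimination step of every fold and
repeat contributes the active features' ranks; a feature's importance is
its mean rank over all models in which it appeared, sorted ascending with
ties broken by name.

## The synthetic cohort generator

The generator emulates the study design: GPS fixes every 15 minutes (96 per
day), gyroscope bursts of 50 samples at 0.1 s every 15 minutes, daily call
and message logs, alternating screen on/off sessions, daily image counts, a
dose schedule (5 mg in the first treatment week, 10 mg the next, then
titration to a per-subject maximum of 10–25 mg), and weekly clinical scores
with CDRS-R trajectories that respect the responder rule exactly.
Group sizes, monitoring length and the responder count default to the
design above (24/10, 35 days, 10 responders).

Concretely: GPS tracks are home-anchored random walks with
gamma-distributed step lengths (shape 2) and uniform headings, scaled so
the expected daily path length equals the subject's distance dial; gyro
bursts are white noise whose momentum is proportional to the subject's
intensity dial; call/message counts are Poisson with log-normal call
durations and shifted-geometric message lengths; contacts are drawn from a
per-subject pool with Zipf weights; screen sessions alternate exponential
off/on holding times whose stationary on-fraction matches the daily screen
target, clipped at midnight. Daily means (240 screen minutes, 5 km, 3
received and 2 sent calls, 10/8 messages, 2 images, ...) and
between-subject dispersions (roughly 25–30% of the means) were chosen once
as values a practitioner would call realistic for an adolescent cohort; the
study itself reports no raw-feature summaries to calibrate against.

**Planted effects** are standardized mean differences at the subject
level: an effect of `d` on a feature shifts the case-group mean of that
feature's generator dial by `d` between-subject SDs. Each of 12 features
has an independent dial; in particular the total call-time and
message-length dials set per-subject daily totals directly (per-event
means are derived by dividing by the subject's count rate), so effects on
totals do not leak into counts or vice versa. The two distinct-contact
features have no dial of their own — they emerge from the contact-pool
draws — and requesting an effect for them is a validation error. The
default case-vs-control effects plant the qualitative group differences
reported for this design (more screen time, more received calls, longer
distances in the MDD group); responder effects default to zero, mirroring
the absence of prominent responder/nonresponder differences in single
features. All randomness flows from one spec-level seed through
deterministic per-subject, per-stream, per-day sub-seeds, so identical
specs yield byte-identical cohorts while streams stay mutually
independent.

What the generator does **not** emulate: circadian and weekday structure,
autocorrelated mobility (trips, routines), heavy-tailed screen sessions,
missing not-at-random gaps, or any coupling between clinical severity and
behaviour beyond the planted mean shifts. Passing tests therefore
demonstrate that the pipeline recovers known structure under clean
conditions — not that the same accuracies would be reached on real
adolescent data; the accuracies printed for the original private cohort
are context, not reproduction targets.

## Validation study conditions

The test suite and `scripts/acceptance.R` run the same frozen designs:

* **Dominant-feature recovery**: effect 3.0 on momentum, all other
  features null; 100 seeded cohorts; the importance table from one
  subject-level 3-fold pass (3 elimination paths over the 14 raw features
  of the baseline week) must top-rank momentum in at least 95 of them. One
  dominant feature against null competitors is the appropriate condition
  because the non-overlap score saturates near 1 for any strongly
  separated feature — two saturated features cannot be ordered reliably by
  any overlap measure.
* **Effect-order recovery**: a wide graded ladder (4.0 down to 0.15 over
  the 8 independently dialled features, counts and contact features null)
  on all monitored days; the median Spearman correlation between planted
  magnitude and inverse averaged rank over 20 seeds must reach 0.8. The
  rungs are widely spaced because with 24 + 10 subjects the realized
  standardized effect scatters around the planted one with an SE near
  0.37 — adjacent rungs closer than that are unresolvable at this sample
  size regardless of method.
* **Null calibration**: subject-level label permutation of a default
  cohort; the repeated-CV mean test accuracy of both classifiers must fall
  inside the 95% binomial interval around the majority-class rate, with
  the interval's n taken as the rows of one CV pass (repeat means are
  strongly dependent, so counting rows × repeats would overstate the
  information).
* **Separability ceiling**: effects of 3.0 on screen time, distance and
  momentum; the full NEWFM → DNN pipeline must reach a mean test accuracy
  of 0.9.

Problem sizes (100/20 seeds, one 3-fold pass for importance, 10 repeats
elsewhere) are the package's validation design.

## Numerical and degenerate-input conventions

Min-max scalers map constant features to 0.5 and flag them. Ties in
feature scores break by ascending feature index; classification ties go to
the first class level; majority-vote ties go to the first level as well.
Zero-variance t-test input returns `p = 1` for equal means and `p = 0`
otherwise. The Fisher test sums hypergeometric probabilities no larger
than the observed table's probability with a relative slack of 10⁻¹²
for floating-point ties. Percentages in baseline tables round half-up.
The pooled Student t is the default variant with Welch exposed; baseline
tables print both because with markedly unequal group spreads (e.g. an IQ
comparison of SD 16.6 vs 6.1 at n = 24 vs 10) the two variants genuinely
disagree (p ≈ 0.10 vs 0.23) and a report should show the difference
rather than hide it.

## Known limitations

Two-class problems only, triangular membership functions only. The DNN is
a plain dense network without regularization — at these sample sizes it
will overfit the training folds (training accuracy near 1), which is
visible in the reports and is why accuracy is always quoted from held-out
folds. The generator's independence assumptions (between days, between
streams) make the synthetic task easier than real behavioural data; the
null-calibration check guards against optimistic bias of the protocol
itself, not of real-world transfer.
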