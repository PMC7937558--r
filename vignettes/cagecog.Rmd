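---
title: "Classifying mouse genotypes from automated home-cage behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mouse genotypes from automated home-cage behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Knock-in mice carrying humanized amyloid-precursor-protein mutations
(`App^NL-G-F/NL-G-F`, "KI") model the preclinical stage of Alzheimer's
disease: amyloid pathology is present while overt cognitive symptoms are
still mild. An automated group-housing cage instruments four corner
chambers and records every corner visit, nose-poke at a doorway, lick at a
drinking bottle, and the task apparatus events (LED cue, door, air puff)
around them, while a battery of five tasks runs: place preference learning
(PP), its reversal (PPR), a serial reaction time task (SRTT), place
avoidance (PA) and delay discounting (DD).

`cagecog` turns those event logs into the canonical battery of 60 behavioral
parameters in 11 groups (daily correct-corner visit rates; daily
premature-trial rates; per-stimulus-duration attention metrics;
place-avoidance error rates per period; per-delay saccharin nose-poke and
lick rates), screens them with per-feature genotype statistics, and asks the
central question: *can the genotype be predicted from behavior alone?* Two
classifiers answer it — a small feed-forward neural network, and a
univariate threshold-vote rule set as the non-neural control — each fed by a
cross-validated stepwise forward feature-selection loop.

## The feature schema

`default_schema()` fixes the 60 parameters with per-group counts
7, 7, 8, 3, 3, 3, 3, 3, 4, 9, 10. Groups 3 (SRTT impulsivity) and 10
(DD nose-poke rates) carry reduced counts — 8 of 10 task days, 9 of 10
delays — because in cohorts of ~27 animals some day/delay cells are
unavailable for more than half the sample. Which cells survive is not
derivable from the battery itself, so the default keeps SRTT days 3–10 and
drops the 0.1 s delay: the earliest training days and the near-zero delay
are the most plausibly sparse cells. Both choices are arguments of
`default_schema()`, and on real data `missingness_filter()` re-derives the
drop empirically (a feature is removed when strictly more than half of its
cells are missing).

Rate-kind parameters live in [0, 1]. For the DD groups the battery only
speaks of "rates" without a denominator; here they are normalized per corner
visit within the delay condition (visits are the natural exposure unit in a
corner-based cage and are robust to session-length differences), so they are
non-negative but may exceed 1.

## Extraction conventions

A *trial* in the SRTT is one corner visit. The first nose-poke initiates the
trial; the waiting period runs from that poke to the LED cue. A trial is
*premature* when any further poke lands inside that window (one trial counts
once, however many pokes). This matters: counting the initiating poke itself
would mark every initiated trial premature. Premature trials abort — the
door never opens — so they are excluded from the correct set, which is
exactly why the correct rate over non-premature trials (group 8) dominates
the correct rate over all trials (group 7) wherever both are defined; the
test suite asserts this inequality on every simulated cohort, along with
the conservation premature + non-premature = total.

An *omission trial* is a visit with no nose-poke at all; an *omission error*
is an initiated, non-premature trial where the door opened and closed
without a lick. The door-open window is read from the `door_open` /
`door_close` events themselves, since the hardware's exact windowing
protocol is not part of the data model. Zero denominators (no visits that
day, no trials at a duration, no pokes in a period) yield missing cells, not
zeros — missingness is information about availability, not behavior.

Correct corners (PP), their diagonal reversal (PPR) and the air-puff corner
(PA) must be supplied; `default_corners()` gives the convention used by the
simulator (1, 3, 2). The saccharin bottle side in DD defaults to `"R"`.

## The synthetic cohorts

The generator exists so that every downstream stage is testable without
animal data, and its defaults are fixed to the cohort design the package
targets: cohorts of
13 WT / 14 KI (phase 1, ages 8–12 months), 14/15 (phase 2, 13–17 months) and
10/10 (animals observed in both phases). Feature-level simulation draws each
mouse's parameter vector independently from
Normal(mean~genotype~, SD), clips to the feature's domain and masks cells
missing. Clipping (rather than resampling) is chosen for speed and
determinism; at the default SDs the induced bias is small and documented.

Effects are planted where the genotype contrast concentrates in each phase:
the `phase1` preset raises the KI delay-discounting nose-poke and lick rates
(groups 10–11, the compulsive-persistence signature) and lowers the KI
reversal day-1 rate; `phase2` lowers the KI reversal-learning rates
(group 2) and keeps the DD contrast. The planted standardized difference is
d = 1.2, a single fixed convention (no empirical per-parameter means or SDs
are assumed anywhere in the generator): d = 1.2 makes a
~27-animal cohort detect the planted features with high power while leaving
the null features at the 5% false-positive floor. Baseline means/SDs (e.g.
visit rates 0.5 ± 0.15, DD lick rate 4 ± 1.5 per visit) are likewise
declared conventions, not reproductions. Missingness defaults to 0 except
groups 3 and 10 (0.1), which exercises the filter.

Event-level simulation draws the same per-mouse targets and then emits a
session log whose extraction recovers them up to binomial/Poisson noise:
PP/PPR visits hit the correct corner with the target probability, PA pokes
hit the avoided corner likewise, and DD saccharin pokes/licks are Poisson
per visit. The SRTT is generated from three per-trial primitives —
omission-trial, premature and lick-given-open probabilities — with the lick
probability inverted from the group-8 target; the group-5/7 rates then
*emerge* from those primitives rather than being driven independently
(the five attention metrics are arithmetically coupled, so they cannot all
be planted at once). The event/feature consistency test therefore covers the
driven groups (1, 2, 4, 6, 8, 9, 10, 11). The generator makes no attempt to
model circadian structure, inter-event waiting times or social interaction;
passing tests show the *analysis* is correct under the stated statistical
structure, not that real cage data follow it.

## Statistics

Genotype contrasts are pooled-variance Student t tests — the pooled form is
identified by the degrees of freedom the cohort sizes imply (25 for 13+14,
27 for 14+15) — with two-sided p values and *no* multiple-testing
correction, matching single-feature screening practice for this battery;
`genotype_tests()` annotates the expected false-positive count
(alpha x 60 = 3) as context. Zero-variance samples return an explicit
degenerate flag instead of an infinite statistic. Paired phase-1 vs phase-2
contrasts use the one-sample t on per-mouse differences (df = n − 1).

## Classifiers

**Network.** A single hidden layer of 8 logistic units, L2 penalty 10^-3,
trained to convergence (cap 500 quasi-Newton iterations) via `nnet`. The
topology is deliberately small for n < 30 and deliberately *not* optimized —
architecture search is out of scope — so all reported differences are about
feature selection, not tuning. Given a seed, training is bit-reproducible.

**Threshold vote (control).** Per feature, candidate cut-offs are the
midpoints between consecutive sorted unique training values; each candidate
is scored by training accuracy under both directions (KI above or KI below
the cut), and ties resolve toward the smaller threshold and the KI-above
direction. Animals are labeled KI when strictly more than half of the rules
vote KI; an exact split goes to WT. The combination rule is the simplest one
consistent with per-feature thresholding; the test suite proves the fitted
rules and the vote equal an exhaustive brute-force search on hundreds of
random small instances.

**Cross-validation.** Stratified 5-fold, repeated 20 times by default, with
the SD taken over repeats (LOOCV is available; it gives no comparable SD).
All preprocessing is fold-local: missing cells are imputed with the training
fold's medians, and the network path z-scores features on training-fold
statistics (zero-variance columns map to 0). Nothing from a held-out animal
touches training — the suite asserts this with a sentinel test where held-out
data shifted by +100 stays shifted after transformation.

## Feature selection and the two accuracy estimates

The starter feature is the best single feature by cross-validated accuracy
(ties: larger |t|, then schema order) — a deliberate design choice among
several defensible screening criteria, made because it sends the starter to
the most discriminative parameter groups. Stepwise forward
selection then adds, at each step, the remaining feature that maximizes the
same cross-validated accuracy, stopping once the running best has not
improved for `patience = 3` consecutive additions (bounded runtime; the
optimum is read from the recorded trace either way, as the smallest prefix
achieving the maximal accuracy).

Because one cross-validation score both selects and evaluates, the resulting
"selection-scored" optimum is optimistically biased: on null cohorts it sits
well above 0.5. `nested_selection_cv()` reports the honest counterpart —
selection re-run from scratch inside each outer training fold, scored on the
untouched outer fold — which concentrates around chance on null cohorts.
Both numbers are first-class outputs because they answer different
questions: the first scores a feature subset the way the selection loop saw
it, the second estimates generalization.

## The experiment grid

`run_experiment()` crosses phases (1, 2, both) with selection regimes
(stepwise; significant features, optionally split by direction; all
features) and classifiers, optionally appending a 0/1 sex input node. The
"both phases" cohort concatenates each mouse's two phase vectors
(`p1_`/`p2_` prefixes) for the animals observed in both windows. Cells that
cannot be computed — an empty directional significant set is the common case
on null data — are marked failed with a reason and never abort the run. The
report carries a config hash and master seed; a fixed (config, seed) pair
reproduces the JSON rendering byte for byte.

## Numerical and sizing choices

Simulation-heavy checks in the tests and the acceptance script use sizes
chosen as a deliberate compromise between Monte-Carlo stability and
turnaround: 1000 replicates for the type-I calibration (binomial SE ≈ 0.003
on the pooled rate), 50 seeds for the nested null accuracy, 20 seeds with
3-repeat inner CV for the planted-effect recovery, and a `max_steps` cap of
8 with single-repeat inner CV inside nested runs (under the null the
stepwise loop has no signal to find, so capping it changes nothing but
runtime). These are analysis choices stated here once; none of them is a
generator parameter.

Known limitations: the threshold-vote tie conventions (equality at a cut and
exact vote splits go to WT) make label-swap symmetry exact only for odd rule
counts; clipped Gaussians slightly bias rate features with means near their
domain edge; and the event grammar is a minimal abstraction of a cage
controller — it is sufficient for every parameter in the schema but does not
model hardware idiosyncrasies such as interrupted visits or door-open
windows that vary by trial.
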