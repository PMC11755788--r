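---
title: "Combined supervised and unsupervised behavioral phenotyping with cagewalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined supervised and unsupervised behavioral phenotyping with cagewalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagewalk)
```

## The assay and its model

`cagewalk` quantifies mouse behavior from two complementary assays and
fuses them into group-level behavioral profiles:

1. a **22-hour home-cage assay**: individually housed animals are
   filmed at a 1-second snapshot interval while a display simulates a
   6-hour daytime phase, a 6-hour nighttime phase, a 6-hour nighttime
   phase with three visual stimulus presentations, and a final 4-hour
   daytime phase. Stimuli appear at elapsed hours 12, 14 and 16 — the
   starts of assay hours 13, 15 and 17. Analyses are organized in
   10-minute periods; the three onsets fall at the starts of periods
   73, 85 and 97, and a full recording spans 132 periods.
2. a **walkway gait assay**: the animal crosses a glass walkway while
   a camera records timestamped paw prints (contact/release times,
   print geometry, print intensity), from which paw, support and step
   parameters are computed per run and averaged per animal.

On the home-cage side, per-frame poses (12 keypoints with tracking
likelihoods) drive a supervised 52-parameter battery, centroid tracks
drive a 15-parameter battery, and an externally produced syllable
label sequence (from an unsupervised segmentation over a 29-syllable
codebook) is summarized as per-syllable bout frequencies and mean
durations. The four blocks concatenate into one profile of
15 + 52 + 29 + 29 = 125 named parameters per animal; group profiles
are means over the animals of each experimental group.

## Coordinate, time and indexing conventions

* image coordinates: origin at the top-left of the cage crop, x
  rightward, y downward, pixel units; a configurable `px_per_cm`
  scale (default 6) converts speed thresholds.
* 0-based frame indices in files, 1-based period numbering (the first
  stimulus onset at elapsed hour 12 is 72 whole periods in, hence
  period 73).
* all intervals (phases, periods, feature windows, syllable windows)
  are half-open `[start, end)`: a boundary instant belongs to the
  later interval.
* reduced-duration timelines (`assay_timeline(hours = 2)`) rescale
  phases, onsets and the period length proportionally, preserving the
  period arithmetic (onsets still index to periods 73/85/97). This is
  how desk-scale simulations keep the full assay topology.

## Likelihood filtering

Pose estimates with likelihood below 0.90 (strict) are masked. The
treatment of masked frames is not standardized across pipelines; this
package linearly interpolates masked coordinates from the nearest
valid neighbours (carrying the nearest value at the recording edges)
so that downstream speed computations never see sentinel values. The
mask is kept on the recording for audit and the masked-entry count is
reported. The operation is idempotent, and a keypoint with no valid
frame at all is an error rather than a silently empty track.

## The feature batteries

The published analyses name a specific set of parameters: movement in
the first hour and the first night hour; movement/scoot/burst/escape/
speed classes; acclimation in % movement and % stretch-attend posture
(SAP); habituation to the moth stimulus and to the first moving-lines
presentation; quadrant occupancy; distance from the nearest wall; and
time near the social window with a partner. The full 15- and
52-parameter registries behind the published counts are supplementary
material not reproduced in the text, so the registry here fixes the
named parameters verbatim and fills the remaining slots with
documented analogues — per-phase speed classes, SAP and hut occupancy,
per-presentation stimulus responses — each labelled
`extension = TRUE` in the registry source. The registry is versioned
(`cagewalk-registry-1`) and stamped into outputs; batteries always
emit exactly 15 and 52 rows, with uncomputable entries flagged missing
rather than dropped.

Parameter definitions with open choices:

* **speed classes**: per-frame speed is centroid displacement times
  frame rate. No instrument thresholds are published; defaults (in
  cm/s: move 0.5, scoot band up to 4, burst from 4) were chosen once
  so the classes are non-degenerate on the synthetic baseline, and are
  fully configurable via `speed_class_config()`.
* **escape** is operationalized as stimulus-locked: burst frames
  within 600 s of an onset whose displacement is directed toward the
  hut. Whether escape should be free-running is not specified
  anywhere; the stimulus-locked reading matches its grouping with the
  habituation parameters.
* **SAP**: elongation (nose-to-tail-base distance over the animal's
  median body length) above 1.2 while below the movement threshold.
* **acclimation** is the metric in period 1 minus period 6 (a simple
  monotone first-minus-later index rather than a slope), positive when
  behavior declines over the first hour.
* **habituation**: each presentation's response is the metric in the
  first period after onset minus the period before onset; the moth
  index is response 1 minus response 3, the first-moving-lines index
  response 1 minus response 2.

## The synthetic cohort generator

The generator exists so every pipeline stage has a parameter-recovery
test surface; it emulates the statistical structure the features
measure, not mouse kinematics. Per animal:

* a two-state rest/active semi-Markov process with mean bout length
  6 s. The transition hazards are parameterized so the stationary
  active fraction *equals* the target occupancy, making % moved linear
  in the knobs: baseline daytime occupancy 0.12, night multiplier 2,
  an acclimation excess (amplitude 1.5, time constant one fifth of the
  first assay hour), and per-onset response boosts (amplitude 1.5,
  group gain, habituation decay 0.5 per presentation).
* active frames advance the centroid by a correlated random walk with
  soft wall reflection and a weak homing bias toward the hut corner;
  rest frames hold position exactly.
* stretch-attend postures are a second occupancy process (baseline
  0.05) expressed during rest via an elongated body template.
* the 12 keypoints sit on a rigid head+trunk template oriented along
  motion, with 0.5 px Gaussian observation noise and likelihood
  dropout below 0.90 at rate 0.03.
* syllables: semi-Markov bout sequences from a row-stochastic,
  zero-diagonal transition matrix (uniform by default, 29 syllables,
  mean bout durations 2–5 s); group usage tilts scale the incoming
  transition probabilities of one syllable and renormalize.
* gait: runs of ~20 steps in the canonical alternate order
  RF-RH-LF-LH at a 0.22 s step interval with duty factor ~0.43 (so the
  support decomposition populates multi-paw categories), per-paw print
  templates, and group knobs for steps per run, print length, hind
  base of support, stand/step-cycle scale, hindpaw intensity gain and
  step-order corruption probability.

All group effects are ratios against the wild-type-young baseline
(`default_effects()`), with directions mirroring the published
contrasts: AD animals hypoactive, more SAP, blunted stimulus response,
fewer steps, corrupted step sequences and shorter front prints when
young; heavier hindpaw loading and a tilted syllable repertoire when
old; cyclosporine-treated old animals resembling old wild types and
the other two treatments resembling young AD animals. Everything is
deterministic under the configuration seed.

What the generator does **not** emulate — realistic posture dynamics,
grooming, inter-animal variation in body size, camera distortion —
bounds what passing tests show: they demonstrate that the pipeline
recovers planted statistical structure, not that it measures real
mice correctly.

## Profiles, weighting and clustering

Group profiles (one row per experimental group, 125 columns) are
z-scored per column; PCA is run on the z-scored matrix and each column
is weighted by the absolute value of its loading on the first
principal component, renormalized to mean 1 (zero-variance columns get
weight 0 and are flagged). Distances are Euclidean on the z-scored
columns multiplied by the square root of their weight — so squared
distance is linear in the weights and equal weights reproduce
unweighted Ward linkage exactly — followed by Ward clustering and a
flat cut at k = 3. Rows are sorted lexicographically before linkage so
tie-breaking is deterministic. Dendrograms export as Newick with merge
heights as branch lengths.

Open choices made here, both with the simpler/better-defined reading:
loadings enter as absolute values (signed weights are meaningless for
distances), and scaling precedes weighting (so the weights are the
sole source of differential column influence). Missing profile cells
(flagged battery entries, durations of unexpressed syllables) are
imputed by the column median across animals, with the imputation count
kept for audit.

## Statistical battery

Shapiro–Wilk gates normality at p ≥ 0.05. Gait parameters use two-way
ANOVA (age × genotype) with the Tukey HSD pairwise table computed only
when the interaction is significant at p < 0.05. Home-cage parameters
use the unpaired two-sided Wilcoxon rank-sum test: the exact null when
both groups have at most 10 observations and no ties, otherwise the
tie-corrected normal approximation. Syllable usage uses
Kruskal–Wallis with Dunn's two-sided pairwise z tests on the joint
mid-ranks (tie-corrected variance). Dunn's adjustment method is not
standardized; the default here is Holm, configurable. Tests are
per-parameter at p < 0.05 without cross-parameter correction,
mirroring the published analyses; Benjamini–Hochberg is available
behind a flag in the significance-matrix layer. Stars are the
conventional \*, \*\*, \*\*\* at 0.05/0.01/0.001 with arrows marking
direction against the reference group.

## Numerical choices and degenerate inputs

* support decomposition defaults to a 1 ms discretization; an exact
  event-driven decomposition over the contact/release breakpoints is
  also available and is used as the convergence oracle. Overlapping
  same-paw prints (double placements) are handled by interval union.
* NSSP uses sliding 4-step windows with per-step attribution, each
  window matched against the six canonical step sequence patterns
  (alternate Aa/Ab, cruciate Ca/Cb, rotary Ra/Rb) up to rotation of
  the starting paw. The six patterns are exactly the six cyclic
  classes of the 24 paw orderings, so a window is normal precisely
  when all four paws appear once; the classifier still matches
  patterns explicitly and is tested against exhaustive enumeration. A
  duration-weighted variant is available. Runs with fewer than 4 steps
  yield a flagged `NA`.
* run compliance is strict: duration < 10 s (a 10.0 s run is
  excluded) and one-directionality (counter-directional heel-track
  excursion above 30 px is a reversal).
* empty feature windows, keypoints with no valid frames, constant
  samples in normality tests, single-leaf dendrograms, and
  non-stochastic transition matrices are all errors, not silent
  results.

## Validation scales

The test suite and the acceptance script run on reduced-duration
cohorts that keep the full assay topology: 1–2-hour recordings at
1 Hz, 20 seeds for stochastic checks, 2 000 null simulations for the
ANOVA calibration, and 1 000 random footfall schedules for the
support partition. The parameter-recovery check (`recovery_check()`)
simulates all ten groups at 2 hours with 8 animals per group — the
wild-type cohort size of the design being emulated. Group profiles
are means over animals, and a one-animal "group" degenerates to a
single-animal profile whose sampling noise at desk scale swamps the
planted structure, so the check runs at a realistic cohort size. At
8 per group the planted night/day ratio, hindpaw intensity gain,
step-sequence deficit and syllable tilt are recovered in direction in
essentially every seed, and the k = 3 weighted-Ward cut separates the
old-wild-type-like from the old-AD-like group. The flat 3-cut on ten
groups is the one check that occasionally misses even without
measurement noise: the treated groups are planted as intermediates
(that is the biology being emulated), and a 3-cut of a continuum can
isolate a singleton elsewhere in the tree.

## Known limitations

* Registry extensions stand in for unpublished supplementary
  parameter definitions; they are explicit stand-ins, not
  reconstructions, and are labelled as such in the registry source.
* Grooming/eating/peeking measures are pose proxies (hut occupancy,
  window time), not video classifiers.
* Print intensity is treated as 0–255 arbitrary units; body-weight
  confounding of intensity is noted but not modelled.
* The generator's group effect table is a stylized rendering of the
  published contrast directions, not a fit to any dataset.
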