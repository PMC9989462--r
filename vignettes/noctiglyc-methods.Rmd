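---
title: "Sleep structure and next-day glycemia: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep structure and next-day glycemia: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noctiglyc)
```

## The problem

Adults with type 1 diabetes frequently sleep poorly, and there is growing
evidence that fragmented or inefficient sleep degrades next-day glycemic
control. Testing that association requires two simultaneously recorded data
streams per person — wrist-actigraphy sleep staging (wake / light / deep /
REM, in epochs) and flash continuous glucose monitoring (interstitial glucose
every 15 minutes) — plus a considerable amount of glue: the streams must be
synchronized, incomplete days removed, per-night sleep and per-day glycemic
variables computed, nights grouped by the *structure* of sleep rather than
just its duration, and the glucose dynamics of those groups compared.

`noctiglyc` implements that whole chain as composable, tested functions, and
pairs it with a synthetic cohort generator so that every stage — including
the statistical conclusions the design is meant to support — can be exercised
and validated without access to device data.

## Ingest and synchronization

CGM exports are read from the flash-meter CSV dialect (historic rows only,
`Record Type == 0`); sleep logs from the tracker JSON dialect (one hypnogram
per main-sleep record). Synchronization snaps every timestamp to the nearest
multiple of 5 minutes, then aggregates sleep-epoch durations into 15-minute
bins (each bin labelled by its majority stage) and resamples glucose onto the
96-slot day grid, taking the nearest snapped sample within ±7.5 minutes and
marking a gap otherwise.

Numerical conventions, chosen once and fixed:

* the 2.5-minute snapping tie rounds **up**;
* a day is discarded when any glucose gap exceeds 90 minutes — *strictly*
  greater, so a gap of exactly 90 minutes survives;
* naps and mislabelled daytime sleeps are removed automatically by requiring
  the sleep midpoint to fall in a configurable nocturnal window (default
  20:00–12:00), replacing a manual curation step that cannot be reproduced
  programmatically;
* timestamps are timezone-naive local times.

Filtering never loses records silently: kept + discarded always equals the
input count and every discard carries a reason.

## Glycemic variables

All range accounting starts from per-minute linear interpolation between
consecutive readings (the Rosendaal method): `interpolate_minutes()` is the
single source of minute series for `time_in_ranges()`, `count_episodes()`,
`mage()` and `mdgd()`.

* **Ranges.** Level 2 hypoglycemia < 55, level 1 hypoglycemia 55 to < 70,
  target 70–180 (both endpoints in range), level 1 hyperglycemia > 180 to
  250, level 2 > 250 mg/dl. The printed band labels overlap at their
  endpoints, so the package fixes closed-on-target bands; the five
  percentages partition the axis and sum to 100 by construction.
* **Episodes.** A maximal run of minutes below 70 (or above 180) counts as an
  episode when it lasts at least 15 minutes; runs separated by even a single
  in-range minute count separately.
* **MAGE.** Classic 1-SD rule: the minute series is smoothed with a 3-point
  moving average, turning points located after collapsing plateaus, and the
  mean absolute peak↔nadir amplitude taken over excursions exceeding one
  (unsmoothed) SD of the day. A 1e-9 absolute guard on the threshold stops
  floating-point wiggle from the moving average registering as an excursion
  on a flat day. When nothing qualifies MAGE is `NA`, not 0.
* **MDGD** is implemented as MODD: the mean absolute difference at matching
  clock times on consecutive days, averaged over day pairs.
* SDs are sample SDs (n − 1) throughout; CV = 100·SD/mean.

Cohort tables aggregate in two stages: per-participant mean ± SD over that
participant's nights, then an overall row that sums counts and takes the
*unweighted* mean of participant means, so participants with more nights do
not dominate. That convention reproduces the published overall rows of the
reference tables shipped in `inst/extdata` exactly, which is how it was
fixed.

## Sleep variables

Total sleep time is the sum of non-wake minutes; efficiency is
100·TST/time-in-bed; sleep onset is the first non-wake epoch; WASO counts
wake minutes strictly after onset (wake before onset is latency); an
awakening is any maximal wake bout after onset, with no minimum length. A
night is **poor** when at least two of three hold: efficiency < 85%,
WASO > 40 min, awakenings > 4 — all comparisons strict, so a night exactly on
every boundary is good. PSQI questionnaires are scored by summing the seven
0–3 components; a global score above 5 flags a poor sleeper.

Disorder of a night is its Shannon entropy in bits. Two definitions are
exposed because the underlying notion ("structure = transitions between
stages") is ambiguous: `states` mode uses the distribution of 15-minute epoch
states (0–2 bits for four stages) and `transitions` mode — the default,
because it responds to *switching* rather than composition — uses the
distribution of adjacent state pairs (0–4 bits).

## Clustering nights

Nights become vectors in one of two ways. The default `transitions` encoding
is the flattened 4×4 matrix of adjacent state-pair counts (16 features),
which matches the transition-based notion of structure and tolerates unequal
night lengths. The `sequence` encoding one-hot-codes all 44 slots × 4 stages
(176 features), padding shorter nights with wake; it is retained because the
literal "cluster the state sequences" reading is equally defensible, and the
choice of representation is the largest genuinely open design decision in
this pipeline. Both are first-class and tested.

k-means (Euclidean, 10 restarts, 300 iterations, mandatory seed) groups the
encodings; k defaults to 4 with a documented silhouette sweep over k = 2..6
(`sweep_k()`). Cluster glucose behavior is summarized by bin-wise means of
member days' 96-slot grids, and clusters are ranked by mean member entropy.

## Motif specificity

To describe *where* in the day a cluster's glucose behaves distinctively,
each day curve is z-normalized, reduced by PAA (block means of 4 samples →
24 points of one hour each), discretized by SAX against equiprobable
standard-normal breakpoints, and cut into words (default length 12, sliding
step 1). The alphabet size is **not** a given of the method; the default of
7 is a common SAX choice and is carried in `sax_config()` into every output.

Clusters act as documents for TF-IDF: `tf` is the within-cluster relative
frequency, `idf = ln(K/df)`, so words common to all clusters weigh zero and
words private to one cluster weigh `tf·ln K`.

The cosine-similarity step admits two readings, and both are implemented.
`cluster_similarity()` compares whole-cluster TF-IDF vectors (one number per
cluster pair). The per-word default used by `specificity()` compares, for
each word, its *positional occurrence profiles* (counts of the word starting
at each window position) between clusters:
`spec(w, c) = 1 − max over other clusters of cos(profile(w,c), profile(w,c'))`,
with cosine against an all-zero profile defined as 0. Hence a word occurring
only in one cluster scores 1 there, and identical corpora score 0
everywhere. A time bin's score is the mean specificity of the word
occurrences whose window covers it (`NA` if uncovered), mapped back from PAA
bins to the 15-minute grid. High-scoring spans are the cluster-specific
glucose segments; low-scoring spans are common to all clusters. Note that
cosine on positional profiles is scale-free: a word used in the same
positions but much more often in one cluster is *not* specific by this
definition — that frequency contrast is exactly what the TF-IDF weights
capture instead.

## Statistics

Participant-level analysis assembles one row per participant (means and SDs
over nights/days of every sleep and glycemic variable — the SD-of-efficiency
and SD-of-mean-glucose columns are the variability measures of primary
interest) and computes a Pearson correlogram; participants with fewer than
two nights have no SDs and are dropped. Cluster-level analysis uses Welch's
heteroscedastic one-way F (`stats::oneway.test`, appropriate because cluster
sizes and variances differ) followed by all pairwise Welch t-tests with
Bonferroni adjustment `min(1, C(k,2)·p)` at α = 0.05. Pairwise tests are
Welch, not pooled-variance, for consistency with the omnibus test. One
property worth knowing: for k > 2 Welch's F does **not** reduce exactly to
the classical F under equal variances — the small-sample denominator
correction keeps it slightly below, converging only as n grows; the test
suite asserts the exact reduction only in the two-equal-group case where it
genuinely holds.

## The synthetic cohort

The generator's defaults describe the study conditions the pipeline targets:
22 participants, 6–16 nights each, nights of 40–44 15-minute epochs starting
22:00–23:00, glucose on the 15-minute grid. Sleep is a first-order Markov
chain over the four stages; four built-in archetypes (fragmented,
consolidated, deep-cycling, REM-cycling) are deliberately well separated in
transition-count space so they can serve as planted ground truth; their
stationary distributions are available analytically
(`stationary_distribution()`) as an independent oracle for the simulator.

Glucose is basal (140 mg/dl) + a 10 mg/dl circadian sinusoid (trough ~04:00,
peak ~16:00) + Gaussian meal excursions (07:30, 13:00, 20:30; 60 mg/dl peak,
45-minute SD) + Gaussian noise (SD 10 mg/dl), clipped to the 40–400 mg/dl
sensor range and rounded to integers as a flash meter reports. The
sleep–glucose coupling inflates the **nocturnal** noise SD additively:
`sd = noise_sd + coupling × (100 − efficiency)` mg/dl, i.e. `coupling` is in
mg/dl per lost percentage point of efficiency. An additive form was chosen
over a multiplicative factor because the coupling strength then has the
units its interpretation suggests, and a fragmented night (efficiency 70,
coupling 2) plausibly triples rather than explodes the nocturnal noise.
With the default coupling of 2.0 the generated cohorts reproduce the
strong positive correlation between night-to-night variability of sleep
efficiency and of mean nocturnal glucose that motivates the design; with
coupling 0 that correlation vanishes, which the tests also check.

What the generator does **not** emulate: insulin dosing and
carbohydrate-counting behavior, sensor dropout and compression lows,
autocorrelated physiologic noise, weekday/weekend habit structure, or any
feedback from glucose back onto sleep. Passing recovery tests on this cohort
therefore demonstrates that the pipeline detects the planted statistical
structure at realistic sizes and noise levels — not that real cohorts
contain that structure.

## Problem sizes and runtime

The validation suite runs recovery experiments at the cohort's natural
scale: correlation recovery on 22 participants (~240 nights), cluster
recovery over five seeds at ~240 nights each, a planted-motif experiment
with 4 × 30 days, oracle-equivalence sweeps of 1000 random instances per
glycemic/symbolic operation, and 10,000 null simulations for the size of
Welch's test. The full suite completes in under two minutes on a single
CPU; a complete end-to-end pipeline run (`run_all()`) takes a few seconds
and emits a manifest (seed, filter counts, stage checksums) that is
bit-identical across reruns of the same configuration.

## Known limitations

* The nap filter is a proxy; genuinely irregular sleepers (shift workers)
  need the window widened or disabled.
* MAGE has many published variants; the one here (symmetric mean of
  qualifying turning-point amplitudes on a lightly smoothed minute series)
  is the classic 1-SD reading, but absolute values are not comparable across
  MAGE implementations.
* Per-word positional cosine specificity is insensitive to pure frequency
  contrast (see above); inspect the TF-IDF weights alongside it.
* The transitions encoding discards the *timing* of stage changes within the
  night; the sequence encoding keeps timing but is sensitive to night-length
  padding.
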