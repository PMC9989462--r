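# noctiglyc

Sleep structure and next-day glycemic control from paired wrist-actigraphy
and flash continuous glucose monitoring (CGM), for researchers studying
sleep–glucose interactions in type 1 diabetes.

The package implements the full analysis chain as tested R functions:

* **Ingest** — FreeStyle-Libre-style CGM CSV exports and Fitbit-style
  sleep-log JSON; 5-minute timestamp snapping, 15-minute resampling,
  discarding days with glucose gaps > 90 min and non-nocturnal sleeps.
* **Glycemia** — per-minute Rosendaal linear interpolation, then time in
  ranges (TIR 70–180; hypo L1 55–<70, L2 <55; hyper L1 >180–250, L2 >250
  mg/dl), mean/SD/CV, ≥15-min hypo/hyper episode counts, MAGE (classic 1-SD
  excursion rule) and MDGD/MODD (mean |ΔG| at equal clock times on
  consecutive days).
* **Sleep** — per-night efficiency (100·TST/TIB), WASO, awakenings, stage
  minutes and ratios, Shannon entropy of the stage sequence, the 2-of-3
  quality rule (poor iff ≥2 of: efficiency < 85%, WASO > 40 min,
  awakenings > 4), and PSQI scoring (seven 0–3 components, global > 5 = poor
  sleeper).
* **Clustering** — nights encoded as 4×4 stage-transition counts (or one-hot
  44-slot sequences) and grouped with seeded k-means; per-cluster average
  24-h glucose profiles and entropy ranking.
* **Motifs** — z-normalize → PAA (n = 4) → SAX → words (length 12) →
  per-cluster TF-IDF with `idf = ln(K/df)` → cosine-based per-word and
  per-time-bin specificity scores in [0, 1] (1 = cluster-specific, 0 =
  common to all clusters).
* **Statistics** — participant-level Pearson correlogram; Welch's
  heteroscedastic one-way F across clusters with Bonferroni-adjusted
  pairwise Welch t-tests (`p_adj = min(1, C(k,2)·p)`).
* **Synthetic cohort** — Markov-chain hypnograms from four planted sleep
  archetypes plus a circadian/meal/noise glucose model with a tunable
  coupling (`sd_noct = noise_sd + coupling·(100 − efficiency)` mg/dl)
  linking night fragmentation to nocturnal glucose variability, written and
  re-read in the same device dialects the ingest module handles.

## Worked example

A complete synthetic study — simulate, write/ingest device files,
synchronize, filter, summarize, cluster, mine motifs, compare — in one call:

```r
library(noctiglyc)

cfg <- run_config(sim = sim_params(seed = 42), cluster_seed = 42)
res <- run_all(cfg)
res
#> <pipeline_result> 22 participants, 249 nights (249 kept, 0 discarded),
#>   k = 4 clusters (sizes 71/38/86/54)

res$entropy_ranking
#>   cluster  n mean_entropy
#> 1       1 71     3.269638
#> 4       4 54     2.263859
#> 3       3 86     2.256529
#> 2       2 38     1.549672

round(res$correlogram["efficiency_sd", "mean_glucose_sd"], 2)
#> [1] 0.92

res$comparisons$tir$welch
#> Welch F(3.0, 113.5) = 264.834, p = 4.564e-51
round(res$comparisons$tir$group_means, 1)
#> cluster1 cluster2 cluster3 cluster4
#>     57.9     90.6     90.3     90.2
```

Reading the output: cluster 1 collects the fragmented-archetype nights — it
has the highest sleep-sequence entropy (3.27 bits) — and, because the
simulated coupling inflates nocturnal glucose noise on inefficient nights,
it is also the cluster with by far the lowest time in range (57.9% vs ~90%),
which Welch's F flags decisively. The 0.92 correlation between each
participant's night-to-night SD of sleep efficiency and the SD of their mean
nocturnal glucose is the planted sleep-variability/glucose-variability
association being recovered at cohort scale.

The package also ships transcribed per-participant summary tables from a
published 22-adult T1DM cohort (243 nights) as fixed inputs for the
aggregation operations:

```r
cohort_overall(hupa_reference("sleep_quality"),
               count_cols = c("nights", "good", "poor"))[, 1:6]
#>   nights good poor sleep_hours_mean sleep_hours_sd efficiency_mean
#> 1    243   54  189         7.145909       1.173636        83.10091
```

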