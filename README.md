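# dfcstates

Dynamic functional connectivity (DFC) states from resting-state fMRI ROI
time series, and their links to acute stress physiology and trait
mindfulness.

`dfcstates` is for researchers who study how the brain's time-varying
connectivity reorganises around a stressor (e.g. the Trier Social Stress
Test) across repeated resting runs (RS1 pre-stress, RS2/RS3 post-stress).
It implements the full analysis chain as a tested R package:

1. **Motion QC** — framewise displacement (FD) and DVARS; volumes with
   FD > 0.2 mm or DVARS > 5% are marked, plus one volume before and two
   after; marked volumes are repaired by linear interpolation (scrubbing
   would break the temporal structure that windowed coupling needs); runs
   with more than 50% marked volumes are excluded; the first 4 volumes of
   each run are discarded.
2. **MTD coupling** — the multiplication of temporal derivatives estimator.
   For ROIs *i*, *j* with BOLD first differences *dx* and run-level
   derivative standard deviations *σ*:

   `MTD_ij(t) = dx_i(t) · dx_j(t) / (σ_i · σ_j)`

   smoothed with a simple moving average over a window of *w* = 7 TRs. A
   300-volume run yields exactly 292 coupling matrices; each 114-ROI matrix
   carries 6441 (= 114 × 113 / 2) unique couplings.
3. **State detection** — coupling vectors concatenated across all subjects
   and runs are clustered by k-means with Manhattan (cityblock) distance
   and the objective-consistent component-wise **median** centroid update
   (*k* = 5, multiple restarts, best inertia kept). Fitted states are named
   (task-ready TRS, high-arousal HAS, low-arousal LAS) by optimal Spearman
   concordance with reference centroids — never by hard-coded anatomy.
4. **Occupancy metrics** — fractional occupancy per run and change scores
   ΔRS2−RS1 (stress) and ΔRS3−RS2 (recovery).
5. **Endocrine summaries** — salivary cortisol at −30, 0, +20, +60, +90 min
   around stress onset, natural-log transformed, summarised by Pruessner
   trapezoidal AUCs: with respect to ground (AUCg) and increase above
   baseline (AUCi = AUCg − c₁ · duration).
6. **Statistical battery** — pre-planned paired t-tests (RS1↔RS2,
   RS2↔RS3 for each named state), Pearson correlations of occupancy
   changes with subjective ratings, cortisol AUCs (family of 6) and
   full-scale FFMQ trait mindfulness (family of 3), with Holm (default) or
   Bonferroni family-wise adjustment, α = 0.05 two-tailed.
7. **Synthetic cohorts** — a first-class generator of covariance-switching
   BOLD whose window-level connectivity alternates among k centroid
   patterns, with a pre-to-post occupancy drop in one state and
   subject-level coupling of that drop with trait score and cortisol
   output, so the whole pipeline is testable without any external data.

## Worked example

Simulate a 40-subject cohort (3 runs × 300 volumes, TR 2 s, 20 ROIs to keep
the demo light) and run every stage:

```r
library(dfcstates)
cfg <- analysis_config(seed = 11, n_restarts = 5,
  cohort = list(n_subjects = 40, n_roi = 20, volumes_per_run = 300,
                mean_dwell = 60))
res <- run_pipeline(cfg, "demo-out")
```

```
[dfcstates] simulate: generating cohort
[dfcstates] prep: motion QC over 40 subjects
[dfcstates] mtd: windowed coupling (w = 7)
[dfcstates] fit-states: k = 5, 34560 windows
[dfcstates] fit-states: named states S5, HAS, LAS, TRS, S4 (min rho 0.84)
[dfcstates] occupancy: fractional occupancy and change scores
[dfcstates] cortisol: AUC summaries (log scale)
[dfcstates] stats: pre-planned battery (holm adjustment)
```

Key rows of `res$stats`:

```
      test variable_a variable_b estimate  n        p p_adjusted         family
  paired_t    TRS_RS2    TRS_RS1  -3.7222 40 0.000622    0.00373   state_change
 pearson_r ffmq_total  delta_TRS   0.4519 40 0.003420    0.01026    mindfulness
 pearson_r  delta_HAS  delta_LAS  -0.0562 40 0.730523    0.73052 state_coupling
```

Reading this: occupancy of the task-ready state drops from RS1 to RS2
(paired t = −3.72 over the 40 subjects, Holm-adjusted p = .004) — the
stress effect built into the generator — and subjects with higher trait
mindfulness show a smaller drop (r = 0.45, adjusted p = .01; the injected
subject-level coupling, recovered through the full BOLD → MTD → clustering
→ occupancy chain). Every table is also written to `demo-out/` as TSV with
provenance headers, plus a JSON edge list of the battery.

The same stages are exposed as functions (`prepare_run()`,
`mtd_windows()`, `fit_states()`, `match_centroids()`,
`fractional_occupancy()`, `change_scores()`, `cortisol_summary()`,
`analysis_table()`) for piecemeal use, and
`inst/scripts/run-pipeline.R` wraps `run_pipeline()` for shell use.

## Vignette

`vignettes/dfc-states-methods.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic cohorts do and do not emulate, numerical conventions
(edge-window convention, tie-breaks, degenerate inputs) and known
limitations.
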