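---
title: "Dynamic connectivity states from MTD coupling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states from MTD coupling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcstates)
```

## The model

`dfcstates` treats a resting-state run as a multivariate time series that
visits a small set of recurring whole-brain coupling configurations
("connectivity states"). The pipeline estimates time-resolved coupling with
the multiplication of temporal derivatives (MTD), identifies states by
clustering, and reduces each run to the fraction of time spent in each
state. The scientific quantities of interest are *changes* in those
fractions across a stressor (run RS1 before, RS2 and RS3 after), and their
subject-level correlations with trait mindfulness (FFMQ) and salivary
cortisol output.

### MTD coupling

For ROI signals $x_i(t)$, the estimator uses backward differences
$dx_i(t) = x_i(t{+}1) - x_i(t)$ and run-level derivative standard
deviations $\sigma_i$ (population convention, mean removed):

$$\mathrm{MTD}_{ij}(t) = \frac{dx_i(t)\,dx_j(t)}{\sigma_i\,\sigma_j},$$

smoothed by an unweighted moving average over $w$ consecutive samples.
Differencing removes per-ROI offsets and the $\sigma$ normalisation removes
per-ROI scale, so coupling is invariant to positive affine rescaling of any
ROI — a property the test suite asserts to $10^{-10}$.

Assumptions worth keeping in mind: the estimator sees only ROI-averaged
series (any voxel-level nuisance structure must have been handled
upstream); $\sigma$ is computed over the whole run, so a run mixing states
with very different derivative scales would share one normaliser; and the
moving average trades temporal resolution for variance (window $w$ sets
that trade).

**Edge convention.** A run of $T$ volumes has $T-1$ derivative samples and
the smoother retains $(T-1)-w$ window positions, dropping the first $w$.
Window $j$ averages raw samples $j{+}1,\dots,j{+}w$ (volumes
$j{+}1,\dots,j{+}w{+}1$). This convention yields exactly 292 windows for
$T = 300$, $w = 7$, matching the standard report of this analysis; centred
or symmetric-trim conventions give 289–293 and were rejected for that
reason. Note the interaction with frame discarding: 292 windows arise when
all 300 volumes enter the MTD stage. The pipeline exposes
`discard_frames` (default 4, giving 288 windows after QC discarding) and
the count always follows $T_{\text{in}} - 1 - w$; both behaviours are
available because published descriptions are ambiguous about the order.

### State detection

Window coupling matrices are vectorised to their $n(n{-}1)/2$ unique
off-diagonal couplings (row-major upper triangle; 6441 values at 114 ROIs),
concatenated across subjects and runs, and clustered by k-means under the
Manhattan (cityblock) distance. The centroid update is the component-wise
**median**: for the L1 objective the median, not the mean, minimises
within-cluster distance, so Lloyd iterations provably never increase the
objective (asserted at every sweep). Ties in assignment go to the lowest
state index; an empty cluster is re-seeded from the point farthest from its
centroid; iteration stops when labels stabilise or after 300 sweeps. The
fit runs `n_restarts = 10` random initialisations (seeds derived from the
master seed) and keeps the lowest-inertia solution; published analyses of
this kind rarely state their restart policy, so the default is explicit and
configurable. The assignment and median steps are compiled (Rcpp) — at
20,000 windows x 435 couplings a full 10-restart fit takes well under a
minute.

States receive names only by matching against reference centroids:
`match_centroids()` computes all pairwise Spearman correlations (average
ranks for ties) and finds the one-to-one assignment maximising total rho by
exhaustive search over injective maps (exact for $k \le 8$; 120
permutations at $k = 5$). Pairs with rho below a configurable floor
(default 0.5 — ambiguity is not quantified in the literature, so the floor
is explicit) or with undefined rho (constant centroid) are reported
unmatched rather than silently named.

### Occupancy and change scores

Fractional occupancy is the proportion of a run's retained windows assigned
to each state (windows are the unit that was clustered, so occupancy is
computed over retained windows only). Change scores are simple differences
of proportions, RS2−RS1 (stress) and RS3−RS2 (recovery). Because each
run's occupancies lie on a simplex, the change scores of all states sum to
zero for every subject — they are compositionally dependent, which matters
for interpreting correlations *among* change scores (see the calibration
note below). Subjects missing a run are excluded from change scores with a
message, never zero-filled.

### Motion QC

Framewise displacement is the sum of absolute backward differences of the
six rigid-body parameters, rotations converted to arc length at a 50 mm
sphere radius (the field-standard convention; the radius is a parameter).
DVARS is the root-mean-square over ROIs of the backward signal difference
as a percentage of the run's global mean signal. The percent denominator
is a documented choice: the classical definition operates on voxel data,
which this package never sees, so the ROI-level percent-of-global-mean
form is an approximation. Volumes with FD > 0.2 mm or DVARS > 5% (strict
inequalities; boundary values are not marked) are marked, plus 1 volume
before and 2 after. Marked volumes are linearly interpolated per ROI from
the nearest unmarked neighbours (ends take the nearest unmarked value) —
repair, not removal, because removal would corrupt the temporal
differencing that MTD relies on. A run fails QC when strictly more than
50% of volumes are marked. The fixed stage order is: discard initial
frames, compute FD/DVARS, mark, interpolate.

### Cortisol

Samples at −30, 0, +20, +60, +90 min around stress onset are natural-log
transformed (concentrations are positively skewed) and summarised by
trapezoidal areas: AUCg over the whole span, and
AUCi = AUCg − c₁·(t_last − t_first) with the first sample as baseline
production. The identity is asserted exactly in tests. Whether published
AUCs are computed on raw or log concentrations is typically not stated;
this package defaults to log (transform precedes integration, matching the
stated analysis scale) with `auc_log_scale = FALSE` available, and the
pipeline records which convention it used. Note that log-scale AUCs can be
negative when concentrations are below 1 µg/dL; only differences and
correlations of these quantities are interpreted.

### The statistical battery

`analysis_table()` runs the pre-planned tests: paired t-tests per named
state for RS1↔RS2 and RS2↔RS3; Pearson correlations of ΔHAS/ΔLAS with
subjective stress and alertness change; AUCg and AUCi against
ΔTRS/ΔHAS/ΔLAS (a family of six); FFMQ against ΔTRS/ΔHAS/ΔLAS (a family of
three) and against baseline TRS occupancy; and the pairwise Δ–Δ couplings.
Raw and family-wise adjusted p-values (Holm by default; Bonferroni
available — the adjustment method in this literature is usually unnamed, so
both are implemented and printed side by side) are reported per row.
Missing data are handled pairwise-complete per test; tests with fewer than
3 complete pairs are skipped with a logged reason. Spearman rho is the
Pearson correlation of average ranks with a t-transform p on n−2 degrees
of freedom.

## The synthetic cohort generator

The generator exists so that every downstream stage has ground truth. Its
defaults are the study conditions the package targets: 40 subjects, three
300-volume runs at TR 2 s, 114 ROIs, k = 5 states named TRS/HAS/LAS/S4/S5.

* **Centroids** are correlation matrices from a signed low-rank factor
  model — random module assignments give block-structured positive and
  negative couplings, plus a dense low-amplitude background factor pair so
  every ROI pair carries a small distinct coupling (empirical coupling
  matrices have no exact zeros, and rank-based centroid matching needs
  informative ranks everywhere). The construction is PSD by design; states
  are redrawn until pairwise Spearman < 0.95.
* **State sequences** switch at block granularity with geometric dwell
  lengths (states persist across windows, which makes window-level recovery
  well-posed). Mean dwell defaults to 60 samples (120 s at TR 2 s) — dwell
  times on the tens-of-seconds-to-minutes scale typical of arousal-linked
  states. An exact-quota mode (largest-remainder apportionment into
  blocks) makes empirical occupancy equal the target exactly; the
  occupancy-readout cohort mode uses it so that injected subject-level
  effect sizes are not attenuated by sequence sampling noise.
* **BOLD** is sampled i.i.d. within a state from a zero-mean multivariate
  normal with the active centroid as correlation (plus independent sensor
  noise, sd 0.1, and a +1000 baseline so percent DVARS has a realistic
  denominator). No hemodynamic convolution, no autocorrelation, no
  physiological noise: this isolates exactly the covariance-switching
  structure the estimator targets, which is also why passing recovery tests
  demonstrate algorithmic correctness, not robustness to real-fMRI
  artefacts.
* **Occupancy shift and couplings.** Group-level occupancy moves from
  (.30, .16, .18, .18, .18) pre-stress to (.24, .18, .20, .19, .19) post;
  per-run, per-state subject perturbations (sd 0.057) are renormalised onto
  the simplex, so sd(ΔTRS) ≈ 0.08 and the expected paired t on the TRS
  drop at n = 40 is ≈ 4.7 — the magnitude of the canonical group effect
  this design is meant to emulate. Each subject's latent ΔTRS then drives
  a trait score (FFMQ scale 39–195, mean 130, sd 15, default correlation
  0.32) and a cortisol response amplitude (default correlation −0.33 with
  ΔTRS, log-normal response magnitude on a rise-at-20-min /
  exponential-decay template, baseline 0.15 µg/dL). Subjective ratings are
  independent by default (no injected coupling). Motion traces are
  random walks (FD ≈ 0.05 mm) with 0.35 mm spikes at rate 0.02/volume.
* **Determinism.** Every generator is a pure function of its seed; the
  cohort generator draws one seed stream from the master seed, and the
  stream is consumed identically with and without BOLD so the two modes
  stay comparable.

## What the recovery checks compute, and at what size

* *MTD correctness*: the vectorised path is compared against a naive
  triple-loop reference on runs of 20–50 volumes and 3–5 ROIs, to
  $10^{-12}$.
* *State recovery*: 23 subjects × 3 runs × 292 windows (20,148 windows,
  ≥ the 20,000 the check requires) at 30 ROIs (435-dim coupling vectors),
  mean dwell 60 volumes, noise sd 0.1. Fitted labels agree with the
  majority-state ground truth of each window ≥ 95% after optimal
  relabelling, the generating permutation is recovered with all centroid
  rho > 0.9, and per-run occupancy errors stay below 0.05. Thirty ROIs is
  the package's chosen demonstration size: the claim being tested (label
  and occupancy recovery at ≥ 20k windows) does not sharpen with more ROIs,
  while the working set grows quadratically.
* *Effect recovery*: with an injected trait↔ΔTRS correlation of 0.6 at
  n = 200 in occupancy-readout mode, the battery's FFMQ~ΔTRS row lands in
  [0.45, 0.72] with the correct sign.
* *Type-I calibration*: 1000 null cohorts (no occupancy shift, zero effect
  sizes, n = 40) give a per-test rejection rate of ≈ 0.05 across the
  battery rows whose null is true by construction. The Δ–Δ state-coupling
  rows are excluded from this rate: differences of simplex coordinates are
  structurally inter-correlated, so their "null" is never exactly zero —
  those rows describe the data rather than test a hypothesis, and readers
  of the battery should treat them accordingly.

## Known limitations

* No voxel-level preprocessing, nuisance regression, filtering or
  registration: the package starts at ROI time series by design.
* The DVARS percent form on ROI series approximates the voxel-based
  original; thresholds tuned for voxel DVARS may need revisiting.
* The synthetic BOLD omits autocorrelation and hemodynamics; recovery
  results bound algorithmic error only.
* Exhaustive centroid matching is exact but limited to ≤ 8 states.
* k is fixed by the analysis design (default 5); the package deliberately
  offers no data-driven selection of k.
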