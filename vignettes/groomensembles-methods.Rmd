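---
title: "Methods: detecting and characterizing striatal grooming ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing striatal grooming ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groomensembles)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter, what
the synthetic generator does and does not emulate, and where the design was
genuinely open. Everything quantitative stated here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## Conventions

All times are seconds stored as doubles; every interval is half-open
`[start, end)`; frame `f` at rate `r` covers `[f/r, (f+1)/r)`; bins tile
their window from its start; bin indexing in the internal maps is 0-based.
A single session seed fans out to per-stage child seeds so each stage is
independently reproducible.

## Grooming detection from 3D pose

A frame counts as grooming when the mouse is **rearing** (snout height
above a threshold, eyes-midpoint to hindlimb-midpoint distance below a
threshold) **and** its **paws are near its head** (paw-midpoint to snout
and to eyes-midpoint distances below thresholds, paw-midpoint height above
a threshold), optionally **and** moving slowly. The conjunction of all
predicates is required; a missing or low-confidence (< 0.6) keypoint fails
its predicates conservatively, i.e. toward "not grooming". Flagged runs
separated by less than 1.2 s are merged (strict inequality: a gap of
exactly 1.2 s is kept) and merged runs shorter than 2 s are discarded.

Threshold values are dimensionless arena-specific quantities and live in
`heuristic_thresholds()`. The defaults are calibrated to the synthetic
arena's millimetre geometry (grooming snout height 32 vs threshold 20;
paw–snout distance ≈ 4 vs threshold 15, and so on) and must be
re-calibrated for any real arena. The speed predicate is off by default
because the postural predicates already separate the two synthetic
postures; it is exposed for real data where locomotion can transiently
mimic the grooming posture.

Agreement between two annotations is the interval Jaccard index: time
covered by both divided by time covered by either. Two empty annotations
return 1 by convention (with a message); the tests pin the equivalence of
the interval computation to a brute-force per-frame IoU.

## Cell-type classification

Units are labeled from two waveform features and the session-mean rate
(total spikes / session duration): SPN iff width > 150 µs **and**
peak–valley > 500 µs **and** rate ≤ 10 Hz; FSI iff width ≤ 150 µs **and**
peak–valley ≤ 500 µs **and** rate ≥ 0.1 Hz; otherwise `other`, which is
excluded from all downstream stages. Boundary semantics are exact as
printed (150 µs is FSI-side, 10 Hz SPN-side). Because the feature
*measurements* are not standardized anywhere, the package defines them
explicitly and isolates them behind `extract_waveform_features()`: peak
width is the full width at half maximum of the dominant deflection with
linear interpolation at the crossings, and peak–valley is the time from
the dominant extremum to the next opposite-sign extremum (`NA` for
monophasic shapes). Alternative definitions can be swapped in without
touching the rule.

## Transition-aligned responses

Bouts are first consolidated (gaps < 3 s merged), then restricted to
well-isolated bouts (start ≥ 10 s after the previous end, first bout ≥ 5 s
into the session) so the ±5 s flanks are grooming-free. Event-triggered
averages use 250 ms bins over a ±5 s window — exactly 40 bins with the
event on the bin-19/20 boundary; events too close to the session edges are
excluded rather than zero-padded.

The 2-SD modulation flag works at 500 ms resolution on bout-averaged
activity: baseline = the six bins in `[-5, -2)` s before start (or
`[+2, +5)` s after end), test window = `[-1, +1)` s around the transition;
a unit is flagged when the test mean exceeds the baseline mean by more
than twice the baseline's sample standard deviation (n − 1 over the six
bout-averaged bins). With an all-zero baseline the rule degenerates to
"any test activity". The flag selects display-worthy examples; it is
deliberately **not** used as a filter anywhere downstream.

Response typing z-scores each unit's 40-bin average across time and runs
PCA with units as observations. Components are time courses; each unit
belongs to the PC1 group if the absolute value of its first weight is at
least that of its second, else PC2, with the sign of the winning weight
recorded. PC signs are unidentifiable, so each component is oriented so
its largest-magnitude time bin is positive; this makes group and sign
counts reproducible. One consequence worth knowing: for a *balanced
two-class* population the variable-centering step makes PC1 the
between-class contrast, so the two classes separate by **sign within the
PC1 group** rather than by group. The recovery checks therefore score the
best mapping of (group × sign) cells onto planted classes.

## Ensemble detection

The grooming matrix restricts the session to grooming bouts padded ±5 s.
Padded intervals that overlap (bouts closer than 10 s) are fused into one
segment so no bin straddles two non-contiguous stretches of time. Each
segment is tiled with 1.5 s bins from its start; a trailing sliver shorter
than one bin is dropped. This last point matters: keeping unequal-exposure
bins plants *shared* structure across all units (every unit dips in a
short bin), which inflates correlations and the eigenvalue statistic —
the package's null-calibration tests fail if slivers are kept, and pass
(0 false ensembles in 25/25 independent-unit sessions) when they are
dropped. A padded segment is at least ~12 s, so short bouts still
contribute ≥ 7 full bins. Counts are min-max normalized per unit over the
concatenated matrix and Gaussian-smoothed (σ = 3 s = 2 bins, kernel
truncated at 4σ and renormalized) within segments only, so activity never
leaks between non-contiguous times.

**How many ensembles?** Each unit's binned counts are z-scored and the
eigenvalues of the resulting unit-by-unit correlation matrix are compared
with the distribution of the *maximum* eigenvalue under independent
per-unit bin permutations (5,000 shuffles by default; the calibration
tests use 1,000). The estimate is the number of real eigenvalues above the
null's 99th percentile. Shuffling preserves every unit's marginal count
distribution and destroys only the temporal alignment, which is exactly
the co-activity being tested.

**Which units form ensembles?** Meta-k-means: 1,000 Lloyd k-means runs
(one greedy k-means++ initialization each, ≤ 300 iterations) clustering
units by their processed activity vectors with k = round(√n). Unit pairs
sharing a cluster in > 80 % of runs define edges; connected components of
that graph are intermediate clusters (components are the minimal closure
of the stated pairwise relation); singleton components are unassigned.
Intermediate clusters are then greedily merged while the mean silhouette
(assigned units only) does not decrease; merging never proceeds below two
clusters, and components are never split.

The distance step operates on **row-z-scored** vectors. Min-max alone
preserves each unit's overall activity level, and Euclidean k-means then
clusters units by *level* — stable but scientifically empty clusters that
defeat the consensus filter's purpose of leaving non-co-active units
unassigned. Z-scoring makes the metric sensitive to temporal pattern only,
which is what "co-active" means. On isotropic control data the consensus
filter leaves essentially all units unassigned; with planted ensembles it
assigns exactly the planted members (recovery ARI 1.0 across the
acceptance sessions) while the unassigned fraction of independent units
averages ≈ 0.84 with ~0.09 between-session spread — the residual
clustering of independent units comes from k-means's anchored partitions
of the leftover cloud, not from the data carrying co-activity.

## Ensemble characterization

Pairwise Pearson correlations are split into within-ensemble and
everything-else pairs, on the grooming matrix and on a whole-session
matrix processed identically (same binning, normalization, smoothing) so
the contrast isolates the time mask. The two samples are compared with
the rank/Mann–Whitney AUC (ties ½). With purely independent background
units both AUCs saturate at 1, so the graded contrast only appears when
background correlations exist; the generator's optional shared slow drift
(below) provides them.

Per-bout activity is linearly time-warped: the bout core is interpolated
onto a fixed number of bins (default: the median core length) while the
5 s flanks are copied unwarped. At a 1.5 s bin size the 5 s flank is not
an integer number of bins; the package uses floor(5/1.5) = 3 flank bins
(4.5 s). Peak times are read off the bout-averaged, [0, 1]-normalized
warped trace (ties → earliest bin) on a normalized axis where the core
maps to [0, 1].

Significance bands come from 1,000 random windows with durations drawn
from the observed bout-duration pool and starts uniform in
`[5, T − 5 − dur]`, each processed exactly like a bout and summarized by
per-bin mean and 2.5/97.5 percentiles. Windows that intersect grooming
are rejected and resampled. This exclusion is essential: with grooming
occupying ≈ 4 % of a session, more than 2.5 % of unrestricted windows
overlap bouts, the upper percentile saturates at bout-level activity, and
no ensemble could ever escape the band — the band is meant to describe
duration-matched *grooming-free* baseline activity. An ensemble is called
significantly grooming-locked when ≥ 2 contiguous warped bins fall
outside the band (the run length is a config knob, since no printed rule
exists for it).

The active-unit variant replaces ensemble-mean rate with the fraction of
member units having ≥ 1 spike in a 1.5 s bin ("active" is not defined
anywhere; one spike per bin is the natural floor at SPN rates).
Cross-session summaries fit ordinary least squares of cluster count and
mean size against unit count, reporting R², slope, and its two-sided
p-value, plus composition counts (SPN-only / FSI-only / mixed).

## Trajectories

Concatenated per-bout activity (250 ms bins, σ = 0.5 s within-segment
smoothing, per-row min-max — kept non-negative) is factorized at rank 3
with NNDSVD initialization, zeros replaced by the matrix mean, and
multiplicative Frobenius updates (≤ 500 iterations, relative tolerance
1e-6). The loss is non-increasing by construction and the deterministic
initialization makes the solve reproducible without a seed. Factors are
sorted by peak-score time so factor 1 tracks bout entry, factor 2 the
core, factor 3 the exit. The trajectory bin size is a package choice (no
printed value exists); 250 ms keeps within-bout dynamics while staying
non-negative after smoothing.

## The synthetic generator

The generator defines the study conditions rather than emulating any
particular recording:

- **Bout schedule**: exponential gaps (mean 258 s) alternate with
  log-normal durations (mean 12.4 s, log-sd 0.75 — right-skewed families
  match the shape of grooming bout-duration histograms). The implied
  grooming fraction 12.4/(12.4 + 258) ≈ 0.046 sits within ±30 % of the
  4.1 % target; the acceptance script reports the realized values.
- **Spike trains**: inhomogeneous Poisson with piecewise-constant rates.
  SPN baselines are drawn from 0.2–8 Hz, FSIs from 5–25 Hz. Ensemble
  members share an active epoch set by the ensemble's profile — step
  profiles span the bout, transient profiles ±1 s around a transition,
  suppressed profiles divide the rate by the gain (suppression extended
  5 s past bout end for the sustained variant) — with a default gain of 5.
  Members also share a per-(ensemble, bout) log-normal gain jitter
  (log-sd 0.6), modelling bout-to-bout participation variability; this is
  what renders two ensembles with similar epochs statistically
  distinguishable and gives each ensemble its own variance direction.
  Default planted profiles cycle through the taxonomy because two
  ensembles with the *same* profile and no participation variability are
  near-collinear in the grooming matrix and unidentifiable in principle.
  Members of suppressed ensembles are drawn from the upper half of the
  baseline range (suppression is unobservable in near-silent units).
  Baselines of excited SPN members are capped so the realized session
  mean stays within the SPN rate rule, keeping planted labels exactly
  recoverable. An optional shared slow log-normal drift (default off,
  log-sd 0.2 where used; 60 s timescale) adds the graded background
  correlations of real recordings — it is off by default so that
  "independent units" sessions are exactly that.
- **Pose**: two postural templates (grooming and locomotion) around a
  slowly wandering body centre, at 125 fps, with optional isotropic
  Gaussian keypoint jitter. The grooming template satisfies every default
  heuristic with ≥ 10 unit margins; the locomotion template violates the
  snout- and paw-height predicates. Bouts are homogeneous epochs: no
  within-bout syntactic phase structure is modelled.

What passing tests therefore do *not* show: robustness to real tracking
artifacts (occlusion, identity swaps, triangulation error structure),
non-Poisson spiking (bursting, refractoriness), electrode drift, or
overlapping behaviors. The generator's role is to verify the analysis
machinery against a known answer, not to claim biological realism of the
noise model.

## Numerical and degenerate-input choices

- Binning is half-open with edge spikes in the right bin; totals are
  conserved (tested).
- Min-max of a constant row maps to zeros (0/0 guard); zero-variance
  rows are dropped with a warning before z-scoring in the eigenvalue
  test and skipped in correlation splits.
- Smoothing kernels are renormalized at segment edges so constants are
  preserved.
- Bout cores shorter than 2 bins are warped by duplication; random null
  windows are retried up to 100 times before erroring.
- Ties: peak times take the earliest bin; a unit with equal PC1/PC2
  weight magnitude goes to PC1.
- Empty intermediate-cluster graphs skip the merge step; silhouette is
  undefined below two clusters and merging stops there.

## Problem sizes used by the checks

The test suite and acceptance script run two-hour, 60-unit sessions for
calibration and recovery (50 null seeds at 1,000 shuffles; 16 recovery
sessions at 1,000 k-means runs — the unassigned-noise fraction has ~0.09
between-session sd, so its mean needs that many sessions for a stable
estimate), one-hour sessions for the AUC contrast and response typing,
and a 30-minute pose track for detection. These sizes are the package's
validation protocol; all of them scale with the config objects.

## Known limitations

- Threshold defaults for grooming detection are meaningful only in the
  synthetic arena frame.
- The consensus filter's unassigned fraction for genuinely independent
  units is ≈ 0.8–0.9, not 1: k-means partitions of the non-ensemble
  cloud retain some run-to-run stability once strong ensembles anchor
  most centroids. This is a property of consensus k-means itself.
- The eigenvalue count under-counts weakly modulated (especially
  suppressed and transient) ensembles at realistic rates; it is a lower
  bound on planted structure.
- With many bouts and strong gains, correlation AUCs saturate; graded
  contrasts require background correlation (shared drift) as in real
  data.
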