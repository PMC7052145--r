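---
title: "Cardiac synchrony of spectator quartets by cross-recurrence quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac synchrony of spectator quartets by cross-recurrence quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crqsync)
```

## The design and the question

`crqsync` analyses sessions in which quartets of spectators attend two
live monologue performances. Each participant contributes a continuous
R-peak record spanning a 2-minute baseline, the two performances
(of which the first and last 2 minutes, T1 and T2, are analysed) and two
2-minute rests. The scientific questions are (1) whether members of the
same quartet show more cardiac synchrony with one another than with
spectators of other sessions, and (2) whether a participant's synchrony
with their group relates to how closely their emotional-intensity rating
of the performances agrees with the group's.

## Pipeline and assumptions

**RR series.** RR intervals are anchored at the second peak of each
interval and interpolated with a natural cubic spline, evaluated on a
4 Hz grid. Two minutes at 4 Hz give 480 grid points; the analysis series
is the central 430 samples of that grid. The fixed length of 430 is
treated as the authoritative series length and symmetric trimming as the
reconciliation with the 2-minute window; both `fs` and `n_target` are
configurable, and the trimming is logged. No artifact interpolation is
attempted: intervals outside (0.25, 3) s are flagged at read time, and a
participant missing any analysable segment is excluded from pairwise
analysis entirely (list-wise), since a quartet design cannot substitute
partners.

**Normalization.** Each per-segment series is z-scored before embedding.
The recurrence threshold is fixed across the dataset, so it can only be
portable across participants on a normalized amplitude scale; RR means
and variances differ between people for reasons (fitness, age, posture)
unrelated to synchrony.

**Embedding.** Delay embedding with τ = 1 sample. The dimension is
chosen by false nearest neighbours: Kennel's distance-ratio criterion
(tolerance 10) *plus* the attractor-size criterion (tolerance 2 SDs of
the series). The second criterion matters: with the ratio test alone, the
FNN fraction of a purely stochastic series drops below any cutoff once
the embedding is a few dimensions deep — nearest-neighbour distances grow
with dimension while the extra-coordinate separation does not — and the
method would report a spurious finite dimension for noise. The global
dimension is the maximum of the per-series dimensions ("consistently
below 0.1" is read as: below the cutoff at the candidate dimension and
every larger tested one, up to `m_max = 15`).

**Cross-recurrence.** For participants A and B, the plot marks
`(i, j)` recurrent when the Euclidean distance between their embedded
points, divided by √m, is at most ε = 0.2. Dividing by √m makes ε a
root-mean-square *per-coordinate* separation, in units of the z-scored
series' SD; the threshold then has the same meaning whatever dimension
the FNN step selects. Two pair-adaptive alternatives (dividing by the
pair's maximum or mean distance) are available in the configuration but
are not the default: scaling by a statistic of the pair's own distance
matrix removes exactly the between-pair differences in absolute
closeness that the in-group/out-group contrast measures. A per-pair
threshold search (`select_threshold_pair()`) implements the
highest-variability rule — the candidate maximising the SD of the
diagonal line-length distribution (or, behind a switch, of the binary
matrix entries) — and `select_threshold_global()` averages the per-pair
choices; the fixed default of 0.2 keeps conditions comparable.

**Metrics.** Recurrence rate (fraction of recurrent cells), diagonal
line-length entropy, laminarity, and longest diagonal line, with minimal
line lengths `l_min = v_min = 2` (the field's convention; determinism is
computed too but unused downstream). Entropy is reported in raw nats by
default. The normalized variant (divided by the log-count of distinct
line lengths) is always emitted alongside, but it is *not* the default
because the two scales disagree in direction under common drive: coupling
lengthens and diversifies diagonal lines, raising raw entropy, while the
normalized ratio can fall as the length distribution gains a dominant
mode. The group contrast of interest runs in the raw-entropy direction.
No Theiler window is excluded: these are cross-plots between different
people, so there is no trivial line of identity.

**Group structure.** In-group synchrony of a participant is the mean of
each metric over the three pairings with their quartet mates; out-group
synchrony uses three spectators drawn uniformly (seeded) from other
quartets, drawn once per run and reused across segments and for the
out-group convergence score. Out-group pairs are always compared within
the *same segment label* — like with like. Laminarity is read with the
focal participant as rows; recurrence rate, entropy and the longest
diagonal are orientation-symmetric, so each unordered pair's plot is
computed once.

**Behaviour.** The convergence score sums `|rating_self − rating_k|`
over the three comparison spectators for the performance
emotional-intensity item and averages the two monologues (range 0–12;
high = disagreement). Pearson correlations of the four metrics (averaged
over the four monologue windows) against the score are tested at the
Bonferroni threshold 0.05/4 = 0.0125, two-tailed. Zero-variance inputs
yield missing correlations rather than zeros. The same machinery
correlates the participant's own mean intensity rating
(`correlate_intensity()`).

## The synthetic-session generator

No recordings ship with the package; `simulate_session()` generates
sessions that emulate the design: `n_quartets = 11` quartets of four,
monologue durations drawn from Normal(5.41, 1.26) minutes truncated at
4 minutes, 2-minute baseline and rests, ten 1–5 Likert items rated per
monologue.

The instantaneous RR of participant *p* in quartet *q* is

    RR_p(t) = μ + σ · [ a·s_q(t) + a_out·g(t) + u_p(t) + ν'·ε_p(t) ] / Z

with μ = 0.8 s, σ = 0.05 s; `s_q` a quartet-shared band-limited driver,
`g` a global driver (gain 0 by default — members of different quartets
never shared a session), `u_p` an individual band-limited process, and
ε white noise whose amplitude ν' is scaled so the *fraction* of
measurement noise is identical across quartets (otherwise coupling
strength would leak into single-series smoothness and contaminate
out-group metrics). The amplitude is `a = 2 × coupling_in`, i.e. a gain
of 1 gives the shared driver four times the individual variance — the
generator's definition of "strong coupling". R-peaks follow by
integrating RR (t_{k+1} = t_k + RR(t_k)).

Three generator choices deserve explanation because they were forced by
the geometry of recurrence analysis rather than taken from convention:

* **Driver band 0.01–0.07 Hz.** For z-scored series the matrix-average
  cross term between two series is identically zero, so an additive
  shared driver cannot change the *average* phase-space distance — it can
  only redistribute mass toward the small-distance tail. A narrow
  oscillatory band (e.g. the classical 0.04–0.15 Hz LF band) has an
  autocorrelation whose positive and negative lobes cancel in that
  redistribution, producing no recurrence-rate response at all; a slow
  drift spanning the very-low-frequency range does produce one. The
  shared driver is therefore given a 0.01–0.07 Hz band — physiologically,
  a shared slow arousal drift rather than shared respiratory sinus
  arrhythmia.
* **Per-window standardization of the latent processes.** A band-limited
  process has roughly `2·B·T ≈ 13` degrees of freedom inside a 2-minute
  window, so its realized in-window power fluctuates with a CV near 40%.
  Left free, that fluctuation — not the configured gain — dominates a
  quartet's realized coupling. Since the module's purpose is
  *controllable* coupling, each latent process is standardized to zero
  mean and unit SD within every analysis window, making the configured
  gain an exact within-window variance share.
* **Ratings.** Each (quartet, monologue, item) draws a quartet mean from
  Uniform(2, 4.5) — spanning the range typical of such rating tables —
  and participant ratings from Normal(mean, 1·(1−agreement) + 0.05),
  rounded and clipped to 1–5. In the linked condition (`rating_link`),
  agreement is `1 − √(1−ρ_q)` where `ρ_q = a²/(a²+1)` is the quartet's
  shared-variance fraction: rating scatter then shrinks with the same
  residual amplitude that governs cardiac closeness, which is the
  cleanest way to build in the negative convergence–synchrony dependence
  the linked condition exists to create.

What the generator does **not** emulate: real ECG morphology and R-peak
detection error, respiratory coupling, nonstationary arousal (beyond the
block structure), actor physiology, and any causal pathway from felt
emotion to ratings. Passing tests on synthetic sessions therefore show
that the *pipeline recovers built-in structure of this additive kind* —
they are not evidence about the physiology of real audiences.

## Numerical choices and degenerate inputs

* Distances: squared-distance thresholding (no square root materialised);
  the maximum norm is available as an option.
* Line scans run in a small compiled kernel; an independent pure-R
  brute-force oracle in the test suite checks all four metrics to 1e-12.
* Threshold search ties resolve to the smallest candidate; an all-empty
  grid returns the smallest candidate with a warning.
* Constant series z-score to all zeros, embed to a single point cloud at
  the origin, and are fully recurrent at any ε > 0; their FNN dimension
  is 1 (no neighbour is ever false when all distances vanish).
* Correlations on fewer than 4 participants are an error; undefined
  correlations are `NA`, never 0.
* Windows that overlap (performances shorter than 4 minutes) warn and
  proceed; windows whose grid exceeds the RR support exclude the
  participant with a logged reason.

## Problem sizes used by the test suite

The unit suite runs small sessions (2 quartets, fixed 4-minute
monologues) and short series; the acceptance suite replicates the full
11-quartet design — 100 seeded replicates for the directional contrast
and permutation-null checks (single monologue window per replicate) and
100 replicates of the coupling-linked condition for the
convergence-correlation signature (all four monologue windows). These
sizes give the sign-rate assertions enough resolution while keeping a
complete run on one CPU within a coffee break. Null-band checks flip
in/out labels at the *quartet* level: quartet mates share their in-group
pairs, so quartets — not participants — are the exchangeable units.

## Known limitations

* The additive shared-driver model is one mechanism of synchrony; phase
  locking, event-locked accelerations, or respiration-mediated coupling
  would express differently in the metrics.
* With ε fixed at 0.2 per coordinate, recurrence rates of weakly coupled
  smooth series sit in the few-percent range; contrasts are small in
  absolute terms and detected through replication, as in the emulated
  design itself.
* Pearson inference treats the 4 members of a quartet as independent
  observations, mirroring the emulated analysis; quartet-level clustering
  makes those p-values optimistic for the in-group tests (where the
  signal lives at the quartet level) — a property of the design being
  emulated, not a bug of the implementation.
* The flip side of that clustering: any quartet-level dependence, such
  as the linked condition's coupling–agreement tie, is effectively
  estimated from `n_quartets` units, not from the participant count.
  With 11 quartets the recovered convergence correlations are reliably
  negative, but their per-replicate significance at the corrected
  threshold is limited by the realization noise of slow drivers inside
  2-minute windows, not by the pipeline.
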