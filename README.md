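# crqsync

Cardiac synchrony of small spectator groups by cross-recurrence
quantification analysis (CRQA).

## The problem

When several people attend the same live performance, their heart rhythms
tend to drift together. `crqsync` quantifies that entrainment from
beat-to-beat (RR) interval data and asks whether it relates to how
*convergently* the group rated the shared experience. The package targets
the quartet design: groups of four spectators, each recorded across a
baseline, two monologue performances (first and last two minutes of each,
T1/T2), and two inter-performance rests.

## The method

For each participant and two-minute window:

1. **Preprocessing** — R-peak times become RR intervals, interpolated with
   a natural cubic spline and resampled at 4 Hz; the central 430 samples
   of the window form the analysis series, which is z-scored.
2. **Embedding** — time-delay embedding with delay τ = 1 sample; the
   dimension *m* is chosen by false nearest neighbours (FNN): the smallest
   *m* whose FNN fraction stays below 0.1, maximised over all series
   (one global *m* for the whole dataset).
3. **Cross-recurrence** — for a pair of participants, the binary matrix
   `CR(i, j) = 1 ⇔ ‖x_i − y_j‖ / √m ≤ ε` with ε = 0.2 (a per-coordinate
   separation in SD units). Four line-structure metrics summarise it:
   - `rec` — recurrence rate, the fraction of recurrent cells;
   - `ent` — Shannon entropy (nats) of the diagonal line-length
     distribution (lines ≥ 2);
   - `lam` — laminarity, the fraction of recurrent points on vertical
     lines ≥ 2;
   - `lmax` — the longest diagonal line, in samples.
4. **Group contrast** — each participant's *in-group* synchrony is the
   mean metric over pairings with their 3 quartet mates; *out-group*
   synchrony uses 3 seeded random spectators from other quartets.
5. **Behaviour** — the *convergence score* is the sum of absolute
   differences between a participant's 1–5 emotional-intensity rating and
   the three comparison spectators' ratings, averaged over the two
   monologues (0 = full agreement, 12 = maximal disagreement). Pearson
   correlations between convergence and each CRQA metric are tested
   against the Bonferroni-corrected threshold 0.05/4 = 0.0125.

A seeded generator (`simulate_session()`) produces quartet-structured
sessions — shared low-frequency RR drivers within quartets, individual
band-limited processes, beat-level noise, integral-pulse beat times, and
Likert ratings with controllable within-quartet agreement — so the whole
pipeline is testable without any recordings.

## Worked example

```r
library(crqsync)

sim <- simulate_fixture_small(seed = 7)        # 2 quartets, 4-min monologues
cfg <- default_config()
cfg$m <- 11L                                   # fix the embedding dimension
res <- run_pipeline(sim$manifest, sim$tachograms, sim$ratings, cfg, seed = 7)

subset(res$contrast, metric == "rec")
#>  metric group_type       mean           se  n
#>     rec         in 0.04357190 0.0009790904 32
#>     rec        out 0.04219146 0.0007966481 32
```

The in-group recurrence rate (0.0436) exceeds the out-group rate (0.0422):
members of the same quartet spend more time in nearby cardiac states than
spectators who never shared a session. `res$correlations` holds the
convergence and intensity correlations with their Bonferroni thresholds,
and `res$synchrony` the per-participant metrics (written as tidy CSV when
`out_dir` is given).

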