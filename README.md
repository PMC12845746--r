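# kicksyn

Muscle-synergy analysis of multichannel surface EMG (sEMG) recorded during
cyclic lower-limb movement — built around the freestyle flutter kick, but
applicable to any cyclic task with labelled cycle events.

## The problem

Training studies of cyclic movements ask two linked questions: did an
intervention change *how much* individual muscles are activated, and did it
change *how* the nervous system coordinates them? The first is answered with
time-domain amplitudes (integrated EMG and RMS per movement phase); the
second with muscle synergies: a small set of fixed muscle-weight vectors
recruited by shared time-varying activation coefficients. `kicksyn`
implements the complete workflow for a two-group (experimental vs control),
pre/post repeated-measures design:

1. **Preprocessing** — 4th-order Butterworth band-pass (20–400 Hz,
   zero-phase), full-wave rectification, 20 Hz low-pass linear envelope,
   normalisation to the maximum voluntary contraction (MVC, best 1 s
   sliding-window RMS across calibration trials), segmentation into kick
   cycles from event timestamps, and linear time-normalisation of the
   representative cycle to 100 points.
2. **Time-domain metrics** — per phase (up-swing, downward, transition) and
   muscle: iEMG = Σ xₙ·Δt (µV·s) and RMS = √(mean x²) (µV) on the rectified
   band-passed signal.
3. **Synergy extraction** — non-negative matrix factorisation
   D ≈ Σᵢ Wᵢ Cᵢ(t) by Frobenius multiplicative updates with uniform
   restarts; the model order is the smallest k whose best-restart
   VAF = 1 − SSE/SST exceeds 90 %.
4. **Reference synergies** — K-means (squared Euclidean, best of 1000
   restarts) on the control-group pre-intervention weight vectors, with the
   cluster count chosen by the Gap statistic
   (Gap(k) ≥ Gap(k+1) − sd(k+1), uniform bounding-box reference, B = 100).
5. **Matching & census** — greedy one-to-one assignment of every synergy to
   a reference by Pearson correlation of weights (threshold 0.6); counts of
   matched and unmatched synergies per group and timepoint.
6. **Activation timing** — per matched synergy: duration (fraction of the
   cycle at ≥ 20 % of peak), peak time, and onset (start of the longest
   circular supra-threshold burst).
7. **Statistics** — 2×2 mixed repeated-measures ANOVA (group × time) per
   outcome with partial eta squared (ηp² = SS_eff/(SS_eff+SS_err), bands at
   0.01/0.06/0.14) and Bonferroni-adjusted simple effects.

Because real athlete recordings of this kind are rarely shared, the package
includes a first-class synthetic-data generator
(`simulate_kick_study()`) that emulates the full recording structure —
known synergy weights and burst activations, amplitude-modulated band-limited
carrier noise at 2000 Hz, MVC calibration trials, kick-cycle events, and
configurable group × time intervention effects — so every stage is testable
by parameter recovery.

## Worked example

```r
library(kicksyn)
res <- run_kick_pipeline(kick_config(), seed = 1)
res
```

```
<kick_results>
  60 recordings, 10 muscles
  synergy count: mean 2.97 (selected orders 2, 3)
  3 reference synergies from CON/pre; 178/178 synergies matched
  54 outcomes with a significant group x time interaction
```

The synergy census (compare: about three synergies per swimmer, stable
across arms):

```r
res$census
```

```
 group timepoint n_syn_mean  n_syn_sd n_syn1 n_syn2 n_syn3 n_unmatched
   CON      post   2.866667 0.3518658     15     14     14           0
   CON       pre   3.000000 0.0000000     15     15     15           0
   EXP      post   3.000000 0.0000000     15     15     15           0
   EXP       pre   3.000000 0.0000000     15     15     15           0
```

The strongest group × time interactions land exactly where the simulated
intervention was injected — the shortened postural-synergy burst
(`duration_syn2`) and the re-weighted propulsion synergy — with large
effect sizes:

```r
int <- dplyr::filter(res$anova, effect == "group:time")
head(dplyr::arrange(int, p), 5)
```

```
                        outcome    F        p eta_p2  band
                  duration_syn2 67.3 8.28e-09  0.714 large
  rms_rectus_abdominis_up_swing 43.0 4.15e-07  0.606 large
    weight_gluteus_maximus_syn3 41.2 7.14e-07  0.604 large
                onset_time_syn2 41.1 7.22e-07  0.604 large
 iemg_rectus_abdominis_up_swing 36.8 1.52e-06  0.568 large
```

Individual fits are broom-friendly:

```r
glance(res$synergies$fit[[1]])
```

```
# A tibble: 1 × 5
      k   vaf restarts_used converged objective_monotone
  <int> <dbl>         <int> <lgl>     <lgl>
1     3 0.983            20 TRUE      TRUE
```

`autoplot()` on a fitted synergy set draws weight bars and activation
profiles; `plot_gap_curve()` and `plot_reference_synergies()` visualise the
reference clustering.

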