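---
title: "Muscle-synergy analysis of cyclic kick sEMG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle-synergy analysis of cyclic kick sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kicksyn` analyses multichannel surface EMG from cyclic lower-limb movement
in a two-group, pre/post repeated-measures design. This vignette is the
package's account of the science: the models it fits, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
numerical decisions taken where the methodology left the design open.

## 1. Signal model and preprocessing

A recording is a muscles × samples matrix at `fs = 2000` Hz with event
timestamps marking cycle starts and the two interior phase boundaries
(up-swing → downward → transition, defaults at 40 % and 80 % of the cycle).
Preprocessing per channel:

1. zero-phase Butterworth band-pass, design order 4, 20–400 Hz
   (`bandpass_filter()`). Forward–backward filtering squares the magnitude
   response; we chose it because a causal filter's group delay would shift
   every downstream timing metric.
2. full-wave rectification and a zero-phase 20 Hz low-pass → the linear
   envelope (`linear_envelope()`), clipped at zero because filter ringing can
   go slightly negative and the factorisation requires non-negative input.
3. MVC normalisation: the denominator per muscle is the *maximum 1 s
   sliding-window RMS* of the band-passed calibration trials
   (`mvc_reference()`). "A stable 1 s window" is operationalised as the
   window maximising RMS — deterministic, no manual stability judgement. The
   alternative reading (envelope peak) is not used; users fitting real data
   should be aware the two differ by a roughly constant factor.
4. the representative cycle (median duration when several are supplied) is
   resampled to exactly 100 points by linear interpolation; phase boundaries
   are rescaled proportionally and rounded to the nearest grid index.
   Normalised-cycle time is reported as index i ↦ i/99 on [0, 1].

Cycle sample ranges are half-open and 0-based (`segment_cycles()`).

## 2. Time-domain metrics

Per phase and muscle on the rectified band-passed signal (microvolt scale,
*not* MVC-normalised, so amplitudes keep physical units):
iEMG = Σₙ xₙ·Δt with Δt = 1/fs (µV·s), and RMS = √(mean x²) (µV). The Δt
factor is included so units are µV·s; a bare sample-sum mode
(`iemg(..., mode = "sum")`) matches the discrete textbook formula. Phase
windows are taken on the original-rate signal, not the 100-point cycle, for
fidelity; both metrics are additive/consistent over the phase partition by
construction.

## 3. Synergy model

The MVC- and time-normalised cycle D (muscles × 100) is factorised as
D ≈ W·C with W ≥ 0 (muscles × k, columns unit Euclidean norm) and C ≥ 0
(k × 100), by Frobenius multiplicative updates. Goodness of fit is
VAF = 1 − SSE/SST with **uncentred** SST = Σ D² — the standard global
convention in the synergy literature; a centred variant is available in
`vaf(..., centered = TRUE)`.

Numerical choices:

* initialisation i.i.d. uniform on (0, max(D)]; zeros are excluded because
  they are absorbing states of multiplicative updates;
* denominator guard ε = 1e−12 in both update rules;
* each restart runs to convergence — |ΔVAF| < 1e−6 per 10-iteration block,
  cap 1000 iterations — and the best-VAF restart wins (20 restarts by
  default, seeded deterministically per input × order × restart). Stopping a
  restart early the moment VAF crosses 90 % would make the reported VAF
  depend on iteration scheduling, so the 90 % rule is applied only to order
  selection;
* model order: smallest k in 1..10 with VAF > 0.90; if none qualifies the
  best-VAF order is returned flagged non-convergent. The sweep is capped at
  the number of muscles (10) because higher orders are degenerate for a
  10-channel montage, even where a larger nominal range is conventional; the
  cap is configurable (`k_range`);
* weight columns are re-normalised to unit norm with compensating row
  scaling of C (reconstruction unchanged); the stored VAF is recomputed from
  the stored factors so the object is self-consistent to 1e−12.

NMF is fitted per subject × timepoint (not on group-concatenated data), so
that subject-level weights exist for clustering and statistics.

## 4. Reference synergies, matching, census

Reference synergies are built from the control group's pre-intervention
weight vectors: K-means with squared Euclidean distance, Lloyd iterations,
best of 1000 random restarts. The cluster count is selected by the Gap
statistic: Gap(k) = mean_b log W*ₖᵦ − log Wₖ against B = 100 reference
datasets drawn uniformly on the raw per-dimension bounding box, with
sd(k) scaled by √(1+1/B), choosing the smallest k with
Gap(k) ≥ Gap(k+1) − sd(k+1). Inside the Gap computation we use 100 K-means
restarts per dispersion evaluation rather than 1000: with ≤ 90 vectors in 10
dimensions, best-of-100 Lloyd is already at the optimum, and the Gap needs
(B+1)·k_max dispersion evaluations. The bounding-box reference (rather than
the PCA-rotated variant) is the simplest published form; its known weakness
— splitting elongated clusters — is visible if within-cluster variability is
strongly anisotropic. `n_reference_clusters` can pin the count when it is
known a priori or when the reference set is too small for selection.

Matching is greedy one-to-one by Pearson correlation of weight vectors with
threshold 0.6: repeatedly take the highest remaining (synergy, reference)
pair at or above threshold; ties break to the lower reference index, then
lower synergy index. One-to-one (rather than many-to-one) was chosen so the
census counts are interpretable as occurrences; the multiset of matches is
invariant to synergy ordering. The census reports, per group × timepoint,
the mean ± SD of the per-subject synergy count, occurrences per reference,
and the unmatched count; occurrences plus unmatched always equal the total.

## 5. Activation timing

Each matched synergy's activation profile is reduced to three parameters on
[0, 1]: peak time (argmax/99, earliest index on ties), duration (fraction of
samples at ≥ 20 % of the profile maximum — the threshold is relative, so
timing is scale-invariant), and onset (start of the longest contiguous
supra-threshold run **treating the cycle as circular**). The circular
convention matters: a burst that begins late in the cycle and peaks just
after the wrap is one burst, and its onset (≈ 0.6–0.9) can numerically
follow its peak (≈ 0.1), which is exactly the pattern early-cycle
propulsion bursts produce. Only the longest burst defines onset; multi-burst
decomposition is out of scope. The 20 % threshold is a common burst-detection
convention and is configurable (`timing_threshold`).

## 6. Statistics

Every outcome (iEMG and RMS per muscle × phase, matched weight per muscle ×
reference synergy, timing parameters per reference synergy, synergy count)
is analysed with a 2×2 mixed repeated-measures ANOVA: group between
subjects, timepoint within, fitted via `aov(value ~ group*timepoint +
Error(subject))`. Group is tested against subjects-within-groups; time and
group × time against the time × subjects-within-groups residual. With two
within-subject levels sphericity holds trivially, so no correction is
applied. ηp² = SS_eff/(SS_eff + SS_err-of-that-effect), banded at
0.01/0.06/0.14 (closed on the left). Sums of squares below 1e−12 of the
total are treated as exact zeros so that degenerate designs (e.g. identical
change scores) resolve to F = 0, p = 1 rather than 0/0 noise. Simple
effects use paired t-tests (pre vs post per group) and pooled-variance
two-sample t-tests (groups per timepoint), Bonferroni-multiplied by the
family size (2) and capped at 1. Subjects missing a timepoint for an
outcome are dropped for that outcome only; no correction is applied across
outcomes, mirroring common practice in this literature (and its caveats).

## 7. The synthetic-data generator

`simulate_kick_study()` emulates the statistical structure the analysis
assumes, with defaults chosen once as the study conditions:

* **design**: 15 subjects per group × {pre, post}; 10 muscles; 3 synergies;
  3 digitised cycles of ~0.5 s (±8 % jitter) per session, flanked by one
  lead-in and one lead-out cycle so the analysed data sit away from filter
  edge transients (trials are continuous swimming);
* **ground truth** (`make_ground_truth()`): each synergy has 2–4 dominant
  muscles (weights ≥ 0.55 before unit-norm, others ≤ ~0.3) and a wrapped
  Gaussian activation burst with a distinct peak. The `"freestyle"` template
  fixes the pattern described for the flutter kick: a plantarflexor synergy
  peaking ~65 %, a postural tibialis-anterior/rectus-abdominis synergy
  peaking ~90 %, and a propulsion adductor/knee-flexor/hip-extensor synergy
  peaking ~12 % whose burst spans the cycle wrap. Muscles without a dominant
  role receive one moderate secondary weight so every channel is phasically
  recruited — near-tonic channels would be unrealistic for cyclic kicking
  and have ripple-limited envelope estimates;
* **variability**: subject weights jitter multiplicatively (log-normal,
  sdlog 0.15) *plus* additively (SD 0.05, clipped at zero, re-normalised).
  The additive part reflects that small weights in real cohort tables vary
  on the absolute scale; it also keeps between-subject clusters roughly
  isotropic, which the bounding-box Gap reference handles well. Sessions
  add smaller jitter of the same form (sdlog 0.08, SD 0.02) — this is the
  within-subject error the ANOVA sees. Subject amplitude is log-normal
  around 0.55 MVC; burst centres and widths jitter mildly;
* **raw signals**: each muscle's stretched envelope amplitude-modulates an
  independent band-limited (20–400 Hz) unit-RMS Gaussian carrier scaled by
  a per-muscle MVC-level amplitude (~250 µV); MVC trials are ramp-plateau
  profiles ≥ 1.5 s at plateau with slight trial-to-trial variation;
  envelope noise is additive Gaussian (SD 0.015 MVC units, clipped);
* **intervention** (`kick_effects()`): EXP-post sessions multiply the
  adductor-longus and biceps-femoris weights of the propulsion synergy by
  1.8 and the postural synergy's burst width by 0.55. The weight multiplier
  is calibrated so the *realised* change in the unit-norm weight (~+0.15,
  ≈1.5 between-subject SDs) matches the magnitude reported for this kind of
  intervention; because two weights are boosted simultaneously,
  re-normalisation absorbs much of the nominal multiplier.

What the generator does **not** emulate: electrode lift-off and motion
artefacts, inter-muscle crosstalk, fatigue drift within a session,
kinematic variability in the event marks, non-Gaussian EMG amplitude
distributions, and any biomechanics (no forward model of the leg). Passing
recovery tests therefore shows the *pipeline* is correct and well-posed
under the assumed signal model — not that real recordings satisfy that
model.

### Known limits shown by the tests

* Envelope recovery of a weakly modulated channel is ripple-limited: a 20 Hz
  demodulating low-pass over ~0.5 s cycles leaves multiplicative carrier
  ripple, so single-cycle shape correlations for low-depth channels
  occasionally fall below 0.9 even though per-muscle averages across a study
  stay well above. This is a property of the linear-envelope method at these
  cycle rates, not of the implementation.
* Because weight columns are unit-norm, boosting two weights necessarily
  lowers the remaining weights of that synergy; and narrowing one synergy's
  burst redistributes temporally overlapped variance into that synergy's
  weight estimates. End-to-end, intervention effects therefore appear in the
  injected outcomes *and* in these causally coupled outcomes; truly
  untouched outcomes stay at the nominal false-positive rate, as does an
  effects-off study.
* Gap selection on real extracted weights is seed-sensitive when clusters
  are anisotropic; the census and matching remain interpretable for any
  selected count, and the count can be pinned.

## 8. Problem sizes used by the test-suite

The packaged tests run the full study at its default size (15 per group) for
the end-to-end and envelope-recovery checks, 50 seeded replicates for
synergy-order recovery, 20 replicates for Gap recovery, 20 oracle tables
plus 2000 null simulations for the ANOVA stage, and a 2-per-group study for
structural and determinism checks. These sizes were chosen to give stable
pass/fail behaviour at desk scale; all of them are configuration, not code.

## 9. Reproducibility

Every stochastic stage draws its RNG stream from one root seed through
`derive_seed()` (a position-dependent integer fold, so permuted labels hash
differently). Rerunning any stage — or the whole pipeline — with the same
configuration and seed reproduces its output exactly.
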