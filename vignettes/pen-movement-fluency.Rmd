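---
title: "Measuring pen-movement fluency in beginning writers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pen-movement fluency in beginning writers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penfluency)
```

## The measurement problem

A skilled handwriter produces each sub-letter feature — a stroke that an
adult would draw in one go, such as the left upright of an uppercase A —
as a single ballistic action: the pen tip accelerates once and decelerates
once, so its tangential speed traces a single smooth bell. Children who are
still learning to write instead produce the same feature with several
acceleration–deceleration episodes ("velocity inversions"), each of which
appears as an additional local maximum in the speed profile. Counting those
maxima therefore measures movement fluency independently of how neat the
final product looks: a perfectly formed letter can hide a very hesitant
movement.

`penfluency` implements this measurement chain end to end:

1. **Trajectory IO** — timestamped pen traces (`t_ms, x, y, pen_down` CSV)
   and sub-letter feature mark-up (JSON, 0-based inclusive sample indices
   on file, 1-based inside R).
2. **Kinematics** — resampling to a uniform grid, tangential velocity by
   central differences, zero-phase Butterworth low-pass filtering, peak
   counting, the per-feature disfluency score, and the signal-to-noise
   velocity peaks difference (SNvpd).
3. **Feature coding** — the 14-character inventory (letters and unfamiliar
   symbols), allograph-aware matching of produced strokes to target
   features, and a parameter-driven rule coder for feature accuracy.
4. **Task scoring** — selection and aggregation rules for the pen-control
   tasks (lines, circles, garlands, figure eights), the dictation trial
   filter, and letter-knowledge scoring with early-termination rules.
5. **Statistics** — nested linear mixed-effects model sequences with
   likelihood-ratio comparison, Satterthwaite inference, marginal
   R-squared and intra-class correlations, plus logistic GLMMs for
   malformation.
6. **Synthetic writer** — a generator of traces, mark-up, and whole
   cohorts with known ground truth, used by the test-suite and by the
   parameter-recovery and type-I-error studies.

## The disfluency score

For each marked feature the pipeline is fixed:

* resample to 133 Hz (tablets deliver samples *around* every 7.5 ms;
  linear interpolation of position, nearest-neighbour pen state);
* tangential speed $v_i = \sqrt{\Delta x_i^2 + \Delta y_i^2}/\Delta t$ via
  central differences (one-sided at the ends), pen-up samples masked;
* 10 Hz fourth-order low-pass Butterworth filter, applied zero-phase:
  a second-order design is run forward and backward, so the magnitude
  response is fourth-order and peaks are not lagged — this matters because
  peak *locations* are attributed to features by their sample span;
* count strict local maxima in the open interior of the feature's span.
  Plateaus count once at their midpoint, span endpoints never count (a
  peak exactly on a mark boundary belongs to neither feature, preventing
  double counting), pen-up gaps split the span and counts are summed.

The count is floored at 1 for any feature with non-zero movement: 1 means
fully fluent for a straight stroke. No amplitude or prominence threshold is
applied to peaks; the 10 Hz filter is the only noise control.

The filter is implemented on top of `signal::butter`, with odd-reflection
padding at both ends before the forward–backward pass. Unpadded
forward–backward filtering leaves edge transients that register as spurious
velocity maxima on short feature spans; reflection padding removes them
without touching interior peaks. `butterworth_gain()` exposes the analytic
two-pass magnitude response (bilinear-design, so including frequency
warping) that the filter realises; the test-suite verifies measured
passband (2 Hz within 2%) and stopband (30 Hz below 5%) gains against it.

## SNvpd

For the repetitive pen-control tasks a fixed number of necessary peaks
cannot be assumed, so fluency is scored as the signal-to-noise velocity
peaks difference: the peak count after 10 Hz filtering minus the count
after 5 Hz filtering of the same resampled speed signal,
$\mathrm{SNvpd} = N_{10} - N_5$. Peaks that survive 5 Hz filtering are
taken as propulsive movement; peaks present only at 10 Hz are
non-propulsive noise. The sign convention (noise minus signal, larger =
less fluent) follows the verbal definition of the measure as the
difference between counts after higher- and lower-band filtering.

Task selection rules: for lines and circles the first two *valid* units
are dropped and the next five consecutive units free of pen lifts are
scored (an error is raised when fewer than 2 + 5 valid units exist);
garlands are scored across all pen movement; figure eights are scored as
the sum over the (up to seven) produced repetitions. Whether the five
line/circle units are summed or averaged is not fixed by the verbal rules;
summation was chosen for consistency with the explicit "sum over eights"
rule. Unit boundaries come from generator ground truth for synthetic data;
for real recordings they must be supplied by an external segmentation
(direction reversals for lines, angular wrap for circles) via the `units`
attribute.

## Accuracy coding

Features are matched to the target character's features allograph-aware
(`match_features()`): each allograph's shape-kind sequence is aligned to
the produced marks by an order-preserving injective match, and the
allograph matching most features wins. A production is *complete* when
every target feature is matched, however badly shaped — this is also the
dictation-task attempt criterion, evaluated against both case variants.

The rule coder is parameter-driven. The uppercase-A upright is the fully
specified exemplar: it must meet the other upright at an angle between 20
and 90 degrees, deviate from straight by at most 1/6 of its length, differ
in length from the other upright by at most 1/6 of that upright's length,
and meet it with a gap or overlap of at most 1/6 of its own length. All
measures are ratios or angles, so verdicts are invariant under scaling and
rigid motion of the character. Other characters carry whichever subset of
the same 1/6-family rules applies (straightness for straight features);
the shipped decomposition of the full character set is a documented
stand-in constrained to reproduce the published feature totals — 20 letter
features (14 straight, 6 curved) and 12 symbol features (8 straight, 4
curved) over the 12 non-practice characters — not a transcription of the
original coding manual.

## The synthetic writer

Because the underlying child data are not redistributable, validation runs
against a generator whose ground truth is known by construction.

* **Sub-movements.** One ballistic stroke is modelled as a minimum-jerk
  speed bell $v(t) = (30A/T)\,\tau^2(1-\tau)^2$, the standard
  motor-control model of a point-to-point movement. Disfluency is injected
  *structurally*: a feature drawn with $k$ sub-movements partitions its
  path into $k$ bells with near-zero speed between them, so the
  ground-truth peak count is exactly $k$. Default bell duration is 0.35 s
  (with a short inter-bell pause), so consecutive peaks are separated by
  well over 150 ms and survive 10 Hz filtering; the dense noise-free speed
  profile is stored with every trace so an independent enumeration oracle
  (`dense_peak_count()`) can verify any count.
* **Tremor** is a separate, filterable channel: a zero-mean sinusoidal
  speed modulation (default test setting 6 mm/s at 20 Hz, comfortably
  above the 10 Hz cutoff and below the 66.5 Hz Nyquist limit). The
  modulation is gated by the base speed (linear ramp, full strength above
  twice the tremor amplitude): tremor perturbs ongoing movement, but a pen
  resting between sub-movements does not oscillate. Note the roll-off
  margin the 4th-order filter needs: tremor at 18 Hz and above leaves
  counts unchanged in ≥ 99% of productions, whereas 12–16 Hz tremor leaks
  20–30% through the 10 Hz filter and can add maxima in low-speed valleys.
* **Timestamps** are jittered uniformly by ±0.5 ms around the 7.5 ms grid
  to exercise the resampling step.
* **Cohorts.** A cohort draws, per child, seven z-scored predictor scores
  (three letter-knowledge, four pen-control) from a correlation matrix
  patterned on first-grade data, then generates per-feature peak counts
  as `max(1, round(mu + resid))` with
  `mu = 1 + curve_offset·curved + beta_pc·pc + beta_lk·enc + u_child + u_item`,
  where `pc` is the standardised mean of the four pen-control scores and
  `enc` the encoding score. Defaults: `curve_offset = 1` (curves cost one
  extra peak, matching adult modal counts of 1 for straight and 2 for
  curved features), `beta_pc = +0.5` and `beta_lk = −0.5` peaks per SD,
  and variance components `sigma_resid = 1`, `sigma_child = 0.61`,
  `sigma_item = 0.49`, chosen to reproduce intra-class correlations of
  about 0.23 (child) and 0.15 (item). Malformation is drawn independently
  per feature at the rates observed in beginning writers (letters 4%/13%,
  symbols 9%/32% for straight/curved). The dictation generator ties
  per-feature expected counts to the child's copy-fluency aggregates and
  (for straight features only, by default) to encoding.

What the generator does *not* emulate: realistic letter aesthetics, pen
pressure or tilt, latency before movement onset, drift in tablet
calibration, or any dependence of malformation on fluency. Passing tests
therefore certify the measurement and modelling chain, not the realism of
any particular simulated child.

### The SNvpd garland fixture

Verifying SNvpd count-for-count against an oracle needs a signal whose
peaks sit far from every counting threshold on *both* sides of both
filters. The ripple-injected garland fixture therefore uses a rounded
trapezoidal speed wave (one propulsive maximum per loop, rise slope
+125 mm/s², fall −187 mm/s²) with a 9.5 Hz ripple burst gated onto the
rising flank of each loop and phase-locked to the gate. At 10 Hz the
ripple's filtered slope amplitude dominates the base slope (one extra
maximum per ripple cycle); at 5 Hz its leakage (analytic gain ≈ 0.07)
stays several times below the base slope (no extra maxima). The garland
path for this fixture uses shallow loops scaled to the designed travel
distance so that path curvature cannot modulate the reconstructed speed
through chord shortening. The oracle applies the analytic two-pass
Butterworth gain at the ripple frequency to the designed components and
enumerates maxima densely; pipeline and oracle agree exactly across seeds
and loop counts.

## Model sequences

The copy-fluency analysis follows a fixed incremental sequence of linear
mixed models over the per-feature peak counts, all with by-child and
by-item random intercepts and fitted by maximum likelihood (not REML, so
likelihood-ratio tests across fixed-effect structures are valid): feature
malformed; feature is a curve; character is a letter; optionally child
age; the four pen-control scores; their interactions with curve and letter
status; the three letter-knowledge scores; and their interaction with
letter status. Each step is assessed by a likelihood-ratio chi-squared
test with one df per added term. Retention policy: a non-significant step
is omitted from all subsequent models, except the letter-status dummy,
which is always retained so that later interactions remain interpretable.
Continuous predictors enter as child-level z-scores; dummies stay 0/1.
Coefficient inference on the best model uses t tests with Satterthwaite
denominator degrees of freedom (via lmerTest); the sequence itself skips
per-coefficient inference for speed. Reported fit statistics are marginal
R² (variance of fixed-effect predictions over total modelled variance) and
ICCs per grouping factor. The dictation sequence (intercept; malformed;
child-aggregated letter- and symbol-copy fluency; letter knowledge) runs
separately for straight and curved features on attempted trials only;
children with no attempts are excluded with a message. Malformation is
analysed with logistic GLMMs (curve, letter, interaction) and z-based
inference; the latent-scale residual π²/3 is used for their R²/ICC.

`run_accuracy_glmm` treats grapheme-to-phoneme decoding as computed but
excluded from default predictor sets (it is nearly collinear with
encoding); the age step defaults to off and uses months when enabled.

## Numerical and design choices

* Peak counting uses run-length compression, so exact ties (plateaus)
  count once; floating-point speech signals essentially never tie, but
  clamped zero-speed stretches do.
* `lowpass` errors at or above Nyquist; `resample_uniform` requires
  strictly increasing timestamps and at least two samples; degenerate
  zero-length segments are errors in the geometry primitives.
* LR statistics are clamped at zero (convergence noise can make the
  larger model's log-likelihood infinitesimally smaller).
* Singular mixed-model fits are flagged on the result, not fatal; GLMM
  convergence warnings likewise.
* Problem sizes in the validation studies: the type-I study runs 500
  replicate null cohorts of 60 children (all betas and the curve offset
  zero, so every sequence step tests a true null); recovery runs 50
  replicate cohorts of 200 children; the peak-count recovery study runs
  1000 feature fixtures across 1–6 sub-movements; the competent-production
  study runs 500 productions.

## Known limitations

* **Floor censoring in cohort recovery.** The cohort generator places the
  competent baseline (expected count 1) *at* the floor implied by
  "realised counts ≥ 1". With a child-level effect of ±0.5 peaks/SD, the
  lower tail of the latent scale is censored for straight features, which
  attenuates fixed-effect estimates from the (correctly specified on the
  latent scale) Gaussian LMM by roughly 30–40% and collapses CI coverage.
  This is a structural property of floored counts near baseline, not an
  estimation bug: the type-I error of every sequence step is nominal under
  the null, and recovery is clean when the outcome is far from the floor
  (as it is in real beginning-writer data, where per-feature counts
  average around 10). The recovery study reports the bias honestly rather
  than switching to a censoring-aware estimator, because the analysis
  pipeline under validation is the field-standard Gaussian LMM.
* The unit segmentation of real (non-synthetic) pen-control traces is out
  of scope; scoring consumes externally supplied unit boundaries.
* The accuracy rule set beyond the uppercase-A exemplar is a
  faithful-by-totals stand-in; per-character parameters are data
  (`inst/extdata/inventory.yaml`), so refining them does not touch code.
* InkML or proprietary tablet formats are not read; the CSV/JSON dialects
  are the interchange formats.
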