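# penfluency

Pen-movement fluency analysis for beginning handwriting.

When an experienced writer forms a letter, each sub-letter *feature* (a
stroke a competent hand produces in one go) shows a single smooth bell in
the pen-tip speed profile. Beginning writers produce the same features
with multiple acceleration–deceleration episodes, each visible as an extra
velocity maximum — even when the finished letter looks perfect.
`penfluency` is for researchers in handwriting development and graphomotor
control who work with digitising-tablet recordings of children's writing
and want a tested, reproducible pipeline from raw pen traces to the mixed
model comparisons that relate movement fluency to pen-control skill and
letter knowledge.

The package provides:

* **Trace and mark-up IO** — timestamped pen samples
  (`t_ms,x,y,pen_down` CSV, 133 Hz nominal) and per-feature mark-up
  (JSON), with strict validation and exact round-trips.
* **Velocity-profile fluency scoring** — tangential velocity, zero-phase
  4th-order Butterworth low-pass at 10 Hz, and the per-feature
  *disfluency score*

  $$\text{disfluency} = \#\{\text{local maxima of } v(t) \text{ within the feature's span}\},$$

  where 1 = fully fluent for a straight stroke; and the signal-to-noise
  velocity peaks difference for repetitive pen-control tasks,
  $\mathrm{SNvpd} = N_{10\,\mathrm{Hz}} - N_{5\,\mathrm{Hz}}$.
* **Rule-based accuracy coding** — allograph-aware matching of produced
  strokes to target features and a parameter-driven malformation coder
  (exemplar rule set: junction angle 20–90°, straightness, relative
  length, and junction gap all within 1/6-of-length tolerances).
* **Task scoring** — drop-2-score-5 selection for lines and circles,
  whole-trace garlands, summed figure eights, the dictation trial filter,
  and letter-knowledge scoring with early termination.
* **Nested mixed-model sequences** — incremental LMMs over per-feature
  peak counts with by-child and by-item random intercepts, likelihood
  ratio comparison, Satterthwaite inference, marginal R² and ICCs, plus
  logistic GLMMs for malformation.
* **A synthetic handwriting generator** — minimum-jerk sub-movement
  traces with tremor and timestamp jitter, geometric defect injection
  with known coder verdicts, pen-control task traces, and whole cohorts
  with known effect sizes for power, type-I-error, and
  parameter-recovery studies.

## Worked example

Generate one synthetic production of the letter A whose three strokes are
drawn with 1, 4, and 2 sub-movements, score it, and code its accuracy:

```r
library(penfluency)

g <- gen_character_trace("A", n_submovements = c(1, 4, 2), seed = 42)
g$trace
#> <pen_trace NA> 353 samples, 2646.6 ms, nominal 133 Hz

trace_fluency_table(g$trace, g$marks)[, c("feature_id", "peak_count", "shape_kind")]
#> # A tibble: 3 × 3
#>   feature_id  peak_count shape_kind
#>   <chr>            <int> <chr>
#> 1 a_upright_l          1 straight
#> 2 a_upright_r          4 straight
#> 3 a_crossbar           2 straight
```

The pipeline recovers exactly the injected sub-movement counts: the first
upright was fluent (1 peak), the second highly disfluent (4 peaks). The
accuracy coder confirms that all three features are well formed —
disfluent movement, accurate product:

```r
inv <- load_inventory()
code_character_accuracy(g$trace, g$marks, inv$characters$A)[, c("feature_id", "verdict")]
#> 1 a_upright_l accurate
#> 2 a_upright_r accurate
#> 3 a_crossbar  accurate
```

Simulate a cohort of 80 children with correlated pen-control and
letter-knowledge abilities (+0.5 and −0.5 peaks per SD by default) and run
the incremental model comparison:

```r
b <- gen_cohort(cohort_config(n_children = 80, seed = 7))
rep <- run_copy_sequence(b$copy_table, b$covariates, inference = TRUE)
rep$comparison[, c("model", "description", "chisq", "df", "p", "retained")]
#> # A tibble: 8 × 6
#>   model   description                 chisq    df        p retained
#> 1 Model 1 feature malformed           1.60      1 2.06e- 1 FALSE
#> 2 Model 2 feature is a curve        208.        1 3.52e-47 TRUE
#> 3 Model 3 character is a letter       0.183     1 6.68e- 1 TRUE
#> 4 Model 4 pen-control measures       27.4       4 1.68e- 5 TRUE
#> 5 Model 5 pen-control x curve        39.9       4 4.57e- 8 TRUE
#> 6 Model 6 pen-control x letter        4.35      4 3.61e- 1 FALSE
#> 7 Model 7 letter-knowledge measures  43.2       3 2.27e- 9 TRUE
#> 8 Model 8 letter-knowledge x letter   1.21      3 7.50e- 1 FALSE
```

The sequence detects the injected curve offset (Model 2), pen-control
effects (Model 4) and letter-knowledge effects (Model 7), while the null
steps are dropped — note the letter-status dummy (Model 3) is retained by
policy despite being non-significant, so later interactions stay
interpretable. The best model here reports a marginal R² of 0.30 with
ICCs of 0.13 (child) and 0.03 (item).

`run_pipeline(run_config(n_children = 50, seed = 1))` chains the whole
thing — simulate → kinematics → code features → score tasks → fit models →
report — into a run directory with provenance headers and bit-identical
tables on re-run.

## Package layout

```
R/                 implementation (IO, kinematics, coding, scoring,
                   models, synthetic writer, pipeline)
inst/extdata/      inventory.yaml — characters, allographs, rule
                   parameters
tests/testthat/    unit, property, and acceptance tests
scripts/           acceptance.R
vignettes/         pen-movement-fluency.Rmd — methods and design notes
```
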