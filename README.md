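# gazecue

Analysis tools for gaze-following (gaze-cueing) experiments in which the
task-irrelevant gaze of a model face interferes with observers' instructed
saccades — and for asking whether that interference depends on the social
relationship between observer and model.

## The problem and who this is for

In the paradigm this package serves, observers saccade left or right on an
imperative color cue while a centrally presented face (one of four model
characters, one per block) simultaneously looks left or right, congruently
or incongruently with the instruction. Gaze capture shows up as lower
accuracy and slower saccadic reaction times on incongruent trials. The
scientific question is whether observers in two affiliation groups (e.g.
left- vs right-wing voters) are captured more by ingroup than outgroup
faces, and whether the capture scales with the perceived personality
similarity between observer and model. The package is aimed at eye-tracking
/ social-attention researchers who want this full analysis as tested,
reusable code, including a seeded synthetic-experiment generator for power
and calibration work.

## What it computes

For observer *i* and character *c*:

* accuracy interference (percentage points):
  `A_ic = 100·[P(correct | congruent) − P(correct | incongruent)]`
* RT interference (ms), kept correct trials only:
  `R_ic = meanRT(incongruent) − meanRT(congruent)`

after saccade scoring (first post-cue horizontal saccade with amplitude
> 2°) and trial filtering (no saccade; latency < 100 ms or > 500 ms).
Observers further than 3 SD from their group's mean in any single character
condition are excluded in one pass.

The indices enter a split-plot ANOVA — group (between, 2 levels) ×
character (within, 4 levels) — with each effect tested against its own
error stratum and partial η² = SS_eff/(SS_eff + SS_err). A bootstrap
F-null (B draws of all N×4 observations with replacement, rearranged into
the design shape) replaces the central F distribution when normality
(Shapiro–Wilk) or homogeneity (Levene) checks fail. Duncan's multiple
range test handles post-hocs; per-cell one-sample tests against zero fall
back to percentile-bootstrap CIs for non-normal cells.

Personality similarity between an observer's self profile and a character
profile (25 Big-Five adjective ratings, 1–5) is
`S = 1 − Σᵢ |selfᵢ − charᵢ| / 100` ∈ [0, 1], in perceived (own ratings)
and objective (sample-consensus ratings) variants; similarity is
correlated with interference with percentile-bootstrap CIs and a
standardized-residual outlier sensitivity check.

## Worked example

```r
library(gazecue)
cfg <- analysis_config(cohort = cohort_config(seed = 11), B = 2000, seed = 11)
report <- run_pipeline(cfg)
print(report)
```

```
== Gaze-interference analysis report ==

Trial filtering summary
                status    n pct_total
                  kept 4466 83.072917
   excluded_no_saccade  726 13.504464
 rejected_anticipation   94  1.748512
        rejected_delay   90  1.674107
no-saccade: 13.5% of total; anticipation/delay: 3.4% of total (4.0% of detected)

-- Accuracy interference (percentage points) --
Split-plot ANOVA (between: group; within: condition)
                effect       ss df       ms     F       p partial_eta_sq
                 group 1843.608  1 1843.608 9.687 0.00447          0.271
             condition  856.189  3  285.396 3.220 0.02720          0.110
       group:condition 1507.498  3  502.499 5.670 0.00145          0.179
 subjects_within_group 4948.491 26  190.327    NA      NA             NA
     condition:subject 6912.804 78   88.626    NA      NA             NA
Bootstrap F-null (B = 2000, unit = observation)
           effect     F p_boot
1           group 9.687 0.0040
2       condition 3.220 0.0255
3 group:condition 5.670 0.0005

-- Perceived-similarity vs accuracy interference --
  character      mode         r  n p_parametric     ci_low   ci_high
 Berlusconi perceived 0.5494805 28  0.002456515  0.2270015 0.7688013
   ...
```

Reading it: ~13.5% of the 5376 trials had no detectable saccade and ~3.4%
were anticipations/delays; the group × character interaction on accuracy
interference is significant both parametrically (F(3,78) = 5.67) and
against the bootstrap null (p = .0005) — the two observer groups are
captured differently by the four faces, as injected by the default
synthetic configuration — while RT interference (not shown) has no group
structure; and perceived similarity with the right-wing leader's face
correlates with his gaze's interference (r = .55, bootstrap CI excluding
zero). `write_report(report, "report.json")` serialises everything,
including provenance (seed + config) sufficient to regenerate the report
byte for byte.

The methods vignette (`vignettes/gaze-interference-methods.Rmd`) documents
the statistical engine, the generator's assumptions, and every numerical
choice.

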