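# arbbt

A headless, fully testable engine for an **augmented-reality Box and
Block Test** (AR-BBT), plus the statistics used to validate such a test
against the physical one in a stroke cohort.

The Box and Block Test measures unilateral gross manual dexterity: 150
one-inch cubes, a box with two compartments separated by a central
partition, 60 seconds to move as many cubes as possible over the
partition with one hand. In the AR variant, the cubes are virtual:
a hand tracker produces 21 landmarks per video frame, a *pinch* is
detected when the thumb-tip/index-tip distance
*d* = ‖p₄ − p₈‖ falls below a threshold (with a hysteresis band so the
pinch does not chatter), and a pinched hand inside a block's square
grabs it. Carrying the block through the divider voids it; opening the
pinch in the target compartment scores it. `arbbt` implements the whole
pipeline downstream of the landmark stream — pinch state, block
lifecycle, 60-s clock, familiarization-plus-assessment protocol,
per-transfer kinematics — with no camera and no renderer, so every path
is deterministic and testable. A closed-loop synthetic subject
(parameterized reach speed, tremor, pinch reliability) generates
landmark streams for any configuration.

The statistics module covers the validation study design around such an
engine: a priori sample size for detecting a correlation ρ between AR
and physical scores via the bias-corrected Fisher z approximation
(atanh(r) ~ N(atanh ρ + ρ/(2(n−1)), 1/(n−3)); n = 29 for ρ = 0.5,
α = 0.05, power 0.80, two-tailed) with a Monte-Carlo power cross-check,
Pearson correlation with Cohen effect-size classes, paired t /
Wilcoxon comparison of AR vs physical scores, cohort eligibility
filtering with disjoint exclusion tallies, 4-level Likert questionnaire
summaries, and a bivariate-normal paired-score generator for
parameter-recovery studies.

## Worked example

Simulate a default (hemiparetic-like) subject through one 60-second
trial and inspect the result:

```r
library(arbbt)
cfg <- session_config()                      # 60 s, 720p @ 60 fps, 150 blocks
subject <- subject_model()                   # reach 300 px/s, tremor 3 px
result <- run_trial(simulated_subject_provider(subject, cfg, seed = 42), cfg)
print(result)
#> AR-BBT trial: 10 blocks in 60 s
#>   grabs 11, drops 0, divider collisions 0, held at cutoff 1
#>   mean transfer 3.43 s, mean path 1227 px, peak speed 1048 px/s
head(result$transfers[, c("block_id", "transfer_duration", "path_length", "peak_speed")], 3)
#>   block_id transfer_duration path_length peak_speed
#> 1        1          2.966667    1041.690  1047.9783
#> 2        2          3.300000    1181.385   758.7736
#> 3        3          3.383333    1200.262   880.7409
```

The score (10 blocks) is what the test reports; the kinematics rows are
the extra information an AR administration yields per transfer:
duration in seconds, fingertip path length in pixels, peak speed in
pixels/second. `write_landmark_stream()` / `run_trial(stream_provider(...))`
record and replay streams bit-faithfully — the same stream always
produces a byte-identical event log.

The study-side statistics, on a synthetic 31-patient table generated
with the cohort's score moments (BBT 36.64 ± 6.14, AR-BBT
11.90 ± 2.11, ρ = 0.918):

```r
sample_size_for_correlation(rho_H1 = 0.5, alpha = 0.05, power = 0.80)
#> [1] 29
tab <- synthetic_study_table(31, seed = 1)
pearson_correlation(tab$bbt_score, tab$arbbt_score)
#> Pearson r = 0.853 (n = 31, t(29) = 8.82, p = 1.06e-09, large effect)
pd <- paired_decrease_test(tab$arbbt_score, tab$bbt_score)
#> paired decrease: t = -45.29, p = 3.5e-29
```

At n = 31 the sample correlation scatters around the generating value
(0.853 here); the parameter-recovery tests quantify this over 1,000
replicates. A command-line front end for the same operations lives in
`inst/cli/arbbt.R` (`simulate`, `run`, `replay`, `stats`).

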