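---
title: "Methods: a headless augmented-reality Box and Block Test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a headless augmented-reality Box and Block Test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arbbt)
```

## The test and what the engine models

The Box and Block Test (BBT) is a standard measure of unilateral gross
manual dexterity: a box with two compartments separated by a central
partition, 150 one-inch cubes in the compartment adjacent to the
assessed hand, and 60 seconds to transfer as many cubes as possible over
the partition. The score is the number of cubes transferred; cubes that
touch the partition do not count.

`arbbt` implements an augmented-reality variant of this test as a
*headless engine*: no camera, no renderer. Its input is a time-ordered
stream of 21-point hand-landmark frames — the standard hand topology in
which landmark 4 is the thumb tip and landmark 8 the index-finger tip,
with coordinates normalized to the image. Any source that yields such
frames satisfies the provider contract: a live hand-tracking adapter, a
recorded JSONL file, or the built-in simulator. Everything downstream of
the landmark stream — pinch detection, the virtual blocks, the clock,
the score — is deterministic, replayable, and testable.

## Pinch detection

The pinch aperture is the Euclidean distance between the thumb-tip and
index-tip pixel positions. The pinch *closes* when the aperture falls
strictly below `grab_threshold` and *reopens* only when it reaches
`release_threshold`:

* `grab_threshold` defaults to 0.05 × frame width (64 px at 1280×720).
  A resolution-proportional default keeps the threshold meaningful at
  both the 720p target and the 480p fallback, and corresponds roughly to
  a closed fingertip pinch with the hand half a metre from a typical
  webcam.
* `release_threshold` defaults to 1.25 × `grab_threshold`. The gap is a
  hysteresis band: an aperture jittering between the two thresholds —
  which per-frame landmark noise produces constantly in practice —
  never toggles the pinch state. Without it, a single noisy frame
  mid-carry would drop the block.

The inequality at the grab threshold is strict, and the state update is
monotone in the threshold: if a frame closes the pinch at threshold *t*
it closes it at every larger threshold. Both properties are enforced by
property-style tests. Depth (`z`) is carried through the data model but
does not gate grabbing; with a single uncalibrated camera the relative
depth values are too noisy to bear rules.

## The arena state machine

The play area is an axis-aligned rectangle over the lower central part
of the view. All rectangles are half-open, `[x0, x1) × [y0, y1)`, with
the origin at the top-left and y downward; this convention is stated
once and used everywhere, which keeps boundary cases (a fingertip
exactly on an edge) unambiguous.

A vertical *divider band* — 24 px wide at a 1280-px frame, rising from
the box floor to 55% of the box height — stands on the box midline. The
geometry deliberately leaves airspace above the band so that the only
route from one compartment to the other is an arc over the divider, as
in the physical test. Divider contact is a closed-rectangle intersection
between the block's square and the band: touching edges count, the
strictest reading of "without contacting the partition".

Blocks are 60-px squares (half-size 30 px at 720p, about one inch at the
modeled camera distance). Of the 150 available, exactly one is live at
any instant — the test prohibits working multiple blocks — and each is
spawned individually at a seeded-uniform position inside the source
compartment, inset by a spawn margin so the cube lies wholly within the
compartment, with a seeded-uniform color among red, green, blue and
yellow. The lifecycle is:

* **RESTING → GRABBED** when *both* fingertips lie inside the block's
  square and the pinch is closed. Requiring both tips (not their
  midpoint) reflects that the fingers themselves must be on the block.
* **GRABBED**: the block tracks the fingertip midpoint each frame,
  clamped component-wise into the box (out-of-bounds checks), then
  tested against the divider. Contact vanishes the block and spawns the
  next one immediately.
* **GRABBED → SCORED** when the pinch opens with the block center
  inside the target compartment: one point, and the block settles to
  the compartment floor, persisting for the rest of the trial.
* **GRABBED → RESTING** when the pinch opens anywhere else: the block
  stays where it was dropped (clamped) and remains grabbable. Only
  divider contact voids a block; an ordinary miss should not destroy
  it, since nothing analogous happens in the physical test.

Every transition appends a typed, timestamped event (SPAWN, GRAB,
CLAMP, DIVIDER_COLLISION, DROP, SCORE), and the whole trial reconciles
three ways: the reported score, the count of SCORE events and the count
of SCORED blocks must agree on every run.

## Trials, clock and kinematics

The clock is driven by frame *timestamps*, not frame counts: landmark
pipelines have tens of milliseconds of processing jitter, and a
count-based clock would stretch or compress the 60-second window.
Frames with no detected hand freeze the arena but let the clock run,
matching a timed test in which the hand leaves the camera view. A frame
stamped at or past the trial duration ends the trial without being
applied; a block still held at cutoff is counted but never scored.

The protocol layer runs five familiarization trials and then one
assessment trial whose score is the reported result — the convention of
the traditional test. Each trial derives its own seed from the session
seed and trial index, so spawn sequences differ across trials but the
whole protocol reproduces exactly.

Per scored transfer, the engine extracts kinematics from the carry
samples: transfer duration, fingertip-midpoint path length (sum of
successive displacements, never below the grab-release chord), peak
speed, and mean pinch aperture. These are the quantities an AR
administration can add over the physical test's single count.

## The synthetic subject

The simulator closes the loop: it reads only the published arena
observation (the live block's position and state) and synthesizes
landmark frames of a hand that reaches the block, dwells a reaction
lag, pinches, carries the block up to a carry height, across the
divider, down to a drop point in the target compartment, and releases.
The 19 non-tip landmarks come from a fixed hand template translated
with the carry point; only the two fingertips carry behavior.

The impairment model has two axes:

* **Tremor** — white Gaussian noise, in pixels, added to every landmark
  every frame. White noise is the simplest falsifiable choice; real
  tremor is band-limited (4–12 Hz) and autocorrelated, and the noise
  source is documented so an autocorrelated model can be swapped in.
* **Pinch reliability** — the probability that a commanded *grasp
  attempt* registers. A fumbled attempt (the close command fails, or
  the tremor-displaced fingertips missed the block) costs a
  corrective-movement penalty (`grasp_retry_penalty`, default 0.8 s)
  before the next attempt. The grip, once registered, is held stably.
  An alternative we rejected was per-frame unreliability of the *hold*:
  it makes accidental mid-carry releases over the target compartment
  score early, so a *less* reliable pinch could outscore a more
  reliable one — the opposite of what an impairment axis must do. With
  the attempt-level model, mean score is monotone: non-increasing in
  tremor and non-decreasing in reliability, which
  `score_vs_impairment_curve()` checks on a paired (common-random-
  numbers) grid.

Default subject parameters (reach 300 px/s, tremor 3 px, reliability
0.97, reaction lag 0.1 s, carry height 85% of box height) emulate a
hemiparetic hand: a dozen or so transfers per 60-second trial, the
range reported for stroke patients on AR versions of the test, well
below the 30+ of the physical test. A `carry_height_fraction` below the
divider's 0.55 produces divider collisions by construction — failure
modes are simulated, not mocked.

What the simulator does *not* emulate: landmark occlusion and
re-detection, handedness misclassification, autocorrelated tremor,
depth noise, fatigue over the minute, and deliberate strategy changes.
Passing tests therefore demonstrate the engine's correctness and the
protocol's determinism, not clinical validity on real video.

## Validation statistics

The statistical surface mirrors how such an AR test is validated
against the physical one in a stroke cohort.

**Sample size for a correlation.** The a priori question is how many
subjects are needed so that a two-tailed test of H0: ρ = 0 at α = 0.05
has 80% power when the true correlation is 0.5. We use the Fisher z
approximation with the small-sample mean correction: atanh(r) is
treated as normal with mean atanh(ρ) + ρ/(2(n−1)) and SD 1/√(n−3), and
`sample_size_for_correlation()` returns the smallest n whose analytic
power reaches the target — 29 for the design above. The bias-corrected
mean matters: the uncorrected transform puts n = 29 marginally *below*
80% power (0.7998) and would return 30, while exact Monte-Carlo power
at n = 29 is ≈ 0.815. A 10,000-replicate Monte-Carlo power check
(`monte_carlo_correlation_power()`) accompanies the analytic value and
must bracket the target; the package's tests pin the rejection rate at
n = 29 to 0.80 ± 0.02.

**Correlation and paired comparison.** `pearson_correlation()` computes
the product-moment r from its sums (cross-checked in tests against
`cor.test`), the t statistic r√(n−2)/√(1−r²), the two-tailed p on n−2
degrees of freedom, and the Cohen class of |r| (≥0.5 large, ≥0.3
medium, ≥0.1 small, else negligible). The paired AR-vs-physical
comparison defaults to the paired t-test with a Wilcoxon signed-rank
alternative selectable — clinical reports frequently do not say which
paired test produced a quoted p-value, so both are exposed and the
direction of the mean difference is always reported.

**Cohort filtering.** Eligibility requires hemorrhagic-stroke etiology,
Ashworth ≤ 3 and ≤ 6 months since the incident; neurological
comorbidities affecting hand motion and musculoskeletal deficits
limiting finger range of motion exclude. A record matching several
reasons is tallied once, under the first in a fixed precedence
(neurological comorbidity → arthritis → joint stiffness → Ashworth →
time → etiology), so exclusion tallies are disjoint and conserve the
record count.

**Questionnaire.** Four-level Likert items are summarized per item as
category percentages plus collapsed agree/disagree, rounded to one
decimal half away from zero — the rounding that printed clinical tables
use (29 of 31 → 93.5%).

**Synthetic paired scores.** Because per-patient data from such studies
are not released, `generate_paired_scores()` draws from a bivariate
normal with specified means, SDs and ρ (via `MASS::mvrnorm`),
optionally integerized to non-negative block counts. Parameter-recovery
tests generate 1,000 cohort-sized (n = 31) replicates at the reported
moments (BBT 36.64 ± 6.14, AR-BBT 11.90 ± 2.11, ρ = 0.918) and require
the Fisher-z 95% CI to cover the generating ρ in ≥ 93% of replicates
(integerization costs a little coverage relative to the nominal 95%)
and the paired test to flag the decrease in > 99%.

## Numerical and design notes

* Seeds: every random draw sits in a derived, saved/restored RNG
  stream; the caller's `.Random.seed` is never disturbed, and derived
  seeds stay below 2³¹.
* Streams serialize to JSON Lines with numbers printed at 17
  significant digits, so write → read restores every double
  bit-for-bit and identical streams replay to byte-identical event
  logs.
* The horizontal-flip utilities (`flip_horizontal()`,
  `mirror_consistency()`) are preprocessing diagnostics: the engine
  consumes already-mirrored selfie-view streams, and the
  mirror-consistency score (minimum mean absolute difference over
  horizontal shifts) lets a caller verify a pipeline's flip stage
  without the engine guessing at intent.
* A vanished block's replacement spawns instantly; the assessment score
  is a single trial, not a mean of several; a release anywhere in the
  target compartment scores (dropping a cube into the compartment from
  above counts in the physical test too). Each of these was an open
  choice; the alternatives would be one-line changes.
* Test problem sizes: property suites run trials of 8–60 s at 30–60
  fps, Monte-Carlo power uses 10,000 replicates and parameter recovery
  1,000 — sizes chosen so the full suite exercises every engine path
  and statistical claim in well under a quarter of an hour on one CPU.

## Limitations

The engine validates logic, not perception: nothing here measures how
well a hand tracker finds landmarks on impaired hands, and the
simulator's noise model is deliberately minimal. The block-size and
threshold defaults encode one plausible camera geometry (≈50 cm, 720p);
deployments at other distances should recalibrate `pinch_config()` and
`block_half_size` together. The statistics module reproduces a study
*design* — power analysis, eligibility funnel, analysis pipeline — and
recovers generating parameters from synthetic data; it cannot, by
construction, reproduce clinical results that depend on unreleased
patient data.
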