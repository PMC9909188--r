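---
title: "Response-to-name screening: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-to-name screening: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtnscreen)
```

## The screening problem

A diminished or absent response to name (RTN) — a toddler failing to turn
their head when called — is among the earliest behavioral markers of
autism spectrum disorder (ASD). In the standardized protocol this package
models, a toddler plays with a toy while an evaluator, and later the
caregiver, calls their name from about 2 m behind. The caller pauses
roughly 3 s between calls and calls at most three times. Human coders
score each trial on an ordinal scale: 0 (no response), 1 (head turn
without eye contact), 2 (head turn with eye contact).

`rtnscreen` implements the downstream, quantitative half of an automated
version of this assessment. The upstream detectors (speech recognition
for call timestamps; face detection, alignment and identity verification)
are assumed to have already run: the package's inputs are their outputs —
a stream of name-call events and a per-frame record of face presence,
identity match and (optionally) 68 facial landmarks or a precomputed head
yaw.

## Data model and timing conventions

A `ProcedureSegment` holds one trial: call events (`t_call`, `caller`,
`call_index` 1–3) plus a frame stream at a fixed frame rate (30 fps by
default — protocol video runs at 30 frames per second). All times are
seconds from segment start; frame *k* spans `[k/rate, (k+1)/rate)` and is
converted to time by its start point, which makes latency arithmetic
unambiguous. Frame streams may be sparse: an absent frame index means no
face was detected in that frame. `SubjectRecord` (group label ASD/DD/TD,
age, sex, up to one segment per procedure) and `Cohort` complete the
hierarchy; S4 validity enforces structural typing, while
`validateSegment()` checks the protocol rules (≤ 3 calls, sorted call
times, ≥ 1 s between calls, strictly increasing frame indices, identity
implies face, 68-point landmark shape) and reports violations as data
rather than exceptions. The minimum inter-call gap is validated at 1 s,
deliberately looser than the protocol's nominal 3 s, because real call
timings jitter; the simulator itself uses 3 s.

Two plain-text dialects are supported (`readCohort()`/`writeCohort()`):
JSONL with one subject per line, and a CSV triple
(`subjects.csv`/`events.csv`/`frames.csv`). Per-segment metadata
(`frame_rate`, `segment_length`) travels as repeated columns of
`events.csv` so the dialect stays a three-file contract.

## Head pose from landmarks

The original system computed head pose from the 68 iBUG landmarks
returned by its face aligner. Here that step is a weak-perspective rigid
alignment: a least-squares 2×3 affine fit of a frontal 3-D template's
rigid subset (jaw extremes, nose bridge and tip, eye corners) to the
observed 2-D points, projected by SVD onto the nearest scaled rotation,
from which yaw, pitch and roll are read off. No camera intrinsics are
assumed because none exist in the data. A fit that lands beyond ±90° of
yaw (a "back of head" explanation) is resolved to its frontal mirror
twin, which exists because the template is bilaterally symmetric. Only
yaw drives the *facing* decision — the caller stands behind the toddler,
so the response head turn is primarily a yaw rotation. The facing
threshold defaults to 30° (|yaw| ≤ 30°, boundary inclusive) and is
configurable; the protocol itself never quantified "turned toward the
caller", and 30° is a conventional half-cone for face-to-face
orientation. Noise-free recovery is exact to well under the 2° contract
for |yaw| ≤ 45°.

## Response features

Two features summarize each trial, with `T_c1` the onset of the first
call and `T_f` the start time of the first *valid* face frame:

- **Latency** `= T_f − T_c1`, where a frame is valid when the face is
  present, the identity matches the child, the head is facing, and the
  frame starts strictly after `T_c1`. If no frame qualifies within
  `(T_c1, T_c1 + 10]` s the trial is a non-response and latency is
  imputed at 10 s.
- **Duration** `= N_f / frame rate`, with `N_f` the total count of
  qualifying frames after `T_c1` (a sum, not the longest run). A
  non-response has duration 0.

Choices the protocol description leaves open, fixed here once:

- The observation window is anchored to the *first* call even when the
  child responds after the second or third, because that is what the
  latency definition states; the window is `(T_c1, T_c1 + 10]`, boundary
  inclusive, so imputation is consistent with the 10 s cap.
- Responses later than 10 s after the first call count as non-responses
  (latency 10, duration 0) rather than being clipped to 10.
- Pre-call face detections never count, for duration as well as latency —
  the validity rule ("only a response appearing after the call") is
  extended to both features.
- Frames carrying neither landmarks nor yaw are treated as facing: the
  detector did report an identity-matched face, and zeroing duration on
  pose-free data would silently bias the features. `strictPose = TRUE`
  reverses this for pose-complete data.

Duration is always an integer multiple of the frame period, and
`responded == FALSE` iff `(latency, duration) == (10, 0)`; both
invariants are property-tested.

## Scoring and joint classification

The machine score is rule-based: 2 when the child responded with latency
≤ 10 s and duration ≥ 0.5 s, else 0. The machine never emits score 1,
which requires gaze information this pipeline does not model. The
defaults (10 s, 0.5 s) reflect that the deployed system's machine scoring
behaved almost exactly like a responded flag; both thresholds are
configurable and learnable from data via `fitStump()` (exhaustive
midpoint search maximizing balanced accuracy, ties to the smallest
threshold).

ASD prediction is joint over the two procedures. The default learner is
a depth-≤ 2 axis-aligned decision tree over the four features
(latency/duration × evaluator/caregiver), grown by exhaustive search with
the Gini criterion; ties break toward the latency features and the
smaller threshold, and leaves take the training majority. This learner
is deterministic and seed-free, keeping cross-validation reproducible.
Subjects lacking either procedure are dropped from the joint analysis by
default (the simulated default design then yields 123 analysis
subjects). Cross-validation is stratified 10-fold; fold assignment is a
function of (subject id, label, seed) — subjects are canonically sorted
before the seeded shuffle — so predictions are invariant to input order.

One empirical property of this design is worth stating plainly: on
cohorts simulated under the default calibration, the Gini tree settles at
a *more specific, less sensitive* operating point than the reference
deployment's 80.0%/69.8% sensitivity/specificity, because greedy purity
splits favor an AND-like combination of the procedures, whereas the
reference operating point corresponds arithmetically to an OR of the two
per-procedure non-response indicators. The pipeline therefore also
offers `jointFeatures = "scores"` (classify on the two machine scores,
which recovers the OR-like shape) and `method = "or"` (an OR-of-stumps
combiner). The acceptance script recomputes the cross-validated metrics
for the default configuration at every run rather than this vignette
quoting fixed numbers.

For ROC analysis a continuous risk score is needed; the assessment
protocol does not define one, so the package uses the mean over available
procedures of `(latency/10 + (1 − min(duration, 3)/3))/2` — 1 for a
double non-response, near 0 for an instant sustained response. The 3 s
duration cap is configurable.

## Statistical suite

All evaluation statistics are implemented from their formulas (and
cross-checked in the test suite against independent implementations —
`stats::kruskal.test`, `stats::chisq.test`, `pROC` — plus brute-force
oracles):

- sensitivity/specificity/accuracy from 2×2 diagnosis tables;
- exact agreement rates, pooled across strata by stratum size;
- Cronbach's alpha over rater columns;
- Kruskal–Wallis by ranks with midrank ties correction;
- Dunn's standardized pairwise post-hoc `z` with Bonferroni adjustment
  capped at 1 (the conventional follow-up to a significant
  Kruskal–Wallis omnibus when groups are compared pairwise);
- Mann–Whitney AUC with 0.5 tie credit and DeLong structural-components
  standard errors, plus the DeLong paired test for two correlated ROC
  curves (invariant under monotone transforms of the scores);
- Pearson chi-square on 2×2 tables, uncorrected by default. The
  method-accuracy comparison is run *without* continuity correction on
  correct/incorrect × method counts: the uncorrected statistic is the
  one consistent with the reference analysis (Yates would give ≈ 2.0
  instead of 2.44 on the bundled tables), and the comparison is treated
  as unpaired, as that reference value implies.

Tests are two-sided with 0.05 significance throughout.

## The synthetic cohort generator

No raw recordings accompany the reference study, so the generator
replaces them with cohorts whose *group-conditional response structure*
matches the published summaries. Per (group, procedure):

- non-response probability from the observed human score-0 proportions
  (e.g. ASD evaluator 37/61, TD evaluator 6/33);
- responder latency: log-normal truncated to (0, 10) s, `sdlog` 0.8,
  with `meanlog` solved (by `uniroot` on the truncated CDF) so that the
  *overall* median — after imputing non-responders at 10 s — hits the
  published group median (DD/TD: 3, 2.17, 2.00, 1.80 s);
- responder duration: gamma with shape 2, scale solved the same way
  against the published duration medians (1.88, 1.73, 1.00, 1.45 s);
- ASD responder distributions are not identifiable from
  imputation-dominated overall medians (more than half of ASD evaluator
  trials are non-responses, so the group median is pinned at 10/0
  regardless); they are fixed at a plausible responder median of 4 s
  latency and 1.2 s duration;
- partial responses (human score 1) with the observed score-1 share of
  responders; a perturbed second rater emulates inter-rater noise.

Skewed positive distributions (log-normal, gamma) are used because only
medians and IQRs are published; the shape parameters are free
configuration. Responder latency draws are truncated at 9.9 s: a draw
within one frame period of the window edge would flip to a non-response
after snapping onto the 30 fps grid, breaking the planted-value
round-trip guarantee (recovery within one frame period).

Non-responders still receive all three calls; responders receive calls
until the response (1 + ⌊latency/3 s⌋, capped at 3). The face run starts
at the first frame boundary after `T_c1 + latency`, is identity-matched
and frontal (|yaw| ≤ 10°), and lasts the drawn duration; optional
pre-call face noise (30% of segments, 0.5 s) exercises the validity rule.
Quota mode plants exactly `round(n(1 − p))` non-responders per
group × procedure, which makes the median-based checks deterministic; the
default design also leaves one ASD and one TD caregiver segment absent,
reproducing the 123-subject joint-analysis set. Generation is
bit-reproducible: each subject draws from a substream derived from the
master seed and its id, so content does not depend on generation order.

What the generator does *not* emulate: detector failure modes (dropped
frames, identity confusions), habituation across calls, any real
machine-human disagreement mechanism (only partial responses and rater
perturbation), or eye gaze. Passing pipeline tests on these cohorts
therefore demonstrates correctness of the measurement, scoring and
evaluation machinery under the published response structure — not
detector robustness on real video.

## Problem sizes and numerical choices

The test suite and acceptance script run at the study's own scale
(125-subject cohorts, 248 segments, 10-fold CV) plus fuzzed small
instances: 1,000 planted segments for the feature round-trip, ≤ 10×10
score sets against a brute-force AUC, n ≤ 50 stump instances against an
exhaustive oracle, a 10,000-resample bootstrap against the DeLong test,
and 8-subject training sets against a nested-loop tree oracle.
Deterministic tie-breaks are fixed everywhere randomness is not
essential: smallest threshold, earliest feature, negative class on leaf
ties. Degenerate inputs (single-class training sets, zero-variance
ratings, empty margins, collinear landmarks) raise informative errors
rather than producing NaNs.

## Known limitations

- Score 1 (head turn without eye contact) is out of the machine's reach
  by design; machine/human agreement is structurally capped below 1 for
  groups with partial responders.
- The 30° facing threshold and the 10 s window are conventions, not
  estimates; sensitivity of downstream metrics to them is exposed via
  configuration, not marginalized.
- The ROC risk score is a package construction (the reference analysis
  does not define its ROC variable), so AUC values on synthetic cohorts
  characterize this score, not the original system's.
- Published AUCs (0.81/0.91) and the paired-ROC Z of the original cohort
  require the unavailable per-subject raw data and are deliberately not
  reproduction targets; the statistics that compute them are instead
  verified against oracles.
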