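---
title: "Methods: tracking and analysing bumblebee scanning flights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking and analysing bumblebee scanning flights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`beescan` turns fixed-camera video of a single bumblebee flying in a
discrimination arena into behavioural events and statistics: where the bee
flew, how fast, which pattern regions it scanned at what body angle, when
it landed, and how its choices evolved over training. This vignette
documents the models and procedures, the tunable parameters, the synthetic
data the test suite relies on, and the numerical choices and limitations a
user should know about.

## Setting and coordinate conventions

The arena is a 60 cm wide, 40 cm tall, 60 cm deep box whose rear wall
carries eight 10-cm discs, four with a plus and four with a multiplication
pattern; each disc centre doubles as a feeder entrance. Two cameras record:
a front camera (default 1280×720 at 240 fps) viewing the rear wall, and a
top camera (default 1280×720 at 120 fps) looking down on the floor plane.
All analysis runs in the arena frame: `x` right along the rear wall, `y`
up, `z` out of the wall towards the entrance, metres throughout. Body yaw
is measured from the wall normal (0° = facing the wall, positive
counter-clockwise seen from above). The two camera views are analysed
separately; fusing them into a single 3-D track is out of scope.

## Tracking

Per frame, the tracker subtracts a bee-free mask image and thresholds the
absolute difference with Otsu's method, clamped below by a configurable
minimum (default 0.1 intensity) so that near-empty difference images do not
produce spurious blobs. Connected components are labelled (via `EBImage`)
and filtered to a bee-sized area window derived from the camera scale and a
body-length range of 1.2–2.0 cm — never hard-coded pixel counts. The
second-central-moment ellipse of the winning component gives the centroid,
axis lengths and the undirected body-axis angle; components with axis ratio
below 1.2 are flagged `ambiguous` and their angle is not trusted. Across
frames, the largest candidate seeds the track and subsequent frames keep
the candidate nearest the previous confirmed centroid, rejected beyond a
50 px/frame gate (decoy rejection). Gaps of up to 5 frames are bridged
linearly; longer gaps split the track into segments. Each segment is
smoothed with a centred moving average (default width 5; end windows
shrink), which guarantees smoothed positions stay within the range of the
raw positions that feed them.

Calibration is a planar projective transform (8-parameter homography,
least-squares DLT) fitted from at least four non-collinear reference points
with known pixel and metric coordinates on the imaged plane. Orthographic
cameras reduce to the affine special case; an obliquely mounted camera is
handled by the same fit, and the renderer's keystone-distortion toggle
exists precisely to test that path.

The undirected axis angle is resolved to a signed yaw by choosing the axis
direction within 90° of the flight direction; below 0.02 m/s the direction
nearest the previous resolved yaw is carried forward. An optional
`ambig_margin` makes near-perpendicular frames defer to continuity as well;
it defaults to 0 because on synthetic flights the plain velocity rule
resolves more frames correctly — the continuity variant can latch onto an
early error and propagate it.

## Flight events

Speed is computed by central differences (one-sided at the ends). The
landing threshold is found by 1-D 2-means clustering of all speeds within
2 cm of any feeder: deterministic initialisation at the sample minimum and
maximum, iterated to convergence, threshold at the midpoint of the two
centres. On bimodal near-feeder speed samples this reproduces the exhaustive
optimal two-segment partition of the sorted sample on ≥99% of points (the
test suite checks exactly that against a brute-force oracle).

A *choice* is a maximal run of frames within 1 cm of a feeder at
sub-threshold speed lasting at least 0.1 s; runs at the same feeder less
than 0.5 s apart merge. Antennal touches cannot be resolved at tracking
resolution, so proximity plus sub-threshold speed is the operational
definition; the defaults (1 cm radius — a 5 mm tube plus antennal reach —
and 0.1 s dwell) are package choices, exposed as arguments.

An *inspection* is a maximal run of frames inside one stimulus ROI
cylinder: ⌀12 cm around the pattern centre, 10 cm out from the wall.
Inspections containing a choice are accepts, the rest rejects. Hover
(inspection) time counts the in-ROI frames up to the landing onset for
accepts and the whole run for rejects: sitting on the feeder is not
hovering, and counting it would make accept times incomparable to reject
times. Scanned regions are classified on the pre-decision frames within
1.5 disc radii: a 3-column × 2-row partition of the disc's bounding square
(left/centre/right thirds; rows split at the horizontal midline; the top
row merged into "top/other"). The event category is `both-corners` when
both lower corners hold at least 10% of frames, otherwise the plurality
lower cell, otherwise `top/other`. The exact grey-region geometry is not
dimensioned anywhere authoritative, so thirds-of-bounding-square is the
package's choice and both the partition and the 10% floor are exposed.
This rule permits events that also visited the lower centre to count as
`both-corners`.

Per-bee test summaries score only choices beginning within a 120 s window
and report the proportion correct (flagged undefined when a bee made no
choice), the first-inspected stimulus, and category-by-decision counts.

## Statistics

*Chi-square.* `chi2_2x2()` implements the Pearson statistic with Yates
continuity correction (default on). The first-choice worked example —
8 of 13 group-1 bees and 5 of 12 group-2 bees first inspecting a plus —
forms the table `[[8,5],[5,7]]` and gives 0.35, p = 0.55 only under the
continuity-corrected group-by-pattern reading; a goodness-of-fit against
50% gives 0.04 and is not what the package computes.

*Wilcoxon tests.* Both the signed-rank and rank-sum tests are reported as
signed z statistics using the normal approximation with midrank tie
correction and a 0.5 continuity correction. Exact-enumeration modes (all
2^n sign assignments; all rank allocations) exist for small samples and
serve as test oracles. A known limitation, measured by the test suite: at
n ≤ 10 the approximation's accept/reject decision at α = 0.05 differs from
the exact test in just under 1% of configurations (normal p ≈ 0.052
against exact p ≈ 0.047 at the boundary); no normal approximation avoids
this, so small-sample decisions near the threshold should use
`exact = TRUE`.

*Learning GLMM.* Correct counts per 10-choice block are modelled as
binomial with logit link, fixed effects colony, group and block index, and
a per-bee random intercept, fitted by Laplace approximation (`lme4::glmer`).
Confidence intervals are Wald; p-values come from the Wald z. The block
index enters uncentred — centring would change only the intercept.
Constant factors (e.g. a single colony) are detected, dropped, and
reported as inestimable rather than fitted. Acceptance is by parameter
recovery (slope recovered to ±0.05 with ≥90% CI coverage over replicate
cohorts; type-I error ≤10% at slope 0), not numerical identity to any
third-party fit.

*Yaw mixtures.* `fit_yaw_mixture()` runs a two-component Gaussian EM on
the linear angle scale with deterministic initialisation at ±median|angle|
plus five seeded random restarts, keeping the best log-likelihood;
components are reported positive-mean first. Angles are treated linearly,
not circularly, because observed yaw stays well within ±180°; fitting
angle data that wraps would need a circular mixture, which this package
does not provide. Component standard deviations are free (not pooled). EM
stops when the relative log-likelihood gain drops below 1e-8 (500
iterations cap); component sds are floored at 1e-3° to prevent collapse,
and the log-likelihood trace is returned so monotonicity is checkable.

## Summaries

Occupancy heatmaps bin stimulus-centred positions (default 5 mm bins over
a ±6 cm window covering the ROI) and normalise to probabilities; pooling
is over all frames by default. Distribution summaries use 0.02 m/s speed
bins, 5 mm distance bins and 5° yaw bins by default and report the median
with a seeded 1000-resample bootstrap SEM, since a standard error of a
median has no convenient closed form. Region-proportion tables compute
each bee's category proportions first and average across bees — the bee,
not the event, is the unit of replication — flagging single-bee cells
whose SEM is undefined.

## The synthetic-data generator

The generator exists so that every stage — tracker, event segmentation,
statistics — can be verified against ground truth. One trial is a
regime-switching flight of at least 120 s at 240 fps: an approach from the
entrance, then cycles of traverse (cruising ~18 cm from the wall, outside
the ROI depth), inspection (waypoint sweeps through the scripted pattern
cells, 1–5 cm from the wall), and accept (steady approach to the feeder,
then a 1 s dwell with ~0.005 m/s jitter) or reject. Per-frame speed is an
AR(1) process (correlation 0.9) around the regime mean; defaults are
0.20 m/s for approach/traverse and 0.11 m/s for inspection, the regime
medians the conditions specify. Body yaw is AR(1) (correlation 0.9) around
a two-component mixture mean — ±27/−33° while inspecting, +51/−55° while
traversing — with the component chosen nearest the smoothed planar flight
direction, so the body axis never opposes the motion; on component
switches the yaw re-draws from the new component, keeping the stationary
distribution centred on the configured means. Scan sequences start in the
lower half of the pattern with probability 0.89, choose the lower-left
over the lower-right corner at 2:1 odds, and continue to the opposite
corner in 25% of corner-first scans; the bee traverses directly towards
the intended first cell, as trained foragers do. Accept probability is 0.9
for rewarded and 0.1 for punished stimuli.

Two generator parameters are calibrations rather than free choices. The
traverse-yaw offset from the flight direction is capped at 60° so that
steep pull-out legs remain resolvable from motion. The mean scan path
(`inspect_path_m = 0.081`) was solved from the measured linear relation
between path length and pre-decision ROI time so that mean inspection time
is 1.5 s at the default inspection speed, accounting for the fixed in-ROI
overheads of the entry descent and the feeder approach; waypoint counts
derive from the mean leg length between uniform points in a cell
(~0.52 × the waypoint-square side).

Ground-truth inspection events are computed by applying the ROI geometry
to the true positions — the same rule the analysis uses, independently
implemented — and each scripted visit's decision, region sequence and
category attach to the geometric run containing its scan frames.

The renderer projects the trajectory orthographically onto each camera
plane (an optional keystone homography emulates oblique mounting), draws
the bee as a single uniform dark 2:1 ellipse of 1.5 cm with a one-pixel
anti-aliased rim, adds the scene (discs and pattern bars for the front
view; wall band and feeder marks for the top view, with a 2 cm
field-of-view margin behind the wall so a landed bee is never clipped at
the image edge) and seeded Gaussian pixel noise (sd 0.02). Frames are
produced lazily by a per-index closure, so long sequences never occupy
memory, and can be written as PNG sequences.

The learning-choice simulator draws each choice as Bernoulli with
logit(p) = intercept + slope·block + group and colony effects + a normal
per-bee intercept, in blocks of 10 choices.

What the generator deliberately does not emulate: wing and leg appearance,
multi-bee scenes, perspective foreshortening of the bee body, antennal
contact, within-scan trajectory shapes beyond smooth waypoint sweeps
(nothing authoritative describes the true scan path along pattern bars),
and non-stationary speeds within a regime. Passing tests therefore
demonstrate that the algorithms are correct under the stated noise and
geometry models — not that real footage with motion blur, shadows or
occlusion will track at the same accuracy.

## Problem sizes and numerical choices

The test suite and the acceptance script choose problem sizes that make
sampling error small relative to the tolerances while keeping runs
desk-scale: tracker fidelity uses ten 500-frame videos rendered at
640×360 (the full geometry at a scale where a 1 px error is ~1–1.7 mm);
event segmentation uses fifty 120-s trials; GLMM recovery uses 50
replicate cohorts of 20 bees × 7 blocks; mixture recovery uses 10,000
draws; Wilcoxon decisions are enumerated exhaustively for n ≤ 10.
Degenerate inputs are errors, not silent results: empty stimulus layouts,
constant speed samples (no 2-means split exists), zero-variance angle
samples, all-tied signed-rank inputs, single-bee GLMM designs. The 2-means
iteration is deterministic, so identical samples always give identical
thresholds; duplication invariance and scale equivariance are property
tests. Homography fits refuse collinear reference points.

## Known limitations

- Yaw is resolvable only up to the 180° ellipse ambiguity; frames where
  the bee translates nearly perpendicular to its body axis are inherently
  ambiguous, and ~2% of moving frames resolve to the wrong side even on
  clean synthetic data.
- The front camera provides no wall distance; its kinematics use a
  configurable nominal distance band (default 3 cm) for that coordinate.
- Linear-scale Gaussian mixtures are inappropriate for angle data that
  wraps; the package targets yaw confined well within ±180°.
- The tracker assumes exactly one animal; a second bee-sized blob is
  rejected only by the nearest-to-previous gate, not by appearance.
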