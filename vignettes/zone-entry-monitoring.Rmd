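---
title: "Monitoring red-zone entries from pose landmarks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring red-zone entries from pose landmarks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonewatch)
```

## The problem

Risk-based contact precautions require healthcare personnel (HCP) to don
gloves and gowns before crossing a perimeter — the *red zone* — around the
bed of a patient carrying a resistant organism. Auditing compliance by
human observation is expensive, so a ceiling camera plus a pose-estimation
model can stand in: the detector reports named body landmarks (nose,
wrists, hips, ankles, ...) in pixel coordinates each frame, and software
decides when a person has *entered* the zone. `zonewatch` implements that
decision layer, detector-agnostically: any source that can emit per-frame
keypoints in the package's JSON-lines schema — a real pose model behind an
adapter, or the built-in simulator — can drive it. It also implements the
evaluation layer: scoring system verdicts against a gold-standard observer
log as a diagnostic test, with sensitivity, specificity and confidence
intervals.

## The entry rule

The zone is a simple polygon drawn in image pixels, canonically by
clicking the four corners of the bed perimeter on the video feed
(`zone_from_corners()`). Physical size (e.g. a 1-foot margin) is the
operator's responsibility when clicking; the engine never converts
physical units to pixels.

A person is *in contact with* the zone in a frame when **any** monitored
landmark lies inside the polygon (`landmarks_in_zone()`). The monitored
set defaults to head (nose, ears), wrists, hips and ankles — the anatomy
that actually breaches a bedside perimeter; eyes, shoulders, elbows and
knees can be added via the `landmarks` argument. Landmarks below the
confidence threshold (`min_confidence`, default 0.5, the common detector
operating point) are ignored; if nothing reaches the threshold the frame
is flagged `insufficient` rather than failing.

Containment itself is even-odd ray casting with an explicit boundary test:
a point within `1e-9` px of an edge or vertex counts as **inside**. The
inclusive rule is a deliberate safety choice — a hand exactly on the
border is an exposure risk, so ties err toward detection. The test suite
checks the ray-casting implementation against an independently written
winding-number oracle on $10^5$ random point/polygon pairs, including
concave polygons.

## Tracking

Counting entries requires knowing that the person now inside is the same
person who was outside a moment ago. `associate()` maintains identities
with globally greedy nearest-centroid matching: all track–detection pairs
within `gate_radius` are sorted by distance and accepted greedily, ties
broken by the upstream detector's provisional id (a hint, never trusted),
then by lower track id, then lower detection index. Unmatched detections
spawn tracks; a track unseen for more than `max_missed_frames` frames is
retired and its id never reused.

Defaults: `gate_radius = 120` px at 640×480 (about one body width) and
`max_missed_frames = 15` (0.5 s at 30 fps), sized so occlusions shorter
than half a second do not split a track. Greedy matching is not in general
the minimum-total-distance assignment — with large per-frame displacements
the two can disagree — but within the gated regime the defaults enforce
(frame-to-frame motion well below track spacing) the two provably
coincide, and the tests assert exactly that. Appearance features, Kalman
prediction and learned re-identification are out of scope; the `associate`
contract is the seam where a stronger tracker could be substituted.

## The entry state machine

Each track carries a three-state machine (`UNKNOWN`, `OUTSIDE`, `INSIDE`)
driven by the per-frame containment flag, with hysteresis:

* `OUTSIDE → INSIDE` after `confirm_in_frames` consecutive contained
  frames — this emits **one** entry event, timestamped at the *first*
  frame of the contained run so debouncing does not delay reported entry
  times;
* `INSIDE → OUTSIDE` after `confirm_out_frames` consecutive clear frames,
  emitting nothing;
* `UNKNOWN` (a freshly spawned track) resolves in either direction by the
  same rules but never emits an event: a person already inside when first
  seen has not been observed entering.

Defaults `confirm_in_frames = 3`, `confirm_out_frames = 15` (0.1 s and
0.5 s at 30 fps) are chosen so a single-frame detector flicker neither
triggers an entry nor re-arms the machine while the person is still at the
bedside. Consequently the per-track event count is bounded by
`total frames / (confirm_in + confirm_out)` — no event storms — and is
monotone non-increasing in `confirm_in_frames`.

### Legacy mode and the double-count failure

Naive implementations of the entry rule double-count: when a partially
occluded person "disappears" mid-zone and reappears, they are treated as a
new individual whose prior state defaults to outside, and a second entry
is logged. `count_entries(..., legacy = TRUE)` reproduces this faithfully:
track memory shrinks to zero (`max_missed_frames = 0`), confirmation
windows collapse to one frame, and — crucially — a new track starts in
state `OUTSIDE` rather than `UNKNOWN`. That initialization is our
modelling choice for the pre-fix behaviour: with `UNKNOWN` initialization
a respawned track could never emit a spurious entry, and the documented
failure mode would be unreproducible. The fix is precisely the combination
of persistent tracking (gaps bridged up to `max_missed_frames`) and the
`UNKNOWN` no-event rule. Duplicate counts inflate the visit denominator
but, because observation-level scoring is binary per window, they do not
move sensitivity or specificity.

## The scene simulator

`simulate_scene()` replaces camera plus detector. Each scripted person is
a rigid 17-keypoint template (fixed offsets from the body centroid,
spanning roughly ±38 px horizontally and −70..+70 px vertically at scale
1) scaled per person by a height factor, typically 0.8–1.2, to emulate
body-size variation. The centre follows piecewise-linear waypoints.
Detector imperfection is modelled as:

* per-keypoint dropout (scalar probability, or a named vector so distal
  landmarks can drop more — used to emulate head-of-bed false negatives);
* Gaussian coordinate jitter (`keypoint_jitter_sd`, px);
* whole-person occlusion intervals during which no detection is emitted —
  the track-splitting failure mode;
* keypoint confidences drawn uniformly from `confidence_range`.

A single RNG is seeded once per scene and the draw order is fixed (frames,
then persons, then dropout → jitter → confidence), so a seed reproduces a
stream byte for byte; the simulator saves and restores the caller's RNG
state. Gold entries are computed from the *noiseless* template positions
with the same any-landmark rule the engine applies, so ground truth is
invariant to the noise model by construction.

`scenario_battery()` fixes six scenes at 30 fps, 8–10 s each (small enough
that the whole battery renders and scores in seconds on one core):
enter-and-leave, walk-past, reach-in (only one wrist breaches the
perimeter, exercising the any-landmark rule), head-of-bed approach with
elevated distal dropout, two persons crossing paths outside the zone, and
an entry with a 0.3 s mid-zone occlusion. The occlusion length is
deliberately shorter than the default track memory (0.5 s), so the default
engine bridges it while legacy mode splits the track and double-counts.
With `noiseless = TRUE` all jitter, dropout and occlusion are stripped;
under those conditions the engine must reproduce gold exactly on every
scenario, and the tests require it.

What the simulator does **not** model: limb articulation and gait,
perspective foreshortening, detector-specific noise spectra, appearance
(skin tone has no analogue in keypoint space and is documented as
unrepresentable here), and realistic ward traffic rates — battery
trajectories are scripted, not sampled from observed HCP behaviour.
Passing the battery therefore demonstrates the *mechanism* (geometry,
tracking, debouncing, scoring) under controlled conditions, not field
accuracy; validating against live observation requires a real deployment.

## Diagnostic accuracy and planning

Evaluation is observation-level: each gold-log row is a time window with
the observer's verdict, and the system verdict is *entered* iff at least
one confirmed entry event falls in the closed window (`[start_s, end_s]`;
boundary events count). Events matching no window are surfaced in a
spillover report rather than dropped. The 2×2 table gives sensitivity
`tp/(tp+fn)` and specificity `tn/(tn+fp)`; a zero denominator raises a
typed error rather than returning 0.

Confidence intervals default to Wald,
$\hat p \pm z_{(1+\gamma)/2}\sqrt{\hat p(1-\hat p)/n}$, clipped to
$[0,1]$ and conventionally reported at two decimals — the arithmetic that
validation studies of this kind print. Wilson (`prop.test`) and
Clopper–Pearson (`binom.test`) are available via `ci_method` and are
statistically preferable near the boundary, where Wald under-covers; the
clipped Wald upper bound of 1.00 at $\hat p = 0.98$, $n = 100$ is a known
artefact of the approximation. Each statistic's interval uses its own
denominator (gold-positive count for sensitivity, gold-negative for
specificity).

For planning, `ci_half_width(p, n)` returns $100\,z\sqrt{p(1-p)/n}$ in
percentage points and `sample_size_for_half_width()` inverts it to the
minimal integer $n$ (e.g. about ±8% at $n = 100$ for proportions near
0.8; exactly 97 observations suffice for ±8% at $p = 0.8$).

`simulate_observation_study()` closes the loop end to end: it injects
per-observation misclassification at chosen true rates and pushes the
result through the same classify → confusion → stats path as pipeline
output. The tests inject error rates (0.02, 0.16) at 2,000 observations
and require the estimates back within three Monte-Carlo standard errors —
a consistency check of the estimator, not a claim about any detector.

## Privacy plumbing

`face_redaction_regions()` computes, per detection, the rectangle an
external blurring step should redact: the padded bounding box of
confident head landmarks, falling back to the upper third of the
full-body box when no head landmark is confident (over-redaction is the
fail-safe; a static room mask is a reasonable alternative we did not
implement). Degenerate boxes are inflated to a 1-pixel minimum. Raw
recordings registered with `register_recording()` carry a sidecar creation
manifest; `purge_expired()` deletes exactly the recordings older than
`retention_hours` (default 48 h) and never touches derived,
non-identifiable artifacts — only files with a sidecar are ever deleted,
and age comes from the sidecar, not filesystem timestamps, which do not
survive copies. Logging above debug level omits landmark coordinates.

## Numerical and format choices

* Boundary tolerance `1e-9` px, absolute: pixel coordinates are O(10³),
  so this is far below any meaningful geometric scale while absorbing
  floating-point residue in the edge-distance computation.
* Polygon validation at construction: ≥3 vertices, no consecutive
  duplicates, a direct collinearity test (a bowtie also has zero signed
  area, so area alone cannot distinguish the two failure modes), and an
  $O(n^2)$ proper-intersection scan over non-adjacent edges.
* Stream serialization uses 17 significant digits, the minimum that makes
  IEEE-754 doubles round-trip exactly; the read–write identity is
  property-tested on simulated streams.
* Timestamps default to `frame_index / frame_rate` when a stream omits
  them; frame indices must be strictly increasing and violations are
  reported with line numbers.
* Tie-breaks everywhere are deterministic (documented sort orders), so a
  fixed seed yields byte-identical streams, event logs and manifests.

## Known limitations

Greedy association can swap identities when two people pass within the
gate radius of each other; a swap outside the zone is harmless for entry
counting, but a swap exactly at the boundary could mis-attribute an
entry's track id (not its count). The rigid body template cannot express
reaching postures — a real reach-in moves only the arm, while the
simulated one translates the whole template. The entry rule is 2-D:
landmarks above the zone (e.g. leaning over the bed from outside a
wall-adjacent perimeter) project into the polygon and count as contact,
which matches the safety-first intent but is a geometric approximation.
Exit analytics, dwell time and glove/gown classification are out of
scope.
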