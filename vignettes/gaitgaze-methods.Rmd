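---
title: "Gaze analysis during real and virtual locomotion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze analysis during real and virtual locomotion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitgaze)
```

## The problem

Mobile eye tracking during locomotion asks where people look while they
walk — along corridors, up and down stairs — and whether gaze behavior in a
virtual copy of a building matches behavior in the real building. The
pipeline in this package covers the full analysis chain for such a
within-subject two-world comparison: binocular-derived gaze streams from two
devices (a VR headset add-on tracker sampling nominally at 120 Hz with a
100° × 110° tracking window, and wearable glasses sampling at 60 Hz with a
60° × 46° window), segmented by terrain type ("sector": corridor, ascending
stairs, descending stairs), summarized by robust statistics, and compared
with within-subject inference.

Gaze is expressed in head-centered degrees with x positive rightward and y
positive **downward** (tracker screen convention). Every function that
depends on this convention (direction histograms, T-shape ratio,
eye-in-world referencing, head pitch) documents the sign handling
explicitly; direction histograms report 0° = rightward and 90° = **upward**
movement, so the vertical displacement sign is flipped at binning time.

## Preprocessing

**Validity.** A sample is invalid when the pupil-size proxy is zero (lid
closure, pupil outside the camera view) or gaze is non-finite. Invalid
samples keep their row — durations, audits, and valid-fraction statistics
need them — and all analysis functions skip them.

**Calibration.** Raw tracker readings are mapped onto the known positions of
a 3 × 3 marker grid with a per-channel bivariate polynomial fitted by least
squares. The default order is 2 (6 coefficients per channel, identifiable
from 9 points); the order is a configuration knob because the original
tracking software does not expose its choice. Any map inside the model class
is reproduced to machine precision, which the tests exploit with affine and
quadratic constructions.

**Drift.** Head-mounted trackers slip; re-presenting the calibration grid at
session end gives per-point offsets (measured − true) whose componentwise
mean and mean Euclidean magnitude summarize the session drift. Crucially,
drift adds a common offset to all gaze samples, so every *relative* measure
(IQR, T-shape, direction and velocity histograms, saccade counts, AOI
distances when the marker track shares the shift) is invariant to it — an
invariance the test suite asserts to 1e-10 over random offsets.

**Exclusion windows.** Disturbance periods are flagged, not deleted, and all
sector slicing removes flagged samples. Intervals are half-open
`[t_start, t_end)` so that adjacent intervals partition time exactly; the
concatenation of all labeled, unclassified, and excluded samples recovers
every sample exactly once.

## Descriptive statistics

**Median/IQR.** Per-cell position is summarized by componentwise median and
IQR (linear-interpolation sample quantiles, type 7 — the paper-style
analysis does not pin a quantile rule, so the package states its choice).
Samples outside the tracking window stay in: their side is reliable even if
their position is not, and order statistics tolerate them as long as less
than half the data (a quarter for the IQR) fall outside on one side.
Directional out-of-range fractions are reported and the median is flagged
unreliable past 50%.

**T-shape ratio.** Natural locomotor gaze often shows a horizontally wide
band above a narrow vertical trunk. The segment is split at the vertical
median; the ratio of the upper half's horizontal IQR to the lower half's
quantifies the "T". Ties at the median are dropped so both halves are
well-defined.

**Direction histogram.** Displacements between consecutive valid samples are
binned into eight 45° wedges centered on the cardinal and oblique axes,
left-closed at the lower boundary, normalized to unit integral per
individual before any cohort averaging. The cardinal/oblique ratio is the
mass ratio of the two wedge families.

**Velocities.** Speed is the Euclidean displacement between *neighboring
valid* samples divided by their time difference — never interpolated across
blinks. Histograms use 11 octave bins (< 1, 1–2, …, 256–512, > 512 °/s),
left-closed so a boundary speed joins the upper bin.

**Heatmaps.** 1° bins spanning ±50°, with out-of-range mass accumulated in
the outermost bins so the pre-smoothing mass equals the valid sample count
exactly. Smoothing uses a Gaussian with FWHM 1 bin (σ = 1/2.3548 bins);
normalization divides all of a participant's maps (per world) by their
global maximum bin, preserving relative density across sectors; log display
adds 5% of the scale as a regularizer. Whether the original normalization
was per participant-and-world or per participant across worlds is not
recoverable from the text; the package defaults to per participant-and-world
via `normalize_heatmaps()` applied to one world's maps.

## Saccade detection

The detector follows the velocity-threshold family: per-axis velocities from
a centered moving-window differentiation kernel (window 5; the generalized
least-squares slope reduces to the classic two-sided kernel), a robust noise
scale per axis σ² = median(v²) − median(v)², an elliptic criterion
(vx/λσx)² + (vy/λσy)² > 1, minimum duration 6 ms, merge gap 20 ms. λ
defaults to 6 but is a per-recording setting, mirroring per-participant
hand-tuning in field practice. σ is estimated per segment because noise
differs by terrain and device; if the median estimator collapses on a short
segment the plain SD substitutes before the function refuses. Invalid gaps
restart detection — events are truncated, never bridged across blinks.
Saccade rate divides the event count by the *valid* segment duration (sum of
inter-sample intervals with both endpoints valid), so blink time never
deflates rates.

## World-referenced measures

**Horizon tracking.** Scene-video horizon positions come from a hybrid
scheme: a manual mark every nine frames anchors a normalized
cross-correlation tracker that assigns displacements to the four preceding
and four following frames (patch 32 px, search ±12 px by default — the
originals are unstated, so both are configuration). Keyframes pass through
their marks exactly; a correlation peak at the search edge flags low
confidence; sub-pixel refinement by parabolic interpolation is skipped on
perfect matches so noise-free fixtures are recovered exactly.

**Eye-in-world.** Vertical gaze minus horizon position (both positive-down)
gives gaze relative to the world; headset-placement offsets move both terms
together and cancel, which is the entire point of the referencing. Gaze is
aligned to the nearest frame (gaze rate ≥ frame rate on both devices), and
the analysis is restricted to the corridor designated as horizon-visible.

**Head orientation.** Headset pitch and roll are referenced to the
participant's corridor mean (the zero point depends on placement), then
summarized per sector by mean and IQR. Yaw is excluded: route turns
contaminate it differently per sector.

## AOI dwell

Navigational markers arrive as per-frame quadrilateral corners with a
detector confidence; observations at confidence ≤ 0.9 are discarded. The
gaze-to-marker distance is the Euclidean distance to the *filled*
quadrilateral (zero inside — which also resolves the distance-to-outline
ambiguity, since interior points score zero under either reading), and a
sample dwells on the marker when that distance is ≤ 1°. Because the VR
window is much larger than the RW window, VR frames are harmonized: a frame
survives only if the gaze point and the whole trapezoid lie within the RW
extents (half-extents 30° and 23°, centered straight ahead — extents are
stated by the devices, centering is the only symmetric placement). The dwell
fraction divides on-marker sample time by total analyzed valid time.
`fit_trapezoid()` recovers corners from rendered masks via the maximum-area
quadrilateral inscribed in the convex hull of foreground pixel centers,
which is exact for axis-aligned rectangles and within about a pixel for
perspective-skewed markers.

## Inference

Every group-level claim uses within-subject tests: paired t-tests (df =
n − 1) and a 2 × 3 repeated-measures ANOVA (world × sector) in which each
effect is tested against its own subject-by-effect interaction term.
Sphericity is assessed per effect by Mauchly's test on the covariance of
orthonormal contrast scores; the Greenhouse–Geisser ε comes from the
eigenvalues of that covariance, bounded by 1/(k−1) and 1, and equals 1
exactly for 2-level effects. Following the reporting rule of the original
analysis, the reported p-value uses GG-scaled degrees of freedom only when
Mauchly's p < 0.05, while uncorrected degrees of freedom are always printed
(`F(2,14) = …, p = …, ε_GG = …`); both corrected and uncorrected p-values
are stored. No multiple-testing correction is applied across metric
families, matching the reporting style being reproduced; readers should
weigh the many tests accordingly. The implementation is validated against an
independent projection-matrix decomposition to 1e-8, against `car::Anova`,
and by a null simulation holding the nominal type-I level.

## The synthetic-data generator

No raw recordings are deposited for this kind of study, so the generator is
the package's ground-truth instrument. Its defaults are the study
conditions: 8 participants × 2 worlds; a route of 6 corridors, 4 ascending
and 2 descending stair segments with connecting unclassified areas filling
the reported session totals (400 s VR, 333 s RW); device rates, tracking
windows and valid fractions (99.5% VR, 85.5% RW); per-cell median gaze from
the reported sector medians; per-cell saccade-rate targets; T-shape spread
ratios; corridor-referenced head pitch (+0.55° ascending, +14.6° descending)
and roll; drift magnitudes drawn per participant from gamma distributions
with the reported mean and SD per world; and dwell-fraction targets (3.5%
VR, 1.8% RW).

The gaze process alternates gamma-duration fixations with raised-cosine
saccades to targets drawn around the cell center. Design choices worth
knowing:

* **Raised-cosine saccade profile.** Any smooth symmetric profile whose peak
  velocity (2·amplitude/duration) exceeds the detector threshold mid-flight
  suffices; the raised cosine is analytic and integrates in closed form.
  Durations follow a simple main-sequence rule (20 ms + 2.5 ms/°).
* **Saccade amplitudes are emergent.** Targets are drawn i.i.d. from the
  cell's spatial distribution, so amplitude follows from the spatial scatter
  rather than a separate dial — keeping spreads and medians exactly
  controllable, which is what the recovery tests need.
* **T-shape construction.** Horizontal target scatter is multiplied by
  √ratio above the vertical center and divided below, so the expected
  upper/lower IQR ratio tracks the parameter (ratio 1 ⇒ expected T-shape 1;
  monotone in the parameter). Transit samples and within-fixation wander
  dilute the realized ratio by a few percent of its excess over 1.
* **Within-fixation wander with cardinal bias.** Fixational scatter is a
  small-step random walk whose step directions are snapped to a cardinal
  axis with probability `cardinal_bias` (uniform otherwise). Wander steps
  carry ~95% of all sample-to-sample movements, so they control the
  direction histogram; saccade directions follow target geometry untouched,
  preserving the engineered spatial distributions.
* **Sector transitions.** Fixations truncate when the effective cell
  changes, so gaze redirects to the new terrain's distribution on entry;
  connecting areas share the corridor cell and are seamless. Without this,
  carry-over across boundaries biases short-sector medians.
* **Blinks.** Poisson onsets with gamma durations; the rate is
  −log(valid_frac)/mean_duration, which makes the *expected unoccupied
  fraction* equal the target valid fraction exactly (an M/G/∞ identity).
  Blinks zero the pupil and void gaze, the preprocessing trigger.
* **Drift.** The reported endpoint drift is modeled linearly (the simplest
  monotone model consistent with a single endpoint measurement). Because the
  cell centers are calibrated to *measured* gaze statistics — which already
  embed placement and drift offsets — cohorts apply the drawn drift to the
  end-of-session validation grids but not additionally to the stream
  (`drift_in_stream = FALSE` by default); doubling it up would double-count
  the offset. Stream drift remains available for invariance testing.
* **AOI tracks.** On-marker episodes are laid out to cover exactly the
  target fraction of each corridor (equal-length glances at random
  non-overlapping positions), the marker is anchored at gaze during
  episodes and placed a safe distance away otherwise — clear of *every*
  gaze sample attributable to the frame, since a saccade can sweep several
  degrees within one frame interval. Confidence values carry a 5%
  sub-threshold tail to exercise the 0.9 filter.
* **Horizon traces.** Placed so gaze sits a configured distance below the
  horizon (2.2° VR, 4.2° RW) relative to the participant's corridor median,
  plus AR(1) bobbing noise — sharing the placement offset with gaze, which
  is exactly what eye-in-world referencing must cancel.
* **Reproducibility.** One master seed; per-session seeds are derived from
  it, so cohorts are reproducible session-by-session.

What the generator does **not** emulate: optic-flow and VOR-driven slow
gaze, pursuit, vergence, photorealistic scene statistics, and
head-translation kinematics. Velocity distributions are therefore more
peaked at low speeds than field recordings, and passing recovery tests shows
estimator correctness under the modeled structure, not robustness to every
property of real data. Distributional forms (gamma fixation durations,
Gaussian target scatter) are conventions chosen for controllability; the
source analysis states none.

## Numerical choices and degenerate inputs

Half-open intervals make partitions exact; ties at the vertical median are
excluded from the T-shape halves; direction and velocity bins are
left-closed so boundary values are deterministic; zero-displacement pairs
are excluded from direction binning; Δt ≤ 0 is a validation error; constant
segments make the saccade threshold degenerate and raise an error rather
than returning noise; a zero lower-half IQR flags the T-shape as undefined
(NaN) with a warning; zero oblique mass flags the cardinal/oblique ratio as
infinite; heatmap smoothing truncates mass only at the grid border; the
Mauchly statistic is skipped (NA) when the contrast covariance is singular
or n − 1 ≤ p, while ε is still reported.

## Problem sizes used in the shipped checks

The validation suite runs a full-length synthetic cohort (8 participants,
both worlds, study-length sessions) for the recovery checks; 240-second
single-sector sessions across seeds for saccade-rate recovery; 10⁵-sample
constructions for the analytic T-shape and direction-histogram
calibrations; 100 random datasets against the ANOVA oracle plus 2,000 null
replicates for the type-I check; 54-frame stacks for the horizon tracker;
1,000 random point/quadrilateral pairs against the geometry oracle; and 200
scaled-down cohorts (10% duration) for the end-to-end inference
calibration. These sizes were chosen so the whole suite completes in a few
minutes on one CPU while keeping Monte-Carlo standard errors well inside the
asserted tolerances.

## Known limitations

* λ hand-tuning per participant cannot be reproduced; the default of 6 is a
  standard choice and the parameter is exposed per recording.
* Sector boundaries are taken as input; deriving them from position
  tracking is out of scope.
* The heatmap normalization scope and the calibration polynomial order are
  interpretations of underspecified text, both exposed as configuration.
* The RW chair detector and the VR re-renderer are replaced by the AOI
  track input contract; only their output format is modeled.
* Eye-in-world referencing assumes a visible, distant horizon; the package
  restricts it to the designated corridor rather than attempting automatic
  horizon detection.
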