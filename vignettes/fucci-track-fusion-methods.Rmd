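---
title: "Methods: two-channel FUCCI track fusion and tissue kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-channel FUCCI track fusion and tissue kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fuccitrackr)
```

# The problem

FUCCI reporters make the cell cycle visible in live imaging: a
cdt1-coupled red fluorophore accumulates through G0/G1, a geminin-coupled
green fluorophore through S/G2/M, and both are present — the nucleus looks
yellow — around the G1→S transition. In a dense, collectively migrating
monolayer each nucleus therefore appears as *two* partial tracks, one per
fluorescence channel, which coexist only during the co-expression window.
Continuous single-cell cell-cycle analysis requires deciding, among
hundreds to thousands of tracks per field, which red track and which green
track belong to the same cell, and then placing the G1→S transition
without a per-analyst intensity threshold.

This vignette documents the models, parameters and numerical choices
behind each stage, and what the bundled synthetic movies can and cannot
establish.

# Track fusion

## Candidate pre-filter

All red × green pairs is a quadratic search. The field of view (FOV) is
divided into `grid_n × grid_n` equal squares (default 10) and a pair is a
candidate iff some square was visited by both tracks at any time during
their trajectories. Squares are half-open, `[x0, x1) × [y0, y1)`, with the
far FOV edges closed, so every in-FOV point maps to exactly one square.
The pre-filter is conservative by construction in the regime where it
matters: two tracks whose average center distance is below the acceptance
threshold (2 px) are three orders of magnitude closer than a grid square
(~205 px at 2048 px FOV) and co-occupy a square in practice. The test
suite verifies, on randomized instances, that matchings with and without
the pre-filter are identical.

## The similarity metric

For a candidate pair, `s_ij` is the average Euclidean distance between the
two nucleus centers over their *temporally overlapping* frames. Averaging
over the overlap only — rather than over either track's full life — is a
deliberate reading: the two tracks cover different cell-cycle stages and
only coexist around G1/S, so a full-lifespan average would be undefined.
Frames bridged by gap closing are linearly interpolated before the
distance is evaluated, so a closed gap counts as an observation.
`min_overlap_frames` (default 2) refuses to score one-frame coincidences.

## Matching

Pairs with `s_ij` strictly below `similarity_threshold` (default 2 px,
appropriate for 10× imaging and meant to be scaled with magnification)
survive; the boundary value is rejected. Among survivors a one-to-one
matching is built greedily in ascending `s_ij`, with ties broken by lower
red id then lower green id, so the result is deterministic. In the
non-degenerate geometry this is the regime for — nuclei far apart relative
to the threshold — the greedy matching coincides with the minimum-total-cost
matching, which the tests confirm by enumeration on small instances. A
true cell pair sits at sub-pixel distance; competing candidates are other
nuclei at tens of pixels, so conflicts are rare and benign.

## Fusion and the G1→S criterion

A fused track's phase is RED on frames where only the red track has an
observation, YELLOW where both do, GREEN where only the green one does.
The fused position on YELLOW frames is the mean of the two centroids
(channel-symmetric and continuous); morphology is carried per channel.
Unmatched tracks are retained as single-phase cells rather than dropped,
so tissue-level counts see every detected nucleus; their `g1s_frame` is
undefined.

The G1→S transition is derived from the co-expression window itself,
which is what makes it user-independent: `window_start` (first YELLOW
frame), `window_end` (last), or `window_mid` — `floor((first + last)/2)`,
the default, a point estimate suitable for event-time analyses. A
one-frame window yields the same answer under all three criteria.

# Tracking

Per-channel tracks are built by linear-assignment (LAP) linking:
frame-to-frame minimum-total-cost one-to-one assignment on centroid
distance, with links beyond `max_link_distance_px` (default 15) forbidden.
The assignment is solved exactly (Hungarian method) in the standard
augmented form in which every detection can opt out at the gate cost, so a
link is made only when it beats leaving both ends unmatched. Costs carry
no intensity term: in FUCCI data, intensity is cell-cycle state, not
identity.

Gap closing is a second, global LAP between stub ends and stub starts,
feasible when `start_frame − end_frame − 1` missing frames are at most
`max_gap_frames` (default 2) and the jump is within `max_gap_distance_px`
(default 15). Chains cannot cycle because connections only run forward in
time. Tracks with fewer than `min_track_length` detections (default 3) are
discarded. Track ids are deterministic (start frame, then y, then x of the
first detection). The defaults mirror an MDCK-like regime imaged at 10×
every 10 minutes, where frame-to-frame displacements are a few pixels.

Division is deliberately *not* handled by track splitting: at mitosis the
green reporter disappears, the green track simply ends, and daughters
start new colorless→red records. Lineage reconstruction is out of scope.

# Segmentation baseline

The built-in segmenter is a classical pipeline: Gaussian smooth
(`smoothing_sigma_px`, default 2), global threshold (Otsu by default, or
fixed counts), hole filling, optional splitting of touching nuclei by
seeded watershed on the distance transform (seeds are distance-map local
maxima separated by at least `watershed_min_distance_px`), and an area
filter (`min_area_px2`, default 9). It exists so the package is
self-contained and desk-scale; production users of deep-learning
segmenters can inject their label masks via `load_external_masks()`, which
validates shape and passes labels through verbatim.

Conventions, used everywhere: 0-based pixel coordinates, `x` = column,
`y` = row, pixel centers at integers; frames 0-based; a constant frame
under Otsu yields an empty mask rather than an error; contours are the
closed polygon through a label's boundary pixel centers, and the perimeter
is that polygon's length (tests rely on areas and centroids, which are
convention-free).

# Tissue-level analysis

## Voronoi areas

Cell footprints in a confluent sheet are approximated by the Voronoi
region of each nucleus center (both channels pooled per frame), clipped to
the FOV rectangle. Clipped areas tile the FOV exactly, which the tests
assert to a relative 1e-9 per frame. Regions touching the FOV boundary are
flagged and excluded from downstream statistics by default — their clipped
areas are biased low. The approximation is only meaningful in dense,
confluent conditions; in sparse cultures Voronoi regions measure empty
space, not cells. Centers closer than 1e-9 px raise an error naming the
frame rather than silently merging seeds.

## Velocity field

Each track contributes a tangential velocity by forward differences of its
(gap-interpolated) positions; the last frame carries the previous vector.
The Eulerian field samples space at 181 points on a triangular lattice:
"full" rows of 10 points with in-row spacing FOV/10 interleaved with
offset rows of 9 points shifted by FOV/20, rows FOV/20 apart, the whole
lattice centered in the FOV (10² + 9² = 181). The row spacing and the
point count pin this construction down; a strictly equilateral lattice
with FOV/20 sides cannot produce 181 points in a square field, so the
stated spacings take precedence and "equilateral" is treated as nominal.
At each sample point the velocities of all nuclei inside the square bin of
side FOV/10 centered there are averaged. Bins are wider than the point
spacing, so neighbouring samples overlap: that is intended smoothing, not
a bug. Empty bins are flagged undefined, never zero-filled. Units are
px/frame unless `px_per_um`/`min_per_frame` are set, in which case the
exported vectors are µm/min.

## Phase counts and area by phase

Per frame, cells are counted by phase label; fractions divide by the
number of cells present, so they sum to 1 whenever any cell is visible.
Area-by-phase joins Voronoi areas to phase labels on `(cell_id, frame)`
and reports mean ± 1.96·sd/√n per frame and phase (normal approximation —
the "95% CI" is not otherwise specified, and n is typically hundreds in
the intended regime); groups with n < 2 get an undefined interval rather
than a zero-width one.

# The synthetic movie generator

The simulator exists so every downstream stage can be tested against
known ground truth without external data. It emulates:

* **Motion**: persistent random walk (heading diffusion scaled by
  `1 − persistence`) plus uniform drift plus soft pairwise repulsion
  (overlap within `repulsion_radius` relaxed at rate 0.25 per frame),
  reflected at the FOV walls. Initial seeding enforces the repulsion
  radius as a hard minimum spacing and keeps nucleus centers at least
  `repulsion_radius/2` from the walls — a nucleus cannot be centered on
  the dish edge.
* **Cell-cycle clocks**: per-cell COLORLESS→RED→YELLOW→GREEN durations
  drawn once from a normal (CV `phase_duration_cv`, truncated at 1 frame,
  rounded); on GREEN expiry the cell divides into two COLORLESS daughters
  offset ±`repulsion_radius/2` along a random axis (or holds GREEN when
  division is disabled). Initial cells start at a uniformly random point
  of their own cycle, which yields a stationary phase mix from frame 0.
* **Reporters**: piecewise-linear profiles evaluated at frame midpoints —
  red rises 0→peak across RED, decays to 0 across YELLOW while green
  rises 0→peak, and green holds at peak through GREEN. The midpoint
  evaluation keeps both reporters strictly positive on every YELLOW
  frame. These kinetics are a stand-in: the true cdt1/geminin dynamics
  are not quantitatively calibrated here, and simulated intensities must
  not be read as MDCK biology.
* **Camera**: isotropic Gaussian spots (sd `nucleus_sigma_px`, default
  3 px) on a uniform background with additive Gaussian read noise,
  clipped at zero, written as 16-bit TIFF.

Defaults (512 px FOV, 150 cells, 10 min/frame, durations 25/8/25/3 frames
for red/yellow/green/colorless, CV 0.15, motility 1 px/frame) sketch a
confluent MDCK-like monolayer at 10×. One global RNG stream is seeded from
`rng_seed`, with rendering noise on a separately derived stream, so equal
configs are byte-identical.

Not modelled: photobleaching, focus drift, nucleus shape and its
anisotropy, apoptosis, out-of-focus light, intensity heterogeneity within
a nucleus, and segmentation-relevant artifacts of real microscopy.
Passing tests on simulated movies therefore demonstrate the correctness of
the algorithms under their stated assumptions — not segmentation accuracy
on real FUCCI microscopy, which depends on exactly the artifacts the
simulator omits and is the reason the mask-import path exists.

# Problem sizes and numerical conventions in the test suite

The suite validates the matcher against brute-force enumeration on random
instances of up to 50 + 50 tracks, and the full
segmentation→tracking→fusion chain on a noise-free simulated movie of 200
cells over 60 frames in a 640 px FOV with safe spacing (minimum
inter-nucleus distance well above 4× the spot sd), where it requires 100%
pairing recovery, zero false merges, and YELLOW windows and `window_mid`
G1→S frames within ±1 frame of ground truth. Voronoi conservation is
checked to a relative 1e-9; velocity-field consistency under uniform drift
to 1e-9 px/frame; determinism at the byte level on every exported table.
Detection on ramping reporters has a one-frame resolution limit: a newborn
red reporter's first-frame amplitude (2% of peak at the default 25-frame
RED duration) sits below any reasonable threshold, which is why ±1 frame
is the honest tolerance for window edges.

# Known limitations

* The pre-filter is heuristic; in the (unobserved) corner case of a true
  pair straddling one grid line for its entire overlap it could be
  missed. Setting `grid_n = 1` disables it at quadratic cost.
* Greedy matching is not globally optimal for adversarial degenerate
  geometries; it is exact in the sub-threshold-separation regime the
  method targets.
* The LAP tracker has no motion model; very fast or strongly accelerating
  nuclei favour a Kalman-style linker, which is out of scope.
* Voronoi areas are only meaningful at confluence; border regions are
  excluded from statistics by default.
* Lineage (mother–daughter) relations are recorded by the simulator but
  not reconstructed by the tracker.
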