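---
title: "Depth-guided segmentation and tracking of mushroom beds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-guided segmentation and tracking of mushroom beds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capseg)
```

## The model

`capseg` treats a mushroom bed as a height field. A registered RGB-D frame
gives, at every pixel, a color intensity and a distance from a downward-facing
camera. White button mushrooms are near-spherical domes rising from a roughly
planar compost surface, which motivates three geometric commitments:

* **a cap apex is a local elevation maximum** — after the compost plane is
  flattened and depth is flipped into elevation, apices are peaks;
* **a cap rim is a ring of steep outward descent** — walking outward from the
  apex, elevation falls gently over the dome and sharply at the rim;
* **a contact line between cojoined caps is a valley** — outward elevation
  falls, then rises again where the neighboring dome begins.

Everything downstream (markers, radial boundary tracing, watershed ridges,
IoU tracking) operationalizes these three statements. The approach is
deliberately appearance-light: color enters only through Otsu foreground
extraction and stitching; all shape decisions come from depth.

Assumptions worth stating explicitly: the camera looks straight down (depth
differences are height differences); the bed background is approximately
planar; caps are convex and dome-shaped (the convex-hull mask step and the
spherical test geometry both lean on this); and the scene is static within a
frame and nearly static between consecutive frames (no motion model is used
in tracking — mushrooms do not move, they only grow or get picked).

## Stage by stage

### Stitching

Rail acquisition yields vertically overlapping frames. The bottom
`template_height_px` (default 100 px) rows of frame *i*, in grayscale
(luma weights 0.299/0.587/0.114), are slid over every vertical placement in
frame *i + 1* at horizontal lag 0 — the rig translates on a one-dimensional
rail, so the search is one-dimensional by construction. The score is the
normalized cross-correlation (Pearson correlation of the mean-centered
template and window), the best placement is `y_offset`, and the overlap
ratio is `(template_height + y_offset) / frame_height`. Only rows past the
overlap are appended (hard cut, no blending), and the same offset is applied
to depth so the two mosaics stay pixel-aligned. A score floor
(`stitch_score_floor`, default 0.5) turns silent misregistration into an
explicit error naming the frame pair; a constant (zero-variance) template or
window scores `-Inf` rather than dividing by zero.

### Preprocessing

Otsu's threshold maximizes between-class variance over a 256-bin histogram of
the grayscale color image; the side with the higher mean is foreground (caps
are light on dark compost — the rule is computed, not assumed, so inverted
palettes still work). All background depth pixels are reassigned their mean,
giving an exactly flat plane (post-homogenization background variance is
zero, an invariant the tests assert). Missing depth is carried as an explicit
mask from file reading (a configurable sentinel, default 0): missing
background is filled by the background mean, missing foreground by an
iterated 3×3 median of valid *foreground* neighbors — the flattened
background would otherwise bleed into cap edges. Elevation is
`background_level − depth`, min-max scaled to [0, 1] per mosaic (per-mosaic
rather than per-bed normalization keeps the module frame-local; nothing
downstream compares absolute elevations across mosaics). A constant input
normalizes to all zeros by convention and is treated as "no scene".

### Markers

A Gaussian-weighted `marker_window` × `marker_window` (5×5) sum at stride 3
emphasizes compact peaks. The Gaussian σ for the window weights is not a
published constant; 1.1 px — the conventional default tied to a 5-px kernel —
was fixed once. The response is smoothed with a bilateral filter (diameter 9,
spatial σ 5 grid cells, range σ 0.1 normalized units; the filter is written
in-package since no installed R package provides one), binarized above the
`response_quantile` (0.80) of the response map, and segmented into
8-connected components. Each component contributes a single marker: the
*full-resolution* elevation argmax inside the component's footprint — the
stride-3 grid is too coarse for apex localization, so the grid only proposes
regions. Markers within `proximity_px` (18 px) of a stronger marker are
removed, processing in descending elevation (keep-strongest is the standard
resolution when a suppression rule names no keeper).

The quantile threshold is scale-free after normalization but is a *global*
statistic: in a sparse scene it sits near the compost level and cojoined
caps merge into one component, whereas in a dense bed it sits mid-dome and
valleys fall below it, splitting contacts. This matters for how test scenes
are built (below).

### Radial boundary estimation

Around each marker a `patch_size` × `patch_size` (23×23) elevation patch is
extracted (reflect-padded at image borders) and min-max normalized within the
patch. Square (Chebyshev) rings `B(r)`, `r = 1..max_ring` (11), expand around
the center; `patch_size = 2·max_ring + 1` is a validated config invariant.
The ring-level profile compares each pixel on `B(r)` with its 8-connected
neighbors on `B(r+1)`: the pixelwise gradient is the clamped mean drop
`max{0, mean(D(p) − D(q))}` and `G(r)` averages over the ring. Clamping
suppresses the negative (rising) transitions caused by adjacent caps — which
is exactly why the *unclamped* signed profile is kept alongside: the
inflection that marks a cojoined boundary is a sign change, and a
non-negative quantity cannot change sign. Ring `max_ring` is the patch
border, so ring-to-ring comparisons exist for `r = 1..max_ring−1` (ten
comparisons with the defaults).

Per-direction boundary points are obtained by scanning `n_rays` (72, 5°
steps) directions; the sample at radius *r* is the bilinear interpolation of
the patch at the real-valued polar point. Two numerical choices deserve
justification:

* **The directional gradient at ring *r* is the drop *into* *r***,
  `g(r) = d(r−1) − d(r)`. A sharp cap of radius *R* then peaks at ring *R*
  (the first ring past the rim), so the traced contour sits on the cap's
  true extent. Attributing the drop to the inner ring instead would bias
  every mask one ring small — at `R = 8` that alone costs ~23% of the area.
* **Ties break toward the smaller radius.** When two rings drop equally, the
  conservative reading (smaller cap) avoids leaking into a neighbor.

Each ray's search is capped at its overlap limit: the first radius where the
signed profile rises after falling (a rise without any prior fall returns
limit 1 — an inverted profile means the marker is in a pit, not on a cap).
An upward step must exceed 1e-9 to count, so exactly-flat compost does not
trigger inflections through floating-point jitter. The strongest in-limit
drop is the primary candidate and the second strongest the backup; rays with
no positive drop contribute nothing, and a fully flat (degenerate) patch
yields an empty point set — a flat patch cannot be a cap, so the instance is
discarded and logged rather than guessed at.

### Refinement and masks

Pass 2 (local consistency): each point's radius is compared with the mean of
its `neighbor_count` (10) angular neighbors, half on each side with
wrap-around at 0/2π; deviation beyond `local_dev_px` (10 px) rejects the
point unless its backup passes the same check, in which case the backup is
substituted. All local means are computed from the original radii so the
outcome does not depend on processing order. Pass 3 (global adjustment):
centroid of survivors, then mean and SD of point-to-centroid distances;
points beyond `global_sd_mult` (2.5) SDs are dropped. A spread below 1e-9 is
treated as exactly zero so that a perfect circle is not decimated by
floating-point noise. The passes always run 2-then-3; fewer than three
survivors at any stage is a degenerate contour error. The surviving points'
convex hull is filled (half-open pixel-center test against the hull edges)
and intersected with the Otsu foreground, so compost that the hull spans is
excluded.

### Overlap resolution

Raw hulls may overlap where caps touch. A coverage count (number of masks
claiming each pixel) separates settled pixels (count 1, owner never changes —
an invariant under test) from contested ones (count ≥ 2). Each involved
instance seeds from its exclusively-owned region eroded with a 3×3 box,
`seed_erode_iters` (2) times, falling back to its single highest-elevation
exclusive pixel if erosion empties it; an instance with no exclusive pixels
gets no seed and cedes the contested area. Seeded growth runs over a ridge
map — Gaussian smoothing (σ 1 px) then Sobel gradient magnitude of the
elevation — restricted to the contested region, assigning every contested
pixel to exactly one instance (`EBImage::propagate`, the CellProfiler-style
marker-controlled primitive, performs the growth). Cleanup removes
8-connected specks below `speck_min_px` (15 px) and fills holes per
instance, claiming hole pixels only from background so the one-owner
guarantee survives cleanup. Seed labeling processes ids in ascending order,
making the whole stage deterministic.

### Tracking

Between consecutive frames, instances are matched by maximizing total mask
IoU under a one-to-one assignment (maximum-weight bipartite matching, the
Hungarian optimum; an infinitesimal preference for older ids makes ties
deterministic). Matches below `track_iou_tau` (0.1) are rejected. Matched
instances inherit their global id; unmatched current instances mint fresh
ids from a monotone counter (ids are never reused); unmatched tracks go
inactive and are terminated once missed for more than `max_missed` frames.
The grace-window length is not a published constant; 3 frames is the
default, config-exposed. Inactive tracks within the window remain eligible
for re-matching using their last observed mask frozen in place
(`rematch_inactive`, default on) — mushrooms are stationary, so a
reappearing cap is where it was; the switch exists because eligibility of
inactive tracks is a genuinely open design point.

### Evaluation

Detection: optimal IoU assignment between predicted and ground-truth
instances, true positives at IoU ≥ `detect_iou` (0.7). Marker-level
detection: a ground-truth instance counts once if any marker falls inside it
(same-instance markers merge; background markers cluster within
`eval_merge_px`, default equal to `proximity_px`, and count one FP per
cluster). Segmentation: pixel counts pooled over matched instance pairs
(micro-averaged), unmatched predictions contributing FP and unmatched truth
FN. Tracking consistency: the percentage of ground-truth tracks carrying one
unchanged predicted id across every frame they appear in — an interruption
counts as a failure even if the id resumes. Zero-denominator precision or
recall reports 0 with an `undefined` flag rather than NaN.

## The synthetic generator

`scene_spec()`/`render_frame()` build beds of spherical caps,
`h(d) = h_max √(1 − (d/R)²)`, on a plane at configurable depth with Gaussian
depth noise, a two-tone color palette with speckle, per-frame multiplicative
radius growth, and harvest frames after which a cap is absent. The spherical
profile (rather than a Gaussian bump) matches the near-spherical caps of the
target crop and produces the sharp rim-edge the gradient analysis is built
around; where caps overlap the higher surface owns the pixel, ties go to the
earlier cap, and rim pixels belong to their disc. Seeding is derived from
the spec seed and frame index (kept below 2³¹), the global RNG stream is
saved and restored, and identical spec + seed is bit-identical — an asserted
invariant. `render_overlapping_strips()` cuts vertically shifted windows
from one rendered bed so stitching can be checked against a known
composition.

What the generator does *not* emulate: real compost texture (its background
is white noise, not structured clumps), specular highlights and shading,
stems and tilted caps, depth-sensor artifacts such as edge dropout or
quantization, and cap flattening at maturity. Passing the synthetic suite
therefore demonstrates the geometric machinery — peak finding, rim
localization, valley splitting, id maintenance — under controlled noise; it
does not certify performance on production imagery, where weak elevation
contrast and occlusion are the dominant failure modes.

### Test-scene geometry

Two scene choices are themselves part of the experimental design:

* **Multi-cap recovery beds** use caps of radius 8–11 px with apex heights
  6–8 depth units and depth noise σ 0.1 — the radius range the default
  23×23/ring-11 patch is sized for, at roughly the working resolution the
  default pixel thresholds (18 px proximity, 10 px deviation) presume.
* **The cojoined-pair scene** uses radius 12 px with apices 1.6R = 19.2 px
  apart on a compact 48×48 region. Both numbers are forced by the method's
  own constants: apices closer than the 18-px proximity radius are merged by
  design (so a resolvable pair must satisfy 1.6R > 18, i.e. R ≥ 12), and the
  quantile threshold only splits a cojoined component when the pair
  dominates the elevation histogram, as it would in a dense bed. The compact
  region emulates that density with two caps.

Unit tests run on beds between 48×48 and 180×50 pixels; the acceptance
script uses the same scenes plus one 779×60 bed for the rail-geometry
stitching pair (two 720-row strips, 100-px template, 59-row step). These
sizes exercise every code path while keeping a full suite run in well under
a minute.

## Known limitations

* Cojoined caps whose apices sit within the 18-px suppression radius yield a
  single marker and a merged instance; no downstream stage can split an
  instance that was never seeded twice.
* Caps larger than `max_ring` saturate at ring 11; raise
  `patch_size`/`max_ring` together for coarser resolutions.
* The response-quantile binarization is global; scenes much sparser than a
  production bed push the threshold toward the compost level and can merge
  neighboring components.
* The watershed split follows the ridge map; a shallow valley between caps
  of similar height can still produce an off-center split, and no corrective
  rule is applied afterwards.
* Per-marker radial scanning is O(markers × rays × rings) in interpreted R;
  dense beds of several hundred caps are minutes-per-mosaic, not real-time.
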