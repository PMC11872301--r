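---
title: "Measuring alveolar crestal height from bitewing landmark detections"
author: "achr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring alveolar crestal height from bitewing landmark detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(achr)
```

## The measurement problem

Radiographic assessment of periodontal bone loss rests on one distance per
tooth surface: the alveolar crestal height (ACH), from the cemento-enamel
junction (CEJ) to the alveolar bone crestal level (ABCL). On a bitewing
radiograph both dental arches are visible at once, so a pipeline that
automates ACH must (a) decide which detections belong to which arch,
(b) decide which detections belong to which tooth side, and (c) convert a
pixel distance into millimeters. `achr` implements this post-processing
deterministically, downstream of any landmark/segmentation detectors, and
classifies each site as severe (ACH at or above 5 mm by default) or not.

The pipeline assumes landscape bitewing geometry: the two arches are
separated predominantly in the vertical (y) direction, teeth are roughly
upright, and the bone crest runs roughly horizontally across each arch.
Under these assumptions a single straight line can separate the arches and
a low-degree polynomial per arch can follow the crest and the CEJ contour.

## Pipeline stages and their parameters

**Landmark fusion.** Two detector channels compensate for each other's
regional misses, so their outputs are pooled. Deduplication is greedy
non-maximum suppression within each landmark class, ordered by descending
confidence, with dedup radius `fusion_radius_px = 30` px — half the 60 px
boxes with which ABCL/CEJ points are conventionally annotated, so two
detections of the same anatomical point fall within one radius while
neighboring sites (a tooth width apart) do not. Ties are broken toward the
first channel, then lower x, then lower y, making the output reproducible
bit for bit. Selecting one member rather than averaging duplicate points
keeps the operation idempotent and its oracle (exhaustive suppression)
exact; with detector jitter of a few pixels the difference is well below
the measurement noise.

**Arch partition.** The separator is the ordinary least-squares line
through *all* ABCL-mask foreground pixels. Because the crest pixels form
two roughly horizontal bands (one per arch), their joint OLS line runs
between the bands. Regression of y on x (not orthogonal regression) is the
right choice for landscape frames, where x-spread dominates. Landmarks
exactly on the line go to the upper arch — an arbitrary but fixed
tie-break. Teeth are assigned to the arch that contains the majority of
their pixels relative to the line (ties to upper).

**Arch curves.** Per arch and per class, a least-squares polynomial
`y(x)` of `curve_degree = 2` (default) is fitted to the landmark points.
Degree 2 follows the mild occlusal curve without the oscillation higher
degrees invite on 4–8 support points. When an arch offers fewer distinct
x values than `degree + 1`, the degree is reduced to `distinct x − 1` with
a warning instead of failing: a sparse arch still yields a usable curve.
Fewer than two distinct x values is a degenerate-geometry error, which the
top-level pipeline converts into "skip this arch, log it".

**Tooth extraction and the crossing gate.** The two teeth masks are
unioned pixel-wise, then 8-connected components with at least
`min_tooth_area_px = 200` pixels become tooth instances (anything smaller
is segmentation debris at bitewing scales). A tooth is measured only if
its outline crosses both of its arch's curves — teeth cut off at the frame
edge, or spurious components away from the dentition, fail this gate. The
crossing test combines a tolerance band (`crossing_tolerance_px = 1` px
around the curve, evaluated at outline pixels) with a per-column
sign-change test (curve strictly between the tooth's y-extremes), so a
constant curve grazing a flat outline is handled deterministically.

**Site pairing and measurement.** Each tooth has two measurable sides,
labelled `left` and `right` in the image frame; true mesial/distal naming
would require tooth numbering, which is out of scope. The side windows are
columns within `fusion_radius_px` of `x_min` (respectively `x_max`).
Within a window, the CEJ and the ABCL candidate nearest to the tooth's
outline (restricted to that window) are selected. "Nearest to the flank"
rather than "nearest to a fixed anchor" makes the choice exact in the
noiseless limit and robust to spurious detections that land in the window
but far from the tooth. ACH is the *Euclidean* distance between the paired
points — the radiologist's ruler distance between two anatomical points —
not the vertical drop and not arc length along a curve; for near-vertical
flanks the difference is negligible, and Euclidean needs no extra
convention when a flank tilts.

**Calibration and severity.** `mm_per_px` is a required input with no
default: pixel spacing is a property of the sensor and acquisition, and a
silently guessed value would corrupt every millimeter in the output. The
severity rule is configurable because both conventions circulate: `ge`
(severe iff ACH ≥ 5 mm, the default) and `gt` (severe iff ACH > 5 mm).
They disagree only when a measurement hits the threshold exactly, which
has probability zero under continuous noise but matters for curated
boundary cases.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds a two-arch bitewing scene with exact ground
truth: rounded-rectangle teeth (default 140 × 300 px, four per arch) on a
mild parabolic occlusal curve (amplitude 20 px) in an 869 × 1200 frame —
the working resolution of the pipeline — with the lower arch offset by
half a tooth gap so the arches interdigitate as real bitewings do. On each
tooth flank the CEJ sits 60 px from the occlusal edge and the ABCL is
displaced apically by the site's bone loss, so true ACH equals the drawn
loss exactly (no rasterization error in the truth). Per-site bone loss is
drawn from a 50/50 mixture of Uniform(2, 4.5) and Uniform(5.5, 8) mm at
the phantom's 0.1 mm/px calibration: severity is unambiguous at the 5 mm
threshold unless a boundary case is requested explicitly via
`bone_loss_mm`. The crest band in the ABCL mask is 3 px thick and follows
the per-tooth crest line.

The oracle detector (`oracle_detect()`) turns this truth into two
independent noisy channels: per-landmark dropout, per-axis Gaussian
jitter, Poisson-distributed uniform false positives, and optional teeth
mask erosion. The channels use independent sub-seeds — the worst case for
fusion, which then has genuine deduplication work. True landmarks carry
confidence 1 so the zero-noise limit reproduces the truth bit for bit.

What the phantom does *not* emulate: anatomical crown shapes, contacting
or overlapping interproximal surfaces, radiographic physics (scatter, beam
hardening, exposure variation), calculus or restorations that confuse real
detectors, and anatomically structured (rather than uniform) false
positives. Passing the phantom suites therefore validates the *geometry
and bookkeeping* of the pipeline under a known noise model — it does not
certify detector-level accuracy on clinical images.

## Evaluation statistics

`evaluate_classification()` reports exact-arithmetic pooled accuracy,
per-image accuracy, severe-class sensitivity and specificity; the pooled
accuracy is by construction the site-weighted mean of the per-image
accuracies. Display rounding is half-up to integer percent; full precision
is retained in the returned object.

For repeated continuous readings, `intraclass_correlation()` implements
McGraw & Wong's ICC(A,1): two-way model, absolute agreement, single
measurement, from the mean-squares decomposition of the n × 2 table

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
  {MS_R + (k-1)\,MS_E + \tfrac{k}{n}\,(MS_C - MS_E)}, \qquad k = 2.$$

Absolute agreement is the appropriate form for intra-rater reliability of
a measurement: a constant shift between occasions is disagreement, and
the consistency form would hide it. The estimate is 1 for identical
non-constant vectors and can be negative (below −1 in adversarial tables)
when disagreement exceeds chance; constant tables are a degeneracy error.

## Validation problem sizes

The shipped suites exercise: fusion against exhaustive suppression on
random instances of up to 12 points; curve fits against a hand-rolled
normal-equations solve (n ≤ 50, degree ≤ 4, relative tolerance 1e-8); the
crossing gate against an exhaustive outline-pixel scan; noiseless
end-to-end recovery on 20 phantoms (16 sites each), where the maximum ACH
error must stay within one pixel (0.1 mm) and severity agreement must be
total; noisy recovery (2 px jitter, 10 % dropout, 2 false positives per
image) on 100 phantoms, where mean absolute error must stay within 3 px
(0.3 mm) and severity accuracy at least 95 % on sites more than 0.5 mm
from the threshold; and a test-retest ICC over 10 phantoms read twice
under independent noise. These sizes give stable statistics (≈ 1600 noisy
sites) while keeping a full run around a minute on one CPU core.

## Known limitations

* One ACH per tooth side, keyed by instance order — no FDI/universal tooth
  numbering, so measurements from different images of the same mouth
  cannot be matched anatomically.
* The arch partition is a single straight line; pathological frames where
  the arches interleave vertically (severe tilt) would need a curved
  separator.
* Side windows inherit the fusion radius; crowded dentitions with tooth
  gaps below ~2 radii could pair a neighbor's landmark, though the
  nearest-to-flank rule makes this unlikely.
* The severity call inherits every upstream error source; near the 5 mm
  boundary a 2 px landmark jitter at 0.1 mm/px flips ~0.3 mm of margin, so
  boundary sites are intrinsically unstable for any pipeline with this
  noise level.
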