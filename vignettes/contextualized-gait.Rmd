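---
title: "Contextualizing free-living gait with egocentric video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextualizing free-living gait with egocentric video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egogait)
```

## The problem

Wearable inertial sensors quantify *how* a person walks, but not *where*:
free-living gait variability can reflect an impaired walker on an easy
surface or a healthy adaptation to a cluttered one. For people with
Parkinson's disease, whose fall risk depends on both intrinsic gait
impairment and extrinsic hazards, this ambiguity matters clinically.
`egogait` implements a pipeline that fuses two wearable streams:

1. **Egocentric video with eye tracking** — per-frame object detections are
   tested for overlap with a geometric model of the wearer's immediate
   walking path, and with the wearer's gaze point; privacy-sensitive
   detections are blurred so raw footage never needs viewing.
2. **Lower-back (L5) accelerometry** — walking bouts are segmented, initial
   and final contact events detected, and step/stance/swing time mean,
   variability and asymmetry computed per bout.

The fused output is a per-bout *contextualized gait report*: temporal gait
characteristics alongside the fraction of frames with an in-path hazard,
gaze-on-path behaviour, and unattended-hazard windows. The package
deliberately emits ingredients, not a fall-risk score: the mapping from
context plus gait to risk remains a clinical judgement.

## Object taxonomy

The built-in taxonomy (`loadTaxonomy()`) has 18 classes in 4 categories.
Each class carries one or more *roles*: `context` (explains gait
fluctuations: stairs, doorways, furniture, signage, vehicles), `fall_risk`
(chairs, animals, wet surfaces, mats/rugs, generic obstacles, raised kerbs)
and `privacy` (persons, screens, text documents). Roles drive downstream
behaviour: hazard flags consider only `fall_risk` classes; the anonymizer
blurs only `privacy` classes. `Person` carries both `context` and `privacy`
— the overlap logic treats people as navigable obstacles while the privacy
filter blurs them. Class-name matching is case-insensitive after trimming,
because annotation files vary in casing; names are stored canonically.

A design question we had to settle: classes listed as both context and fall
risk (chair, animal, wet surface) could in principle have their hazard flag
suppressed in "context-only" situations. No rule for that exists, so both
roles are always active; a chair in the path is always a flagged hazard.

## Walking-path model and overlap detection

The immediate walking path is an isosceles trapezoid in scene-camera
coordinates. Its base sits on the bottom frame row and spans the middle 50%
of the frame width — a wide, logical area directly in front of the wearer.
The top edge is narrower, representing the converging forward perspective.
Two parameters are not pinned down by any measurement and are package
defaults, chosen to match the qualitative shape of such overlays and
exposed as configuration: `topWidthFraction = 0.15` and
`topYFraction = 0.55` (top edge at 55% of frame height). Whether the
trapezoid should stop short of the frame bottom is equally open; we fix the
base on the last row.

Overlap detection is mask-based: each bounding box, the gaze point (a
filled circle, default radius 30 px — the true gaze-marker size is a
configuration choice, not a measurement) and the path trapezoid are
rasterized to binary masks and intersected. Full-resolution masks are
wasteful, so masks are downscaled to 200 x 200 cells. Two implementation
decisions matter:

* **Direct rasterization.** Masks are built at 200 x 200 directly by
  coordinate scaling rather than building full-size masks and resizing.
  The contract is identical; the cost is two orders of magnitude lower.
* **Outward rounding.** A cell is set when its pixel footprint *intersects*
  the shape (floor on minima, ceil on maxima). Masks are therefore
  supersets of their shapes, and a true object-path or object-gaze overlap
  can never be missed; the only possible errors are false-positive
  verdicts for near-misses thinner than about one cell (about 5 px at
  1080p). In a fall-risk context a missed hazard is the costly error, so
  the bias is deliberately conservative. With the mask resolution set to
  the frame resolution the verdicts equal per-pixel geometry exactly.

Missing or invalid gaze samples yield `gazed = FALSE` rather than an error:
eye trackers drop samples routinely, and a frame without gaze still has
valid path context.

`attentionOnHazards()` aggregates frame verdicts into fixed windows and
reports, per window, the fraction of hazard-present frames whose in-path
hazard was gazed. A window with hazards present and attention fraction zero
is an *unattended hazard window* — a computable proxy for the clinically
interesting event of a wearer not looking at an upcoming hazard. This
aggregation rule is a convention of this package, not a validated measure.

## Selective anonymization

Every privacy-role detection's region of interest is replaced by its
Gaussian-blurred version; all other pixels are bit-identical to the input.
The kernel is 157 x 157 by default with the standard automatic sigma
`0.3 * ((k - 1) * 0.5 - 1) + 0.8` (about 23.9 px at k = 157), strong enough
to obliterate faces and text at typical scene-camera resolutions. The blur
is computed on the ROI crop in isolation with reflect-101 borders, so no
pixel information crosses the ROI boundary in either direction. Overlapping
ROIs are blurred sequentially in detection order — the intersection is
blurred either way, order only changes its exact values. Confidence
thresholds are ignored on purpose: any privacy detection blurs, erring
toward over-obscuring. Images are handled as 8-bit RGB arrays via PNG
sequences, and audio is never ingested anywhere in the package.

## Gait analysis

**Bout segmentation.** The moving standard deviation of the acceleration
magnitude (0.5 s window) is compared with an activity threshold of 0.05 g;
active runs separated by gaps shorter than 0.3 s are merged and runs
shorter than 3 s discarded. These four defaults are a desk-scale stand-in
for validated free-living activity segmentation, and all are configurable.

**Event detection.** Following the established approach for an L5-mounted
sensor, the mean-detrended vertical acceleration is integrated and then
differentiated with a derivative-of-Gaussian (continuous wavelet) filter;
initial contacts are the local minima of that signal, and final contacts
the local maxima after a second wavelet differentiation. The smoothing
scale defaults to one sixteenth of the step period, with the step period
estimated from the periodogram peak in 1.4-3 Hz. Candidate extrema pass a
prominence test (40% of the peak-to-mean range) and a minimum separation of
0.45 step periods; event times are refined to sub-sample precision by
parabolic interpolation. Alternation is then enforced: each FC must sit
strictly between two consecutive ICs, keeping the strongest response per
gap. A known property of this detector family is a small constant early
bias in FC timing of the order of the smoothing width (tens of
milliseconds); it cancels in step and stride statistics and in all
asymmetry measures, but absolute stance/swing means inherit it.

**Temporal statistics.** With ICs `t_1 < t_2 < ...`, step time is
`t_(k+1) - t_k`, stride time `t_(k+2) - t_k`, stance time runs from `t_k`
to the FC following `t_(k+1)` (the same foot's toe-off, roughly 62% of the
stride later), and swing is stride minus stance — an identity that holds
exactly by construction. A single lower-back sensor cannot label left and
right feet, so *asymmetry* is defined as the absolute difference between
the means of alternating (even- vs odd-indexed) series elements, a standard
proxy. The consistency `mean step = mean stride / 2` for symmetric gait is
part of the test suite. Neither an asymmetry formula nor a sample rate is
imposed by the data source; both are documented defaults (100 Hz for the
generator). Per-bout and pooled reporting are both supported, since
free-living reports may summarize single bouts or aggregates.

## Synthetic data as ground truth

Real egocentric video of patients cannot be shared, so every module is
exercised against generators whose ground truth is computed independently
of the code under test.

*Scenes* (`generateSceneSequence()`): frames carry class-labelled solid
rectangles on a seeded value-noise background (a constant background would
make blurring a no-op and hide locality bugs). With probability `p` per
frame a fall-risk box is planted solidly inside the path trapezoid (with a
margin of several mask cells); otherwise any hazard box is placed with a
clearance of several cells, so the frame-level hazard truth is an exact
Bernoulli draw. Overlap truth is computed from continuous geometry — the
trapezoid's monotone width profile and point-rectangle distances — never
from the mask engine it tests. The gaze trajectory is a smooth random walk
pulled toward the lower frame centre.

*Gait* (`generateGaitSignal()`): the vertical channel is a locomotor
oscillation whose trough coincides with each planted IC, plus a sharp
negative Gaussian pulse (50 ms full width at half maximum) at each IC and a
positive pulse at each FC, plus white noise; this width keeps the wavelet
detector's extrema aligned with the planted times within sampling
tolerance without tuning the generator to the detector's internals. Step
times alternate `mean ± offset/2`, making the true asymmetry `|offset|` by
construction; FCs sit at `IC_k + 0.62 * stride_k`. Defaults (step mean
0.55 s, STD 0.01 s, 100 Hz) sit at the values typical of an unimpaired
lab walk. What the generator does *not* emulate: turning, stops and starts
within a bout, sensor tilt drift, double-support spectral content, or the
gait of a severely impaired walker — so passing tests demonstrate correct
algorithmic behaviour, not clinical validity on patient data.

Problem sizes used by the automated checks were chosen to exercise the
operating conditions at desk scale: 1000 random frames at 1088 x 1080 for
the overlap-oracle comparison, 100 frames for privacy locality, six
120-second signals (step means 0.45/0.55/0.70 s, offsets 0/0.05 s) for gait
recovery, and a 100-frame / 60-s scenario for the end-to-end smoke run.

## Evaluation utilities

The detection-evaluation module implements IoU on half-open pixel boxes and
mAP50 with greedy per-class matching (descending confidence, ties broken by
input order for determinism; one match per truth box; IoU at least 0.5).
AP uses all-point interpolation — the convention of modern detector
toolkits — with an 11-point mode behind a flag, since "mAP50" alone does
not fix the interpolation. The mean is taken over classes with at least one
ground-truth instance; classes absent from the validation truth cannot
contribute an AP and are excluded rather than zero-filled. Training or
fine-tuning an object detector is out of scope: the replay backend serves
stored annotations as confidence-1.0 detections so the full pipeline runs
without any model weights.

## Degenerate inputs and numerical choices

* Boxes are 0-based, half-open pixel intervals everywhere; converters from
  centre/size (YOLO) or 1-based corner (VOC) formats land on this
  convention, making areas and intersections integer-exact.
* Boxes clipped to nothing, frames with no detections, and bouts with too
  few events all produce empty-but-valid results; errors are reserved for
  contract violations (inverted boxes, unknown classes, even kernels,
  non-uniform sampling).
* A constant accelerometer segment yields zero gait events, not an error;
  a bout shorter than three expected steps is an error because statistics
  would be meaningless.
* Confidence ties in evaluation matching are broken by input order,
  documented, so results are reproducible to the byte.
* JSON reports round-trip losslessly; all CSV/JSON outputs are
  byte-identical under a fixed seed and configuration.

## Limitations

The walking path is a fixed 2-D overlay: no depth, ground-plane or
ego-motion estimation, and no object tracking across frames. Gaze is a
point sample with a nominal radius, not a fixation model. The privacy
filter blurs rectangles, which over-obscures relative to pixel-accurate
segmentation and carries no formal irreversibility guarantee beyond the
blur itself. Gait analysis covers temporal characteristics only — no step
length, velocity, turning metrics, freezing-of-gait detection or clinical
scale mapping. Real-time throughput is explicitly not a goal.
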