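---
title: "Motion-based semi-supervised animal tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-based semi-supervised animal tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentrack)
```

`pentrack` tracks `K` animals in low-frame-rate top-view grayscale video
with minimal human supervision. This vignette explains the underlying
model, the parameters that matter, the numerical conventions, and what the
synthetic benchmark does and does not demonstrate.

## Motion model

The pixel signal is `p(x, y, t)` in `[0, 255]`, with 0-based coordinates,
`x` along image width, `y` along height, origin top-left. Motion over an
inclusive window `[t_b, t_l]` is the mean absolute deviation from the
window mean:

$$m_{t_b,t_l}(x,y) \;=\; \frac{\sum_{t=t_b}^{t_l} \lvert p(x,y,t) - \bar p(x,y)\rvert}{t_l - t_b}.$$

Two conventions deserve a note. First, a *signed* deviation sum would be
identically zero by definition of the mean, so the model uses the absolute
deviation; a squared-deviation alternative (`deviation = "squared"`, the
sample variance since the denominator is the window length minus one) is
available for heavier penalization of large intensity jumps. Second, the
denominator is `t_l − t_b` (window length − 1), not the frame count; with
the squared option this makes `m` exactly the unbiased sample variance.

The score map at frame `t0` sums motion over flanking windows
`k = 1..k_max` (default `k_max = 2`, i.e. two frames before and after, or
±1/3 s at 6 fps):

$$s_{t_0} = \sum_{k=1}^{k_\max}\big( m_{t_{0}-k,\,t_0} + m_{t_0,\,t_0+k} \big).$$

Windows extending past the clip ends are clamped to `[0, T−1]` and
dropped when they collapse to a single frame, so the first and last
frames are still scorable from one side. The flanking design means an
animal present at `t0` contributes from both its arrival and departure,
concentrating score mass on its body at `t0` rather than along its whole
path.

**Assumptions.** The camera is static; illumination is constant at the
window time-scale; animals are the dominant moving objects; an animal
that does not move at all over `±k_max` frames produces no motion
evidence (motion detection proposes *start points*, it is not the
tracker).

## POI extraction

Scores are strongly right-skewed: almost all pixels are static
background. The binarization threshold is therefore the per-frame 99th
quantile of all `H·W` scores (linear interpolation between order
statistics, `stats::quantile` type 7), and a pixel becomes a POI iff its
score is *strictly greater* than the threshold. This caps POI at ~1% of
the frame plus ties; for a degenerate all-equal map nothing is selected.

Noise rejection convolves the 0/1 POI map with a normalized Gaussian
kernel (default 5 × 5, σ = 1 px) and re-thresholds at 0.5. The response
at an isolated single POI pixel equals the kernel's centre weight
(≈ 0.162 < 0.5), so isolated flickers vanish, while pixels with full
kernel support inside a compact blob keep response 1. The exact kernels
are configuration choices: the Gaussian half-width/σ and the edge kernel
(default 3 × 3 Laplacian-style: centre −4, edge neighbours 1, corners 0)
can be overridden. The edge kernel is applied to the *refined* map —
applying it before refinement would resurrect the noise just removed —
and a contour pixel must both respond to the edge kernel and be a refined
POI, so filled interiors drop out. All convolutions use reflect padding,
which avoids manufacturing spurious edges at the frame border.

## Identity proposal

Contour pixels are clustered into the user-declared `K` identities by
agglomerative clustering with Ward linkage on Euclidean pixel
coordinates, constrained to merge only clusters adjacent in a symmetric
k-nearest-neighbour connectivity graph (default 5 neighbours per pixel).
The constraint encodes spatial coherence — a cluster cannot jump across
the pen — which is the role a similarity matrix plays in constrained
agglomerative clustering; if the graph fragments into more components
than `K`, the closest pair of clusters is merged unconstrained.
Connected components smaller than `min_cluster_pixels` (default 5) are
discarded first as residual noise. Labels `0..K−1` are assigned by
ascending centroid x (ties by y), making identities deterministic.

Note that the cluster count is `K` by construction, so a single moving
blob asked for `K = 3` yields three sub-clusters rather than an error;
only an insufficient number of POI pixels raises "insufficient POI",
which signals the caller to provide manual start positions.

## Tracking

Trackers implement a two-function contract (`init`, `step`) so
third-party algorithms can attach via `register_tracker()`. Two
self-contained trackers ship with the package:

* **`template_ncc`** — captures the bounding-box crop at initialization
  and, each frame, places it at every integer offset within
  `search_radius` of the previous centre, scoring placements by
  normalized cross-correlation. Confidence is the best correlation
  (clamped to `[0, 1]`); ties prefer the smallest displacement so static
  scenes do not drift. The template is fixed by default
  (`template_alpha = 0`): drift-free and fully deterministic, at the
  cost of slowly failing under appearance change; an exponential update
  is available.
* **`sparse_flow`** — seeds up to 25 high-gradient points on a grid in
  the box and advances each by iterative local least-squares optical
  flow (7 × 7 window, up to 10 Gauss–Newton iterations, bilinear
  sampling). The centre moves by the median point displacement — robust
  to a minority of failed points — and confidence is the fraction of
  points whose flow converged.

Key defaults: `box` 31 × 31 px (covers roughly half an adult pig body at
the half-scale fixture geometry; boxes should cover texture-rich body
area), `search_radius = max(box)` so an animal moving less than one box
per frame stays in the window at 6 fps, `confidence_floor = 0.5`. A state
whose confidence drops below the floor is flagged *lost* and frozen — it
never silently re-acquires, because a re-acquisition after the animal has
left the search window is usually a lock onto the wrong target. A
`SupervisionEvent` (frame, animal, corrected centre) re-initializes the
tracker on that frame; supervised rows are marked in the output and
`count_supervisions()` reports the human labour a clip required. Centres
are clamped to the frame and boxes clipped at walls, since animals lean
against pen edges.

Interactive front-ends typically colour-code per-frame tracking error;
here the `confidence` column carries that information (1 − confidence is
the displayed error proxy).

## Evaluation and analytics

The standardized error of a prediction against ground truth is the
Euclidean distance divided by the frame diagonal `sqrt(W² + H²)` —
dimensionless, in `[0, 1]` for in-frame points, comparable across
resolutions. Centimeter conversion uses a single configured scalar,
262.9 cm per standardized unit (26.29 cm per 0.1), valid for the
reference geometry (848 × 480 camera 2.25 m above the pen); it is a
calibration constant, not estimated from images.

Distance series are centroid-to-centroid. Movement per frame is the
displacement between consecutive tracked centres; accumulated movement is
its running sum (total path length). Movement synchrony is the sample
Pearson correlation of two movement series with the two-sided t-transform
p-value. Frames where either tracker is lost are excluded pairwise
(complete-case) from distances and correlations — frozen centres would
otherwise fabricate zero movement. The activity heat map is the per-pixel
intensity variance across all frames, min–max scaled to `[0, 1]` (an
all-constant map scales to zeros); the mean-absolute-deviation variant is
selectable for consistency with the motion model.

## The synthetic benchmark

`pen_scene()` renders textured ellipses (body texture rigidly attached,
so template tracking is meaningful) over a static textured background,
with reflecting walls, optional transient single-pixel flickers, and
exact ground-truth centres. Rendering is deterministic given the seed,
and each agent draws from its own fixed-offset substream so adding an
agent leaves the others' paths unchanged. The standard presets use 300
frames at 424 × 240 (half the reference camera scale, which keeps the
full test suite under a minute of rendering) and 6 fps: calm presets walk
at ≤ 3 px/frame; `two_blob_fast` walks at ~8–10 px/frame and includes one
scripted 60 px dash that exceeds the default search radius, guaranteeing
a tracker loss for the supervision-recovery scenario; `noisy_two_blob`
injects 12 single-pixel ±90-level flickers near the pen walls, away from
the agents' roaming box. Texture amplitudes are bounded (smoothed uniform
noise, worst case ±2 × amplitude) so that body pixels always contrast
with the background by more than 25 levels.

What the fixtures do **not** emulate: occlusion and body contact between
animals, appearance change (posture, rotation, motion blur), illumination
drift, shadows, and camera noise correlated in space. Passing the
synthetic suite therefore demonstrates the correctness of the motion
model, POI pipeline, clustering, tracker mechanics, supervision
bookkeeping and analytics — not field-grade robustness on farm video,
where identity swaps during close contact remain the dominant failure
mode and more supervisions should be expected.

## Numerical conventions

* Quantiles: type 7 (linear interpolation); binarization strictly `>`.
* Convolution: reflect padding (half-sample symmetric).
* Gaussian kernels normalized to sum 1 within 1e−12; edge kernels must
  sum to 0 (checked to 1e−9).
* NCC degenerate windows (zero variance in template or window) score 0,
  so a tracker on a featureless region reports no confidence rather than
  a spurious match; exact NCC ties resolve to the smallest displacement.
* Ward clustering uses the Lance–Williams update on squared Euclidean
  distances; clustering is exactly reproducible (no randomness).
* All randomness in simulation flows from the scene seed through fixed
  per-purpose offsets; the package never touches the global RNG state
  without restoring it.
* Trajectory CSVs round-trip all numeric fields to at least 6 decimals
  (readr writes full precision).

## Known limitations

* No identity re-association after tracker swaps (template learning is a
  natural extension but out of scope).
* `template_ncc` searches integer offsets only; sub-pixel accuracy comes
  from supervision or the flow tracker.
* The sparse flow tracker has no image pyramid, so it degrades beyond
  ~5 px/frame displacements; at 6 fps this is the regime where human
  supervision is expected anyway.
* The centimeter calibration is a single scalar; pens imaged at other
  heights need their own constant.
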