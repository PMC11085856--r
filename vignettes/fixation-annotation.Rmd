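---
title: "Annotating fixations by fusing segmentation and detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating fixations by fusing segmentation and detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazefuse)
```

## The problem

Head-worn eye trackers produce two synchronized streams: a forward-facing
scene video and a gaze signal in the video's normalized coordinates. For most
research questions the unit of analysis is not the raw gaze sample but the
*fixation* — a period in which gaze rests on one object — together with the
identity of that object. Labeling fixations by hand is so slow (hours of
annotation per minute of video) that the semantic side of mobile eye-tracking
data is often discarded. `gazefuse` automates the labeling step: it detects
fixations, maps each one onto a video frame, asks two complementary
perception models what is under the fixation point, and fuses their answers
into a single label per fixation.

The two models play different roles. A *semantic segmentation* assigns every
pixel exactly one class, so its masks partition the frame: a fixation always
lands inside exactly one mask, and mask boundaries are pixel-precise — ideal
near object edges. But segmentation vocabularies trained on street scenes
lack everyday objects, and they cannot separate instances. An *object
detector* localizes individual objects as labeled boxes with confidences,
covers a broader everyday vocabulary, but its boxes overlap freely when
objects are close together or at different depths, so "which box is the
fixated one?" is genuinely ambiguous. Late fusion keeps both outputs and
resolves them per fixation.

## Fixation detection (IDT)

Fixations are detected with the dispersion-threshold algorithm. The
dispersion of a sample window is

$$D = (\max_i x_i - \min_i x_i) + (\max_i y_i - \min_i y_i),$$

in normalized units. The sweep initializes a window spanning the minimum
duration; if $D$ is at or below the dispersion threshold, the window grows
sample-by-sample while it stays below, emits a fixation (centroid = mean of
member coordinates), and resumes after the window; otherwise it slides
forward one sample. Emitted fixations are disjoint and ordered, each
satisfies both thresholds by construction, and loosening either threshold can
only increase the fixation count.

Parameters (`idt_config()`):

* `dispersion_threshold` — default 0.02 *degrees*. Degree thresholds are
  converted to normalized units by dividing by the horizontal field of view
  (`fov_deg`), the same factor on both axes. A caution: 0.02° is far below
  the 0.5–1° range typical of IDT settings; it reproduces a published
  mobile-eye-tracking configuration and likely reflects that exporter's
  internal scaling. The package keeps the value faithfully and documents the
  anomaly rather than silently "fixing" it; for the synthetic studies in
  this package we pass explicit normalized thresholds (0.05) instead.
* `duration_threshold` — 0.100 s. A 90 ms dwell is *not* a fixation under
  this setting, and the tests plant one to prove it is rejected.

Each fixation is reduced to one representative point and frame: the centroid,
and the frame at the temporal midpoint (`assign_frame()`). The midpoint
avoids the motion blur typical at fixation onset. One frame per fixation is
processed, not one per sample.

## The fusion step

For a fixation at pixel $(p_x, p_y)$ (normalized coordinates floored onto the
pixel grid, origin top-left):

1. **Mask.** `mask_at_point()` extracts the binary mask $M$ containing the
   point. By default this is the 4-connected component of the point's class
   (`component_mode = "component"`); `"class"` uses all pixels of the class.
   The component default exists because with class-level masks, unrelated
   same-class regions elsewhere in the frame would contribute to the
   coverage of boxes far from the fixated object. The choice is recorded in
   the output metadata.
2. **Coverage.** For each detected box $(x_1,y_1,x_2,y_2)$, the mask
   coverage is
   $$C = \frac{\sum_{(i,j) \in R} M_{i,j}}{(x_2-x_1)(y_2-y_1)},$$
   where $R$ is the restriction of $M$ to the box. Numerator and denominator
   are integer counts; only the final division is floating point, so $C$ is
   exact.
3. **Candidates and selection.** Candidate boxes are those containing the
   fixation pixel (edge-inclusive: $x_1 \le p_x \le x_2 - 1$) with $C > 0$
   (at least one mask pixel). The candidate with the largest $C$ wins; ties
   break by higher confidence, then smaller area, then lowest $(x_1, y_1)$.
   The tie chain ends lexicographically so that selection is fully
   deterministic. This is what disambiguates nested boxes: a tight box that
   matches a small fixated object has $C \approx 1$, while a large box
   around a nearer occluding object has small $C$.
4. **Resolution.** `resolve_label()` combines the mask label (always
   present) and the selected box label (possibly absent) with a four-branch
   cascade, first match wins: (1) no box → mask label; (2) labels agree
   after merging → keep (the raw mask-side label is returned, segmentation
   being the boundary-precise source); (3) exactly one merged label is on
   the user's priority list → that side; if both are listed, the earlier
   entry wins; (4) otherwise the box label wins only if its confidence *and*
   coverage reach their floors (`conf_floor`, `cov_floor`, both default
   0.5), else the mask label. The branch taken is recorded per row for
   auditability. The floors are deliberate design choices where the
   underlying procedure only says to "consider" confidence and coverage;
   they are exposed in `resolution_config()`.

Because segmentation is total, every in-frame fixation gets a non-empty
resolved label — there is no "background" bucket.

## Label merging

Related classes split across the two vocabularies can be merged into broader
classes at resolution/evaluation time: the default map folds
`sidewalk`/`road`, `person`/`rider`, `car`/`truck` and
`tablet`/`cell phone`. Merging is idempotent, applied outside the fusion
core so the raw labels survive in the output CSV, and extensible (e.g. a
`vehicle` super-class). The `tablet`/`cell phone` merge encodes a pragmatic
stance: common detector vocabularies have no tablet class, so a tablet
consistently called "cell phone" is correct at the merged semantic level.

## Evaluation

`evaluate_annotations()` joins predictions to a manual-label CSV by frame
index and reports accuracy, per-class precision/recall/F1, macro (unweighted
over classes with positive support) and weighted (support-weighted) averages,
plus row-normalized confusion matrices whose zero cells render blank. Two
conventions are explicit because they are not universal: a class that is
never predicted has precision 0 by default (`zero_division = "zero"`;
`"exclude"` drops such classes from the precision means), and classes with
zero support are excluded from macro/weighted means. For single-label data
the weighted recall equals accuracy algebraically — both are
$\mathrm{trace}/N$ — and the test suite asserts this identity to $10^{-12}$
alongside agreement with an independent per-label reference implementation
to $10^{-9}$.

## The synthetic world

Real perception models and recordings are deliberately outside the test
loop; instead a deterministic generator produces everything the pipeline
consumes.

* **Scenes** (`scene_spec()`, `render_scene()`): layered rectangles and
  ellipses with unique depth ranks, rasterized by the painter's algorithm so
  masks partition the frame, while each ground-truth box keeps its full
  pre-occlusion extent — boxes overlap exactly where real detector boxes do.
  Two presets mirror the two study regimes: `exp1` (a calm street, few
  objects) and `exp2` (a busy crossing: 15 layered objects, occlusion,
  handheld devices, and vocabulary gaps — a bus the segmenter can only call
  "car", a tablet absent from both vocabularies).
* **Gaze** (`gaze_plan()`, `simulate_gaze()`): dwell targets with Gaussian
  jitter (default $\sigma$ = 0.002 normalized, a realistic fixational
  scatter at 200 Hz) joined by 40 ms linear saccades. Sample counts follow a
  global `round(duration × rate)` schedule so they are exact.
* **Corruption** (`corruption_spec()`, `corrupt_perception()`): missed
  boxes, label swaps on either side, box jitter, Poisson false positives,
  and mask dilation/erosion applied to object geometry before re-rendering
  (so the corrupted segmentation still partitions the frame). All generators
  are pure functions of their spec and seed.

The fusion-benefit study in the test suite runs the `exp2` regime with a 30%
detector miss rate and 15% segmenter label swaps, 200 fixation points per
seed and 5 seeds, and requires fused accuracy to be at least the better of
the two single-model baselines — the qualitative core of why late fusion is
worth its complexity. Problem sizes throughout (320×240 scenes, 64×64
coverage oracles, hundreds of random cases per property) were chosen as the
smallest at which every geometric regime of interest — occlusion, nesting,
vocabulary gaps — actually occurs.

What the synthetic world does *not* emulate: photorealistic appearance,
motion blur, camera ego-motion, correlated model errors, or gaze-tracking
error around the fixation point. Passing tests therefore demonstrate the
correctness of the pipeline's logic — detection, geometry, selection,
resolution, scoring — not the field accuracy of any particular perception
model, which depends entirely on the models plugged in.

## Numerical and degenerate-input choices

* Normalized coordinates are floored onto the pixel grid and capped at the
  last pixel, so the mapping is total on [0, 1]; frame indexing is
  `floor(t × fps)` capped at `n_frames − 1`, so `t = duration` is valid.
* Out-of-range gaze samples (common around blinks) are clamped by default,
  with counts logged; `drop` and `error` policies are available.
* A recording shorter than the duration threshold yields an empty fixation
  set, not an error; an empty pipeline run writes a header-only CSV and
  warns.
* Coverage refuses zero-area boxes; candidate filtering requires at least
  one mask pixel (`C > 0`) — "contains the mask" is interpreted as ≥ 1
  pixel, the weakest reading that keeps the criterion meaningful.
* When an export carries its own frame-index column it takes precedence
  over the fps mapping, trusting the device's synchronization.
* The normalized y-axis is assumed to point down (top-left origin); a
  `y_axis = "up"` flag covers exporters with the opposite convention, which
  must be confirmed per device.

## Limitations

Fusion quality is bounded by the perception backends: the package ships
contracts and a synthetic backend, and real-model adapters are intentionally
thin, replaceable, and outside the tested surface. The pipeline assigns each
fixation to exactly one object deterministically; it does not model eye
tracker spatial error, scanpath context, or fuzzy multi-label cases, which
ambiguous boundary fixations would need. Video decoding is delegated to
pre-split frame directories (`extract_frames()`); rendered overlays carry no
burned-in text — labels live in the CSV.
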