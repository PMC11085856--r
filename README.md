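# gazefuse

Automatic fixation annotation for mobile eye-tracking: detect fixations in a
wearable tracker's gaze stream, map each onto a scene-video frame, and label
the fixated object by fusing a dense semantic segmentation with object
detection boxes.

## Who this is for

Researchers using head-worn eye trackers in unconstrained environments
(urban wayfinding, pedestrian navigation, human–environment interaction),
where manually labeling what each fixation landed on takes hours per minute
of footage. `gazefuse` replaces manual areas-of-interest with per-frame
perception output and produces one labeled row per fixation.

## The method

1. **IDT fixation detection.** Consecutive samples whose dispersion
   `D = (max x − min x) + (max y − min y)` stays below a threshold for at
   least a minimum duration (default 100 ms) form a fixation; its centroid
   and temporal-midpoint frame represent it.
2. **Mask-coverage fusion.** At the fixation pixel, the segmentation
   contributes the (4-connected) mask `M` containing the point. Every
   detector box containing the point and at least one mask pixel is a
   candidate, scored by mask coverage

   ```
   C = (# mask pixels inside the box) / ((x2 − x1) · (y2 − y1))
   ```

   and the box with the highest `C` is selected (ties: confidence, then
   smaller area, then lexicographic). High `C` picks the tight box around
   the fixated object even when larger boxes of nearer objects also contain
   the point.
3. **Label resolution.** A four-branch cascade combines the two labels: no
   box → mask label; agreement (after optional class merging such as
   `person/rider`, `tablet/cell phone`) → keep; exactly one side on a
   user-defined priority list (e.g. navigation devices) → that side;
   otherwise the box label wins only with confidence ≥ 0.5 and coverage
   ≥ 0.5. Every fixation gets a non-empty label.
4. **Evaluation.** Against a manual-label CSV: accuracy, per-class
   precision/recall/F1, macro and weighted averages, and row-normalized
   confusion matrices with blank zero cells.

A deterministic synthetic backend (layered scenes with occlusion and
split vocabularies, simulated gaze plans, seeded corruption models) makes
the entire pipeline testable without pretrained weights or recordings.

## Worked example

```r
library(gazefuse)

scene <- scene_preset("exp1")                 # calm street: car, person, phone
rendered <- render_scene(scene)
plan <- preset_gaze_plan(rendered, n_targets = 8, seed = 2)
rec <- simulate_gaze(plan, seed = 2,
                     meta = video_meta(320, 240, fps = 30, duration = 3))

out <- run_pipeline(pipeline_config(
  gaze = rec, backend = synthetic_backend(scene),
  idt = idt_config(0.05, "normalized"), output_dir = tempdir()))

out$annotations[, c("frame_index", "mask_label", "box_label", "coverage",
                    "resolved_label", "branch")]
#>   frame_index mask_label  box_label  coverage resolved_label        branch
#> 1           3   building       <NA>        NA       building        no_box
#> 2          11       road       <NA>        NA           road        no_box
#> 3          19   sidewalk       <NA>        NA       sidewalk        no_box
#> 4          26        car        car 1.0000000            car     agreement
#> 5          32     person     person 0.8003086         person     agreement
#> 6          39     person cell phone 1.0000000     cell phone threshold_box
#> 7          46   building       <NA>        NA       building        no_box
#> 8          52       road       <NA>        NA           road        no_box
```

Eight fixations were detected in the simulated stream. Rows 1–3 fell on
regions only the segmenter can name (`no_box`: the detector is silent, the
mask label stands). Rows 4–5 show both models agreeing. Row 6 is the
interesting one: the fixation landed on a phone held by the person — the
segmentation calls the whole region `person`, but the tight `cell phone`
box covers the fixated mask completely (`coverage = 1.0`) and clears both
floors, so the detector's finer label wins.

Evaluating against ground truth:

```r
truth <- data.frame(frame_index = out$annotations$frame_index,
                    label = out$annotations$resolved_label)
ev <- evaluate_annotations(out$annotations, truth,
                           merge_map = default_merge_map())
ev$metrics
#> <metrics_report> n = 8, accuracy = 1.000
plot_confusion(ev$normalized)   # heatmap, zero cells blank
```

A command-line front end over the same functions lives in
`inst/cli/gazefuse.R` (subcommands `annotate`, `detect-fixations`,
`evaluate`, `make-fixtures`).

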