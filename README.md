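# adaptanchor

Anchor-based detection of **small, partially clustered objects** in
radiograph-like images, built around one idea: instead of fixing the IoU
thresholds that label anchors positive or negative, **ramp them up during
training**.

The motivating application is automated erosion scoring on bilateral hand
radiographs of rheumatoid-arthritis patients: 32 joint sites per image, each
graded 0-5 (Sharp/van der Heijde erosion score). The joints are tiny
relative to the image, and the ten carpal sites sit in one tight cluster.
Against a standard anchor lattice almost no anchor reaches an IoU of 0.5
with such objects, so with conventional static thresholds nearly every
anchor is labeled negative, the focal loss is minimized by predicting
background everywhere, and the detector collapses to zero detections. An
adaptive schedule

```
pos_iou(e) = end_pos_iou * min(e / adaptive_epochs, 1)
neg_iou(e) = end_neg_iou * min(e / adaptive_epochs, 1)
```

hands the network abundant positive anchors early (learn *what and where*
joints are) and tightens localization later. The package implements the
full pipeline in R:

* `apply_window()`, `zscore_normalize()`, `resize_with_boxes()` — DICOM-style
  window/level normalization to [0, 4096] and box-consistent resizing;
* `generator_config()` / `generate_image()` / `generate_split()` — a seeded
  synthetic bilateral-hand generator (32 annotated joints per image, carpal
  clusters, bone-shaft clutter, class-imbalanced erosion scores) so the
  whole pipeline is testable without clinical data;
* `augment_config()` / `augment()` — the gamma / shift / crop / 90-degree /
  scale / rotation augmentation chain applied identically to image and
  boxes;
* `generate_anchors()`, `adaptive_schedule()`, `current_thresholds()`,
  `match_anchors()` — the anchor lattice and the static/adaptive
  IoU-threshold assignment with a best-anchor fallback;
* `build_detector()`, `focal_loss()`, `smooth_l1()`, `train()` — a small
  residual + feature-pyramid detector (p2/p3 levels, one box-regression and
  two classification subnetworks) with hand-written forward/backward passes
  on BLAS, trained with ADAM, plateau scheduling and per-epoch re-matching;
* `evaluate()`, `map_eq3()`, `kendall_tau()` — the bespoke metrics: the
  IoU >= 0.3 + exact-score accuracy rule, per-class-precision mAP, mean
  IoU, row-normalized score confusion matrices, Kendall tau-b agreement;
* `experiment_grid()` / `run_grid()` — the 18-configuration threshold grid
  (six positive/negative pairs x static / 50 / 100 adaptive epochs);
* `inst/cli/adaptanchor.R` — a command-line wrapper
  (`make-data`, `train`, `evaluate`, `grid`).

## Worked example

Desk-scale end-to-end run (one CPU, about three minutes): train the same
small detector twice on the same seeded synthetic dataset — once with
static 0.5/0.4 thresholds, once ramping to the same end values — and
compare.

```r
library(adaptanchor)

pre <- desk_preset(seed = 1)          # 96x96 images, 4-8 px joints, 21/3/6 split
splits <- generate_split(pre$generator)

run <- function(adaptive) {
  tcfg <- pre$train
  tcfg$schedule <- adaptive_schedule(0.5, 0.4,
                                     if (adaptive) pre$scale_adaptive(50) else NULL)
  fit <- train(pre$model, tcfg, splits)
  evaluate(fit$checkpoint, splits$test,
           score_threshold = tcfg$score_threshold, nms_iou = tcfg$nms_iou)
}
run(adaptive = TRUE)
run(adaptive = FALSE)
```

```
<eval_report over 6 images>
  accuracy  0.536 +/- 0.075
  mAP       0.045 (per-class precision)
  mean IoU  0.358 +/- 0.013

<eval_report over 6 images>
  accuracy  0.036 +/- 0.042
  mAP       0.017 (per-class precision)
  mean IoU  0.069 +/- 0.015
  tau (per joint): tau = -0.059 (negligible), p = 0.395, n = 192
```

Reading the numbers: with **static** thresholds the detector finds
essentially nothing — no anchor ever reaches IoU 0.5 with a 4-8 px joint,
so its only supervision is one fallback anchor per object and training
collapses (accuracy 0.04, mean IoU 0.07). The **adaptive** run, identical
in every other respect, detects and correctly grades about half of the
joints (accuracy 0.54) and localizes them at a mean IoU of 0.36. That is
the scaled-down version of the contrast the method is designed to produce.
Two desk-scale caveats are visible in the report: per-class-precision mAP
stays low because the rare erosion grades (a handful of test joints) are
seldom graded exactly right, and the adaptive report prints no per-joint
tau because at this scale the detector grades every found joint as score 0
(the majority class), leaving the predicted ranking degenerate.

The anchor-supervision mechanism can be inspected directly:

```r
anchors <- model_anchors(pre$model)
ab <- rbind(anchors$p2$boxes, anchors$p3$boxes)
it <- generate_image(pre$generator, 1)
table(match_anchors(ab, it$annotations, 0.5, 0.4)$label)    # static end state
table(match_anchors(ab, it$annotations, 0.05, 0.04)$label)  # early in the ramp
```

```
positive negative   ignore
      32     6448        0
positive negative   ignore
    2964     3141      375
```

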