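---
title: "Multi-stage pseudo-labeling for fruit segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage pseudo-labeling for fruit segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pixel-wise segmentation of fruit against vegetation is the first step of
camera-based orchard monitoring: fruit counting, growth tracking and yield
estimation all start from a binary fruit/background mask. Training a
segmentation network normally requires dense manual annotation of field
images, which is slow and error-prone in cluttered canopy scenes. `pomseg`
implements a semi-supervised alternative: a *multi-stage transfer-learning
cascade* in which labels are produced automatically at every stage, and a
network trained on easy, controlled images is progressively extended to
hard field imagery through pseudo-labeling.

The cascade trains four nets:

1. **First CE net** — trained on close-up photographs of fruits on a
   neutral background under uniform light (*set1*), labelled fully
   automatically by colour thresholding plus morphological cleanup.
2. **CE net** — retrained after adding images of the same arrangements
   under harsh, non-uniform light (*set2*). These cannot be colour-
   thresholded reliably (shadows), so they are *pseudo-labelled* by the
   First CE net, with the same morphological cleanup applied to the
   predicted masks.
3. **TNA net** (true-negative augmented) — the CE training set plus
   fruitless field-style images carrying all-zero masks, aimed at
   suppressing false positives.
4. **FIA net** (field-image augmented) — the CE training set plus a small
   number of field frames pseudo-labelled by the CE net, with *no*
   morphological finishing, aimed at balancing false positives and false
   negatives.

Every model is evaluated on a shared, held-out field-style test set with
the full pixel-wise metric suite (precision, recall, F1, global/mean
accuracy, mean/weighted IoU, four-colour error maps).

## Synthetic scenes as the experimental substrate

Real orchard imagery cannot ship with a package, so `pomseg` carries a
seeded scene generator whose outputs come with *exact* ground truth. It
emulates the four acquisition conditions the cascade consumes:

- **set1** — fruits as filled ellipses (axis ratio 0.7–1.0, deep
  red/crimson: R in [150, 220], G and B in [20, 80]) on a neutral grey
  background (≈120), uniform light. Fruits optionally carry a thin
  protruding stem (2–4 px wide, 10–25 % of the major axis), which is
  *excluded* from the ground truth, so stem removal is measurable.
- **set2** — the same arrangements with a multiplicative illumination
  gradient and elliptical cast shadows, both scaled by `shadow_strength`.
- **negative** — fruitless field-style vegetation: textured green foliage,
  brown branch strokes and dry-leaf blobs. The mask is all zeros.
- **field** — foliage, branches, fruits under non-uniform light, plus
  yellow-brown "dry leaf" confuser blobs (R 180–220, G 140–180, B 40–90)
  whose colour range deliberately overlaps the fruit hue in the red-minus-
  green direction; these reproduce the false-positive failure mode that
  motivates the third cascade stage.

Two scale decisions matter and are deliberate:

- **Close-up vs far-view scale.** Controlled scenes emulate bench
  close-ups, so fruits are large (semi-major axis 0.09–0.16 of the image
  side). Field and negative scenes emulate far views from a moving ground
  platform, so their fruits are leaf-sized (0.05–0.09). This split is what
  makes field imagery genuinely harder than controlled imagery: at leaf
  scale, a fruit's pooled context is foliage-dominated and overlaps the
  appearance of confuser blobs.
- **Separation in controlled scenes.** Fruits in set1/set2 are placed
  non-overlapping (as they would be laid out on a bench). Touching fruits
  merge into elongated blobs that an eccentricity-based stem filter would
  wrongly discard; that situation belongs to field scenes, where no
  eccentricity filtering is applied.

Determinism is a hard contract: a scene spec (including its seed)
reproduces a bit-identical image and mask, and generation never perturbs
the caller's RNG stream. Each sample exposes its analytic shapes (fruit
ellipse parameters, stem and confuser pixel sets) so tests can assert mask
soundness against the geometry rather than against the renderer's output.

What the generator does *not* emulate: photorealism, occlusion by leaves,
depth-of-field and motion blur, specular highlights, fruit colour
variation across ripeness, and within-scene scale variation. Passing
cascade properties on these scenes therefore demonstrate the *mechanics*
of the curriculum (label flow, data hygiene, the precision/recall
trade-offs of the stages), not field-ready accuracy.

## Automatic labelling

Controlled uniform-light images are labelled by a red-dominance test
applied per pixel — fruit iff

$$R \ge 130,\quad R - G \ge 40,\quad R - B \ge 40$$

— followed by three cleanup operators, in order:

1. **Noise removal.** Connected components with area *strictly below*
   `min_area` are dropped. The default 64 px is calibrated for 256×256
   frames and scales quadratically with resolution
   (`scaled_min_area()`).
2. **Stem discarding.** The mask is eroded by a disk (radius 3 px),
   which deletes or detaches thin stems; any remaining component whose
   moment-equivalent ellipse has eccentricity above 0.92 (axis ratio
   below ≈0.39 — far more elongated than any fruit) is discarded; the
   surviving bodies are restored by a disk dilation of equal radius.
3. **Hole filling.** Background regions not connected to the image border
   become foreground, repairing interior holes left by shadows or
   specularities.

Numerical conventions worth recording:

- Connectivity defaults to 8-connected foreground; hole filling uses the
  complementary background connectivity (4-connected), the standard
  digital-topology pairing.
- Erosion treats out-of-image pixels as foreground and dilation as
  background (the convention of the common image-processing toolboxes),
  so fruit touching the border is not eaten away by the restore step.
- Component ellipses come from second-order central moments with the
  pixel-as-unit-square correction (+1/12 on each second moment), so
  single-pixel and 1-px-wide components have well-defined finite axes;
  for analytic ellipses with semi-axes ≥ 10 px the eccentricity matches
  the closed form $\sqrt{1-(b/a)^2}$ within 2 %.
- Structuring elements are analytic disks ($dx^2+dy^2 \le r^2$).

The thresholds themselves (130/40/40, 0.92, radius 3) are calibrated to
the synthetic palette; on real imagery they would be re-tuned. On the
synthetic uniform-light scenes the full labeller recovers the generator's
ground truth with mean IoU ≈ 0.99.

## Augmentation

Each original yields exactly 20 derived images: the 8 right-angle
geometric variants ({0°, 90°, 180°, 270°} × {identity, horizontal flip})
cycled against photometric slots — 8 geometric-only, 8 with a contrast
gain sampled uniformly in [0.7, 1.3] (about mid-grey 128), 4 with an
exposure offset sampled in [−30, +30], clipped to [0, 255]. Right-angle
geometry keeps masks binary without interpolation; photometric changes
never touch the mask. Plans are deterministic in `(seed, sample_id)`, so
an augmented dataset is reproducible sample-by-sample. Elastic
deformation, cropping, scaling and noise injection are deliberately out of
scope.

## The segmentation model

No deep-learning framework is assumed: the package's network is compact
and fully self-contained, and was designed so that the whole cascade
trains on one CPU in about two minutes.

- **Fixed feature pyramid (the "backbone + spatial pyramid").** Per
  pixel: RGB in [0, 1], plus — for each dilation rate $r \in \{1,2,4,8\}$
  — box-pooled RGB context over a $(2r{+}1)^2$ window and the local
  luminance standard deviation at that scale. 19 channels in total,
  computed exactly via integral images. The multi-rate pooling plays the
  role of atrous spatial pyramid pooling: context at several receptive
  fields feeds a per-pixel classifier.
- **Trainable head.** A two-layer 1×1-convolution network (16 hidden
  ReLU units, 2-channel softmax), trained with pixel-wise cross-entropy
  by minibatch Adam. This is the transfer-learning surface: stages
  warm-start from the previous stage's weights, and
  `pretrained_weights` initialises everything *except* the final 2-class
  classifier from a saved model.
- **Training regime.** 600 pixels are sampled uniformly per training
  image (fully convolutional inference uses all pixels); defaults are 40
  epochs, batch 1024 pixels, learning rate 0.01. Losses are logged per
  epoch and must remain finite; divergence aborts. Given identical data,
  hyperparameters and seed, training is bit-reproducible.
- **Prediction.** Per-pixel argmax of the two score channels; ties break
  toward background, the conservative choice for precision. The model is
  resolution-independent, so no resizing is required at inference.

The backbone choice is deliberately modest: the cascade — not the
backbone — is the subject of this package, and every cascade property is
asserted at this scale. A deeper residual encoder would change absolute
numbers, not the label-flow mechanics. Only the `"tiny"` backbone is
provided; requesting anything else errors.

## Cascade orchestration

`run_stage()` assembles each stage's training set exactly as the
curriculum prescribes (auto-labels for stage 1; stage-1 pseudo-labels
*with* cleanup for stage 2; zero-mask negatives or no-cleanup field
pseudo-labels for stage 3), applies the 20-fold augmentation, trains and
tags the model, and logs pre/post-augmentation counts. Data hygiene is
enforced: field frames never enter stage-1/2 training, and the held-out
test set's scene seeds are disjoint from every training scene.

Open choices, decided as follows:

- Stage-3 nets restart from the CE weights (rather than from scratch);
  the stage is a refinement of the CE net, and warm-starting is what
  transfer learning prescribes.
- Negatives and field pseudo-labels are augmented exactly like positives
  (so 410 originals always yield 8200 training images).
- The "first few seconds of field acquisition" becomes the first
  `n_field_train` generated field frames.
- Negative scenes are rendered as fruitless *field-style* vegetation
  (foliage, branches, dry leaves) rather than neutral grey: true
  negatives exist to teach the net what non-fruit field content looks
  like, and grey backgrounds carry no such information.
- The manual-comparison arm (optional) uses generator ground truth in
  place of hand labels, mimicking a conventional supervised baseline.

Desk-scale defaults (16 set1, 12 set2, 12 negatives, 12 field-train, 40
field-test scenes at 96×96) keep a full cascade run around two minutes on
one CPU; they are the sizes at which all shipped properties are asserted.

## Evaluation

Confusion counts treat fruit as the positive class. Precision, recall and
F1 follow their defining ratios with explicit empty-mask conventions: a
fruitless frame predicted fruitless scores 1 on all three (it is a perfect
prediction), while `tp = 0` with any error zeroes the undefined member.
Per-class IoU is $TP/(TP+FP+FN)$; mean IoU averages fruit and background;
weighted IoU weights each class by its ground-truth pixel share. Global
accuracy is the fraction of correct pixels; mean accuracy averages the
per-class recalls. Test-set numbers are per-image metrics averaged
arithmetically (the headline), with aggregate-pixel metrics computed on
the summed confusion counts reported alongside — on imbalanced imagery
the two genuinely differ, and both views are useful. Error maps encode
TP/TN/FN/FP as white/black/magenta/green.

The identity $F1 = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ (fruit class) holds
to machine precision and is asserted in the tests, as is exact agreement
of every metric with per-pixel brute-force oracles on random masks.

## What the cascade does and does not reproduce

On the synthetic benchmark, across seeds:

- The **CE net** keeps high recall but loses precision on field scenes —
  its false positives concentrate on the yellow-brown confuser blobs and
  on branch pixels, content it has never seen labelled.
- The **TNA net** raises precision to near 1 (negatives teach it field
  vegetation, including the confuser palette) at a measurable cost in
  recall, concentrated on small, shaded, foliage-surrounded fruit. Both
  orderings — TNA precision above CE, TNA recall below CE — hold
  reliably and are asserted in the tests.
- The **FIA net** tracks the CE net closely rather than beating it. This
  is a structural property of pseudo-labeling when teacher and student
  share one deterministic feature representation: the teacher's labels
  are then a deterministic function of the student's own inputs, so
  retraining reproduces the teacher's decision rule — including its
  false positives — rather than denoising them. For field-image
  augmentation to *correct* confuser false positives, the teacher's
  errors must be incoherent in the student's feature space (as they can
  be for high-capacity stochastic models), or the teacher must mislabel
  under half of the confuser pixels so that majority-label training
  flips them. Neither holds at this package's scale: the measured CE
  false-positive rate on confuser pixels is ≈ 0.7 and coherent in colour
  space. The package reports the FIA ordering honestly instead of
  engineering the benchmark around it; the corresponding test documents
  the behaviour rather than hiding it.

This limitation is informative rather than incidental: it delineates when
adding pseudo-labelled field frames can help (scattered, inconsistent
teacher errors; teacher error rate below one half on the confusable
content) and when only true negatives can (systematic teacher errors on
unseen content).

## Known limitations

- Synthetic scenes are stylised; absolute metric values do not transfer
  to real orchard imagery.
- The colour-threshold defaults are palette-specific.
- The model is a per-pixel classifier over pooled context: it has no
  shape prior, no learned texture filters, and no instance notion.
- Only binary (fruit/background) segmentation is supported.
- Timing claims are limited to the desk-scale configuration sizes stated
  above.
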