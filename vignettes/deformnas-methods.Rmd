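---
title: "Deformable convolution and a NAS-searched pyramid neck for MRI lesion detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable convolution and a NAS-searched pyramid neck for MRI lesion detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deformnas)
```

## The problem

Bone marrow oedema shows up on fluid-sensitive lumbar MRI as bright regions
of variable size and shape inside vertebral bodies, surrounded by organ and
fat tissue of similar brightness. Detecting it is a small-object detection
problem with two specific difficulties: the lesion geometry is irregular
(so fixed-grid convolutions sample it poorly) and the discriminative
context spans several spatial scales (so a single-path feature pyramid
discards useful shallow information).

`deformnas` implements a two-stage detector that addresses both:
deformable convolution and deformable RoI pooling in the feature
extractor, and a feature-pyramid aggregation neck whose wiring is found by
one-shot neural architecture search plus an evolutionary algorithm.
Everything — including training — runs on one CPU at desk scale, which is
what makes the implementation testable end to end.

## Deformable sampling operators

A regular convolution samples the input `x` on a fixed grid
`R = {(-1,-1), ..., (1,1)}` around each output position `p0`:

    y(p0) = sum_n w(p_n) x(p0 + p_n)

The deformable version adds a learned, position-dependent 2D offset to
every tap:

    y(p0) = sum_n w(p_n) x(p0 + p_n + dp_n)

Since `dp_n` is fractional, `x` is read through the separable bilinear
kernel `G(q, p) = g(q_r, p_r) g(q_c, p_c)` with `g(a, b) = max(0, 1 - |a - b|)`,
summing over the at most four integer neighbours of the sampling point.
Deformable RoI pooling applies the same idea per pooling bin: the RoI is
split into equal sub-rectangles, each bin averages the integer positions it
contains, and a learned per-bin displacement shifts those positions before
the bilinear read.

Conventions fixed across the package (and asserted in tests):

* coordinates are 0-based `(row, col)` pairs; boxes are half-open in
  continuous coordinates; offsets are `(d_row, d_col)`;
* reads outside the map contribute zero, consistently with zero-padded
  convolution and the finite support of `G`;
* a pooling bin that contains no integer position contributes one bilinear
  sample at its centre, which keeps the output finite and differentiable;
* the convolution weight is indexed by the tap `p_n`. (Some presentations
  write `w(p0)`; that reading would make the weight constant across taps
  and the operation would no longer be a convolution, so the tap-indexed
  form is used and documented here rather than changed silently.)
* the offsets themselves are predicted from the input feature map by a
  plain convolution with `2K` output channels whose weights are
  zero-initialized, so training starts exactly in the plain-convolution
  regime. An open design question is whether the offset predictor should
  itself be deformable; the plain predictor is the default because it
  matches the original deformable-convolution design and keeps the
  initialization argument simple.

Every operator has a brute-force oracle twin in the test suite (a literal
loop transcription of the defining sum), and the differentiable versions
are verified against central finite differences at tolerance `1e-4`.

## The six information paths

The neck operates on a 4-level pyramid P2..P5 (strides 4/8/16/32, shared
channel width). Six path kinds map a pyramid to a pyramid of identical
shape:

* **top-down** — `F_i = W_i (U(F_{i+1}) + P_i)` built from level 5 down,
  seeded with `F_5 = W_5 P_5`;
* **bottom-up** — the mirror recursion built from level 2 up with
  downsampling;
* **scale-balanced** — per level, the sum of the upsampled convolution of
  the level above, the convolution of the level itself and the downsampled
  convolution of the level below, with missing neighbours dropped at
  levels 2 and 5;
* **fuse-split** — two intermediate maps (`alpha_s = P4 + U(P5)` at level
  4, `alpha_l = D(P2) + P3` at level 3) are cross-fused by channel
  concatenation and a 2C-to-C convolution, then redistributed to the four
  levels by resampling;
* **null** — the zero pyramid (the additive identity, used by the search
  to prune redundant connections);
* **skip** — the identity (no parameters).

Resampling is deliberately parameter-free: `U` is nearest-neighbour 2x
replication and `D` is 2x2 max pooling, so each path's parameter count is
exactly its convolution content and can be asserted in closed form. The
level-2 convolutions are regular while levels 3–5 use deformable
convolutions, uniformly across all four parameterized kinds. The
scale-balanced path shares its three kernels across levels (they carry no
level index); the regular-vs-deformable split is then applied by operand
level — the shared kernel is used without offsets when it reads level 2.
In the scale-balanced equation the term from the level below must be
resampled before the three terms can be summed; it is downsampled with the
same `D`, matching how scale-equalizing pyramid convolutions align their
lower term.

## One-shot supernet and evolutionary search

The neck's search space is a fully connected DAG over nodes
`P, X_1, ..., X_N, O` (`N = 5` by default, 21 edges) with one of the six
path kinds per edge; a genotype ("subnet code") assigns a kind to every
edge. Node values are the element-wise **sum** of their incoming paths
(the aggregation rule is a design choice; summation keeps the null path a
true identity and makes a sequential chain a special case). A code is
valid when at least one `P -> O` route uses only non-null edges —
otherwise the output node would receive nothing; invalid draws are simply
re-drawn. The channel width is reduced to 112 (from the conventional 256)
to keep the supernet small; the detection head width is reduced to match.

Supernet training follows single-path one-shot practice: each SGD step
samples one code uniformly and updates only the parameters that code
touches. Each edge holds private parameters for each of the four
parameterized kinds (no cross-edge sharing), so two codes differing on one
edge share all other weights; the test suite asserts both the sharing and
the gradient isolation.

The search itself is a plain evolutionary algorithm over codes: `S = 50`
random valid codes, ranked by AP50 on a validation set using the shared
supernet weights (no retraining), the best `k = 10` carried over
unmodified (elitism, which makes the best-so-far fitness monotone), and
the population refilled with `mutate(crossover(elite, elite), p = 0.1)`
children. Mutation resamples each edge independently with probability `p`
over all six kinds; resampling can repeat the current kind, so at `p = 1`
the expected changed fraction is 5/6 — this exact constant is used as a
calibration check. A child that duplicates a code already in the new
population is re-drawn (bounded tries) to keep the population diverse, the
usual practice in evolutionary one-shot search. Two published details are
underdetermined and resolved as follows: the number of rounds is not
stated (default `n = 20`; the enumerable-space tests use 15), and
"mutation of a random subnet boundary" admits a single-edge reading, which
is available via `mutation = "single-edge"` while the per-edge reading is
the default.

## Detector assembly and loss

The backbone is either `resnet50` (the full-scale architecture shape,
bottleneck stages 3/4/6/3, deformable 3x3 convolutions in stages 3–5,
randomly initialized — no pretrained weights exist at desk scale) or
`tiny` (four small conv stages, the configuration every end-to-end test
uses). Stage outputs C2..C5 are projected by 1x1 convolutions to the
pyramid width, the neck transforms the pyramid, and the neck output is
superimposed on the projected backbone pyramid by element-wise addition —
the 1x1 lateral projection doubles as the channel-matching projection.

Proposals come from a standard RPN (3 scales x 3 aspect ratios per cell,
IoU 0.7/0.3 assignment); RoIs are pooled by the deformable RoI pooling
operator on 7x7 bins, with the per-bin offsets predicted from the plainly
pooled features by a zero-initialized fully connected layer, and
classified by a 1024-dimensional fully connected head (64 in the tiny
configuration). The loss is

    L = sum(L_cls + L_loc) + mu * L1

where the sum runs over both stages (RPN and head), `L_cls` is
cross-entropy, `L_loc` is smooth-L1 over positive matches, and `L1` is the
mean absolute value of the neck weights active in the current forward
pass, weighted by `mu = 0.11`. The decomposition
`total = l_cls + l_loc + mu * l1_reg` is recorded at every step and
asserted exactly. The regularization scope is a config knob
(`l1_scope = "neck"` or `"all"`); the neck-only default reflects that the
regularizer exists to prune the aggregation module.

Because every deformable offset predictor starts at zero, the freshly
initialized detector is numerically identical to its plain-convolution
twin — a property the tests check by weight transplantation.

## What the synthetic generator does and does not emulate

No public dataset exists for this task (the study data are private
clinical images), so the package ships a seeded generator of MRI-like
scenes: a grey background, a column of medium-intensity vertebral bodies
(rounded rectangles), bright elongated distractor ellipses outside the
spine (organ/fat tissue), and 0–3 bright rotated-ellipse lesions placed
fully inside vertebrae, each annotated with a tight axis-aligned box in
COCO convention. Lesion placements whose boxes would overlap an existing
lesion are rejected (bounded retries, then the lesion is skipped): two
overlapping bright ellipses would merge into one blob carrying two
ambiguous boxes, which is neither clinically meaningful — distinct oedema
foci are distinct regions — nor learnable as two targets. Additive
Gaussian noise (sigma = 0.02) is applied last.
Default study conditions: 256x256 images, lesion semi-axes 4–30 px,
lesion intensity 0.3 above the vertebral level, 416 training and 105 test
images written as PNG + COCO JSON.

The generator reproduces the *appearance statistics that matter to the
detector* — bright variably-shaped targets among bright distractors on a
grey background — but none of the physics: no acquisition noise model, no
bias fields, no partial-volume effects, no anatomical variability, no
multi-slice geometry. Passing tests therefore demonstrate that the
implementation is correct and trainable, not that the architecture
reaches any particular accuracy on clinical data.

Augmentation follows the training recipe: horizontal mirror with
probability 0.5 and a random crop of 0.6–1.0 linear scale. Boxes are
clipped to the crop and dropped when less than 25% of their area survives
(the published recipe does not say how to treat cut boxes; 25% is the
package's choice). The training loop pads cropped images back to a
multiple of 32 so the five-level pyramid stays well-defined.

## Problem sizes, numerical choices, defaults

* End-to-end tests run the tiny configuration on 64x64 images with lesion
  semi-axes 4–10 px — the full-scale geometry scaled to one quarter —
  with 16 channels throughout, `N = 1`, and SGD (momentum 0.9,
  `lr = 0.005`, batch 2). Under that configuration the detector overfits
  a 10-image training set to AP50 = 1.0 within 1000 steps, the package's
  end-to-end correctness check; training is evaluated every 50 steps and
  stops once the target is reached. The full-scale defaults
  (`detector_config()`) mirror the published recipe: batch 4, lr 0.001,
  30 epochs, `N = 5`, 112 channels, `mu = 0.11`.
* Full-scale training hyperparameters do not transfer to the tiny
  problem: lr 0.001 underfits in the step budget and lr 0.02 diverges,
  so the tiny configuration fixes `lr = 0.005` with a 5x decay after
  step 600 in the overfit run.
* The bilinear kernel's derivative is taken one-sided at integer
  coordinates (a subgradient choice); gradient checks avoid the kinks by
  testing at fractional offsets.
* SGD updates only parameters that received gradients, so supernet steps
  leave unsampled edges untouched, momentum buffers included.
* AP50 uses the COCO convention: greedy per-image matching at IoU 0.5 in
  descending score order, one match per ground truth, and 101-point
  interpolated precision averaging.
* The reported F1 is the harmonic mean of AP50 (as the precision
  surrogate) and recall on the percent scale, rounded half-up to one
  decimal; this is the reading consistent with the summary tables this
  implementation follows, though not every published row satisfies it, so
  a score-thresholded precision/recall/F1 report (`detection_report()`)
  is provided alongside.

## A small worked example

```{r example, eval = FALSE}
spec <- scene_spec(image_size = 64, n_vertebrae = 3, lesion_axes = c(4, 10),
                   lesion_count = c(1, 2))
train_set <- lapply(1:10, function(i) {
  g <- generate_image(spec, seed = i)
  list(image = g$image, boxes = coco_to_xyxy(g$boxes))
})
code <- c("P>X1" = "TOP_DOWN", "P>O" = "SKIP", "X1>O" = "SKIP")
det <- build_detector(tiny_detector_config(), code = code, seed = 1)
det <- train(det, train_set, steps = 400, batch_size = 2,
             augment_data = FALSE, seed = 1)
dets <- lapply(train_set, function(it) infer(det, it$image,
                                             score_threshold = 0.5))
average_precision_50(dets, lapply(train_set, `[[`, "boxes"))
```

## Known limitations

* Pure-CPU desk scale: the compiled kernels are single-threaded reference
  implementations, not GPU kernels; full-scale training of the `resnet50`
  configuration is out of reach and only its forward pass is exercised.
* Modulated (v2) deformable convolution, dilation > 1, pyramid depths
  other than 4, and gradient-based architecture search are not
  implemented.
* The synthetic data bound the claims: results on it say nothing
  quantitative about clinical MRI.
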