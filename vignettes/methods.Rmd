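---
title: "Student-t slice attention and penalty-weight loss: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Student-t slice attention and penalty-weight loss: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsliceattn)
```

## The problem

A knee-MRI exam is an ordered stack of `S` grayscale slices; `S` varies
per exam (17–61 in the public MRNet-style layout this package mirrors).
The diagnostic target is binary: is an anterior-cruciate-ligament (ACL)
tear present? Two structural facts shape the design. First, tear signs —
both direct (ligament discontinuity) and indirect (oedema, meniscal
damage) — concentrate in the *central* slices, while slices at the ends
of the stack carry mostly irrelevant content: heavy noise, subcutaneous
fat, coil flare. Second, tears are the minority class (roughly one exam
in five), so a symmetric objective tends to favour the majority.

The package addresses both with two components layered on a
convolutional backbone: a **Student-t slice-attention module** that
derives a per-slice importance weight from the data and the slice
position, and a **penalty-weight loss** that replaces cross-entropy with
an expected misclassification cost.

## Slice attention

Let `M` be the backbone feature stack of one exam, shaped
`S x C' x H' x W'`. The module proceeds:

1. *Pooling* (`pool_slice_features`): global average and global maximum
   over the spatial grid give two `S x C'` descriptors; the average
   captures each slice's global context, the maximum its most salient
   local response.
2. *Cross-similarity* (`similarity_pair`): `S1 = softmax_rows(avg %*% t(max))`
   and `S2 = softmax_rows(max %*% t(avg))` — each row is one slice's
   attention distribution over all slices.
3. *Initial weights* (`initial_weights`): `D = (S1 + S2)/2`, reduced to
   one weight per slice by **column** means and normalized to the
   simplex. The column reduction is forced: every row of a
   row-stochastic matrix sums to one, so the row reduction returns the
   uniform vector on *any* input (the package carries a test proving
   this degeneracy).
4. *Moment fit* (`fit_t_params`): treating the initial weights as a
   probability mass over positions `1..S`, the location is
   `mu = sum(omega * s)` and the degrees of freedom come from the
   weighted variance `v` through the Student-t variance identity
   `v = nu/(nu - 2)`, inverted to `nu = 2v/(v - 1)`.
5. *Position weighting* (`slice_weights`): the unit-scale t density
   `T(x; mu, nu)` is evaluated at the integer positions and normalized,
   then applied multiplicatively to the feature stack
   (`apply_weights`).

The result: slices near the similarity-weighted centre of mass keep
their features; end slices are strongly attenuated. Because the fit
re-runs on every forward pass, the weighting adapts per exam — if the
backbone's features make a particular region salient, `mu` tracks it.

### Numerical choices in the fit

* **Clamping `nu` to [2.05, 200]** (defaults): the moment inversion
  requires `nu > 2` for the variance to exist; the upper clamp keeps the
  density bounded away from a point spike. A weighted variance `v <= 1`
  has no admissible moment solution and maps to `nu_max`, i.e. a
  near-point weighting. `nu` can also be fixed by configuration, in
  which case no fit is performed.
* **Degenerate stacks**: `S = 1` short-circuits to the weight vector
  `[1]`.
* **Positions are 1-based integers** `1..S`.
* The similarity-to-omega path is differentiable, but the scalar fit
  `(mu, nu)` and the resulting weights are treated as constants of each
  forward pass: the gamma-function fit is a statistics step, not a
  learned layer, and it adds no learned parameters.

### Weight scale at the model level

`slice_weights` returns simplex weights (they sum to one) — that is the
module contract and what the tests check. Applied verbatim inside the
classifier, however, simplex weights scale every exam's features by
roughly `1/S`, and under max fusion the exam score then varies
systematically with the slice count rather than the pathology; in
scaled-down experiments this inverted score rankings outright. The
model therefore applies the weights with a **mean-one rescale**
(`w * S`, option `weight_rescale = "mean_one"`): the average slice keeps
unit gain, relative attenuation across slices — the actual filtering
signal — is untouched, and exams of different lengths live on one score
scale. `weight_rescale = "sum_one"` restores the verbatim behaviour.

## The classifier

`slice_model()` assembles: backbone per slice → optional slice
attention → per-slice global average pooling (`S x C'` vectors) →
coordinatewise **max fusion** across slices (`aggregate_max`) → linear
head → softmax. Because global average pooling is linear, weighting the
feature maps and then pooling equals pooling and then weighting the
per-slice vectors; the implementation uses the latter and never
materializes the weighted 4-D stack.

The head is a **bias-free cosine classifier** (option
`head_norm = "cosine"`, the default): each class score is the cosine
between the L2-normalized exam vector and an L2-normalized class
weight vector, times a fixed scale (`logit_scale`, default 4). This is
load-bearing for the penalty loss. Being linear in the probabilities,
that loss has gradients that vanish multiplicatively at confident
errors; with an unbounded affine head, training from random
initialization under 4:1 imbalance reliably drifted into saturated
constant-"healthy" scores within the first epoch and never recovered
(observed as every test score collapsing to exactly 0). Bounding the
logits keeps the gradients alive, and dropping the bias matters too: a
free bias absorbs the class prior at almost no cost and pins training
at the majority-collapse plateau (epoch-mean loss frozen at the
prior's expected cost) — without it the prior must be expressed through
the same weight geometry the features use. The cosine head also
removes residual scale differences between exams (slice counts,
attention scaling). All four ablation variants share the same head, so
ablation comparisons are unaffected; the affine alternatives (`"l2"`,
`"none"`) remain available.

The backbone registry (`backbone_registry()`) contains deliberately
small CPU-trainable networks: `tiny` (avgpool + three 3x3-conv blocks,
~3.6k parameters; the default and the test workhorse), `vgg_small`
(double-conv blocks) and `resnet_small` (residual blocks). They are
desk-scale analogues of the standard ImageNet families; no pretrained
weights are shipped, and full-scale pretrained backbones are outside
this package's scope. Grayscale input is used natively
(`in_channels = 1`); replication to three channels is available for
RGB-shaped architectures. Stacks whose resolution differs from the
configured `image_size` are resampled by nearest-neighbour indexing.

## Penalty-weight loss

With `n` classes, the base cost matrix `W` has `W[i, j]` = cost of
predicting class `i` when the truth is `j`, unit diagonal by
convention, and off-diagonal costs that grow with the ordinal deviation
(default `|i - j|`). The corrected matrix `W'` zeroes the diagonal and
adds one off-diagonal, after which the loss is the expected cost of the
softmax output,

    loss = sum_i W'[i, j] * p_i ,

zero exactly when all mass sits on the true class. The base form (with
`q_i = p_i` off the true class and `1 - p_j` on it) is algebraically
identical whenever the diagonal is unit; the package implements both
and tests the identity on randomized instances. The gradient with
respect to pre-softmax scores is `p_k (W'[k, j] - loss)`.

Two practical notes:

* **Cost asymmetry.** The loss exists to encode class structure, and
  for an imbalanced binary task the natural structure is a heavier
  price for missing the minority class. `penalty_matrix()` defaults to
  symmetric costs; the training pipeline, when the penalty loss is
  selected and no explicit costs are given, sets the cost of calling a
  true tear "healthy" to the negative:positive ratio of the training
  split (capped at 10). This counterweights the imbalance — the loss's
  stated purpose — and in scaled-down experiments is the difference
  between the loss helping and the loss quietly collapsing to the
  majority class.
* **Vanishing gradients at confident errors.** Being linear in `p`, the
  loss backpropagates `p_wrong`-scaled gradients: a confidently wrong
  prediction yields almost no signal (unlike cross-entropy, whose
  gradient saturates at full strength). This is benign when features
  are already informative and is the reason for the normalized head
  above when they are not.

## Evaluation protocol

`roc_auc` sweeps all unique score thresholds (predicted positive means
score strictly greater than the threshold), yielding FPR/TPR per the
usual confusion-matrix definitions and the trapezoidal AUC — which for
this construction equals the Mann–Whitney pairwise statistic with ties
counted one half (tested against an O(n²) oracle). Model selection
takes the epoch with the best validation AUC (earliest on ties);
`adaptive_threshold` then maximizes validation accuracy over the
midpoints of adjacent sorted unique validation scores (sentinels at
±Inf; ties resolved to the smallest threshold, which favours
sensitivity). The frozen threshold is applied to the test split —
never fitted on it — and `eval_report` recomputes accuracy, precision,
recall, specificity and F1 from the confusion counts, returning 0 with
a warning on degenerate denominators so batch evaluation never aborts.

## The synthetic phantom

`synthetic_spec()` / `generate_dataset()` emulate the statistical
structure the attention mechanism assumes, not MRI physics:

* per-exam slice count uniform on a configurable range (default 17–61);
* smooth anatomy: Gaussian blobs shared across slices with per-slice
  random-walk drift, plus Gaussian pixel noise (`noise_sd`, default
  0.08 on a [0, 1] intensity scale);
* **end slices** (default 2 per end) carry no label signal: heavy pixel
  noise plus one to three bright blob artifacts emulating subcutaneous
  fat and coil flare — the structures that make unfiltered max fusion
  misfire;
* positive exams receive a bright circular lesion (default contrast
  0.35, the brightest compact structure in the image, consistent with
  the hyperintense appearance of tears on fluid-sensitive sequences)
  stamped into a contiguous run of slices (default 5) whose centre is
  drawn from `Normal(S/2, lesion_center_sd)` (default 1.5 slices — the
  ligament is near-midline anatomy, so its signs sit in a narrow
  central band of the stack) and clamped to the informative range;
* labels are Bernoulli draws at 20% prevalence, matching the ACL
  fraction of the real cohort; everything is reproducible from one
  seed.

What the phantom does *not* model: k-space artefacts, bias fields,
anatomically shaped ligaments, inter-site intensity variation, or
correlated annotation noise. Tests passing on the phantom demonstrate
that the mechanisms work where their structural premises hold; they do
not certify performance on real MRI.

## Training protocol and scaled-down experiment sizes

Training follows the protocol of the study this design targets: Adam,
batch size one exam, up to 50 epochs with early stopping once the
epoch-mean training loss falls below `early_stop_epsilon` (default
1e-4), best-validation-AUC checkpointing, stratified 8:1:1 splits.
Each step's gradient is clipped to a global L2 norm of 5
(`grad_clip`), a standard guard against the occasional divergent run
at desk scale. The
canonical learning rate for full-scale pretrained backbones is 1e-5;
the package default is 1e-3, appropriate for the randomly initialized
tiny backbones it ships (a rate of 1e-5 makes no visible progress at
this scale within the epoch budget).

The in-package experiments (tests and the acceptance script) run at
desk scale by design: 250 exams of 64×64 pixels with 8–16 slices, the
tiny backbone, 10 epochs, five training seeds on one fixed stratified
split. At this scale a single training run takes seconds and the full
2×2 ablation grid over five seeds runs in minutes. The slice-attention
gain over the unfiltered baseline is stable in the mean over seeds
even though individual 25-exam test AUCs are noisy. The penalty-loss
variants are *not* uniformly favourable at this scale: trained from
random initialization, the bounded expected-cost objective possesses a
majority-collapse local optimum with vanishing escape gradients (see
above), into which a minority of seeds still fall despite the
mitigations; with pretrained, already-informative features — the
regime the loss was designed for — this handicap is not expected.

## Known limitations

* The attention window implied by the unit-scale t density is narrow
  (roughly ±2–3 slices around `mu`); stacks whose informative region is
  wide rely on the similarity-driven `mu` to land well.
* The penalty loss from random initialization is sensitive to class
  imbalance (see above); with pretrained features this sensitivity
  should largely disappear.
* AUC on 25-exam test splits is granular; conclusions in this package
  are always stated over seed means.
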