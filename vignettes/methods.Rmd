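---
title: "Cascade U-net WMH segmentation: model, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascade U-net WMH segmentation: model, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhcascade)
```

## The problem

White matter hyperintensities (WMH) are bright lesions on T2-FLAIR MRI and a
core imaging marker of cerebral small vessel disease. Clinically they are
scored separately for two compartments: periventricular lesions (pvWMH),
which extend from the wall of the lateral ventricles, and deep lesions
(dWMH), which sit in deep white matter away from the ventricles. The two
compartments carry different etiologies and correlates, so a useful
segmentation tool must not only find lesions but also dichotomize them.

`wmhcascade` implements a two-stage cascade U-net that does both at once on
2D FLAIR slices, together with two comparison architectures, the training
augmentation scheme, a full metric suite, and a synthetic phantom generator
that stands in for clinical data, which are not redistributable.

## The cascade model

Stage 1 is a U-net (1 input channel, 2-class softmax) that segments the
binary WMH mask. Stage 2 is a second U-net with **2** input channels: the
original slice concatenated with stage 1's foreground probability map. Its
3-class softmax (background / pv / d) produces the final differentiated
label map by per-pixel argmax. Both stages form one computation graph, so
the joint loss propagates differentiation errors into the segmentation
weights.

The combined loss is the unweighted sum

$$CLoss = \underbrace{1 - \frac{2\sum_n p_n g_n + \epsilon}
{\sum_n (p_n + g_n) + \epsilon}}_{\text{DSC loss, stage 1}}
\; + \;
\underbrace{-\frac{1}{N}\sum_{n}\sum_{i} y_{ni}\,\log \hat y_{ni}}_{\text{CE loss, stage 2}}$$

with $p_n$ the stage-1 foreground probability at pixel $n$, $g_n$ the binary
WMH target, $\hat y_{ni}$ the stage-2 class probabilities, $N$ the pixel
count and $\epsilon = 10^{-4}$ guarding the denominator. The CE term runs
over **all** pixels of the slice, not just inside lesions, because the sum
is over $n = 1 \dots N$. Per batch, losses are means of per-slice losses,
keeping the objective batch-size invariant.

Two comparison architectures are built from the same parts:

* **pipeline** — the same two stages, but trained sequentially and
  independently: stage 1 with DSC + 2-class CE, then stage 2 with 3-class CE
  on top of the frozen stage-1 probability map;
* **separate** — two independent binary U-nets, one per lesion class, each
  trained with DSC + 2-class CE. Their thresholded masks can claim the same
  pixel; the package reports this overlap (`overlap_mask`) rather than
  resolving it, since the overlap pathology is precisely what distinguishes
  this design from the argmax partition of the cascade.

### Backbone and its numerical choices

The backbone is a Ronneberger-style encoder–decoder: two padded 3×3
convolutions + batch normalization + ReLU per resolution level, 2×2
max-pooling down, factor-2 bilinear upsampling with skip concatenation up,
and a 1×1 convolution head. Design points that the source description left
open, decided here:

* padded convolutions (output size = input size) avoid crop bookkeeping;
* batch normalization after every convolution (convolution bias is dropped
  as redundant with the BN shift);
* bilinear upsampling in the decoder;
* channel widths $C \cdot 2^{\ell-1}$; the full-scale configuration uses
  $C = 64$, tests use $C = 8$ with configurable depth;
* weight init is He-normal, deterministic given a seed; softmax-head biases
  are initialised to log class priors (98 % background), the standard
  rare-foreground stabilization — an untrained net then already predicts
  the background-dominated class frequencies, so early gradients target
  lesion pixels instead of first crushing background logits. At short step
  budgets this decides whether the rare classes emerge at all;
* argmax ties break toward the lower class index (background first), making
  the pv/d partition exact by construction;
* CE probabilities are clipped at $10^{-12}$ before the log.

The engine itself is written on BLAS matrix products (shifted-input gemm
formulation of convolution, with the input gradient computed as the "same"
convolution with the mirrored transposed kernel); analytic gradients of
every layer and of both loss terms are verified against finite differences
in the test suite.

## Training recipe

Adam with constant learning rate $2\times10^{-3}$ and default moments,
batch size 6, shuffled across subjects each epoch. The cascade's stage 1 is
pretrained alone (DSC + 2-class CE, mirroring the pipeline stage-1 recipe)
before joint training; full-scale counts are 200 pretraining + 500 joint
epochs, both configurable and counted separately since the source is
ambiguous on whether they overlap. Validation loss — the training objective
evaluated without augmentation, with batch-norm in inference mode — is
computed every epoch, and the checkpoint with minimal validation loss is the
prediction model. Slices with empty labels stay in training; the DSC loss
handles them exactly (a correct empty prediction costs 0). A non-finite
loss aborts with a diagnostic rather than training through NaNs.

Splits are subject-level: no subject's slices cross train/validation/test.
The full-scale default mirrors the study population: 253 subjects, 176
training (18 of them validation), 77 test.

### Augmentation

Five transforms, fresh draws per slice per epoch, in fixed order: gamma
intensity change first (the formula references the raw min/max, so it runs
before normalization), then one composed affine map (flip → scale →
rotation → integer-pixel shift) applied bilinearly to the image and by
nearest-neighbour to the labels. Ranges: rotation $[-30°, 30°]$, shift
$[-26, 26]$ px per axis, scale $[0.9, 1.1]$, horizontal flip with $p = 0.5$
(no per-transform probability is stated in the source; all five are applied
every epoch), $\gamma \sim U[0.5, 1]$. Out-of-frame pixels are filled with
the image minimum (background-like) and label 0. Z-score normalization is
per-slice over all pixels — the source does not state the normalization
scope, and per-slice matches the strictly 2D slice-wise input; a constant
slice maps to zeros to avoid NaN propagation.

## The phantom generator

Each phantom slice contains an elliptical bright brain (white matter 0.7),
two dark ventricle lobes (CSF ≈ 0.08, emulating FLAIR nulling), and
hyperintense lesions (white matter + `lesion_intensity`). Periventricular
lesions are caps grown from random points of the ventricle wall (plus a
confluent halo at grade 3); deep lesions are elliptical blobs placed in
mid-white-matter — their centres are kept at least ~14 % of the image
height away from the ventricle (relaxing gracefully on crowded grids, with
the tolerance invariant always enforced by clipping) and never touch a pv
lesion. The wide placement band is deliberate: it keeps the two classes'
distance-to-ventricle distributions separable rather than merely disjoint,
so the pv/d boundary a network must learn is a region, not a sub-pixel
line. Ground truth is produced by the same distance rule
that the package exposes as `assign_lesion_classes()`: an 8-connected
in-plane component is periventricular iff its minimum Euclidean distance to
the ventricle is ≤ `contiguity_tol_px` (default 1 px — "extending from the
wall" means touching, with one pixel absorbing rasterization). Because
generation and classification share the rule, re-applying the classifier to
the union mask reproduces the truth exactly, which the acceptance suite
asserts.

Burden grades 0–3 per lesion type map to monotone count/size tiers (none /
few small / more and larger / confluent). At the native 256×256 grid with
0.9×0.9×5.5 mm voxels, grade-1 subjects carry median-scale burdens of
roughly 0.6 ml pv and 0.6 ml d, matching the small early-stage lesion loads
of the emulated population (medians 0.82 and 0.44 ml). Tier radii are
floored at ~2 px so that lesions remain resolvable on the small grids used
in tests; the floors never bind at 256×256. The default cohort grade
distribution is skewed so ~90 % of subjects have total grade < 3, mirroring
an early-stage community cohort. In-plane spacing scales as
$0.9 \cdot 256 / \text{rows}$ mm, so volumes in ml are resolution-invariant.

What the phantoms do **not** emulate: brain anatomy beyond ellipses, MR
physics (noise is additive Gaussian, not Rician — phantom realism is not
the acceptance surface), bias fields, 3D lesion continuity across the
5.5 mm slices, and inter-rater ambiguity of manual delineation. Passing the
scaled-down study therefore demonstrates that the architecture, losses,
optimization and evaluation chain work end-to-end — it does not certify
clinical performance, and the original study's numbers (e.g. test DSC
0.605 for total WMH) are not reproducible without its private cohort.

## Evaluation conventions

Metrics are computed per subject over all pooled slices, then reported as
mean ± SD across subjects, matching the reporting shape of the emulated
study's tables; stratified reports group pv rows by pv grade, d rows by d
grade and total-WMH rows by total grade. TN counts run over the whole grid
(no brain mask). Empty-mask conventions: both masks empty → DSC = MCC =
precision = recall = 1; gold empty with a non-empty prediction → recall 1,
DSC = precision = 0. This is the only convention consistent with a
Fazekas-0 stratum reporting recall 1.000 ± 0.000 alongside near-zero DSC.
MCC returns 0 for degenerate denominators except the two perfect-agreement
cases (±1). Volume correlation is ordinary least squares of predicted on
gold volumes with the two-sided zero-slope p-value.

## Scaled-down study sizes

The test and acceptance runs use phantoms at 64×64 with 3 slices, easy
contrast (`lesion_intensity` 0.5, `noise_sigma` 0.02), cohorts of 40
subjects (32 train / 5 of them validation / 8 test), a cascade with
$C = 8$ and depth 2, and 10 pretraining + 30 joint epochs at the full-scale
learning rate and batch size. The augmentation shift range is scaled with
the grid (26 px at the 512 delineation grid ≈ 3 px at 64): the range is
stated in pixels for the native resolution, and an unscaled ±26 px shift
at 64×64 would move ~40 % of the anatomy out of frame, turning most
training views into crops without ventricle context. All other transform
ranges are resolution-free and stay at their native values. These sizes are the package's choice of a
desk-scale experiment: large enough that the cascade demonstrably learns
(held-out total-WMH Dice ≥ 0.6, per-class ≥ 0.5, volume $R^2 \ge 0.8$),
small enough to run routinely. The unit-test fixtures are smaller still
(32×32, depth 2, $C = 4$, 1–3 epochs) because they exercise contracts, not
accuracy.

## Known limitations

* The network engine is single-threaded R on BLAS; it is meant for
  desk-scale experiments and contract verification, not for training at
  512×512 with $C = 64$.
* Batch-norm inference statistics come from training-time running moments;
  very short runs (a few batches) evaluate with partly warmed statistics.
* The separate architecture's label-map file output codes overlap pixels as
  pv for storage only; quantitative evaluation always uses the unresolved
  masks.
* Lesion-wise detection metrics (per-component hits) and surface distances
  are out of scope; so are clinical covariate associations.
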