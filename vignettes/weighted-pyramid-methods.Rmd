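---
title: "Weighted pyramid fusion for pressure-injury staging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted pyramid fusion for pressure-injury staging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfpn)
```

## The problem and the model

Pressure-injury staging is a fine-grained, four-class image problem: the
classes share almost all of their appearance (they are all skin), and the
clinically decisive cues — granulation texture, eschar, the sharpness of an
edge, how dark a necrotic core is — live at high spatial resolution, while
class semantics live in deep, low-resolution features. The model fuses the
two: a backbone hierarchy $\{B_4, B_5, B_6\}$ (strides 16/32/64) enters a
dual-pathway neck whose every fusion site mixes its inputs by
*fast-normalized weighted fusion*

$$O = \sum_i \frac{w_i}{\sum_j w_j + \epsilon}\, I_i, \qquad w_i \ge 0
\text{ learnable}, \quad \epsilon = 10^{-4},$$

so the network learns how much each scale contributes rather than averaging
blindly. The top-down pathway projects each $B_n$ to the pyramid width with
a $1\times1$ convolution, fuses it with the upsampled level above and
smooths with a $3\times3$ convolution; the pyramid top is
$F_6 = \mathrm{Conv}_{1\times1}(\mathrm{AvgPool}(B_6) +
\mathrm{MaxPool}(B_6))$ with *global* pooling. Each $F_n$ is refined by a
CBAM block (channel attention, then spatial attention), and a bottom-up
pathway rebuilds $\{P_4, P_5, P_6\}$ by fusing each refined map with the
downsampled level below. Three per-level classifiers (global average
pooling, two fully connected layers) emit score vectors that a second
weighted rule ensembles:

$$\mathrm{pred} = \frac{\sum_k w_k\,\mathrm{out}_k}{\epsilon + \sum_k w_k}.$$

Note the asymmetry, which we implement exactly as specified: in per-site
fusion $\epsilon$ joins the weight sum inside each coefficient, while in
the ensemble it is added once to the shared denominator.

## Design choices at genuinely open points

Several details are not pinned down by the architecture description; the
package resolves them as follows and treats them as part of its definition.

* **Origin of $B_6$.** A five-stage convolutional trunk ends at stride 32.
  $B_6$ is synthesized by an extra stride-2 $3\times3$ convolution on
  $B_5$ — the construction RetinaNet uses for its P6 level. Its width is
  256 channels; the wide default profile records 1024 and 2048 channels at
  strides 16 and 32, the widths of the deepest stages of a ResNeXt-50
  trunk.
* **Backbone adapter.** The backbone is a pluggable interface: anything
  mapping an $N\times3\times H\times W$ batch to the three-level hierarchy
  with recorded channel counts works (`backbone_adapter()` documents the
  contract, and the test suite swaps in a custom profile to confirm the
  downstream contracts hold). The built-in trunk is a plain strided
  conv–BN–ReLU hierarchy, chosen so the whole network remains trainable on
  one CPU; it is not a ResNeXt replica.
* **Non-negativity of fusion weights** is enforced by rectifying the raw
  parameters; raw weights start at 1 so every input begins with equal say.
* **Resize operators.** Upsampling is nearest-neighbour (a spatial
  broadcast when the source is $1\times1$, which the global pooling in
  $F_6$ makes the rule rather than the exception at level 6); downsampling
  is average pooling at integer factors, global average pooling when the
  target is $1\times1$. Consequently the level-6 pathway carries global
  context with no spatial extent — we implement the printed equations
  literally and accept that degeneracy.
* **Lowest bottom-up node.** $P_4$ has no finer input and passes $F''_4$
  through unchanged, mirroring the special-casing at the pyramid top.
* **Per-node, per-level parameters.** Every fusion site owns independent
  scalar weights (not shared, not per-channel), and every pyramid level
  owns an independent CBAM block with reduction ratio 16 (the standard
  CBAM default; the spatial $7\times7$ convolution uses padding 3 and
  degenerates gracefully on $1\times1$ maps).
* **What gets ensembled.** The per-level outputs are raw scores (logits),
  not probabilities; the loss is cross-entropy on the ensembled prediction
  only, with no per-level auxiliary losses. Predicted label = argmax, ties
  broken toward the lowest class index.
* **Batch normalization.** The backbone stages are conv–BN–ReLU and each
  fusion smoothing convolution is followed by BN. The backbone families
  this architecture sits on are batch-normalized networks, and without
  normalization the prescribed optimizer settings (AdamW at learning rate
  $2\times10^{-4}$) cannot move a randomly initialized deep stack
  appreciably at small-data scale: activations shrink by roughly 4× per
  CBAM block alone (two sigmoid gates near 0.5), and logits at
  initialization sit orders of magnitude below one. Evaluation mode uses
  running statistics and is fully deterministic.

## Training parameters

`train_config()` carries the recipe: AdamW with initial learning rate
$2\times10^{-4}$ and decoupled weight decay $10^{-4}$; batch size 16;
input side 224 (any multiple of 32 is accepted); an 8:2 stratified
train/validation split; channel normalization by the dataset-level RGB
mean/std triples `r paste0("[", paste(pi_norm_stats()$mean, collapse=", "), "]")`
/ `r paste0("[", paste(pi_norm_stats()$std, collapse=", "), "]")` (recompute
for new data with `dataset_stats()`). The learning rate follows the cosine
closed form over the configured epoch count $E$ (default 100, configurable
— the epoch budget is an open parameter of the recipe):

$$lr(e) = lr_{\min} + \tfrac12 (lr_0 - lr_{\min})
\left(1 + \cos\frac{\pi (e-1)}{E-1}\right), \qquad e = 1,\dots,E,$$

so the first logged step is exactly $lr_0$ and the last exactly the floor
(default 0). No augmentation is applied beyond resizing and normalization.
The best-by-validation-accuracy epoch is checkpointed (parameters plus BN
running statistics).

**The stratified split** gives each class $\lfloor (1-r)\,n_c \rfloor$
validation items. On the reference cohort's per-stage totals (385, 523,
318, 293) this flooring rule reproduces every published per-stage row
(308/77, 419/104, 255/63, 235/58); the published grand totals (1,216/303)
disagree with their own row sums (1,217/302), an internal inconsistency of
the source table — the package follows the per-stage rows.

## The synthetic generator

`synthetic_spec()`/`generate_images()` emulate the *structure* of the
staging problem, not its appearance: four classes drawn over one shared
skin-toned background distribution (backgrounds never depend on the class,
so any classifier must use lesion features), differing only in
parametric lesion cues — a diffuse reddish patch (stage 1), a small
sharp-edged pale break (stage 2), a crater with dark core and granular
ring (stage 3), a large dark region with a high-contrast rim (stage 4).
Lesions are ellipses/annuli with seeded octave value-noise texture. A
`separability` scalar interpolates every class parameter between the
across-class mean (0: one shared distribution, classifiers can only reach
chance) and the full archetypes (1: maximally distinct). Defaults: 50
images per class, 64-px side, noise sd 0.05 — enough images that an 8:2
split leaves a usable validation set, at a side length that keeps CPU
training in seconds-per-epoch territory.

This is a determinism-first test fixture. It contains none of the things
that make clinical staging hard — depth information, specular lighting,
anatomical context, inter-rater ambiguity, class imbalance across centres
— so passing tests demonstrate that the architecture, optimization and
evaluation machinery behave as specified, not that the model would reach
any particular clinical accuracy. The published validation figures of the
reference experiments require the real multi-centre cohort and ImageNet
pre-training and are out of scope here.

## Numerical and degenerate-input conventions

* $\epsilon = 10^{-4}$ in both weighted rules guards division by zero; the
  fusion coefficients therefore sum to $\Sigma w / (\Sigma w + \epsilon) <
  1$, an intentional, slight shrinkage.
* Weight init: He-normal for convolutions and hidden layers; BN gains 1,
  shifts 0; all fusion/ensemble raw weights 1.
* Max-pooling ties (global and across channels) resolve to the first
  position, making every forward pass bit-reproducible.
* Metric cells with zero denominators (a class never predicted, say)
  report 0 with a logged note. A class absent from the truth has undefined
  one-vs-rest AUC and is excluded from the macro mean with a warning.
  ROC curves collapse tied scores into single threshold points, so the
  trapezoidal AUC equals the Mann–Whitney statistic with the usual ½ tie
  credit.
* Overall accuracy (trace/total) is the headline "accuracy"; macro recall
  is reported alongside, since per-stage accuracies in normalized
  confusion matrices are recalls.
* Inputs must have spatial sides divisible by 32; the hierarchy invariant
  $\mathrm{side}(B_{n+1}) = \lceil \mathrm{side}(B_n)/2 \rceil$ then holds
  for every level.

## Problem sizes used by the test suite

The suite exercises the full pipeline at fixture scale, chosen to keep a
single-CPU run in the low minutes: gradient checks on maps of a few
thousand elements; shape/contract checks at 224 px on the wide profile
(one forward pass); training runs on 32-px synthetic images with the
narrow backbone profile — a 30-epoch, 40-image overfit run, short
schedule-verification runs, and a twice-repeated 32-image end-to-end
reproducibility run; metric oracles on 100 randomized 40–56-record tables.
The README's worked example (120 images, 12 epochs) is the intended
entry-level use.

## Known limitations

Pure-R training is CPU-bound and practical up to roughly hundreds of
small images; the wide default profile is intended for forward-pass and
architecture work rather than training from scratch. Only PNG/JPEG input
is supported. Pre-trained backbone weights can be injected by assigning
into the parameter nodes, but no weight files ship with, or are required
by, the package. Unstageable and deep-tissue-injury categories are outside
the four-class scope.
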