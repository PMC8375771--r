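---
title: "Methods: comparing representations of adversarially perturbed images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing representations of adversarially perturbed images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Adversarially perturbed images dissociate perception in convolutional
classifiers from perception in people. *Adversarial-noise* (AN) images look
like structured noise to a human but are classified into a familiar
category with near-certain confidence; *adversarial-interference* (AI)
images are regular (RE) images plus a barely visible perturbation that
flips the classifier's label. Comparing how the two systems *represent*
these stimuli — rather than merely how they label them — asks whether a
system's internal geometry is consistent with its perceptual output.

`advrep` implements the full computational chain of such a comparison as a
reproducible, synthetic-data pipeline:

1. a trainable eight-stage convolutional surrogate classifier exposing
   per-stage activations and input gradients;
2. adversarial image generation against that classifier (gradient-ascent
   AN images; accept/reject hill-climb AI images; a gradient AI variant);
3. representational similarity analysis (RSA) with bootstrap and
   permutation inference and Mann-Kendall trend tests over stages;
4. a simulated cortical sheet whose vertex responses have *controllable*
   representational coupling to the regular-image responses;
5. searchlight maps and split-half-consistency vertex selection;
6. sparse forward encoding models (regularized orthogonal matching
   pursuit) trained on regular images and tested for generalization to the
   adversarial images.

Because no measured brain data ship with the package, the cortical side of
the experiment is synthetic by design: the generator records its ground
truth so that every downstream statistic can be checked against the
parameters that produced the data.

## The surrogate classifier

The model (`train_surrogate()`) follows the canonical deep-classifier
layout at desk scale: five 3x3 convolutional stages with ReLU gating
(2x2 max-pooling after stages 1, 2 and 5), two fully connected ReLU
stages, and a softmax output. Default widths are 8/16/16/16/32 channels
and 128/64 units on 32x32x3 images. Local response normalization is
omitted: it alters the surrogate only quantitatively and none of the
downstream statistics depend on it. Activations are extracted in
inference mode — there is no dropout — and the stage count is fixed at
eight so that the 5-ROI x 8-stage bookkeeping of the encoding analysis is
preserved.

Training is mini-batch Adam (rate 1e-3, batch 32) on the softmax
cross-entropy, fully deterministic given the seed. The trained model must
reach 95% held-out accuracy on the synthetic classes; a shortfall raises a
classed error with per-class diagnostics instead of silently returning a
weak model. Gradient correctness is verified against central finite
differences on a small instance of the same architecture (relative error
below 1e-3; in practice ~1e-9).

## Synthetic stimuli

Image classes (`generate_image_classes()`) are parametric: each class is a
deterministic (orientation, spatial frequency, RGB weighting) combination
rendered as a Gaussian-windowed grating, and each exemplar draws seeded
nuisance jitter (phase, window position and width, amplitude, pixel
noise). Natural-image content is irrelevant to every statistic in the
pipeline, which only sees activation vectors; parametric classes keep the
classifier trainable in seconds while the jitter rules out pixel-level
template matching. Pixels live on the familiar [0, 255] scale. The
default stimulus set is 40 classes with one regular exemplar each, so the
full experiment uses 120 images (40 RE + 40 AN + 40 AI).

## Adversarial generation

**AN images** maximize the target-class probability minus an L2 penalty
toward the mean image, \(P_c(I) - \lambda\,\lVert I - I_{mean}\rVert_2^2\),
starting from the mean image, with pixels clipped to [0, 255] after every
step and a 0.99 stopping probability. Two numerical choices matter:

* *Normalized steps.* Raw probability gradients of a confident softmax
  classifier are of order 1e-5 in pixel units, so fixed-step ascent on the
  raw gradient stalls. The ascent therefore normalizes the gradient to
  unit maximum absolute value; `step_size` (default 1.0) is the per-step
  pixel movement. The gradient can be taken on the probability (default)
  or the log-probability.
* *Proximal anchor.* The \(\lambda\) penalty is applied as an implicit
  (proximal) shrink toward the anchor after each gradient step. This is
  unconditionally stable for any \(\lambda\) and makes the
  \(\lambda \to \infty\) limit pin the image exactly to the anchor, which
  the explicit-gradient form does not. The default \(\lambda = 10^{-4}\)
  (per squared pixel unit) is a weak pull chosen once; it is exposed in
  `adversarial_config()`.

Convergence is declared when the stopping probability is reached; the
search also halts (flagged `converged = FALSE`, never silently) when the
maximum pixel change stays below 1e-3 for 10 consecutive iterations or at
the iteration cap.

**AI images** follow the accept/reject scheme: add fresh uniform noise in
[-5, 5] to every pixel, keep the perturbation only if the designated
wrong class's probability strictly increases, stop once it exceeds 0.5
(the wrong class becomes the top-1 label). The wrong class for each image
is a seeded derangement of the class labels. The gradient AI variant
reuses the AN ascent anchored at the regular image with a 0.99 stopping
probability. Hill-climbs occasionally stall on plateaus where random
noise essentially never improves the wrong-class probability; such images
are flagged unconverged and remain usable as stimuli (they are still
regular images plus bounded accumulated noise).

## The synthetic cortical sheet and response model

`make_sheet()` lays vertices on jittered unit-spaced grids, one disjoint
block per (ROI, hemisphere) with ROIs V1-V4 and LO in both hemispheres.
The sheet is already flat, so Euclidean distance on it plays the role the
geodesic flat-map distance plays on a real reconstructed surface.

`simulate_vertex_responses()` gives each vertex a source stage and a
sparse random tuning: its regular-image response is a `sparsity_k`-sparse
(default 3) linear combination of that stage's unit activations,
standardized across images, plus additive Gaussian repetition noise
(default sd 0.4, two presentations). Responses to the adversarial images
are generated at the response-pattern level:

\[ z_{AI} = \rho_{AI}\, z_{RE} + \sqrt{1 - \rho_{AI}^2}\;\epsilon, \]

and likewise for AN — an equal-variance mixture of the vertex's regular
tuning curve with independent noise. The defaults \(\rho_{AI} = 0.8\),
\(\rho_{AN} = 0\) encode the qualitative finding the pipeline is built to
study: interference images evoke regular-like cortical patterns, noise
images do not. Simulating at the pattern level (rather than feeding
adversarial images through a simulated brain) is deliberate: the coupling
becomes a directly controllable ground-truth parameter, so recovery can
be tested quantitatively (monotonicity of the estimated similarity in
\(\rho_{AI}\), null calibration at \(\rho_{AI} = \rho_{AN}\)). Blank
trials carry no signal and no betas; hemodynamics and GLM estimation are
out of scope — the dataset stands in for single-trial beta estimates.

## RSA conventions

* Dissimilarity is 1 minus Pearson correlation between item patterns
  (configurable to Euclidean). Correlation distance is the field-standard
  default for comparing response patterns of different overall gain.
* RDM comparison is Spearman rank correlation over the strictly upper
  triangle with average ranks for ties; the diagonal and lower triangle
  carry no information.
* The difference test resamples 80% of units without replacement 1000
  times; the replicate distribution supplies a percentile 95% CI and an
  add-one one-sided p-value \((1 + \#\{d \le 0\})/(n_{boot}+1)\) for the
  directional hypothesis (RE-AI above RE-AN). At `frac = 1` the replicate
  distribution collapses to the point estimate.
* Absolute similarities are tested against label-permutation nulls: the
  regular-image labels are shuffled against their patterns and the
  similarity recomputed, with the permutation nested inside the same 80%
  unit subsample as the resampling scheme. One-sided add-one p-values;
  plain (not bias-corrected) percentiles throughout.
* Trends over the eight stages use the Mann-Kendall test with
  tie-corrected variance and continuity correction.
* Both presentations are averaged before any RDM except in the
  split-half consistency map, which needs them separate.

The calibration of the directional bootstrap was checked by simulation
(equal coupling, 200 seeds): its false-positive rate at the 0.05 level
falls within [0.01, 0.10].

## Vertex selection

For each vertex, the disk of same-hemisphere vertices within 3 sheet
units is collected (disks with fewer than 3 vertices are undefined — an
RDM needs at least a few units). A regular-image RDM is computed per
presentation trial from the disk patterns and the two RDMs are compared
by Spearman correlation, yielding the consistency map; the 100 most
consistent vertices per hemisphere per ROI (200 per ROI; a 400-per-ROI
variant is one argument away) are retained. Ties break by ascending
vertex id so selection is a deterministic function of the map, and only
regular-image data enter the computation.

## Forward encoding models

Each selected vertex's regular-image responses (repetitions averaged) are
regressed on one stage's activations: \(y = Xw\) with \(X\) of size
m x (n+1), m = 40 training images, and a trailing all-ones intercept
column. Since m is far below n, the fit is the sparsest solution found by
regularized orthogonal matching pursuit: shortlist the `sparsity_s`
largest residual correlations, regularize the shortlist to its most
energetic factor-of-2-comparable subset, add it to the support, refit by
least squares, and stop at a support of `2*sparsity_s` features or a
residual below `1e-6 * ||y||`. Defaults: `sparsity_s = 10` (m/4), chosen
once as a quarter of the training size. Feature columns are standardized
on the training images (intercept exempt) because matching-pursuit
correlations are scale-sensitive; the stored scaling is reused verbatim at
test time. Rank-deficient support fits fall back to the minimum-norm
solution with a warning. On noiseless `sparsity_k`-sparse synthetic
vertices the solver matches exhaustive-subset least squares to 1e-6.

Generalization: predictions for the adversarial images are correlated
with the measured responses per vertex across images (Pearson; the
per-image-across-vertices orientation is the other natural reading and is
available by transposing the inputs), averaged over the ROI's vertices,
with an 80%-vertex bootstrap CI and an image-label permutation p per
(ROI, stage) cell. Accuracies are averaged on the r scale without Fisher
transformation; at the observed accuracy magnitudes the difference is
negligible.

## Problem sizes

The shipped analyses and tests use: a 40-class, 32x32 stimulus set with
25 training exemplars per class for the surrogate (held-out accuracy 1.0
in practice); 250 vertices per hemisphere per ROI (500 per ROI) for the
end-to-end synthetic experiment; 1000 bootstrap and 1000 permutation
replicates at full scale, scaled to 60-100 for the smoke-scale
configurations; and 200 simulation seeds for the calibration battery at
60 vertices. These sizes were chosen so the complete pipeline runs on a
single CPU in a few minutes while every count the experiment fixes (120
stimuli, 129 trials per run, 241 conditions, 40x40 RDMs, 200 selected
vertices per ROI, 40 encoding-model groups) is at its reference value.

## What the synthetic experiment does and does not show

Passing tests demonstrate that the *procedures* are correct and that the
pipeline recovers the representational structure its generator encodes:
coupled interference responses and decoupled noise responses yield the
expected similarity ordering, searchlight topology, selection behavior
and encoding generalization, with calibrated inference. They do not show
anything about measured brains: real vertex responses have spatial noise
correlations, hemodynamic structure, inter-subject variability and
retinotopic organization that the generator deliberately omits, and the
surrogate classifier is far smaller than a production network trained on
natural images. One visible consequence: mid-stage RE-AN similarities of
the surrogate are high (its AN images share the strong class-defining
spectral structure of the parametric stimuli), whereas large
natural-image classifiers show low early-stage RE-AN similarity. The
package therefore treats network-side layer profiles as descriptive
output, not as acceptance-critical quantities.

## Known limitations

* The real-network adapter is an interface contract (any object with the
  `surrogate_cnn` forward/gradient surface can be substituted); no
  pretrained weights are bundled and nothing in the tests requires them.
* Persistence uses plain-text containers (CSV/JSON); there is no HDF5
  dependency.
* No noise-ceiling estimation and no RDM model comparison beyond the two
  pairwise similarities.
* The blank-trial placement within a run is uniformly random; the
  reference experiment does not specify it.
* `sparsity_s`, \(\lambda\), step size and iteration caps are declared
  defaults, not estimates of any reference implementation's values.
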