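---
title: "CANet: model, training and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CANet: model, training and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canet)
```

This vignette is the package's account of the science it implements:
the autoassociative model, the exact algebra of the laterally inhibited
reconstruction layer, the constructive-pruning architecture search, the
committee decision rule, and the numerical and design choices made where
the method leaves room. It states no empirical number that the test
suite or `scripts/acceptance.R` does not itself compute.

## The model

A CANet learns *one* class of images from positive examples only. It is
a three-layer autoassociator whose target output is its input:

* **Input layer.** One weight $w^I_{u,v}$ per pixel. Intensities are
  normalized to $[0,1]$ (8-bit value / 255) because the output layer is
  sigmoidal and can only reproduce values in $(0,1)$.
* **Hidden (constructive) layer.** Each hidden neuron $j$ owns a
  rectangular receptive field $R_j$; the fields are pairwise disjoint
  and tile the image exactly, and the same footprint is used in the
  input and output layers. The neuron computes
  $z^C_j = b_j + \sum_{(u,v)\in R_j} w^I_{u,v}\,x_{u,v}$,
  $y^C_j = \varphi(z^C_j)$ with $\varphi(z) = 1/(1+e^{-z})$.
* **Reconstruction layer.** One neuron per pixel, *without* bias, so
  every output neuron inside a receptive field receives the same
  excitatory stimulus $e_{u,v} = w^H_j\, y^C_j$. Lateral inhibition
  couples neighboring output neurons (below), and the reconstruction is
  $y^O_{u,v} = \varphi(z^O_{u,v})$.

The bottleneck (few hidden neurons, one output neuron per pixel) forces
the hidden layer to extract features; reconstruction accuracy on a new
image then measures membership of the learned class.

### Lateral inhibition: the exact algebra used

The inhibitory field is parameterized by a radius $I$ (pixels) and a
strength $A > 0$. This package fixes the algebra as:

$$h_{u,v} = \frac{1}{A}\cdot\frac{1}{|N_I(u,v)|}\sum_{(p,q)\in N_I(u,v)} e_{p,q},
\qquad z^O_{u,v} = e_{u,v} - h_{u,v},$$

where $N_I(u,v)$ is the square neighborhood of Chebyshev radius $I$
centered on $(u,v)$, **excluding the pixel itself** and truncated at the
image borders. The design constraints behind this choice:

* the three stimuli are computed in one feed-forward sweep (excitatory,
  then inhibitory from the *same-sweep* excitatory values, then
  activation) — no recurrent settling;
* larger $A$ means weaker inhibition, and `enabled = FALSE` is exactly
  the $A \to \infty$ limit (verified to $10^{-9}$ in the tests; $I = 0$,
  an empty neighborhood, behaves identically);
* the *mean* over the neighborhood (rather than the raw sum) keeps the
  inhibitory term on the scale of a single excitatory stimulus
  regardless of $I$ and of border truncation, so the same strength $A$
  is meaningful at every image size and position. With the default
  $A = 17$ the inhibitory term is a mild, contrast-like correction
  rather than a dominant drive.

Defaults are $I = 6$, $A = 17$, the best configuration of the method's
published parameter study on 40×40 face images. For the 16×16 synthetic
benchmarks below the package uses $I = 2$, the same field scaled to the
smaller image.

## Training

The loss is $E = \tfrac12\sum_{u,v}(y^O_{u,v}-x_{u,v})^2$ per image,
summed over the full batch. Backpropagation proceeds in the reverse of
the forward sweep. With $\delta^O = (y^O - x)\,\varphi'(z^O)$, the
sensitivity of the excitatory stimulus must account for every output
neuron whose inhibitory field contains the pixel (the transpose of the
inhibition coupling, including the $1/|N_I|$ border weights):

$$\frac{\partial E}{\partial e_{u,v}} = \delta^O_{u,v}
  - \frac{1}{A}\sum_{(p,q)\,:\,(u,v)\in N_I(p,q)}
    \frac{\delta^O_{p,q}}{|N_I(p,q)|}.$$

From there, per hidden neuron $j$ with region sum
$S_j = \sum_{(u,v)\in R_j} \partial E/\partial e_{u,v}$:
gradients are $\partial E/\partial w^H_j = y^C_j S_j$,
$\delta^C_j = \varphi'(z^C_j)\, w^H_j S_j$,
$\partial E/\partial b_j = \delta^C_j$, and
$\partial E/\partial w^I_{u,v} = \delta^C_{j(u,v)}\, x_{u,v}$.

This is the exact chain rule of the forward pass; the binding contract
is the central-difference oracle (`numeric_gradient()`), against which
the analytic gradients agree to a relative error below $10^{-5}$ for
every parameter class, with inhibition on and off, across 100 seeded
cases in the acceptance tests. The "sensitivity of the same layer" is
therefore aggregated *after* the output sigmoid derivative is applied;
aggregating the raw image error first would not differentiate the loss
and would fail the oracle.

### RProp

Weights are updated with resilient propagation, which uses only the
gradient *sign* over the full batch with a per-parameter adaptive step
$\Delta$:

* same sign as the previous epoch: $\Delta \leftarrow \min(\Delta\,\eta^+, \Delta_{max})$,
  step $-\mathrm{sign}(g)\,\Delta$;
* flipped sign: $\Delta \leftarrow \max(\Delta\,\eta^-, \Delta_{min})$,
  the stored gradient is cleared and **no step is taken** that epoch
  (the no-backtracking variant, chosen so single steps are exactly
  reproducible in tests);
* zero gradient: nothing moves.

Constants are the standard published defaults
($\eta^+ = 1.2$, $\eta^- = 0.5$, $\Delta_0 = 0.1$,
$\Delta_{min} = 10^{-6}$, $\Delta_{max} = 50$), overridable in
`train_config()`. The epoch budget defaults to 200 with patience 20 on
the validation mean absolute error (MAE); MAE is only a monitoring
metric — the optimized loss stays quadratic. `fit()` restores the
parameters with the best validation MAE, so early stopping never
returns a worse model than an earlier epoch.

Weight and bias initialization is uniform on $[-0.1, 0.1]$ under the
configured seed. The scale is small enough that initial hidden inputs
sit on the quasi-linear part of the sigmoid yet large enough to break
symmetry; it is recorded in the model container, and all fits are
deterministic given seed, configuration and data.

## Constructive-pruning architecture search

`build()` starts from one hidden neuron covering the whole image,
fitted on all parameters. Each iteration then:

1. computes the per-pixel mean absolute reconstruction error over the
   training images;
2. scores each leaf by the **spread** (max − min) of that surface over
   its receptive field — a leaf with very uneven error mixes
   heterogeneous image regions and is the most promising split;
3. expands the eligible top scorer (ties: smallest id) by quadtree
   division, and refits with only the affected connections trainable;
4. stops when another expansion would exceed `n_max` hidden neurons or
   no leaf is divisible, and returns the snapshot with the lowest
   validation error regardless of its size.

Design choices where the procedure was genuinely open:

* **Quadrant sizing for odd sides.** The first block takes the ceiling
  ($\lceil h/2\rceil \times \lceil w/2\rceil$); only even splits are
  prescribed by the quadtree description, and the ceiling-first rule
  keeps children as balanced as possible.
* **Parent persistence.** Splitting adds *three* neurons while the
  field divides into four, so the expanded neuron survives holding the
  top-left quadrant with its trained output weight and bias — the three
  newcomers get seeded fresh parameters and record the parent's
  position as their label.
* **Retraining scope.** After an expansion, the four quadrant neurons'
  output weights and biases plus the input-pixel weights inside the
  parent's original field are trainable; everything else is frozen
  (the one-hidden-layer constructive strategy of freezing previously
  trained weights). Frozen parameters are bitwise untouched, optimizer
  state included.
* **Eligibility.** Leaves with either side of length 1 cannot divide
  into four and are skipped; a grid of 2×2 images therefore allows at
  most one expansion.
* **Default `n_max`.** 25% of the pixel count, the best-performing
  ratio in the method's published parameter study.

### Pruning

After the constructive search, `prune()` ranks every output neuron by
its mean absolute error over the training images and retains the
`r_keep` best (default 50% of the pixels, again the published best
setting); ties break in row-major pixel order so the selection is
deterministic. Pruning only sets the retained mask — weights and the
forward pass are untouched, and the mask restricts which pixels enter
the dissimilarity measure. Pruning after (not before) the
validation-based snapshot selection matches the order of the original
procedure: the architecture is chosen first, then the unreliable output
neurons are dropped.

## Committee classification

The dissimilarity between an image and a class model is the mean
absolute difference $\frac{1}{|M|}\sum_{(u,v)\in M} |y^O_{u,v}-x_{u,v}|$
over the retained pixel set $M$. Normalizing by $|M|$ makes distances
comparable across committee members with different masks, which the
minimum-distance decision requires. `classify()` returns the argmin
label (ties: first class in committee order, which is first-appearance
order of the training labels) along with the full distance vector;
`evaluate()` reports accuracy and a row-normalized confusion matrix.

Per-class training is fully independent: the seed of each member is
derived from the class *label* (not its position), so reordering the
training data cannot change any member's weights.

## The synthetic fixture

`make_prototypes()` builds one smooth prototype per class — a seeded
mixture of 2–4 signed Gaussian bumps plus one oriented sinusoidal
grating, min-max normalized to $[0,1]$ — and redraws the set (bounded
retries) until every pair differs by a mean absolute distance of at
least $5\sigma$, i.e. well above the pixel noise. Images are the
prototype plus i.i.d. Gaussian noise clipped to $[0,1]$ (clipping, not
renormalization, keeps pixels independent). The bump-plus-grating
design gives classes *spatially localized* differences, which is what
exercises the quadtree's region-targeted expansion.

The fixture's default conditions, used by the tests and the
reproduction script, are: 3 classes, 16×16 pixels, $\sigma = 0.05$, 12
images per class, half of them training. The benchmark training
configuration is 60 epochs with patience 12, `n_max = 13` (four
expansions), `r_keep = 128` (50% of pixels), inhibition $I = 2$,
$A = 17$. These sizes keep a full committee run in the order of a
second while leaving the search non-trivial.

What passing these benchmarks does and does not show: the fixture has
smooth, well-separated classes with homogeneous noise, no pose or
illumination variation, no occlusion, and no class imbalance. Success
demonstrates that the machinery — gradients, growth, pruning,
committee — works as specified, not that the method reaches any
particular accuracy on real face databases.

## Numerical choices and degenerate inputs

* Gradient checks use central differences with $\varepsilon = 10^{-5}$
  and relative error $|a-n|/\max(|a|,|n|,10^{-6})$; the floor only
  guards division when both gradients vanish.
* The inhibition sums are computed with a padded summed-area table, so
  a forward or backward pass is $O(HW)$ regardless of $I$.
* Histogram equalization uses the textbook 256-bin rule
  $(\mathrm{cdf}(v)-\mathrm{cdf}_{min})/(N-\mathrm{cdf}_{min})$ on the
  8-bit quantization; a constant image (degenerate histogram) is
  returned unchanged.
* PGM writing quantizes with round-half-up; P2 and P5 dialects encode
  identical pixels. Rescaling is bilinear (via EBImage).
* The model container stores doubles as `%.17g` strings inside JSON:
  plain JSON numbers do not round-trip the last bits, and the package
  guarantees bitwise-identical forward outputs after save/load.
* Degenerate constructions error early with actionable messages:
  non-positive image dimensions, empty batches, out-of-range `r_keep`,
  regions outside the grid, dimension mismatches, unknown leaf or
  parameter ids, version-bumped or truncated model files.

## Known limitations

* Receptive fields never overlap and there is a single hidden layer;
  overlapping fields, non-square inhibitory fields and deeper models
  are out of scope.
* The committee has no rejection option: every probe is assigned the
  nearest class even when all distances are large.
* Full-batch training only; the constructive loop refits after every
  expansion, so training cost grows linearly with the number of
  expansions.
* The synthetic generator does not attempt photorealism or the
  statistics of face databases; external datasets can be plugged in
  through the manifest + PGM/PNG interface and the preprocessing chain
  (crop, rescale, equalize), whose crop rectangle and target size are
  configuration values.
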