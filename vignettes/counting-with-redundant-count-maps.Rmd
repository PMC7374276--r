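---
title: "Counting cells with redundant count maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cells with redundant count maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcountr)
```

## The counting problem and the model

Cultured epithelial-like cells imaged in phase contrast are hard to count
by segmentation: their outlines are polymorphic and non-convex, their sizes
vary, and they grow in dense, overlapping clusters. `cellcountr` sidesteps
segmentation entirely. Each cell is annotated by a single pixel, and a
fully convolutional network is trained to regress a *redundant count map*:
output pixel $(i, j)$ predicts how many annotated cells fall inside the
$k \times k$ window centred on it. Every cell therefore contributes to
exactly $k^2$ output pixels, and the image count is recovered as

$$\hat N = \frac{1}{k^2} \sum_{i,j} \hat y_{ij}.$$

Because each cell is counted $k^2$ times, independent per-pixel errors
partially cancel in the sum (redundancy averaging); counts are kept as
reals and only rounded for display.

Targets use the *full-convolution* extent: for an $H \times W$ frame the
map is $(H + 2p) \times (W + 2p)$ with $p = (k-1)/2$, and images are
padded with $p$ zero pixels per side before prediction. This is the only
extent in which a cell at the frame border still contributes exactly $k^2$
pixels, which the $\sum / k^2$ rule requires. With the default $k = 65$,
$p = 32$ and a $1040 \times 1392$ frame quarters to $520 \times 696$
tiles padded to $584 \times 760$.

## Architecture

The network is an inception-style fully convolutional regressor:

* stem: $3 \times 3$ convolution;
* five inception blocks, each concatenating parallel $1 \times 1$ and
  $3 \times 3$ convolutions;
* a chokepoint ($1 \times 1$ convolution halving the channel count);
* two large same-padded convolutions whose kernels are sized so the
  nominal receptive field reaches $k$ (for $k = 65$:
  $3 + 5 \cdot 2 + 26 + 26 = 65$, i.e. two $27 \times 27$ kernels; for
  $k = 33$: two $11 \times 11$);
* a final chokepoint ($1 \times 1$ convolution to one channel, linear).

All convolutions are stride-1 with zero same-padding, so the spatial
extent is preserved end to end — "chokepoints" reduce channels, never
spatial size, because any spatial reduction would break the counting rule.
Batch normalisation follows every convolution or inception block except
the output; activations are rectified linear; weights are Glorot-uniform.
A configuration whose receptive field is below $k$ is rejected at
construction: an output unit that cannot see the whole $k \times k$ target
window cannot predict its count.

Since no deep-learning framework is a dependency, the network — forward
pass, backpropagation, spatial batch normalisation, Adam — is implemented
in compiled code inside the package. Convolutions are computed as $k^2$
shifted GEMMs, which keeps temporaries cache-sized; gradients are verified
against numerical differentiation in the test suite.

### Numerical choices

* **Loss.** Mean absolute error per count-map pixel (the choice of the
  antecedent count-map work) or mean squared error via
  `model_spec(loss = "l2")`. L1 regresses the conditional median, which
  under imperfect features biases counts low; L2 regresses the mean and
  is count-unbiased, which matters when the epoch budget is small — the
  reduced-scale protocol below therefore uses L2.
* **Count-consistency term.** A per-pixel loss is nearly blind to a
  small uniform bias whose integral over a tile amounts to whole cells
  (one cell spread over a 96 × 96 tile moves each pixel by about 0.1),
  yet that integral is exactly what the method reports. The training and
  validation loss therefore add a squared per-tile count error,
  `count_loss_weight * ((sum(pred) - sum(target)) / k^2)^2`, with a small
  default weight (0.005) — the term's gradient is spatially coherent, so
  large weights destabilise training. This also makes best-epoch
  selection sensitive to counting accuracy rather than pixel accuracy
  alone.
* **Gradient clipping.** With batch size 1, single-tile gradients spike
  on dense clusters; the global gradient norm is clipped (default 5)
  before each Adam step, which smooths the validation trajectory that
  best-epoch selection depends on.
* **Tile loss weights.** Training items carry a loss weight; red-masked
  tiles default to weight 4 because their sparse targets would otherwise
  contribute an order of magnitude less loss than plain tiles and remain
  under-fit.
* **Batch normalisation.** With batch size 1, training-mode statistics
  are per-channel spatial moments of the single tile. Running averages
  (momentum 0.99) are tracked during training and frozen at inference,
  so prediction is deterministic, and strictly local: one output unit is
  influenced only by its nominal receptive field. The test suite verifies
  this locality by single-pixel perturbation probing.
* **Output clipping.** The final layer is linear; negative raw outputs
  are clipped to zero before count inference.
* **Model selection.** Per-epoch validation loss is recorded and the
  weights of the epoch with the lowest validation loss are kept (first
  occurrence on ties). The recorded validation loss uses a stronger
  count-error weight (`select_count_weight`, default 0.1) than the
  training gradient: selection can afford full sensitivity to count bias
  because it takes no gradient steps, whereas the training term must stay
  small for stability. Two epochs with near-identical pixel loss can
  differ by whole cells per tile; selection must see that.
* **Determinism.** Weight initialisation and epoch shuffling draw from a
  seeded private RNG stream; fixed-seed runs reproduce loss curves
  bit-for-bit.

## Training protocol

The full-scale defaults in `train_config()` follow the published
protocol: Adam, learning rate 0.001, batch size 1, 400 epochs, an 8:2
train/validation split of the labelled corpus, and augmentation by the
three 90-degree rotations. Tiles are the quadrants of full frames
(rows and columns split at the floor of the half-extent), padded by $p$;
each frame annotation falls in exactly one quadrant, so quadrant counts
add to frame counts exactly when predictions are exact.

## Fluorescent-positive counting

Red-fluorescent (biosensor-positive) cells are counted by binarising the
red channel at an intensity threshold in $[0, 255]$ (inclusive $\ge$;
service default 100), zeroing the grayscale image outside the mask, and
running the ordinary counting model on the masked image. RGB frames are
converted to grayscale with the ITU-R BT.601 luma weights
($0.299 R + 0.587 G + 0.114 B$); the counting model itself always takes
one grayscale channel. At threshold 0 the mask passes everything, so the
red count equals the plain count of the grayscale image by construction.

Masked frames are mostly black — far from the phase-contrast background
the counter is otherwise trained on. The training pipeline therefore can
emit, per training frame, an additional red-masked quadrant set annotated
with the red cells only (`prepare_training_tiles(red_masked = TRUE)`),
which puts masked inputs in-distribution. This is a deliberate departure
from treating fluorescent counting as pure inference-time composition;
without it a counter trained only on plain tiles has undefined behaviour
on the masked distribution.

## The synthetic scene generator

Real annotated microscope frames are not distributable with the package,
so all end-to-end behaviour is exercised on a seeded generator of
phase-contrast-like scenes that emulates exactly the properties that make
the problem hard:

* **morphology** — cells are radially perturbed ellipses (star-convex,
  non-convex outlines; `shape_irregularity` scales harmonic amplitudes),
  with variable radii and orientations, dark interiors and a bright halo
  rim on a noisy mid-gray background;
* **clustering** — a fraction of cells (default 0.5) is placed by a
  Thomas cluster process (uniform parents, Gaussian offspring,
  `cluster_sd` 9 px), the rest uniformly; bodies may overlap, centroid
  marks stay at least 2 px apart and are deduplicated to distinct pixels;
* **fluorescence** — `round(red_fraction * n_cells)` cells are painted
  into the red channel at an intensity drawn from `red_intensity_range`
  (default 160–240); the red channel otherwise carries only a 25%
  bleed-through of the phase signal plus noise, mimicking a composite in
  which the fluorescence channel maps to red, so thresholding separates
  positives at any sensible threshold;
* **ground truth** — the one-pixel annotation of each cell is the integer
  centroid of its body, so scenes are their own oracle.

Default conditions: 128 × 128 px scenes with 40 cells (about the areal
density of a half-confluent culture at the reduced scale), noise SD 6 on
a background of 128, red fraction 0.2. The generator does **not** emulate
photorealistic phase-contrast optics, illumination gradients, debris, or
mitotic/apoptotic morphology changes — passing tests on synthetic scenes
demonstrates that the method's machinery is correct, not that the shipped
configuration reaches any particular accuracy on real cultures (the
bundled 26-image benchmark table documents what full-scale training
achieved on real data).

## Reduced-scale study conditions

The test suite and the acceptance script train a reduced instantiation
chosen to keep a CPU-only run in minutes: $k = 33$, stem 12 channels,
inception branches 6 + 6, chokepoint 6, large convolutions 6 channels;
a 16/4/8 train/validation/test suite of 128 × 128 scenes (the 16:4 split
mirrors the 8:2 labelled-corpus bookkeeping); quadrant tiles 64 × 64
padded to 96 × 96; 50 epochs without rotation augmentation (quartering
alone yields 64 training tiles, and the masked-tile variants double
that); Adam with the default learning rate 0.001, decayed ×0.1 after
60% of the epochs, L2 count-map loss plus the count-consistency term,
gradient clipping at norm 5, and masked tiles weighted 4. Held-out
performance is measured as mean relative count error over the 8 test
scenes, for total counts and for red counts at threshold 100.

## Evaluation metrics

Per image: absolute error $|\hat N - N|$ and relative error
$100 \, |\hat N - N| / N$ (the denominator is the expert count).
Aggregates: mean per-image relative error, totals, the overall difference
$100\,|N_\Sigma - \hat N_\Sigma| / N_\Sigma$ — which is typically smaller
than the mean per-image error because signed errors cancel across images
— the maximum per-image error, and the fraction of images under a 5%
error. The package ships a published 26-image benchmark table
(`benchmark_counts()`) whose printed per-image and aggregate statistics
are reproduced exactly by `evaluate_counts()` / `summarize_counts()`.

## Time-course statistics

Batch counts join a sample sheet into tidy records (group, dose, field of
view, time index, total and red counts, red percentage). Because groups
start at different baseline percentages, each field's series is
baseline-subtracted (first value subtracted from all values). Endpoint
changes per field are compared between all group pairs with a two-sided
Mann–Whitney test: mid-ranks under ties, reported statistic
$U = \min(U_a, U_b)$, and a two-sided p-value computed by exhaustive
enumeration of all group assignments for combined sizes up to 12 —
exact under ties, and deterministic where common implementations switch
behaviour — with the tie- and continuity-corrected normal approximation
above that. Bonferroni correction multiplies by the number of pairs,
capped at 1. Regression-style longitudinal modelling (e.g. Poisson GEE)
is out of scope by design: the tidy records CSV is the hand-off point to
any standard tool.

## Known limitations

* Cells whose bodies straddle a quadrant boundary can be fractionally
  counted in both quadrants by a real model; annotations never are. This
  matches the frame-quartering design (no overlap-tiling) and is an
  accepted error source.
* The counter is only calibrated on inputs resembling its training
  distribution. A completely featureless mid-gray frame — which the
  fixture suite never contains, since every scene carries cells — is an
  extrapolation, and the reduced-scale model can assign it a nonzero
  count; empty-field behaviour should not be inferred from the synthetic
  benchmarks. (All-black frames, which masked training tiles do cover,
  count near zero.)
* The bundled reduced-scale network is sized for CPU minutes, not
  accuracy parity with the full-scale configuration.
* Fluorescent counting inherits any red/gray channel cross-talk of the
  input composite; only the red channel is thresholded (no green/blue
  filters).
* The JSON-RPC server is a minimal single-threaded loop intended for
  local scripting; the handler function is the tested surface.
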