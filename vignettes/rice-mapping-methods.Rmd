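---
title: "Phenology-aware rice mapping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenology-aware rice mapping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricesits)
```

## The problem

Mapping paddy rice from optical satellite time series is hard exactly where
it matters most: humid subtropical plains where the rice season coincides
with the cloudy season, and where urbanization has fragmented fields into
small, scattered parcels. Single-date classification fails there for two
reasons. First, individual clear scenes are scarce during the growth
period, so any given date may be missing for a given pixel. Second, at many
single dates rice is spectrally confusable with weeds, other crops, or
moist soil. What is distinctive about rice is its *trajectory*: transplanting
into flooded fields (low canopy cover, high surface water), a steep
green-up through tillering and heading, and senescence with field drainage
before harvest.

`ricesits` implements a complete pipeline built around that idea:

1. **Reconstruction** of per-pixel vegetation-index series through clouds
   (quality masking, Savitzky-Golay smoothing, harmonic-regression gap
   filling).
2. **Phenological features**: NDVI, LSWI and EVI per time step, plus two
   temporal-derivative families — the temporal difference TDVI
   (`VI(t+dt) - VI(t)`) and the normalized change rate NCRVI
   (`(VI(t2) - VI(t1)) / VI(t1) x 100`) — which encode green-up and
   senescence rates explicitly.
3. **A time-series transformer** with phenology-specific enhancements:
   a parallel three-branch input embedding recalibrated by channel
   attention, adaptive positional encodings built from the day of year, a
   phenology attention gate on the encoder outputs, and an optional
   3D-convolutional spatio-spectral patch branch.
4. **Leakage-safe evaluation**: polygon-group train/test splitting,
   confusion-matrix metrics with Cohen's kappa, and paired McNemar
   comparisons between classifiers.
5. **A synthetic scene generator** that emulates the statistical structure
   this method assumes, so the full pipeline is testable end to end with no
   satellite downloads.

## Time-series reconstruction

Observations are masked using scene-classification quality codes; the
default mask set is cloud shadow (3), water (6), medium/high-probability
cloud (8, 9), cirrus (10) and snow (11), configurable wherever it appears.

Smoothing and gap filling are deliberately split into two stages, in this
order: first a **Savitzky-Golay filter** for local noise reduction of the
*valid* observations, then a **harmonic regression** fitted to the smoothed
valid observations to estimate the cloud-obscured values. Fitted values
replace gaps only; valid observations are never overwritten by the harmonic
model. The alternative (replacing everything with the fitted curve) would
discard real high-frequency signal that the transformer could use.

Two choices here are worth justifying:

* **SG on the day-of-year axis.** The classical filter assumes uniform
  sampling; after cloud masking the valid subsequence is irregular. We
  therefore fit the local least-squares polynomial in day-of-year
  coordinates (window of 7 valid observations, degree 2 by default; at the
  series boundaries the window is shifted, not shrunk). This keeps the
  filter exact for polynomials up to the chosen degree on *any* grid — the
  property the test suite asserts at 1e-9 — and reduces to the classical
  filter on uniform grids (cross-checked against `signal::sgolayfilt` in
  the tests). Window 7 at a 5-day revisit spans ~35 days, long enough to
  suppress observation noise and short enough not to flatten the
  transplanting trough.
* **Harmonic order K = 2, period 365 days.** One harmonic captures a single
  annual green-up/senescence cycle; the second captures its asymmetry
  (fast green-up, slower senescence). Higher orders start fitting noise at
  the ~20-30 valid observations per season typical here; the fit requires
  at least `2K + 1` valid points and raises an error naming the sample
  otherwise.

## The feature set

All indices use Sentinel-2 band conventions (B2 blue, B4 red, B8
near-infrared, B11 shortwave infrared), reflectances in [0, 1]:

* `NDVI = (B8 - B4) / (B8 + B4)` — canopy greenness;
* `LSWI = (B8 - B11) / (B8 + B11)` — surface/canopy water, the flooding
  signal that separates paddies from dryland crops;
* `EVI = 2.5 (B8 - B4) / (B8 + 6 B4 - 7.5 B2 + 1)` — the standard
  three-band formulation with the blue-band aerosol/soil correction,
  useful where NDVI saturates at high biomass.

TDVI and NCRVI are computed **between consecutive valid time steps** for
each of the three indices; the first valid step receives 0, a convention
that is padding-neutral after standardization. The day gap to the previous
valid step is carried as metadata but TDVI is deliberately a plain
difference, not a rate — the adaptive positional encoding already informs
the model about irregular spacing, and dividing by small, gap-dependent
intervals would amplify reconstruction noise.

The `complete` preset therefore has 9 channels (3 indices x {level, TDVI,
NCRVI}). Whether the derivative families should cover all three indices or
NDVI only is genuinely open; both are implemented (`complete` vs
`ndvi_deriv`), with `complete` the default since the ablation presets need
the full factorial. NCRVI is guarded: when the baseline value is within
1e-6 of zero the rate is undefined and 0 is emitted with a flag.

Standardization (per-channel mean/sd) is fitted on training samples only
and stored with the model; test data is always scaled by the frozen
training statistics. Standard deviations are floored at 1e-8.

## The classifier

The backbone is a post-norm transformer encoder — 4 layers, 8 heads, model
dimension 64, feed-forward dimension 256, GELU activations, dropout 0.1
throughout, masked global average pooling and a two-layer MLP head with
softmax. On top of it sit four enhancements, each independently switchable
(which is what the architecture-ablation presets toggle):

* **Three-branch embedding** (`embed_multibranch`): per time step the
  feature vector passes through (A) an affine projection, (B) a two-layer
  GELU perceptron, and (C) all `C(C+1)/2` pairwise feature products
  projected down — direct features, deep abstractions and explicit feature
  interactions. The concatenation is recalibrated by squeeze-and-excitation
  channel attention (masked temporal mean, bottleneck, sigmoid weights) and
  projected to the model dimension.
* **Adaptive positional encoding** (`pos_adaptive`): the sum of (a) a
  learnable embedding of the phenological stage bin of the day of year —
  transplanting below DOY 172, growth to DOY 258, ripening above, bin
  edges configurable — and (b) a learnable affine map of sinusoidal DOY
  features. Encodings depend only on the DOY, never on the sequence index,
  which is what makes irregular, gap-ridden sampling well-posed. The
  non-adaptive fallback is the fixed sinusoid.
* **Phenology attention gate** (`gate_enabled`): a two-layer sigmoid MLP on
  the concatenation of each encoder output token with its positional
  encoding produces per-dimension gates in (0, 1) that rescale the token —
  the model can amplify time steps from informative growth stages before
  pooling. Disabled, the stage is the identity.
* **Spatio-spectral patch branch** (`use_patch_branch`): two 3D
  convolutions (3x3x3 kernels, stride 1, same padding, 64 filters, GELU)
  over the P x P x bands neighborhood of each pixel, flattened and
  projected, applied time-distributed and added to the feature embedding.
  The default patch size is 5. This branch is off by default: the package's
  primary inputs are index sequences, and joint 3D-conv training is
  expensive on one CPU core; it is fully implemented (forward and backward,
  covered by the gradient checks) for patch-based work.

Where the two embedding pathways meet, fusion is additive in the model
dimension — the simplest junction consistent with both being "token
embeddings". Masked time steps are excluded from attention (as keys), from
the channel-attention squeeze and from pooling, so a masked step is exactly
equivalent to a deleted one; the test suite asserts this to 1e-10.

### Implementation

No deep-learning framework is available in this stack, and the model *is*
the package's core, so the network is implemented from first principles in
C++ (RcppArmadillo): forward pass, fully hand-derived backward pass, and
AdamW. The code is templated on the floating type — float for training
throughput on a single CPU core, double for inference and for verification.
Correctness of the backward pass rests on central-finite-difference
gradient checks run in double precision with every module enabled
(multibranch embedding, channel attention, adaptive encodings, gate, patch
branch, masking); agreement is at the 1e-11 level, far below any
plausible implementation error.

GELU uses the sigmoid form `x * sigmoid(1.702 x)` — a standard, cheaper
variant of the exact Gaussian form — identically in forward and backward
passes. Attention uses hand-rolled masked softmax kernels; dropout masks
come from a dedicated xorshift generator seeded from the run seed, so
training is bit-reproducible given the seed under single-threaded BLAS.

### Optimization

AdamW (learning rate 1e-3, decoupled weight decay 0.01 applied to weight
matrices only), cross-entropy loss, batch size 32, global gradient-norm
clipping at 1.0, and cosine annealing by default with reduce-on-plateau
available (factor 0.5, patience 5, monitoring a validation split of 10% of
the *training polygons* when none is supplied). Weights are initialized
Xavier-uniform, biases zero, deterministically from a seed. The published
configuration trains 100 epochs; the package default follows that, while
the bundled experiments use fewer (below). The feed-forward width is an
acknowledged ambiguity in its source — both 256 and "2x the hidden
dimension" (= 128) are stated; we follow the explicit 256.

Training aborts with diagnostics if the loss becomes non-finite. The
gradient-clip count, per-epoch loss/accuracy/learning rate and optional
validation metrics are returned as the training history.

## Evaluation

Rice is the positive class. Besides accuracy, precision, recall and F1, we
report Cohen's kappa in its standard form `(Po - Pe) / (1 - Pe)` with
`Pe = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN)) / N^2`. Ratios with empty
denominators are reported as `NA` with a flag, never silently as 0 or 1.

Paired model comparisons use the McNemar test on discordant predictions,
`(|b - c| - 1)^2 / (b + c)` with the continuity correction by default (the
uncorrected form is available; with no discordant pairs the statistic is 0
and p = 1). No multiple-comparison adjustment is applied by default, since
the comparisons are reported as individual paired tests; a Bonferroni
option would be a one-line wrapper for users who need it. A deliberately
weak comparator, a temporal-mean logistic regression, is included so the
paired test has a meaningful partner in the synthetic experiments: it sees
the same features aggregated over time but none of the trajectory shape.

Train/test splitting is **polygon-grouped**: all sample points of a field
polygon go to the same side, stratified by label at the polygon level.
Point-level splits would leak, since points within a polygon share
phenology up to pixel noise, and the generator reproduces exactly that
correlation structure so the tests can demonstrate the difference.

## The synthetic scene generator

The generator is first-class, tested code, not a fixture. It emulates the
structure the method assumes:

* **Acquisition**: a 5-day revisit from DOY 152 to 304 (early June to late
  October, T = 31 steps) — one full single-season rice cycle.
* **Rice phenology**: a double-logistic NDVI curve parameterized by stage
  durations (transplanting ~18 days within 10-30, growth ~90 within
  60-110, ripening ~42 within 30-60; transplanting onset DOY 160). The
  green-up ramp is centered at 45% of the growth period with rate
  0.16 x growth length; the senescence ramp at 60.5% of the ripening
  period past the growth end with rate ripening/8. These constants were
  chosen so the curve provably rises throughout the growth window and
  falls throughout ripening (the TDVI sign structure the features rely
  on), verified numerically in the tests. NDVI spans 0.35 (transplanting,
  sparse canopy over water) to 0.85 (full canopy). LSWI follows a
  flood-drawdown: ~0.35 while flooded, draining toward ~0.02 from ~70% of
  the growth period.
* **Confusers**: water (flat NDVI -0.15, high LSWI), urban (flat low
  NDVI), forest (high NDVI with a mild seasonal cosine), and `other_crop`
  — a rain-fed crop with a rice-like canopy curve shifted ~5 weeks earlier
  and essentially no flooding signal. The last is the scientifically
  interesting one: it forces the classifier to use trajectory timing and
  moisture dynamics, not peak greenness.
* **Bands from indices**: reflectances are generated by inverting the
  index definitions given a near-infrared profile
  (`B8 = 0.10 + 0.38 max(NDVI, 0)`, brighter under canopy) and a flat blue
  level of 0.04, so recomputing the indices from the generated bands
  reproduces the intended curves (to 1e-9 absent clipping) and EVI emerges
  without being separately simulated.
* **Correlation structure**: polygon-level parameter jitter (transplanting
  date sd 4 days, amplitude sds 0.02-0.03) shared by the polygon's points,
  plus independent per-observation Gaussian noise (sd 0.02 by default) —
  the structure that makes group splitting matter.
* **Missingness**: i.i.d. Bernoulli cloud loss per observation (default
  rate 0.3, matching a cloudy-season regime), never leaving a sample with
  zero valid steps.
* **Default scale**: 10,000 polygons x 3 points = 30,000 samples,
  binary-balanced (5,000 rice polygons; the non-rice classes split the
  rest evenly), matching the sampling design the method was built for. An
  80/20 polygon split yields exactly 24,000/6,000 points.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate — includes spatially structured (non-i.i.d.) cloud
cover, mixed pixels at field boundaries, atmospheric-correction residuals,
inter-annual phenology shifts, multiple rice varieties or cropping systems,
and georeferencing. Results on the synthetic scenes validate the
machinery, not real-world accuracy.

## Experiment sizes in the bundled checks

The packaged experiments scale the study design down to sizes a laptop
core handles comfortably: the classification experiment uses a
2,500-polygon scene (7,500 points, 6,000 train / 1,500 test after the 20%
polygon split) trained 30 epochs; the ablation experiment uses a harder
600-polygon rice-vs-confuser scene (observation noise 0.05, cloud rate
0.4, confuser transplanting at DOY 140 with a weak 0.15 flooding signal)
trained 12 epochs across three seeds, comparing the complete against the
baseline feature preset and the gated against the ungated architecture.
The split-arithmetic check runs at the full 30,000-point design scale.

## Known limitations

* Training is single-core CPU; the default 100-epoch configuration at the
  30,000-sample design scale is an hours-long run. The bundled experiment
  scales are the practical envelope for quick iteration.
* The patch branch trains but is slow at the default 64 filters on CPU;
  it is intended for inference-scale or small-filter experimentation here.
* Raster (GeoTIFF) input/output is out of scope in this build; inference
  operates on feature tables. The CSV interfaces carry everything the
  pipeline needs.
* The harmonic model assumes one dominant annual cycle; double-cropping
  systems would need a shorter period or more harmonics.
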