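---
title: "Methods: a hierarchical SOM model of face identity/expression separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hierarchical SOM model of face identity/expression separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Visually responsive areas of the primate brain contain physically separate
subpopulations of neurons tuned to facial identity and to facial expression,
even though every face the visual system ever sees carries both at once.
`facesom` implements a rate-coded model of how that separation can emerge
from unsupervised learning alone: a feedforward hierarchy of four
self-organising maps (SOMs) — standing in for V2, V4, TEO and TE — driven by
a V1-like filter bank, with Hebbian learning in the feedforward connections.
Identity and expression are modelled as two independent unidimensional
stimulus spaces carried by disjoint facial features (eyes + nose for
identity, eyebrows + mouth for expression). Because the features of one
identity co-occur with *every* expression (and vice versa), the two spaces
are statistically decoupled, and competitive Hebbian learning should carve
out cells tuned to a region of one space invariantly across the other.

## Model

**Stimuli.** `render_face()` draws 128×128, 256-grey-level cartoon faces.
Forty identity transforms linearly interpolate eye size/position and nose
shape; forty expression transforms interpolate eyebrow tilt/height and mouth
curvature (smile → frown), giving a 40 × 40 grid of 1600 complete faces.
Identity features and expression features occupy disjoint pixel bands at
every combination, so the complete face is exactly the union of the two
isolated renders.

**Retina.** `apply_filterbank()` convolves the image with 32 oriented
difference-of-Gaussians filters — 4 spatial frequencies (0.0625–0.5
cycles/pixel, octave spaced) × 4 orientations (0°–135°) × 2 signs — and
half-wave rectifies, the ± sign channels carrying the positive and negative
parts of the same linear response (on/off simple cells).

**Layers.** Each of the four 32×32 sheets computes, per presentation:

1. linear afferent activation \(h_i = \sum_j w_{ij} y_j\) over a sparse
   set of afferents (272/100/100/100 per neuron) drawn from a Gaussian
   envelope around the topologically corresponding position of the previous
   stage, with the envelope scale calibrated so the stated radius
   (6/6/9/12) contains ≈67% of the connections;
2. a Mexican-hat lateral convolution
   \(\Lambda(a,b) = \delta_E e^{-(a^2+b^2)/2\sigma_E^2} -
   \delta_I e^{-(a^2+b^2)/2\sigma_I^2}\)
   (short-range excitation, longer-range inhibition — the SOM interaction);
3. a steep sigmoid \(y = 1/(1+e^{-2\beta(r-\alpha)})\) whose threshold
   \(\alpha\) is the 95th percentile of the current lateral-filtered
   activations, pinning the firing sparseness at 5% and producing
   near-binary rates.

Learning is Hebbian, \(\Delta w_{ij} = \eta\, y_i y_j\) with \(\eta = 0.1\),
applied to existing connections only, followed by rescaling each neuron's
weight vector to unit Euclidean length. Layers are trained one at a time
(50/100/100/75 epochs; one epoch = all 1600 faces in seeded shuffled
order), with each frozen layer's responses to the whole stimulus set cached
as the next layer's input.

## Analyses

* `test_complete_faces()` – per-cell 40×40 response matrices; identity
  cells appear as vertical bars (invariance over expression), expression
  cells as horizontal bars.
* `test_isolated_spaces()` + `classify_cells()` – tuning curves to the 40
  identity-only and 40 expression-only images; cells are typed
  identity-selective / expression-selective / dual / multi-region /
  unresponsive by counting contiguous supra-threshold runs (threshold 0.5,
  minimum run 2).
* `clustering_statistic()` – join-count fraction of 4-neighbour cell pairs
  sharing a preference label, against ≥999 label permutations.
* `ranked_information_profile()` – single-cell stimulus-specific
  information: one space is quantised into 5 contiguous blocks of 8; the
  central transform of each block (4th element: 4, 12, 20, 28, 36) is
  paired with all 40 transforms of the other space; responses are
  binarised at 0.5 and
  \(I(s,R)=\sum_r P(r|s)\log_2 P(r|s)/P(r)\)
  is maximised over the 5 stimuli. The ceiling is \(\log_2 5 = 2.32\)
  bits, attained exactly by a cell firing for all transforms of one
  stimulus and never otherwise.

## Numerical and design choices

These are the points where the published description leaves the
implementation open; each choice is fixed in one constants block and
exercised by the test suite.

* **Soft-edge rendering.** Features are rasterised through a signed
  inside-ness field with a deterministic one-pixel coverage edge (full
  256-level range). Hard binary rasterisation loses sub-pixel geometry
  steps, making some adjacent transforms bit-identical; the soft edge
  guarantees all 40 transforms are distinct while staying bit-reproducible.
* **Balanced line-drawing design.** All features are strokes (eyes and
  nose are outlined, not filled): filled shapes concentrate their energy
  in the low-frequency filter bands and starve the high-frequency channels
  that carry 201 of layer 1's 272 afferents. Feature geometry ranges were
  set so the identity and expression feature sets inject comparable energy
  into each frequency band and sweep comparable distances through the
  retina-code space across their 40 transforms. An unbalanced design makes
  the map allocate most of its territory to the stronger space, and cells
  of the weaker space lose invariance to the stronger one — the separation
  result presumes deliberately balanced stimuli.
* **Filter constants.** The centre Gaussian width is set so the filter's
  passband peaks at its nominal frequency
  (\(\sigma_c = \sqrt{\ln 2 / 2\pi^2}/f\)), the surround is \(\sqrt2\)
  wider, the orthogonal envelope 3× wider, truncation at 3 envelope widths,
  exact zero DC enforced by rescaling the negative lobe, unit L2 norm.
  Convolution zero-pads (the uniform background maps to zero drive), and
  responses below \(10^{-10}\) of the maximum are zapped so undriven
  locations are exactly zero.
* **Retina gain control.** Each spatial-frequency band of the response
  array is scaled to unit L2 energy per stimulus (contrast normalisation
  within frequency channels), then the whole code to unit L2 norm. Without
  the per-band step the lowest frequency band carries an order of magnitude
  more energy than the 0.5 cycles/pixel band, so the 8 low-frequency
  afferents would dominate every layer-1 neuron's drive and the 201
  high-frequency afferents of the connection table would be irrelevant.
* **Connectivity calibration.** Afferents are *distinct* per neuron
  (duplicate synapses are indistinguishable from doubled weights). Drawing
  n distinct afferents flattens the realised distribution relative to the
  raw Gaussian, so the Gaussian scale is calibrated under distinct-draw
  inclusion probabilities \(\pi_i = 1-e^{-c w_i}\); the empirical
  within-radius fraction then lands on 0.67 ± 0.01 at both presets.
* **Boundaries.** The lateral convolution wraps (toroidal sheet), keeping
  competition homogeneous; layer-to-layer connection sampling also uses
  torus distances; retina sampling clips at the image border. A clipped
  lateral variant is available (`wrap = FALSE`).
* **Sigmoid scale convention.** The sigmoid keeps the
  \(1/(1+e^{-2\beta(r-\alpha)})\) form but operates on the layer's
  rank-normalised activation scale (empirical CDF of the lateral-filtered
  activations, threshold exactly at `percentile`/100). The published
  per-layer slopes are meaningful only relative to a declared activation
  scale: the lateral contrast parameters stretch raw activations by orders
  of magnitude between layers, and on the raw scale the slopes reduce the
  sigmoid to a hard step — competition then degenerates and the trained
  winner set provably collapses to a single blob for every stimulus (we
  observed exactly this: all single-cell information identically zero after
  full training). On the rank scale the slopes produce graded firing over
  the top few percent of cells, sparseness is exact, and the dynamics are
  invariant to monotone rescaling of activations — consistent with the
  reported robustness of the model to large learning-rate changes.
* **Naming.** The published description reuses one symbol for both the
  sigmoid threshold and the learning rate; here they are distinct
  (`alpha` attribute, `learning_rate`).
* **One Hebbian update per presentation**, no settling iterations; test
  dynamics are identical to training dynamics.
* **Information estimation.** \(P(r)\) pools all 200 presentations
  (stimuli are equiprobable by design); responses are binarised at 0.5 by
  default (configurable equal-width bins); no finite-sampling bias
  correction is applied (responses are deterministic rates).

## The desk preset, and what a green test establishes

`default_config("desk")` scales the experiment to continuous-testing size:
16×16 sheets, a 10×10 stimulus grid spanning the same parameter ranges,
epochs 10/20/20/15. Table-scale afferent counts are infeasible on a 16×16
sheet (a radius-3 torus disc holds 29 grid positions, fewer than 100
distinct afferents), so layers 2–4 use 50 connections at radii 4/5/6;
layer 1 keeps its 272 retina afferents. The desk run exercises the
identical dynamics end to end and is what the acceptance tests train.

The synthetic faces emulate the *design* of the stimulus set — independent,
unidimensional, retinally non-overlapping identity and expression spaces —
not real faces: no photometric variation, no overlapping feature encodings,
no multidimensional spaces. A green emergence test therefore establishes
that the implemented dynamics separate statistically decoupled feature
spaces under the stated conditions; it says nothing about real-face
generalisation.

## What the trained model does and does not reproduce

At the full published operating point the trained output layer develops
hundreds of identity-selective and expression-selective cells in roughly
equal numbers, spatially clustered (join-count permutation p = 0.001), and
a subpopulation of expression cells carries the maximal 2.32 bits about
the quantised expression — of the order of the published counts — while no
untrained network has any cell at ceiling. The mirrored property for
identity comes close (top cells ~2.1 bits) but does not reach ceiling
under this package's reconstruction of the stimulus geometry; at reduced
scale the asymmetry reverses (identity reaches ceiling, expression falls
short). Which space wins the competition for the output sheet's limited
winner slots is decided by fine details of the stimulus geometry that the
published description does not pin down; we balanced per-band energy and
code-space path lengths between the two feature sets, and report the
residual asymmetry rather than tuning the stimuli to the expected counts.

A second structural finding: an *untrained* network's preference map is
already spatially clustered under the join-count label-permutation test
(p ≈ 0.001). Neighbouring cells share afferents and interact through the
Mexican-hat kernel, so untrained responses are spatially smooth; the
label-permutation null destroys all spatial structure, not just the
learned structure, and therefore rejects for untrained maps too. The
trained/untrained contrast that is diagnostic is the information ceiling
(trained > 0 = untrained), not the clustering p-value.

## Known limitations

* The hierarchy is purely feedforward (no backprojections), rate-coded,
  and trained layer-wise; these are properties of the modelled system, not
  shortcuts.
* Exact cartoon geometry (coordinates, stroke widths) is not recoverable
  from the published description; the generator reproduces the design
  constraints, not the original pixels. Quantities that depend on the
  precise stimulus geometry — e.g. the exact number of output cells at the
  information ceiling after full training — are reproduced as properties
  (nonzero, exceeding the untrained count) rather than as exact counts.
* An untrained network already shows spatially smooth responses (shared
  afferents plus lateral interactions), so its preference map is not a
  spatially unstructured control; see the acceptance test notes.
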