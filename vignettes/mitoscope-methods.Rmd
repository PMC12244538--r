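---
title: "Detecting mitotic figures in H&E tiles: models, parameters and design choices"
author: "mitoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mitotic figures in H&E tiles: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mitoscope implements a complete mitosis-detection pipeline for
hematoxylin-and-eosin (H&E) histopathology tiles: stain normalization, a
fixed 150-slot descriptor bank, wrapper feature selection by a hybrid
jellyfish-search / walrus-optimization metaheuristic, a skip-connected
fully convolutional detector trained with focal loss, and an eleven-metric
evaluation suite. This vignette explains the models behind each stage, the
parameters that matter, and the design decisions taken where more than one
reasonable realization exists. Everything runs on seeded synthetic data;
no external images are ever downloaded.

## The stain model and normalization

Light absorbance by histological stains is approximately additive in
optical density (OD). A pixel's OD is

$$\mathrm{OD}_c = -\log_{10}\!\frac{I_c + \varepsilon}{I_0}, \qquad
  \varepsilon = 1/255,\; I_0 = 255,$$

and a two-stain tile is modeled as $\mathrm{OD} = C\,M$ with $M$ the
$2\times 3$ matrix of unit-norm hematoxylin and eosin OD vectors and $C$
the per-pixel concentrations. The $\varepsilon$ term keeps the transform
finite at zero intensity; the inverse map rounds back to 8-bit intensities
and round-trips every level in $[1, 255]$ within $\pm 1$.

`estimateStainProfile()` recovers $M$ from a reference tile by the robust
geometry of the OD point cloud: tissue pixels (OD magnitude above 0.15)
are projected on the top-two principal plane, and the 1st/99th percentile
angular extremes define the stain directions. The row with the larger
red-channel absorbance is labeled hematoxylin — hematoxylin absorbs red
and green strongly while eosin absorbs mostly green. Concentration scales
are per-stain 99th percentiles, robust to isolated dark debris.
`normalizeToReference()` estimates the source tile's own profile, rescales
concentrations so the robust maxima match the reference, and re-renders
through the reference matrix. Least-squares concentrations are *not*
clipped at zero: clipping would bias the background re-rendering, and the
negative excursions are noise-scale. On tiles rendered by the package's
own generator the self-normalization error is below one intensity level
and repeated application is idempotent to the rounding tolerance.

Degenerate references — near-blank tiles or chroma-free (grayscale)
images, where no stain plane exists — raise errors; the chroma-free case
can instead fall back to the published default H&E vectors
(`fallbackDefault = TRUE`), which are also the fallback when a tile being
normalized has no recoverable profile of its own.

Preprocessing resizes tiles (default 227 × 227, the detector's input
side), applies a per-channel 3 × 3 median filter (kernel width is a
parameter; 3 is the smallest that removes impulse artifacts without
blurring chromatin texture), and resizes masks by nearest neighbour so
they stay binary. Dataset splits default to 0.7/0.15/0.15, stratified,
with largest-remainder rounding so per-class counts deviate from exact
proportionality by at most one item; the seed is mandatory.

## The 150-slot feature bank

Four descriptor families fill a fixed, versioned registry of 150 slots:
56 + 30 texture, 42 shape, 22 color. The category shares (57.3%, 28%,
14.7%) sit inside the 50–60% / 25–30% / 10–15% bands reported for
selected-feature compositions in this problem domain.

**Local directional patterns (LDP, 56 slots).** Each interior pixel is
convolved with the eight Kirsch compass masks; the indices of the three
largest absolute responses form an 8-bit code with exactly three set bits.
Ties are broken toward the lowest mask index — on a constant image all
responses are zero and every pixel maps to the single code with bits
0, 1, 2, a useful degeneracy check. The $\binom{8}{3} = 56$ admissible
codes, in ascending order, index a histogram normalized to sum to one.

**Local frequency patterns (LFP, 30 slots).** No standard operator exists
under this name, so the package defines one and versions it in the
registry: a bank of DC-free even Gabor kernels at 5 radial bands (center
frequencies $0.25/\sqrt{2}^{\,b-1}$ cycles/pixel) × 6 orientations, each
normalized to unit gain at its center frequency. Per slot the package
records the fraction of pixels whose absolute response exceeds its own
9 × 9 local mean by a margin of 0.35 input standard deviations. The margin
carries the absolute scale: purely ratio-based codes are invariant to the
per-slot response amplitude and cannot rank bands. Convolution uses
replicate padding so DC-freeness survives at the boundary; a constant
image scores exactly zero everywhere, and a pure sinusoid at a band's
center frequency makes the matching (band, orientation) slot maximal.

**Shape (42 slots).** Connected components of the mask (ground truth when
present, otherwise Otsu on the hematoxylin concentration channel, logged)
contribute area, perimeter, eccentricity, circularity $4\pi A/P^2$ and
solidity. Perimeter is the boundary-chain length with the standard 0.95
digitization correction — raw boundary-pixel counts underestimate curved
contours badly enough to push a disk's circularity to 1.26. Solidity uses
the convex hull of pixel *corners*, not centers, so an axis-aligned filled
square scores exactly 1. Each of the five descriptors is aggregated over
components with mean, sd, min, max, median, IQR, skewness and sum (40
slots), plus component count and foreground fraction. An empty mask yields
the zero vector.

**Color (22 slots).** Means and standard deviations of R, G, B,
saturation and value on the [0, 1] scale; hue is treated circularly (in
turns) with the resultant-length standard deviation. An 8-bin
mass-normalized hue histogram assigns undefined hue (zero saturation) to
bin 0 by convention; grayscale intensity entropy (bits) and the
Hasler–Süsstrunk colorfulness index complete the set.

## The metaheuristic core

The core implements two swarm optimizers over box-bounded continuous
spaces as a strict minimizer with greedy acceptance; maximization wraps
the objective as $1 - v$.

The jellyfish-search optimizer (JSO) initializes positions from the
logistic chaotic orbit $y \leftarrow 4y(1-y)$ seeded at $Q_0$ (the orbit's
fixed and periodic points $\{0, .25, .5, .75, 1\}$ are rejected), assigned
agent-major and mapped affinely into the bounds. Movement is gated by the
time-control function $\mathrm{TCF}(t) = |(1 - t/t_{\max})(2r - 1)|$,
one draw per agent per iteration, reused in that agent's passive/active
choice. At or above $\kappa = 0.5$ the agent follows the ocean current
$Y' = Y + R\,(Y^* - 3R\,\lambda_c)$ with $\lambda_c$ the population mean
and $R$ fresh per-dimension uniforms; below it, passive motion adds
$R \cdot 0.1\,(UB - LB)$, and active motion steps toward a random partner
when the partner is fitter, away otherwise. Out-of-bounds coordinates wrap
to the opposite limit (the wrap is applied once and then clamped, covering
steps larger than one box width).

The walrus optimizer (WaOA) contributes three phases: feeding
($Z' = Z + (W^{st} - RI\,Z)\,r$ with $RI \in \{1,2\}$ per dimension),
migration toward/away from a random partner, and an escape/fight phase
sampling a perturbation from a local neighborhood. As printed, the local
bounds of the escape phase equal the global bounds, which makes it a
global restart; the package implements both readings behind
`neighborhoodMode` and defaults to the shrinking neighborhood (the global
box scaled by $1/t$ and centered on the agent), which is what the
algorithm family intends and what makes the phase an exploitation step.
WaOA clamps to bounds, since no boundary rule is printed for it.
Non-finite objective values are treated as $+\infty$: the move is
rejected and counted, never stored.

On the 5-D sphere with $n = 30$ and 200 alternating iterations the driver
reaches $10^{-2}$ in at least 9 of 10 seeds — a sanity benchmark of the
implementation, not a claim from the source literature.

## Hybrid wrapper feature selection

Feature subsets are encoded as continuous positions in $[0,1]^d$,
binarized at 0.5 (ties select). Subset fitness is the stratified
3-fold cross-validated F1 of a regularized diagonal linear discriminant on
the z-scored selected columns, with predictions pooled across folds. The
discriminant shrinks per-feature variances toward their mean (10% plus a
floor), which keeps it defined for constant columns; because the
discriminant is linear in the input, each fold reduces to one
matrix-vector product computed from per-(fold, class) sufficient
statistics — the wrapper loop is what makes this speed matter. An
explicit quadratic implementation (`diagLDAPredict`) is retained and the
tests verify the two paths agree prediction-for-prediction. Results are
memoized by mask, and the empty mask scores zero.

Each hybrid iteration gives every agent a JSO candidate and a WaOA
candidate (the WaOA phase cycles feeding → migration → escape across
iterations). With probability 0.8 (the crossover rate) the candidates
recombine by per-dimension uniform crossover; otherwise the fitter is
taken. With probability 0.2 one uniformly chosen dimension is resampled.
Greedy acceptance against the incumbent closes the iteration; the best
mask ever evaluated is returned, with ties broken toward fewer selected
features and then the lexicographically smaller mask. Runs stop after 100
iterations or 15 without improvement. Population 50, crossover 0.8,
mutation 0.2 and the iteration cap follow the published optimizer
settings.

The reported 35–50 selected features and the category-share bands are
treated as diagnostics: `selectionReport()` flags them but nothing
enforces them, because the source states them as observations, not
constraints (its two statements — "top 50%" and "35–50 of 150" — also
conflict, which is reason enough not to enforce either).

## The detector

The detector is a VGG-16-style backbone — 13 convolutional layers (3 × 3,
same padding, ReLU) in the 2-2-3-3-3 block layout with ceil-mode 2 × 2 max
pooling — converted to a fully convolutional network. The three former
fully connected layers are realized as 1 × 1 convolutions, the last
replaced by a fresh 1-channel scoring layer. Upsampling is staged: three
transposed convolutions (kernel 4, stride 2, bilinear-initialized) each
followed by center cropping and fusion with a 1 × 1-convolution skip from
pool4, pool3 and pool2 respectively, then a final kernel-8/stride-4
transposed convolution cropped to the input size. Skip weights start near
zero (×0.01) so the deep path dominates early training. Ceil-mode pooling
plus center cropping makes every input side ≥ 32 reachable, including the
227 default.

`widthScale` multiplies channel counts only — layer structure never
changes — so the full architecture is structurally testable at desk
scale. Training uses Adam on the focal loss
$-\alpha\,(1 - p_t)^\gamma \log p_t$ (α = 0.25, γ = 2; with γ = 0, α = 1
it is exactly mean binary cross-entropy, which pins down the constant-α
convention used here), L2 coefficient $10^{-4}$, dropout 0.3 on the
FC-equivalent layers, plateau-based halving of the learning rates after
two flat validation epochs, and early stopping at patience 5. Transferred
layers (the first two convolutions, when a local weight file is supplied;
nothing is ever downloaded) train at $10^{-5}$, everything else at
$10^{-3}$ — the two learning rates printed in different places of the
source are reconciled as a two-group schedule. Batch size defaults to 32
(the tuned value; the alternative printed value 4 is config-reachable).
Augmentation applies joint image/mask flips, brightness offsets U(−20, 20)
and contrast gains U(0.8, 1.2). The backward pass is verified against
central finite differences layer-by-layer in the test suite.

Probability maps are post-processed by thresholding (0.5), connected
components, a minimum-area filter (10 px) and score-ranked centroids;
detections are matched to ground truth by the centroid-within-mask rule,
each truth component matched at most once.

## Metrics

From a 2 × 2 tally the suite reports sensitivity, specificity, accuracy,
precision, F-measure, critical success index TP/(TP+FN+FP), balanced
accuracy, Fowlkes–Mallows index $\sqrt{P \cdot \mathrm{Sen}}$, markedness
(precision + NPV − 1), negative likelihood ratio $(1-\mathrm{Sen})/
\mathrm{Spec}$, and the false positive/negative rates. Identities
(BA, FPR, FNR, NLR, FMI) are enforced to $10^{-12}$ by the class validity
check. Zero denominators yield a sentinel 0 plus an entry in the report's
`degenerate` field, so reports always serialize. Markedness is the
standard definition; the markedness values printed in the source
comparison table (≈0.03–0.06 for classifiers at ≈0.99 precision) are
inconsistent with any standard formula, so the package documents rather
than reverse-engineers them, and likewise computes FPR/FNR from counts
where the source table's rows deviate slightly from 1−Spec/1−Sen.

## Synthetic data: what it emulates and what it does not

`genHETile()` renders an eosin-tinted smooth background field,
hematoxylin-tinted elliptical nuclei and mitotic figures as darker,
star-convex-perturbed chromatin clusters (radial harmonics 2–5, so shape
and texture descriptors see genuine signal), composes them through the
package's own OD stain model with per-tile angular jitter of the stain
vectors, and adds Gaussian intensity noise. The mask marks exactly the
mitotic figures, which are placed with a separation floor so mask
components never merge. The easy preset (high chromatin contrast,
well-separated objects) drives the smoke tests; the hard preset (lower
contrast, crowding, stronger jitter) exists for robustness work. A
separate `stainSeed` renders the same scene under a different stain,
giving the paired tiles used to test that normalization contracts
stain-induced differences.

What the generator does **not** emulate: out-of-focus blur, tissue-fold
and pen artifacts, scanner-specific color response, mitosis look-alikes
(apoptotic bodies, hyperchromatic nuclei), and the extreme class imbalance
of whole-slide data. Passing tests therefore demonstrate that the
implementation is correct on data obeying its own stain model and that
the pipeline's moving parts compose; they do not certify clinical-grade
accuracy on real slides.

`genFeatureTable()` draws informative columns with a standardized
between-class shift (theoretical per-column AUC $\Phi(\delta/\sqrt2)$,
≈ 0.92 at the default effect size 2) and equicorrelated nuisance columns
via a single shared factor; labels are allocated exactly.

## Problem sizes and numerical choices

Study sizes used by the tests and the acceptance script, chosen once as
desk-scale conditions: the feature-selection experiments use n = 300
samples (d = 12 for the exhaustive-oracle comparison — 4096 subsets — and
d = 150 for recovery, 5 informative columns, effect size 2); the sphere
benchmark runs 30 agents for 200 iterations; stain experiments use
96-pixel tiles and 20 seeded pairs; the detector smoke test trains the
quarter-width network on forty 64-pixel easy tiles and scores twenty held
out. The 227-pixel input side remains the preprocessing and full-network
default; 64 is a generator parameter, not a different architecture.

Numerical conventions collected in one place: OD uses ε = 1/255 and
background 255; stain estimation needs ≥ 5% tissue and rejects
chroma-free references; logistic-map seeds avoid fixed points;
`wrapBounds` wraps once then clamps; the focal loss clamps probabilities
at $10^{-7}$; fitness caching keys on the selected index set; equal-F1
masks prefer fewer features then lexicographic order; Adam uses
$\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$; training pins the BLAS to
one thread for the duration (many small matrix products; thread
synchronization costs more than it saves) and restores the previous
setting. Seeds are mandatory everywhere randomness exists, and one global
pipeline seed derives per-stage seeds by a string hash so stages can be
rerun independently.

## Known limitations

The LFP operator is this package's own versioned definition of an
underspecified descriptor; results citing it should cite the registry
version. The selector's fitness is tied to the internal discriminant —
a deliberately fast evaluator; richer classifiers would change the
selected sets. The detector trains on CPU at desk scale; the full-width
227-pixel configuration is structurally identical but is not trained in
the tests. Object-level evaluation uses the centroid-within-mask rule
only; IoU-based matching is out of scope. The hybrid's crossover step is
one concrete realization of a prose description ("combine the updated
positions from both"), and other recombinations are plausible. Finally,
the handcrafted-feature path and the network path are composable but
independent — the package makes no claim about fusing selected features
into the network, because no such mechanism is specified in the source
method.
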