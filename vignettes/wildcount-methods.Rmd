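---
title: "Counting animals in aerial imagery with rotation-invariant Fourier HOG features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting animals in aerial imagery with rotation-invariant Fourier HOG features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildcount)
```

## The counting problem

Transect aerial censuses photograph a sampling strip at fixed intervals,
producing on the order of two thousand frames per survey in which a single
species (here, wildebeest-scale herbivores) must be enumerated. Animals
appear as small dark elongated bodies, a handful of pixels across, at
arbitrary orientation. A standard histogram-of-oriented-gradients (HOG)
detector is orientation sensitive — it would need to be trained and scanned
at many rotations. `wildcount` instead uses a Fourier reformulation of HOG
whose features are analytically invariant to rotation, so one classifier
handles every heading.

## The descriptor

**Gradients.** The grayscale image is differentiated with central
differences in the interior and one-sided differences on the border rows
and columns, giving a complex field `G = dI/dx + i dI/dy` with polar form
`r e^{iθ}` per pixel. Coordinates are row-major with origin at the top
left; `x` is the column index, `y` the row index (increasing downward),
both 0-based in the public API.

**Fourier encoding.** A pixel's gradient-orientation distribution is a
Dirac delta at `θ` weighted by `r`; its Fourier series coefficients are
encoded as `F_m = r e^{imθ}` (angular-frequency convention, so that the
rotation angle `α` appears directly in the shift property below). Mode 0
is the gradient magnitude itself, and `|F_m| = r` for every mode. Modes
`m = 0 … M` are kept; negative modes are complex conjugates of positive
ones and carry no extra information.

**Circular-harmonic pooling.** Each mode map is pooled by convolution with
basis kernels

```
U_{j,k}(ρ, ψ) = w_j(ρ) e^{ikψ},   k = 0 … K
```

where `w_j` is a Gaussian annulus centred on radius `ρ_j` with width
`σ`, zeroed outside the inscribed disc of the window and normalized to
unit total weight. The annuli play the role of HOG's pooling cells, but
concentric rings keep the construction isotropic. The convolution is
implemented as cross-correlation with the conjugated kernel under
reflected image borders; with that orientation convention a rotation of
the image by `α` maps each raw feature to

```
X'_{k,m} = e^{iα(m−k)} X_{k,m}.
```

**Invariant combinations.** Three families of entries are rotation
invariant and make up the real-valued descriptor:

* *singles* `X_{k,m}` with `m = k` (real and imaginary parts);
* *composites* `X_{k1,m1} · X_{k2,m2}` with `m1 − k1 + m2 − k2 = 0`
  (real and imaginary parts);
* *magnitudes* `|X_{k,m}|` for every computed triple.

`build_invariant_features()` refuses any requested entry violating these
conditions — silently accepting one would produce an orientation-dependent
detector, so this is treated as a hard error rather than a warning.

### Parameter defaults and why

| parameter | default | rationale |
|---|---|---|
| window | 25 px | covers an animal (~10 px body) plus context; odd so the window has a centre pixel and 90° grid rotations map it onto itself exactly |
| `M` (modes), `K` (wavenumbers) | 4, 4 | captures body elongation and limb-scale structure; feature count stays tractable (240 entries) |
| radial profiles | 4 Gaussian annuli at radii 0, s, 2s, 3s with `σ = s/2`, `s` = window radius / 3 | smooth, overlapping rings spanning the window |
| composite budget | 50 pairs | all valid pairs grow combinatorially; pairs are restricted to radial indices differing by ≤ 1 (nearby rings see the same structure) and ordered deterministically by `(j1,k1,m1,j2,k2,m2)` before truncation, so the descriptor layout is reproducible |
| magnitudes | included | trivially invariant and cheap; the learner is free to ignore them |

The descriptor maps a complex invariant to two real entries (real and
imaginary part) because the boosted learner consumes real values; using
magnitudes alone would discard relative phase between rings, which carries
shape information.

## The detector

Scanning classifies **every pixel** inside a local-contrast mask: pixels
whose windowed intensity standard deviation (7 px window) exceeds 0.02 are
candidates, uniform grassland is skipped. The mask is a pure speed device;
its threshold trades compute for recall on very low-contrast animals and
is configuration-exposed, as is a stride for coarser scanning.

The classifier is discrete AdaBoost over depth-2 `rpart` trees (100
rounds, learning rate 1). Boosting stops early if a round's weighted error
reaches zero (the remaining rounds would not change the vote) or exceeds
0.5 (no weak learner beats chance; prediction then falls back to the class
prior). The score of a pixel is the weighted fraction of positive votes,
in [0, 1], thresholded at 0.5 by default. Training is deterministic:
`rpart` has no stochastic component, so a fixed seed makes train + detect
bit-reproducible.

Positive pixels are grouped with **8-connectivity** (diagonal adjacency on
a small body must not split one animal in two) via the components of the
pixel-adjacency graph; each maximal component is one detection with its
centroid, area and maximum score. No minimum-area filter is applied by
default; `min_area` exists for cluttered imagery.

Training data for the synthetic path harvests positives at ground-truth
centroids and negatives at uniform random pixels at least one window
diameter from every centroid — an algorithmic stand-in for the manual
sample correction a field workflow would use. `bootstrap_train()`
implements that iterative workflow: detections on unlabelled images are
passed to a correction callback (an oracle from ground truth in tests, a
human otherwise) and appended with corrected labels; if the callback
fails, the partial set is preserved on disk before aborting.

## The synthetic scene generator

The generator's purpose is to make the full pipeline testable with known
ground truth. A scene is

* a background of Gaussian-blurred white noise (blur σ 6 px, amplitude
  0.06 about a base level of 0.55) — smooth grassland texture;
* `n_animals` (default 20 in a 192×192 px strip) dark anisotropic Gaussian
  bodies, half-axes 3.2×1.3 px (body ≈ 13×5 px), contrast 0.35,
  orientations uniform on [0, 2π), centroids one body length from the
  border and ≥ 14 px apart (overlapping bodies would conflate the counting
  question with the unmodelled occlusion problem);
* optional clutter: long high-contrast streaks (σ 12×1 px, ±0.3) *not*
  recorded in ground truth, emulating the landscape structure that drives
  false positives in real imagery;
* a global `light_level` multiplier in (0, 1] emulating exposure/sun
  angle, the covariate of the undercount regression.

Bodies are rendered from their parametric form, never by resampling an
image, so a rotated instance is exactly the rotated object — this is what
allows orientation-invariance tests at arbitrary angles. Reproducibility
is strict: the same config and seed yield bit-identical scenes, and an
`orientation_seed` re-draws body orientations while keeping background and
centroids fixed, isolating orientation as an experimental variable.

What the generator does **not** emulate: overlapping/occluding animals,
shadows cast at low sun angle, JPEG compression artifacts, vegetation
mimicking body shape, and species mixtures. Passing synthetic tests
therefore demonstrates the correctness of the pipeline and its rotation
invariance, not field-accuracy on survey photographs; on real imagery the
published experience is substantially noisier (precision ≈ 74%, recall
≈ 86% on the census this package's evaluation statistics mirror).

## Evaluation statistics

For a count table (per image: two independent first-pass manual counts, a
final consensus count, and automated counts), `evaluate_counts()` reports
per counter: total, mean per image, coefficient of variation, RMS
per-image error `sqrt(mean(D_i^2))` and mean (bias) error `mean(D_i)`,
with `D_i` the difference from the final count. The CV uses the sample
(n−1) standard deviation; at census scale (~2000 images) the choice is
numerically negligible but it is fixed and documented here for
reproducibility.

Detection/truth matching is greedy by increasing centroid distance with a
default radius of half the window; greedy matching equals the optimal
assignment whenever pairings are unambiguous (the test suite checks this
against an exhaustive oracle) and is transparent to report. True negatives
follow the region convention — the number of non-overlapping animal-sized
regions in the image minus those occupied — and are reported but excluded
from precision/recall, which do not use TN.

The undercount regression drops images where the algorithm over-counted
and images with a true count of zero (the fraction `1 − automated/true` is
undefined there), reports the dropped indices, and fits OLS of the
fraction on mean HSV value (per-pixel max of R, G, B). A constant response
returns slope 0 and R² 0 rather than an undefined fit.

## Numerical behaviour and known limitations

* **Exact invariance is algebraic, not photometric.** Under 90°/180°/270°
  rotations everything on the grid is exact and descriptors agree to
  ~1e−12 relative. At arbitrary angles the invariance is limited by
  discretization of the *image content*, not of the algebra: the default
  body is only ~2.6 px wide, near the sampling limit, so a 37° re-rendered
  body changes descriptor entries by up to ~20% relative (≈7% for a body
  twice as wide). Phase errors grow linearly in `m`, so high modes are the
  most affected. The boosted classifier's margin absorbs this — detection
  results are unchanged under orientation re-draws — but applications
  needing tighter analytic invariance should enlarge the ground sampling
  distance or lower `M`.
* **`k = 4` kernels on coarse rings.** On the inner rings the angular
  quadrature of `e^{i4ψ}` over few pixels is imperfect; the k = 4 kernels
  sum to ≤ 0.06 instead of exactly 0 (k = 1…3 vanish exactly by the grid's
  fourfold symmetry). This is a property of any sampled circular harmonic
  at low radius.
* **Convolution borders.** All convolutions use symmetric reflection
  padding; descriptors within one window radius of the border are computed
  but mildly distorted. Detection does not exclude the border strip.
* **Problem sizes in tests.** The suite and the acceptance script train on
  500+500 descriptor samples from 25 scenes and evaluate on 30–50 held-out
  scenes of 20 animals each, with loop-oracle comparisons on 15×15 images
  and a 9×9 window — sizes chosen to exercise every code path while keeping
  a full run in the order of a minute or two on one core.
* **Scale invariance is out of scope.** The survey geometry has
  near-constant ground sampling distance; no image pyramid is built.
* **Touching animals are counted once.** Connected-component grouping
  cannot split overlapping bodies; the generator's minimum separation
  reflects that known limitation rather than hiding it.
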