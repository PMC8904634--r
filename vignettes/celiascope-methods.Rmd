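---
title: "celiascope: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{celiascope: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celiascope)
```

# The screening problem

Celiac disease destroys the villi of the small-bowel mucosa. On capsule
endoscopy the damage is visible as a set of artefacts rather than a single
lesion: paler, less red mucosa with a visible submucosal vascular pattern;
depressions ("cracks") resembling dry land; and reduction or loss of the
circular Kerckring folds. `celiascope` quantifies these artefacts per frame
with a small bank of hand-designed filters, summarizes them per video, and
classifies the summaries with deliberately simple learners. This vignette
records the model, its assumptions, and every place where the design was
genuinely open.

# Per-frame processing

## Cleaning

Capsule recorders stamp timestamps and device information near the frame
edges, and the circular optics leave a black border. Both must go before
any statistic is computed, since overlay pixels are white and would bias
every intensity feature.

*Overlay removal.* The frame is converted to gray (ITU-R BT.601 weights
0.299/0.587/0.114 — a convention choice; the source material never states
its conversion), binarized with Otsu's histogram threshold, and its
8-connected regions labeled. Any region whose centroid falls within 20 % of
the height from the top/bottom edge or 20 % of the width from the left/right
edge is erased by zeroing — the mucosa field's centroid is central, text
centroids are not. Zeroing (rather than inpainting) is deliberate: the
downstream crop and features treat black as "no signal". The operation is
idempotent, which the suite checks.

*Cropping.* The black border is removed by taking the tight bounding box of
pixels non-zero in any channel, equivalent to scanning inward until a
non-black value is met.

Open choices made here: 8-connectivity for foreground regions (with
4-connectivity for the background complement during hole filling, the
topologically consistent pair); Otsu for every "auto" binarization. A
constant image yields a threshold equal to its own value so that nothing
exceeds it — the degenerate case that makes an all-black frame pass through
unchanged.

## The filter bank

*Fold edges.* The Sobel pair `Gx`, `Gy` (one core the 90-degree rotation of
the other) gives the gradient magnitude `sqrt(Gx^2 + Gy^2)`. Raw Sobel on
mucosa fires everywhere, so contrast is first windowed to
`[mean - 0.2 sd, mean + 0.2 sd]` and rescaled to `[0, 1]` with clipping.
The window is narrow by design: almost all wall texture saturates to 0 or
1, leaving large flat patches whose boundaries — the fold edges — are the
only strong gradients. The magnitude is normalized by its maximum and
binarized (Otsu; the choice was open). A constant image is defined to map
to mid-gray 0.5, so its edge mask is empty.

All convolutions are true convolutions (kernel flipped relative to
cross-correlation) with mirror boundary handling (the row beyond an edge
reflects to the row inside it, without repeating the edge row). The
boundary rule was open; mirror padding keeps constant images constant all
the way to the border, which in turn keeps the constant-input laws exact in
tests rather than interior-only.

*Cracks.* A 3×3 kernel with row-major coefficients
`A..I = (-2.3, -1, -0.3, -1.4, 7.8, -1.4, -0.3, -1, 0)` amplifies the
centre pixel and subtracts its neighbourhood. Coefficients sum to 0.1, so
flat tissue of 8-bit value `c` responds with `0.1 c` — about 7–8 for
typical mucosa — while a dark depression pulls the response far negative.
Thresholding at 5 yields a mask in which tissue is 1 and cracks are 0: a
*high* crack-mask pixel sum means *few* cracks. Two things about this stage
are fixed on purpose: it operates on the 0–255 scale (the printed threshold
is meaningless on unit-scale values), and the threshold applies to the raw
response (applying it to an offset response was the other reading; raw was
adopted). The printed sign layout of the kernel's table is internally
inconsistent (letters repeat and two are missing); the nine assigned values
`A..I` taken row-major are authoritative here, asymmetry (`A = -2.3` vs
`I = 0`) preserved as printed.

## The ten descriptors

Per cleaned frame: gray-intensity mean and population standard deviation;
R, G, B channel means; edge-mask pixel sum; crack-mask pixel sum; Shannon
entropy of the 256-bin gray histogram (0 bits constant, 8 bits uniform);
and counts of large and small regions. Region counting fills each
8-connected edge-mask component's holes (flood fill from the border
complement), then counts components with area ≥ 1000 px as large and those
with 10 ≤ area < 1000 as small. The lower bound of 10 px excludes
single-pixel noise and was an open choice (no lower bound is stated
anywhere); the 1000 px threshold is the stated default. The pre-fill mask
feeds the edge pixel sum; whether the source used pre- or post-fill sums is
unknown, pre-fill was adopted.

## Per-video summaries

Each descriptor is reduced to mean, standard deviation, and *variation*
across a video's frames. "Variation" is read as the variance (std²): in the
published per-class tables the third column consistently equals the square
of the second to printed precision (e.g. 0.0063² ≈ 3.97e-5 against a
printed 3.92e-5). Population (N) normalization is used throughout — table
roundings cannot distinguish N from N−1, so the simpler convention was
chosen and used consistently for summaries, spectral statistics, and the
contrast window.

A video therefore becomes 30 numbers. Whether the original classifiers
consumed per-frame vectors or per-video summaries is the largest
reconstruction ambiguity in this package; per-video summaries were adopted
because the reported test counts are counts of *videos*.

# Classification

The feature table spans five orders of magnitude (channel means ~0.2,
pixel sums ~1e4), so columns are z-scored with training-set mean and
population standard deviation; zero-variance columns map to 0. The split is
stratified 50/50 by class, seeded.

* **Fine 3-NN** — majority vote among the three Euclidean-nearest training
  videos. Majority ties (possible only for even vote splits) resolve to the
  class of the nearest tied-class neighbour; equidistant neighbours keep
  input order. Both rules were open and are deterministic.
* **Weighted 3-NN** — votes weighted by inverse Euclidean distance, so two
  very close neighbours outvote one distant one. An exact-coordinate match
  short-circuits to the matched label (the infinite-weight convention).
* **Linear SVM** — hinge loss, convergence tolerance 1e-3, fitted
  intercept, class weights inversely proportional to class frequency
  ("balanced"). Fitted by dual coordinate descent with deterministic
  sequential sweeps; the intercept rides as an appended constant feature
  (and is therefore mildly regularized, the standard trick in
  coordinate-descent SVM solvers). The regularization strength `C = 1` is
  not stated anywhere and is exposed as a parameter.

Evaluation takes celiac as the positive class (a convention; the source
never states one): accuracy in percent, precision, sensibility (recall),
and `F1 = TP / (TP + (FP + FN)/2)`, algebraically the harmonic mean of
precision and recall. One published F1 table is reproducible only if the
harmonic mean is *truncated* (not rounded) to two decimals; `f1_from_pr()`
exposes that behaviour behind an explicit flag, and ordinary rounding is
used everywhere else.

# The synthetic world

Patient videos are not deposited, so the package carries a generator whose
defaults *are* the stated world of the tests:

| parameter | healthy | celiac | basis |
|---|---|---|---|
| base RGB mean | (0.4265, 0.2914, 0.1551) | (0.3340, 0.2749, 0.1654) | published per-class channel means |
| texture std | 0.08 | 0.10 | chosen so per-frame intensity std lands near the published 0.17–0.20 once dark corners, folds and cracks contribute |
| folds per frame | 6 | 2 | fold reduction/loss in celiac |
| crack density (Poisson mean) | 1 | 12 | crack prevalence in celiac |
| crack darkness | 0.1 | 0.1 | renderer choice |
| field radius fraction | 0.8 | 0.8 | leaves a croppable black border |
| frame size | 128×128 | 128×128 | scaled down from the capsule's 576×576 for desk-scale testing |
| frames per video | 100 | 100 | nominal video length |

Rendering details that matter:

* **Texture is smooth by design.** Colour noise is generated on a coarse
  ~16 px grid and bilinearly upsampled. Mucosa colour varies at the scale
  of tissue patches, not pixels — and the pipeline depends on this: with
  iid pixel noise the crack filter's tissue response straddles its
  threshold everywhere and the narrow contrast window degenerates to
  salt-and-pepper.
* **Cracks are shaded depressions**, 3 px wide with a half-darkened 1 px
  penumbra, not hard 1 px steps. Hard steps generate bright halo responses
  that cancel the dark core in the crack-mask sum; shaded edges match both
  the physical object and the filter's premise.
* **Folds** are bright arcs (+0.15) of thickness 2; **overlay text** is a
  5×7-style bitmap timestamp near the top-left corner, white, safely
  outside the mucosa disk at the default radius.

The generator reproduces the *orderings and trends* the pipeline assumes
(healthy redder than celiac; crack-mask sum decreasing in crack density;
edge sum increasing in fold count — both verified by permutation trend
tests), and the spectral features land near the published per-class scale.
It does not reproduce the published pixel-sum magnitudes (those scale with
frame area) and does not model optics: no specular highlights, bubbles,
debris/"mud", motion blur, or lens distortion. A green test therefore
establishes that the implementation measures what it claims on frames with
known ground truth — it is not evidence of clinical performance.

# Numerical choices and degenerate inputs

* Constant image: contrast window returns 0.5 everywhere; Otsu returns the
  image's own value so binarization is all-zero; entropy is 0.
* All-black frame: passes overlay removal unchanged; cropping it is an
  error (there is no content to crop to).
* Gray values are quantized to the 8-bit grid (`round(g * 255)`) for
  histograms and thresholds, so entropy's 0/1/8-bit landmark cases are
  exact.
* `standardize()` uses population moments so that a two-point column
  z-scores to exactly (−1, +1).
* The SVM's mirrored-data symmetry (negated decision values under origin
  mirroring with swapped labels) holds to solver precision and is tested;
  it is a consequence of the dual being invariant under that transform.

# Known limitations

Beyond the synthetic-world caveats above: the pipeline assumes a roughly
circular bright field on black (true for capsule optics, not for flexible
endoscopes); overlay removal assumes text never overlaps the mucosa field;
JPEG I/O is lossy and will perturb pixel-exact features; and with very few
frames per video the std/variation summary columns are sampling-noise
dominated, which degrades the distance-based classifiers first — the
package's own acceptance run uses the nominal 100 frames per video for
exactly that reason.
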