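---
title: "Flexible upper-face landmarks from an infinity-shaped sampling curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible upper-face landmarks from an infinity-shaped sampling curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemark)
```

## The problem

When a facial mask covers the nose, mouth and cheeks, the fixed 68-point
annotation that most expression-recognition systems rely on loses most of its
signal: only 26 of the 68 landmarks (38%) sit on the visible upper face, and
of those only the 12 eye-contour points (18% of the total) move appreciably
between emotions. The jaw corners, eyebrow points and nose-bridge points are
nearly stationary across expressions, so the distances
`d(L_m, emotion1, L_m, emotion2)` that drive downstream classifiers collapse
toward zero (`upper_set()`, `lower_set()` and `partition_stats()` expose this
arithmetic).

facemark implements an alternative: instead of a fixed annotation, it detects
a *flexible* set of landmarks wherever a sampling path crosses a strong
intensity boundary on the upper face — eye contours, lash lines, brow edges —
and lets both the number and the location of landmarks vary with the
expression. The landmark set itself, not just its geometry, then carries
class information.

## The sampling curve

The path is the Lissajous figure

$$x = \cos t, \qquad y = \frac{\sin(\alpha t)}{\beta}, \qquad t \in [0,\, c\pi],$$

a figure-eight when $\alpha = 2$: the same shape the two eye regions form.
The defaults ($\alpha = 2$, $\beta = 2$, $c = 20$, $n = 50$) traverse the
figure ten times ("rounds") with five points per round. Two details matter:

* **Inclusive sampling.** The $n$ parameter values are spread inclusively
  over $[0, c\pi]$ with step $c\pi/(n-1)$. With the step $c\pi/n$ that a
  naive reading of the point-listing suggests, both $\cos t$ and
  $\sin 2t$ are periodic over exactly five steps, so every round would
  revisit the same five points and nine of the ten rounds would add no
  information. The inclusive step makes consecutive rounds drift, so the
  fifty points blanket the eye/eyebrow band instead of ten copies of five
  points. The repeating variant remains available
  (`infinity_config(sampling = "algorithm1")`) for comparison.
* **Long chords, not a smooth curve.** Consecutive points are far apart in
  $t$, so the polyline segments are long chords that criss-cross the upper
  face. The intensity profile along each chord is what gets analysed; the
  chords crossing the eyes and brows repeatedly in slightly different
  neighbourhoods are the method's redundancy.

The curve is scaled per image (`normalize_to_image()`: the observed $x$ and
$y$ ranges map affinely onto the crop width and height) and translated so its
centroid lands on a seed point. Border handling moves the whole shape back
inside the frame rather than clipping points, because clipping would distort
the chords; rounding to integer pixels (half away from zero) happens only at
placement so that earlier rounding cannot erase the round-to-round drift.

## The seed point

The seed anchors the curve between the eyes: `x_seed` is the brightest column
of the raw vertical projection (the nose-bridge highlight), `y_seed` the
darkest row of the horizontal projection after Savitzky–Golay smoothing
(window 31, polynomial order 3). Smoothing matters because three contrast
regimes occur in practice — eyes darker than brows, brows darker than eyes,
or both blended — and the raw row minimum jumps between the eye and brow bands
accordingly; after smoothing the minimum settles between the two bands in all
three regimes. The vertical projection is left unsmoothed: the brightest
column is unambiguous, and the package's generator renders the highlight as a
peaked ridge rather than a flat stripe for exactly that reason. Windows longer
than the profile are reduced to the largest valid odd window instead of
failing, and argmin/argmax ties resolve to the lowest index after zapping
sub-micro floating-point noise.

## Landmarks as left bases of prominent peaks

For every three consecutive placed points, the two connecting segments are
rasterized (Bresenham, canonicalized so that reversing the endpoints reverses
the pixel list) and the image intensity is read along the trace. A landmark
is declared where a peak in this 1-D profile has both

* **prominence** `>= min_prominence` — the peak rises well above the higher
  of its two bounding valleys, i.e. the chord genuinely crosses from a dark
  region to a bright one and back; and
* **full width at half prominence** `>= min_width` — the bright run spans
  several pixels, rejecting single-pixel noise spikes.

The landmark coordinate is the peak's *left base*: the rising-side valley
pixel, the place where intensity turns from low to high — the dark edge of an
eye or brow. The peak analysis (plateau-midpoint maxima, prominence bounded
by the nearest higher sample, interpolated half-prominence widths) is tested
exhaustively against an independent brute-force oracle over every ternary
profile up to length 12 plus random real-valued profiles.

**Threshold defaults.** The thresholds are the method's two free parameters
and no canonical values exist; the defaults are `min_width = 3` samples and
`min_prominence = 76.5`, i.e. 30% of the 8-bit dynamic range. The prominence
default is deliberately high: a true feature-to-skin boundary swings by
roughly half the dynamic range, while specular highlights (the nose bridge
seen over bare forehead) and skin texture stay well below a third of it. With
a permissive threshold (10% of the range) the detector admits the
highlight-over-forehead peak, whose left base is a noise-random flat-skin
pixel — an outlier rather than a boundary. Both thresholds are exposed in
`pipeline_config()`; lowering the prominence threshold reproduces the
outlier-prone behaviour, and the landmark count is monotone non-increasing in
both thresholds.

## Descriptors and the 74-value feature

Each landmark contributes its pixel coordinates plus a 72-value histogram of
oriented gradients computed on the 20 × 20 blob around it: central-difference
gradients with replicated edges, quadrant-aware angles in $[0°, 360°)$,
2 × 2 spatial cells of 10 × 10 pixels, 18 signed 20° orientation bins per
cell with magnitude-weighted linear interpolation between adjacent bins, and
one L2 normalization over the concatenated 72 values (epsilon $10^{-6}$).
The layout realises exactly 72 values; the alternative reading of
"direction and magnitude" as 36 + 36 separate values is not used. Blob
extraction clamps at the near image edge and zero-pads the far edge so the
descriptor grid is always 20 × 20. Normalization makes the descriptor
contrast-invariant; the histogram mass before normalization equals the total
gradient magnitude of the blob. Coordinates enter the feature in raw pixels
by default; `normalize_coords = TRUE` rescales them to $[0, 1]$, which
matters for training (below).

## The classifier

Per image, the landmark features are assembled into a fixed-length sequence
(default 64 rows, zero-padded and masked; when an image has more landmarks
than rows, the lowest-prominence ones are dropped first — prominence is the
method's own saliency measure, and the source text specifies no ordering).
The network is a 1-D convolutional extractor along the 74-value feature axis
(kernel 3, ReLU, max-pool 2 per layer), flattened per landmark, followed by
an LSTM over the landmark sequence and a dense softmax. The LSTM uses the
standard cell update $c_t = f_t \odot c_{t-1} + i_t \odot \tilde{c}_t$; the
nonstandard power-law forget-gate variant described alongside it in the
source material does not compose with the standard update as written (it
redefines the gate as a function of timestep indices with unspecified
constants) and is recorded as an unimplemented variant. Training is
mini-batch Adam on categorical cross-entropy with manual backpropagation —
no deep-learning framework is required — and is deterministic given the
config seed; the gradients are verified against numerical differentiation in
the test suite, and the parameter count is reported at build time for
comparison with published model sizes.

One practical note: the raw feature mixes pixel coordinates (order $10^2$)
with unit-norm descriptor values. At desk scale the imbalance slows learning
noticeably; the end-to-end demo therefore enables `normalize_coords = TRUE`.

## The synthetic world, and what a green test establishes

No public face dataset ships with the package. Instead `synthetic_face_spec()`
/ `generate_upper_face()` render the structural facts the method depends on,
with ground truth: a light skin background (level 180), a peaked nose-bridge
highlight (+50 at the centre column), two dark elliptical eye regions and two
dark brow arcs (levels near 60), 8-bit quantization, and additive Gaussian
noise (sd 4, clipped). The default canvas is 236 × 96 — the average upper-face
crop of frontal lab-posed portraits — with a 100 × 46 "small" profile
mirroring in-the-wild crops. Eight emotion classes deform the geometry
(surprise raises the brows and opens the eyes, anger lowers and flattens the
brows, and so on) with 1 px within-class jitter; three contrast regimes
(eyes darker / brows darker / blended) exercise the seed-point smoothing.

Two rendering choices deserve justification:

* **The lash-line rim.** Eyes are rendered as a filled dark ellipse with a
  ~1.5 px darker rim. Real eyes are darkest at the lash/lid boundary, and the
  landmark definition — the darkest point of the dark run preceding a bright
  peak — only marks a *boundary* if the dark region's minimum lies at its
  edge. A uniformly dark disc would put the left base at a noise-random
  interior pixel, which is neither realistic nor what the method exploits.
* **The peaked highlight.** A flat bright stripe makes the brightest-column
  argmax ambiguous within the stripe; a Gaussian-falloff ridge keeps the
  maximum identifiable, as it is on real nose bridges.

What the generator does *not* model: skin texture, glasses, hair occlusion,
pose, shading gradients, or photometric variation between subjects. A green
landmark-recovery test therefore establishes that the geometry pipeline —
seed, placement, profile analysis, left-base mapping — is correct on images
with the stated structure, not that the method attains any particular
accuracy on photographs. Likewise the classification test uses descriptor-
shifted classes to verify the training machinery separates separable data;
published benchmark accuracies on licensed datasets are out of scope.

## Numerical choices

* Ties in argmax/argmin: lowest index, after rounding away sub-$10^{-6}$
  float noise.
* Integer rounding: half away from zero, applied only at curve placement.
* Peak search runs on the raw profile (no pre-smoothing); bright peaks by
  default, `invert = TRUE` for dark valleys. On an inverted image, inverted
  detection reproduces the bright-peak landmarks exactly.
* Duplicate landmarks are dropped only on exact pixel equality;
  near-duplicates carry distinct (overlapping) descriptor neighbourhoods and
  are kept.
* Degenerate inputs: uniform images yield no landmarks and seed (1, 1);
  empty landmark sets yield an all-padding sequence with a warning; a
  single-class training set is an error.
* The balanced label-permutation control in the acceptance suite shuffles
  labels within each true class; an unbalanced shuffle against a perfectly
  separable feature lets the model learn the majority permuted label per
  class and produces a bimodal rather than chance-level outcome.

## Worked example

```{r example, eval = FALSE}
face <- generate_upper_face(synthetic_face_spec(rng_seed = 3))
seed <- find_seed(face$image)
placed <- generate_infinity_points() |>
  normalize_to_image(ncol(face$image), nrow(face$image)) |>
  place_at_seed(seed, ncol(face$image), nrow(face$image))
landmarks <- detect_landmarks(face$image, placed)
features <- landmark_features(face$image, landmarks)
dim(features)  # one 74-value row per landmark (plus bookkeeping columns)

report <- run_end_to_end(pipeline_config(
  hog = list(normalize_coords = TRUE),
  classify = list(max_landmarks = 24, hidden_size = 16, conv_channels = c(8),
                  epochs = 30, batch_size = 8, learning_rate = 0.01),
  rng_seed = 1
), n_per_class = 24, classes = c("neutral", "surprise"))
report$evaluation
```

## Known limitations

* Landmarks are integer pixels; no sub-pixel refinement.
* The curve covers the full crop height by default (`height_ratio = 1`);
  strongly raised brows can escape it, in which case eye-area landmarks still
  anchor the classification, but brow information is lost.
* Very dark or very low-contrast upper faces defeat the prominence test —
  there is no boundary signal to find — and yield few or no landmarks.
* The classifier is desk-scale by design; its architecture hyper-parameters
  are exposed but untuned.
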