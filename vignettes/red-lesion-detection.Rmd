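---
title: "Detecting red lesions in fundus images with entropy-rate superpixels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting red lesions in fundus images with entropy-rate superpixels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retsuperpix)
```

## The problem

Microaneurysms (MAs) and hemorrhages (HEs) — collectively *red lesions*
(RLs) — are the earliest visible signs of diabetic retinopathy. In color
fundus photographs they appear as small dark reddish spots: MAs as round
dots a few pixels across, HEs as larger blobs with irregular margins. A
screening pipeline must find them against a background that also contains
dark vessels, a dark fovea, and wide image-to-image variation in color,
illumination and contrast.

`retsuperpix` implements a complete detection pipeline whose central idea
is to classify *superpixels* rather than pixels: the image is partitioned
into perceptually uniform regions by entropy-rate graph clustering, the
clearly-not-dark regions are discarded, and a small neural network
separates true red lesions from vessel fragments and other dark
structures. No separate vessel segmentation is required — vessel-shaped
candidates are rejected by the classifier, using among others a
multiscale line-operator feature that responds to elongated structures.

## Pipeline stages and their models

### Appearance normalization

Each image is first normalized so that downstream thresholds mean the
same thing in every image:

1. **FOV geometry.** The circular field of view is found from the red
   channel: a diagonal intensity profile thresholded at half its dynamic
   range gives an initial diameter `D`, refined by a restricted circular
   Hough vote over gradient-magnitude edges (fallback: a circle fitted to
   the largest bright component). `D` is the length unit for every
   spatial parameter below.
2. **Bright border artifact removal.** Bright crescents on the FOV rim
   are found on the blue channel as the part of the bright-excess map
   `B - Bmean` reachable by morphological reconstruction from the FOV
   contour, where `Bmean` is a ~D/10 *FOV-masked* mean (a plain mean dips
   at the rim because the window includes the black surround, faking an
   excess on every image). The reconstruction is thresholded at the
   larger of Otsu's split and an absolute 0.05 excess — artifacts are by
   definition *excessively* bright — and cleaned by a disc opening whose
   radius scales as `round(D/100)` (clamped to 2..8); flagged pixels are
   inpainted from their neighbors.
3. **Background extension.** The black surround is replaced by colors
   grown ring-by-ring outward from the FOV boundary (each new pixel the
   mean of already-assigned 8-neighbors), so no later filter mixes tissue
   with black.
4. **Illumination and color equalization** in HSI space:
   `I_eq = I + mu - I * hm1`, with `hm1` an optic-disc-sized (~`D/5`)
   mean filter, flattens slow illumination; hue and saturation are
   shifted additively onto common targets, the hue shift modulo 2*pi with
   the mean hue computed circularly, `atan2(sum sin, sum cos)`. Targets
   default to a mid-bright orange-red retina and are re-estimated from
   the training set in training mode.
5. **Denoise + CLAHE.** A 3x3 mean filter, then contrast-limited adaptive
   histogram equalization on the intensity channel only (8x8 tiles, clip
   limit 2x the uniform bin height), which boosts lesion contrast without
   rotating hues.

All stages clip to `[0, 1]` and are deterministic.

### Multiscale darkness map

Dark structures are scored against local background estimates at scales
`s = D/48, D/24, D/12, D/6, D/3` with weights `alpha_s = 1 - 3.84 s / D`
(0.92 at the finest scale, zero at `D/3.84`, -0.28 at `D/3`; combined
with the max over scales and the clip at zero the negative weight almost
never contributes). First a bright map `Ibri = max_s alpha_s (Iasf -
Ibg_s)` is computed on an alternating-sequential-filtered image (disc
openings/closings of radius 1..`round(D/60)`), then the darkness map

`Idark = max_s alpha_s (Ibg_s - (Iprep - Ibri))`,

where subtracting `Ibri` prevents the rims of bright structures (optic
disc, artifacts) from scoring as dark. Finally `Idark` is rescaled by its
maximum over the FOV, so it expresses darkness *relative to the image's
own darkest structures*. This normalization is what makes the downstream
0.3 keep-threshold the coarse, contrast-independent rule it is meant to
be: absolute multiscale contrasts vary several-fold between images (and
shrink markedly for lesions comparable in size to the smallest background
window), while the darkest vessels and lesions always sit near 1 on the
relative scale.

### Entropy-rate superpixels

Pixels of `Idark` become vertices of an 8-connected lattice; edge weights
are `w_ij = exp(-d(v_i, v_j)^2 / (2 sigma))` with `d` the Euclidean
distance of the two 3-channel darkness triples on a 0-255 scale times the
spatial distance (1 or sqrt 2). The 0-255 scale is what makes the default
bandwidth `sigma = 2` meaningful: one gray level of difference already
decays the weight substantially, so superpixels hug lesion boundaries.

A subset `A` of edges is selected greedily to maximize
`H(A) + gamma B(A)`, where `H` is the entropy rate of the random walk
restricted to selected edges (unselected mass stays on self-loops) and
`B` is cluster-size entropy minus cluster count. `gamma = beta K lambda`
with `beta` the ratio of the maximal single-edge gains of `H` and `B`.
The greedy engine (C++) starts from all-singletons, keeps marginal gains
in a lazy max-heap — both gain terms shrink as the selection grows, so
stale entries are upper bounds and lazy re-evaluation reproduces exact
greedy — tracks components by union-find, never adds intra-component
edges, breaks ties toward the lowest edge index (a fixed raster
enumeration), and stops at exactly `K` components.

Defaults `K = 2000`, `lambda = 0.08`, `sigma = 2`. `K` and the 30-pixel
image rule (below) are defined at a 700x700 reference area and scale with
the actual working area, so superpixel granularity is a constant fraction
of the image at any resolution. Two remarks on behavior worth knowing:

* The balancing pressure is proportional to `K * lambda`. At the
  operating point it is mild; on a perfectly constant image the final
  components are therefore *not* size-balanced (low-strength border
  vertices merge last and can remain tiny). Raising `lambda` to ~0.5
  produces balanced tilings (max/min component size below 4, which is
  what the balance property test asserts); at `lambda = 0.08` boundary
  adherence, not balance, is what the objective buys — appropriate,
  since real darkness maps are far from constant and non-dark
  superpixels are discarded anyway.
* Graph weights are floored at 1e-12 so vertex strengths stay positive
  even across hard boundaries where the Gaussian underflows.

### Candidate reduction and merging

Superpixels whose mean green-channel darkness does not exceed 0.3 are
removed (green is where blood contrasts most). Surviving neighbors with
similar color are then merged iteratively: candidate mean darkness
triples are mapped to CIELAB (D65) rescaled to unit ranges (`L/100`,
`(a+128)/255`, `(b+128)/255` — raw Lab distances would make the 0.24
threshold merge almost nothing), and the globally closest adjacent pair
merges first, means and adjacency recomputed, until no adjacent pair is
within 0.24. Merging repairs the fragmentation of large structures into
several superpixels.

### Features, selection, classification

Each candidate yields 39 features: 11 shape descriptors (area, bounding
box, convex-hull area, second-moment ellipse axes and eccentricity, hole
count, extent, crack-length perimeter, solidity), 24 intensity statistics
(mean / median / SD / 256-bin histogram entropy per RGB channel of both
the preprocessed image and the darkness map), the mean Prewitt gradient
magnitude over the 1-px inner boundary (green channel), the mean
multiscale line-operator response (12 orientations, line lengths ~D/120,
D/80, D/48, on the inverted green channel — high for vessel segments),
and centroid distances to the optic disc and fovea divided by `D`.
Landmarks can be supplied; otherwise a deliberately simple baseline
estimates them (OD = brightest D/5-scale blob of the ASF image; fovea =
darkest smooth point 2-3 OD-diameters away, with an FOV-center fallback).

The fast correlation-based filter ranks features by symmetrical
uncertainty with the class label (10 equal-frequency bins for continuous
features; the relevance threshold is 0, i.e. any positive SU qualifies)
and removes features that share more information with an already-kept
feature than with the class.

The classifier is a 3-layer perceptron — tanh hidden units, one logistic
output read as a posterior probability — trained by Moller's scaled
conjugate gradient on

`E = (1 - upsilon) * cross-entropy + upsilon * mean(w^2)`,

the performance-ratio form of weight regularization; `upsilon = 0.6` and
30 hidden units are the canonical operating point, selectable by
stratified 10-fold grid search. Weight initialization is uniform in
±1/sqrt(fan-in) from a seed; the epoch cap is 500 with a 1e-6
gradient-norm stop. Inputs are z-scored; zero-variance columns are
dropped with a warning and the statistics travel with the model.
Training candidates are labeled positive on any ground-truth overlap
(mirroring the evaluation rule) and the majority class is undersampled to
balance, seed-deterministically.

### Evaluation

Pixel level: a detected candidate is correct if it touches the
ground-truth mask in at least one pixel; all its pixels then count as
true positives and all pixels of non-overlapping detections as false
positives (`PPVp`). Symmetrically, a ground-truth lesion (8-connected
component) counts as covered once any detection touches it, and `SEp` is
the covered fraction of lesion pixels. This symmetric reading of the
superpixel relaxation is one of two defensible choices for the `SEp`
denominator; it is configurable in the sense that the raw counts are
returned alongside the rates. Image level: an image is pathological when
at least 30 pixels (at the reference area; proportionally fewer at
reduced working areas) are detected, and `SEi`/`SPi`/`ACCi` are the usual
confusion rates over images.

## The synthetic study

Because expert-annotated fundus databases cannot ship with a package, the
generator renders fundus-like scenes with exact ground truth: a circular
FOV on black, a reddish background under a random low-order illumination
field, a tapering random-walk vessel tree rooted at a bright optic disc,
a dark smooth fovea, planted lesions — MAs as flat-top ("balloon")
profiles of radius 2-4 px, HEs as unions of jittered discs of radius
5-25 px, both blended toward a dense-blood color slightly darker than
vessel blood — an optional bright rim crescent, and Gaussian sensor
noise (sd 0.01). All sizes are stated at the 700x700 default frame;
rendering at a smaller frame scales every structural size with it, i.e.
the same retina imaged at lower resolution. Lesion contrasts were fixed
by calibrating once against the candidate-segmentation stage so that most
planted lesions survive at default parameters at the native frame
(verified by a regression test); they were not tuned thereafter.

The canonical study pairs one scene per seed: even seeds pathological
(8 MAs + 3 HEs), odd seeds healthy, every seventh seed with a rim
artifact; seeds 0-39 train, seeds 40-79 evaluate. The shipped study runs
at a 350x350 frame (effective `K` 500, pathological rule 8 px), sized so
the whole train-plus-evaluate cycle fits comfortably in a desk-scale run;
at this resolution the smallest MAs genuinely approach the pixel grid and
are often lost — as the method's authors themselves observe for small
MAs — so hemorrhages carry most of the image-level decision, and the
hemorrhage recovery rate is reported separately. What passing this study
shows is that the pipeline's stages compose correctly and recover planted
structure; it does not certify performance on real retinas, whose
texture, lesion photometry and annotation ambiguity the generator does
not emulate.

## Numerical choices and degenerate inputs

* Every image stage clips to `[0, 1]`; hue arithmetic is modulo 2*pi and
  hue means are circular (perfectly dispersed hues raise an error).
* A zero-saturation image has no defined hue; the hue shift is skipped
  with a warning.
* CLAHE requires tile-divisible dimensions; the intensity plane is
  edge-padded to the next multiple and cropped back.
* `0 log 0 = 0` throughout the information-theoretic code; SU returns 0
  when both marginal entropies vanish.
* Single-pixel regions have SD 0 and entropy 0 by convention; the
  second-moment ellipse uses the 1/12 pixel-square correction so a
  1-pixel region has finite axes.
* Degenerate frames (all dark, all bright, no circular transition) make
  FOV detection fail with an explicit error, which `preprocess()`
  re-raises with the stage name attached.
* Greedy determinism is total: a fixed edge enumeration, lowest-index tie
  break, and no randomness anywhere in segmentation.

## Problem sizes used by the shipped tests

Unit fixtures are 120-250 px frames; the ERS oracle checks enumerate all
edge subsets of graphs with at most 6 vertices and 9 edges; the lesion
survival regression runs one native 700-px scene; the end-to-end study
uses the 80-scene suite at 350 px. These sizes are the package's choices
for a reproducible desk-scale validation of each property.

## Known limitations

* The landmark estimator is a baseline, not a faithful optic-disc/fovea
  detector; provide coordinates when you have them.
* The `SEp` denominator convention and the unit-Lab rescaling behind the
  0.24 merge threshold are documented interpretations of under-specified
  conventions in the literature on which the pipeline builds.
* Bright-lesion (exudate) detection is out of scope; the bright map is
  only an intermediate.
* The pure-R + C++ implementation targets desk-scale images; megapixel
  frames are supported but are best run through the working-resolution
  limit (`max_side`), which rescales `K` and the pixel rule consistently.
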