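---
title: "rootmorph: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rootmorph: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Perennial root systems such as asparagus combine two functionally distinct
root classes: thick storage roots that hold reserve carbohydrates, and fine
fibrous roots responsible for water and nutrient uptake. Root-rot pathogens
destroy these classes at different rates, so a useful phenotype is not one
number but *root length per diameter class*, split into fibrous and storage
fractions and converted to length, volume and surface area.

`rootmorph` implements an automated image-analysis pipeline for this
phenotype. The input is a stack of roughly five co-registered photographs of
a washed root system spread on a bright DIN-A4-sized tray, taken with a
stage-mounted camera at a known resolution (about 450 DPI). The output is a
per-plant trait table. Because original photographs of any given study are
rarely deposited, the package also contains a synthetic tray generator with
exact ground truth, so that every stage — and the whole pipeline — is
testable end to end without external data.

## Pipeline model

Each tray is processed in five stages.

**1. Stack reduction.** The exposures are reduced by a pixel-wise *temporal*
median across the stack. A median over ~5 frames removes transient specks
(dust, sensor impulse noise) without blurring edges, which a spatial median
would. Even-length stacks use the lower median (order statistic
$\lceil n/2 \rceil$), so output intensities are always observed values — an
interpolated value would sit between the background and root modes and blur
the mixture fitted next. An optional 3×3 spatial median
(`imaging$spatial_median`) is off by default. The median filter is attached
to the stack rather than to a single image; a purely spatial reading of the
same step is accommodated by the optional flag.

**2. Frame removal.** The tray's bright sheet produces four strong straight
edges. A Sobel gradient map with hysteresis thresholds (defaults 0.1/0.3 on
[0,1] intensities) feeds a standard Hough line transform,
$\rho = x\cos\theta + y\sin\theta$, with resolutions of 1 px and 0.5° and a
vote floor of 0.3× the smaller image dimension — frame edges span most of the
image, roots never do. The outermost near-horizontal and near-vertical line
pairs (within ±5° tilt) define the frame; the image is cropped to the
largest axis-aligned rectangle strictly inside all four lines, shrunk by a
3 px safety margin. Coordinates are 0-based and half-open throughout, so
crops compose exactly. No rotation correction is applied: the frame is a
stage-mounted fixture, and for small tilts the inscribed axis-aligned
rectangle loses only a narrow border strip.

**3. Root segmentation.** Pixel intensities are modelled as a $K=3$
Gaussian mixture (bright sheet, dark root, intermediate dirt/shadow), fitted
by EM on a random subsample of at most 50 000 pixels. Initialisation is
k-means++-style seeding from the configured seed; a variance floor of
$10^{-6}$ is applied each M-step; iteration stops when the absolute
log-likelihood gain falls below $10^{-6}$ or after 300 iterations. The fit
is deterministic given the seed and the log-likelihood trace is retained so
monotonicity can be asserted. Grayscale intensity is the default feature
space: the scene is effectively achromatic, and 1-D mixtures are fast and
robust; RGB features are available. The mixture is fitted per tray, since
illumination varies between exposure sessions.

A pixel is classified as root when its posterior probability under the
darkest component reaches 0.5 (the maximum-a-posteriori rule; ties are
included). Two guards handle degenerate trays: identical-intensity samples
yield a flagged single-component model rather than an error, and if no
component is darker than the brightest by at least `seg$min_contrast`
(default 0.2), the tray is declared root-free — otherwise a tray with no
roots would have its noise floor segmented.

**4. Dirt and speck removal.** 8-connected components smaller than 25 px are
deleted; enclosed background holes smaller than 100 px are filled (rot can
hollow a root to its rhizodermis and central cylinder, which images as a
hole in an otherwise sound outline). Remaining components are kept when
their second-moment elongation (major/minor axis ratio of the inertia
ellipse) is at least 3 *or* their area exceeds 50 000 px: washed roots are
elongated, soil crumbs compact, and very large mats are kept regardless of
shape. Removed components are returned with area/elongation/solidity stats
for audit. Dirt is thus caught twice — by the mixture's intermediate
component where its intensity differs from roots, and by shape where it does
not.

**5. Measurement.** The mask is thinned to a 1-px, 8-connected medial axis
(Zhang–Suen, followed by a connectivity-preserving cleanup that removes
staircase corners — without it, link-based length estimates inflate by up to
~25 % on near-axis curves). The local diameter at a skeleton pixel is twice
the Euclidean distance transform of the mask. Length is estimated from the
skeleton's adjacency links (orthogonal count $N_o$, diagonal count $N_d$,
with short-circuited diagonals not double-counted):

* `chain`: $L = N_o + \sqrt{2}\,N_d$;
* `kimura` (default): $L = \sqrt{N_d^2 + (N_d + N_o/2)^2} + N_o/2$ per
  connected path.

The chain estimator overestimates an oblique straight line by up to ~8 %
(factor $\cos\theta + (\sqrt2 - 1)\sin\theta$, worst near 22.5°), which
would alone exceed the package's 5 % length-accuracy budget; Kimura's
corrected estimator bounds the straight-line error at about 3 % over all
orientations, hence the default. Each degree-1 skeleton pixel additionally
receives its EDT value (`measure$end_correction`, default on), compensating
the half-width retraction of the medial axis at a flat-capped stroke end.

Each skeleton pixel's length share falls into the diameter class of its
local diameter: 0.1 mm classes from 0 to 10 mm by default. The class width
is fine enough that the later Otsu split is insensitive to binning; the
upper bound comfortably exceeds any storage root. Bin mass is conserved
exactly: the histogram total equals the skeleton length estimate.

## Per-plant traits

Histograms from a plant's trays are cumulated bin-wise (identical bin grids
are required; there is no silent rebinning). The fibrous/storage threshold
is found with Otsu's method applied to the *length-weighted* diameter
distribution — length is the only mass in the diameter-versus-length table —
scanning every interior bin edge for the maximum between-class variance
$\sigma_B^2(t) = w_0 w_1 (\mu_0 - \mu_1)^2$ and breaking ties toward the
smallest threshold. Because $\sigma_B^2$ is constant across an empty
diameter gap, the tie rule lands on the edge just above the largest fibrous
mass, which separates the classes correctly. The split is per plant by
default (`trait$otsu_mode`), matching the cumulate-then-discriminate order
of operations; severely diseased plants can lose one class entirely, in
which case the histogram is degenerate, all mass is classified fibrous, and
the plant is flagged rather than failed.

Traits then follow a cylinder geometry per bin midpoint $d_i$ (mm) and bin
length $l_i$ (cm):

$$L = \sum l_i, \qquad
  V = \sum \pi (d_i/20)^2\, l_i \;\mathrm{cm}^3, \qquad
  A = \sum \pi (d_i/10)\, l_i \;\mathrm{cm}^2,$$

with the length-weighted mean radius $\sum (d_i/2) l_i / \sum l_i$ (mm).
Fibrous is strictly below the threshold, storage at or above — a fixed,
testable tie rule. Midpoints are used because they are unbiased for fine
bins and keep the formulas closed-form. Units follow field reporting:
lengths cm, diameters mm, volumes cm³, areas cm²; all px↔physical
conversions go through a single `scale_calibration(dpi)` (px/cm =
dpi/2.54). DPI is a required user input, never read from file metadata,
which is frequently wrong.

## The synthetic tray generator

`generate_tray()` emulates the imaging protocol: a bright sheet
(intensity 0.9) on a darker stage (0.35), dark root strokes (0.15), dirt
blobs of intermediate intensity (0.55), five exposures with Gaussian noise
(sd 0.02) plus sparse impulse specks so the median projection has work to
do. Ground truth is recorded before noise.

Strokes are constant-width serpentines (sine arcs with bounded curvature),
placed by rejection so that they never touch each other, themselves, or the
frame — emulating roots carefully separated on the tray. Their centerline
arc length is the exact truth length. Design choices worth noting:

* **Flat caps.** Stroke ends are clipped by the end-tangent planes. The
  rendered solid is then a true cylinder ($V = \pi r^2 L$ exactly), and the
  medial axis retracts half a width at each end, which the EDT end
  correction compensates exactly. Round caps would make the end correction
  double-count by one width per stroke.
* **Widths snapped to bin midpoints.** Stroke widths are quantised to the
  0.1 mm histogram midpoint grid, so the closed-form truth traits and the
  histogram-route traits coincide to float precision — the generator and the
  analyzer can be cross-checked exactly.
* **Bimodal width model.** Widths are drawn from truncated normals: fibrous
  0.45 ± 0.10 mm on [0.3, 0.8], storage 2.5 ± 0.45 mm on [1.5, 4]. A peaked
  storage distribution reflects the fairly uniform diameter of storage roots
  and makes the fibrous/storage dichotomy well-posed: with widths spread
  *uniformly* over a 2.5 mm storage range, Otsu's criterion frequently
  prefers to split the storage class internally, and no threshold method
  could be expected to recover the class boundary reliably.
* **Capacity capping.** Stroke lengths are drawn uniformly from 2–20 cm and
  progressively shortened (15 % per 25 failed placements) when a crowded
  tray cannot hold them without contact; a stroke that cannot be placed at
  all raises an error advising fewer or shorter strokes.
* **Tray scale.** `scale` shrinks the sheet linearly; 0.5 is A6, a quarter
  of an A4 sheet, used for the length-accuracy scenes (a 20 cm root cannot
  physically coil into anything much smaller at 4 mm width without
  self-contact). Unit tests use scales 0.15–0.3; the test files state the
  scene they use.

What the generator does *not* emulate: root tapering and branching, root
crossings, lesion colouring, shadows, vignetting, perspective distortion and
photorealistic texture. Passing tests therefore demonstrate correctness of
the algorithms under the stated scene model, not robustness to every
property of field photographs; on real trays the practical accuracy limit
is the physical separation of roots, which the protocol (not the software)
controls.

## Numerical choices and degenerate inputs

* Even-stack median: lower order statistic (no interpolation).
* EM: k-means++ seeding, variance floor $10^{-6}$, absolute tolerance
  $10^{-6}$, 300-iteration cap, per-iteration log-likelihood retained;
  vanished components keep their mean and are floored rather than crashing.
* Hough peaks: accumulator cells ≥ all 8 neighbours, sorted by votes then
  (θ, ρ) for determinism; ties in the Otsu scan break toward the smallest
  threshold; posterior ties at the classification threshold are included.
* Local diameter of an isolated pixel is 2 px (2×EDT); an isolated skeleton
  pixel receives the end correction twice (once per free end).
* Sub-seeds for every tray and stage are derived from the global seed and
  the tray identifier with a 31-bit multiplicative hash, so batches are
  bit-reproducible and order-independent.
* Histogram diameters beyond the last bin edge are clamped into the last
  (closed) bin.

## Problem sizes in the test-suite and acceptance script

The shipped tests run the full pipeline on sub-A4 trays (linear scales
0.15–0.5 at 450 DPI, i.e. ~0.4–5 megapixel scenes) with 3–13 strokes per
tray: 100 single-tray plants for the class-split recovery check, 30 plants
for the volume-correspondence check, 20 seeds for segmentation quality, and
6 A6 trays (54 strokes) for length accuracy. These sizes were chosen so the
whole suite reruns in minutes on one CPU while every stage still operates at
realistic stroke widths (a 0.35 mm fibrous root is ~6 px wide at 450 DPI).

## Known limitations

* Crossing or touching roots are merged into one component; the physical
  separation step of the protocol is assumed.
* The diameter read 2×EDT is quantised to whole pixels and biased about
  +½ px for even-width strokes; at 450 DPI this is ~0.06 mm, negligible for
  storage roots and a small positive bias for the finest fibrous roots
  (volume, being quadratic in diameter, feels it most).
* The Hough crop is axis-aligned; frames tilted beyond ~5° lose border area
  and should be rectified upstream.
* Otsu's split assumes the diameter distribution is genuinely bimodal; on
  plants with a continuum of diameters the threshold is reported but the
  class split is arbitrary, and the degenerate-histogram flag only catches
  the extreme case.
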