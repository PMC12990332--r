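---
title: "Morphometric quality control of neural organoids: models and methods"
author: "morphoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric quality control of neural organoids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscreen)
```

## The screening problem

Neural organoids grown from the same starting cell number diverge widely in
gross morphology within their first weeks, and gross morphology — size,
shape, surface complexity, texture — predicts tissue quality before any
molecular readout is available. A day-18 organoid whose perimeter carries
many neuroepithelial buds ("ventricles") tends to develop more and larger
neural-tube-like units; a smooth, featureless sphere usually does not.
`morphoscreen` turns one calibrated 2D brightfield image per organoid into a
quantitative record and decides, against a curated reference pool of
good-morphology organoids, whether each input organoid should be retained or
discarded. The decision is unsupervised: input and reference organoids are
embedded in a common PCA morphospace and clustered; an input organoid is
retained exactly when its cluster also contains reference organoids.

## The measurement model

### From image to contour

Segmentation is a classical intensity pipeline: Gaussian pre-smoothing
(`blur_sigma_px`, default 2 px), a global Otsu threshold, morphological
closing (radius 3 px), hole filling, and selection of the largest connected
component. Object polarity defaults to `auto`: a brightfield organoid is a
dark object on a light field, and the automatic choice picks the polarity
whose largest component does not touch three or more image borders. Two
conditions the bench workflow handles by re-inspection are surfaced
explicitly: no component above the minimum-area floor (0.5% of the frame) is
an *empty segmentation* error — discard the image or trace manually — and a
second component above half the size of the largest attaches an ambiguity
warning (more than one organoid in the field of view).

A global Otsu cut crosses a blurred edge away from the edge midpoint
whenever the object interior is broadly shaded, displacing the boundary by
roughly a pixel. Because every size descriptor inherits that bias, the final
mask is refined by a *half-maximum* cut by default: the blurred image is
re-thresholded at the midpoint of the median intensities sampled in thin
bands 4–8 px inside and outside the initial boundary. On rendered ground
truth this reduces the boundary error from about 1 px to under 0.3 px
(Jaccard ≥ 0.98 against the true mask).

The outer boundary is extracted at the 0.5 iso-level of the binary mask with
marching squares (`grDevices::contourLines`), giving a sub-pixel polygon
rather than a pixel-corner chain; this materially stabilizes curvature
estimates. Contours are expressed in microns, in a y-up frame, and oriented
counterclockwise (positive shoelace area). Manual ImageJ `.roi` polygons
take precedence over automatic segmentation when supplied, are checked for
self-intersection, and are orientation-normalized.

### Differential geometry of the contour

All curvature quantities are computed on a unit-speed parameterization:

1. resample the closed polygon to `n_samples` (default 1024; 2048 in the
   validation suites) points uniformly spaced in arclength;
2. optionally smooth x(s), y(s) with a periodic Gaussian whose standard
   deviation is `smooth_frac` of the perimeter (default 1%; use 0 for exact
   analytic contours), then resample again;
3. first and second derivatives by periodic central differences, so
   dx² + dy² ≈ 1 and the curvature denominator is well conditioned;
4. signed curvature κ = (dx·dyy − dy·dxx)/(dx² + dy²)^{3/2}, positive on
   convex arcs of a counterclockwise contour.

From κ the package derives:

* **Mean / Std curvature** — arithmetic mean and standard deviation of the
  per-point κ (units 1/µm). For any convex closed curve the arclength mean
  is exactly 2π/perimeter. An alternative reading of the spread statistic
  (standard deviation of the per-point log squared-curvature contribution)
  is available via `std_curvature_mode = "log_energy"`; the default reading
  matches the per-micron units of the printed table header.
* **Weighted curvature** — Σ κᵢ·Δsᵢ. For every simple closed
  counterclockwise curve this equals the total turning 2π (a built-in
  sanity invariant: the pipeline recovers 2π within 0.05 on all generator
  shapes). Although dimensionless, the printed table assigns it 1/µm units;
  the header is kept as printed.
* **Inflection points** — sign changes of κ around the closed profile.
  Raw sign changes are noise-dominated on rasterized boundaries, so a
  persistence filter merges any same-sign run shorter than `min_arc_frac`
  of the perimeter (default 2%) into its neighbours before counting. The
  count is even for any closed curve. For the polar test family
  r = R(1 + a·cos nθ) the curvature numerator r² + 2r′² − r·r″ attains its
  minimum (1−a)(1 − a(1+n²)) exactly at the lobe waists, so the true count
  is 2n when a > 1/(1+n²) and 0 otherwise — note that one- and two-lobed
  shapes of moderate amplitude are genuinely convex, and the pipeline
  correctly reports 0 for them.
* **Dirichlet normal energy (DNE)** — the log bending energy of the
  boundary. The variation of the unit normal n = (dy, −dx) projected on the
  tangent t = (dx, dy) satisfies n′·t = −κ under the Frenet relations, so
  DNE = log ∫ κ² ds. The natural log is the default (`log_base = "log10"`
  is available); a circle of radius R gives ln(2π/R) exactly, and scaling a
  contour by c shifts DNE by −ln c. A numerically flat profile returns the
  log of the machine floor with a degenerate flag rather than −∞.
* **Average radius R0** — mean distance from the area centroid to the
  uniformly resampled boundary. DNE and Std curvature are multiplied by R0
  downstream (DNExR0, R0 × Std curvature) to remove the 1/size scale of
  curvature so that surface complexity can be compared across organoid
  sizes.

### Region and texture descriptors

Area and perimeter come from the shoelace formula and edge sums. Feret
diameters use the convex hull: the maximum caliper equals the hull diameter;
the minimum width is minimized over hull-edge-aligned directions (the
minimum width of a convex polygon is always attained flush with an edge).
Roundness = 4·Area/(π·Major²) takes its major axis from the second-moment
equivalent ellipse — the measurement-vocabulary convention of ImageJ — not
from the bounding box; the bounding-box width/height ratio is reported
alongside as `bbox_aspect` for the literal reading, and the default aspect
ratio is the moment-ellipse axis ratio (always ≥ 1). Circularity =
4π·Area/Perimeter² is reported unclipped; coarse polygons may exceed 1 by a
discretization sliver.

Transparency is the mean absolute response of a scale-normalized (σ²·LoG)
Laplacian-of-Gaussian filter (σ = 2 px by default) over the mask interior
eroded by 2 px, so boundary gradients do not leak in. A mean *absolute*
response is the default because the plain mean of a LoG is ≈ 0 by
construction; `"square"` (RMS) and `"signed"` aggregates are available. The
RMS aggregate has a useful property used in validation: independent image
components (shading, texture, noise) add in quadrature, so the texture
channel can be isolated as √(t² − t₀²).

## The decision model

Nine of the seventeen table columns enter the analysis by default — Area,
Perimeter, Feret, Roundness, Circularity, Inflection Points, DNExR0,
R0 × Std curvature, Transparency — the remainder (pixel size, average
radius, aspect ratio, MinFeret, weighted and mean curvature) being redundant
with them or uninformative for morphology. Input and reference records are
pooled *before* standardization so both populations share one scale; each
feature is centered and scaled to unit sample variance (n−1), and the
morphospace is a scaled PCA (`prcomp`). Component signs are fixed by making
the largest-magnitude loading of each component positive, so scores are
reproducible across runs and platforms. Per-component percent variance is
kept at full precision internally and rounded only for display. The cos²
table (loading × sdev)² reports each feature's quality of representation;
with scaled input its rows sum to 1.

Clustering retains the leading principal components whose cumulative
variance fraction *strictly exceeds* `variance_threshold` (default 0.9 —
the strict inequality follows the reference rule), then runs
`stats::kmeans` with k = 3, 25 random restarts and `set.seed(123)`. Because
the reference workflow is itself R's k-means, seeding R's own generator
reproduces its partitions exactly; re-implementing Lloyd's iteration with a
private generator would only decouple the two. Labels are canonicalized by
first occurrence so reports are byte-stable. The retain/discard rule is the
formalization of the worked decision: an input organoid is retained iff its
cluster contains at least one reference organoid. k is a genuine
sensitivity of the method — the per-cluster composition is always reported
so the decision can be supervised, and `k = 1` triggers an explicit
"uninformative" warning while retaining everything.

## The synthetic generator: what it emulates and what it does not

Validation runs on a polar-harmonic family
r(θ) = R·(1 + Σ aᵢ·cos(nᵢθ + φᵢ)), chosen because it admits closed-form
curvature — the independent oracle — while visually mimicking budded
organoids. Amplitudes are capped (Σ aᵢ < 0.45) to keep r > 0, and boundary
jitter is realized once, at construction, as a band of random order-9–24
harmonics so the radius function stays deterministic and analytically
differentiable. Contour samples are taken by inverting the arclength
integral and evaluating the polar form exactly at uniform-arclength angles,
so oracle comparisons are free of chordal interpolation noise.

Rendered frames emulate an 8-bit brightfield field of view at 6 µm/px
(384 px frame): light background (220), darker organoid whose dense core
(90) sits under a more transparent neuroepithelial rim (150) carrying
band-limited texture, radial shading blended over 60 µm, Gaussian intensity
noise (sd 4), and final 8-bit quantization (which can be bypassed for
intensity-linearity checks). The default cohort emulates the screening
design: 20 reference organoids of complex morphology (one dominant lobe
order 6–8, amplitude 0.2–0.3), three complex and three smooth (amplitude
≤ 0.05) input organoids, base radii log-normal around 450 µm (≈ 0.9 mm
diameter, typical of day-18 organoids) with 15% spread in *both* classes
and truncated at 2.5 sd so every shape fits the frame — size deliberately
does not separate the classes, surface complexity and texture must.

What the generator does **not** model: Matrigel halos, attached debris and
migrating outgrowth, internal cysts, multiple organoids per field, uneven
illumination, and out-of-focus blur. Passing the synthetic suites therefore
demonstrates correctness of the measurement and decision machinery, not
robustness to every real imaging artifact; on real data the workflow's
manual-ROI path and the per-image warnings exist precisely for those cases.

## Numerical choices and degenerate inputs

* Uniform resampling default n = 1024 (2048 in validation); spacing
  coefficient of variation above 5% is a hard error instructing resampling.
* Boundary smoothing default 1% of perimeter; 0 disables. Validation
  against analytic contours runs with 0 — smoothing exists to tame
  rasterization, and attenuates a lobe harmonic of order m by
  exp(−½(2πm·σ/L)²), which is a few percent at m = 6–8.
* Inflection persistence default 2% of perimeter; an all-zero curvature
  profile returns 0 with a degenerate flag.
* Zero-dynamic-range images map to 0 under bit-depth narrowing.
* Calibration never overwrites raw files unless `write = TRUE`; the
  default protects raw data, the flag restores the overwrite behaviour of
  the original batch macro.
* CSV headers are written in ASCII ("um", "um^2", "um-1"); Unicode micron
  and minus spellings are normalized on read. The printed plural
  "Inflections Points" is preserved in the table dialect; the singular
  spelling is accepted on read.
* ImageJ ROIs are written with the sub-pixel float32 coordinate block;
  round trips are exact for float32-representable coordinates and within
  ~1.5e-5 px otherwise.
* The pixel calibration is stored as the TIFF rational XResolution =
  10⁷ / (pixel_size·10⁷) px per unit, so the pixel size survives the
  round trip exactly for sizes below ~214 µm/px.

## Problem sizes used in validation

The shipped validation suites run at desk scale: 100 seeded shapes for the
oracle comparison (every geometry descriptor within 3%, pointwise curvature
within 2% of the closed polar form at 2048 samples, DNE within 3% on the
energy scale), 200 seeded rosettes for inflection recovery against the
closed-form concavity rule, 25 shapes for the turning-number invariant, and
50 seeded cohorts (26 rendered images each) for end-to-end recovery, which
must retain exactly the complex inputs in at least 95% of cohorts.

## Known limitations

* Single organoid per image; no instance segmentation.
* The intensity-based reconstruction of the original segmentation macro is
  parameterized, not byte-identical to it; users matching a specific Fiji
  setup should tune `segmentation_params` empirically against manual ROIs.
* The retain/discard rule is purely co-clustering-based; with an
  unrepresentative or too-small reference pool the decision degrades, and
  homogeneous smooth-by-design protocols (e.g. dual-SMAD-patterned
  organoids) invalidate surface-complexity descriptors altogether — change
  the reference pool rather than the rule.
* 2D brightfield only: the surface complexity of the equatorial outline is
  a proxy, not a measurement of 3D ventricle count.
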