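---
title: "The stacked-ellipse method for 3-D ultrasound uterine segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stacked-ellipse method for 3-D ultrasound uterine segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackedellipse)
```

## The problem and the model

Delivering adaptive radiotherapy for uterine cervix cancer requires knowing
where the uterus is at treatment time. The uterus moves and deforms daily
with bladder and rectal filling, and 3-D transabdominal B-mode ultrasound can
image it at the treatment couch — but only if the organ can be segmented
quickly and reliably on images that carry speckle, shadowing and a field of
view that may clip the target.

The stacked-ellipse approach exploits two robust priors about the uterus on
B-mode ultrasound: it is *hypoechoic* (darker than its surroundings), and its
cross-sections, taken approximately orthogonal to the curved fundus-to-cervix
path, are *roughly elliptical*. The organ is therefore modelled as a stack of
planar ellipses

$$\frac{(x-c_1)^2}{a^2} + \frac{(y-c_2)^2}{b^2} = 1,$$

one per semi-axial slicing plane, where the in-plane $x$ axis is anatomical
left–right (LR), so $a$ is the LR semi-axis and $b$ the semi-axis along the
slicing plane's anchor line.

A single manual input drives everything: a closed contour on a mid-sagittal
slice with four ordered landmarks (fundus-top, cervix-top, cervix-bottom,
fundus-bottom). The landmarks split the contour into a top surface, a bottom
surface and two end caps. Anchor points are placed arclength-uniformly on
the top surface and matched (by arclength fraction measured from the fundus
end) to points on the bottom surface; each anchor pair defines one slicing
plane spanned by the anchor line and the LR direction. The pair immediately
supplies two of the five ellipse parameters — the centroid (anchor midpoint)
and minor semi-axis $b$ (half the anchor distance) — while the LR semi-axis,
which the sagittal view cannot see, comes from a population model.

### The training phase

Gold-standard 3-D contours are cut by the same slicing planes
(`parameterize_contour()`, using exact triangle–plane intersection and
segment chaining rather than voxelised sections, so training carries no
rasterisation error) and a direct least-squares ellipse is fitted to every
cross-section. Pooling all slices of all training patients, ordinary least
squares gives the linear axis model

$$a = m\,b + K,$$

implemented in `fit_axis_model()`. The package ships
`default_axis_model()` with $m = 1.01$, $K = 11.3$ mm ($R^2 = 0.60$), so
segmentation is usable without retraining; `train_axis_model()` rebuilds the
model from any set of contour meshes. The regression is deliberately
unweighted and pooled — per-patient fits are computed only as a diagnostic
(attribute `"per_patient"`), because a new patient's slope is unknown at
segmentation time and the pooled trend is the only defensible prior.

### The segmentation phase

For each slice the pipeline is:

1. **Resample** the volume onto the plane's grid by trilinear interpolation
   (`resample_plane()`). Nodes outside the volume are flagged in a validity
   mask rather than failing, because the field of view need not cover the
   whole organ.
2. **Directional edge map** (`directional_edge_map()`). The image is
   smoothed with a Gaussian of standard deviation $\sigma$ pixels; the
   smoothed gradient is dotted with $J(x,y)$, the unit ("phase") gradient of
   the signed distance map of the initialisation ellipse, which points away
   from the interior. This *agreement* term is positive only where contrast
   goes dark-to-bright outward, the polarity a hypoechoic organ must show.
   The edge map is
   $$f(x,y) = \begin{cases}\lvert \nabla V_1 \cdot J \rvert^2 \, R(x,y) & \nabla V_1 \cdot J > 0\\ 0 & \text{otherwise,}\end{cases}
   \qquad R = \Bigl(1 - u^k\Bigr)e^{-u^k},\; u = \frac{d}{\max d},$$
   where $d$ is the unsigned distance to the initialisation contour and the
   maximum is taken over the slice's own grid. $R$ equals 1 on the contour
   and falls to 0 at the farthest pixel, down-weighting boundaries far from
   the prior; smaller $k$ penalises them harder.
3. **Deform** (`deform_contour()`): along the ray from the ellipse centroid
   through each of the contour points, a profile of $f$ of total length $r$
   pixels centred on the point is sampled at 1-pixel steps; the point moves
   to the strict local maximum nearest its start, and stays in place when
   the window holds no peak.
4. **Regularise** (`regularize_contour()`): a direct least-squares ellipse
   through the deformed points smooths the boundary and damps outliers that
   latched onto residual spurious edges.
5. **Assemble** (`assemble_3d()`): the final ellipses are sampled, mapped to
   world coordinates and lofted into a single watertight triangulated
   surface.

The whole pipeline (`segment_volume()`) is deterministic, and per-slice
failures (empty overlap, degenerate fits, implausible fits) degrade to that
slice's first-guess ellipse instead of aborting, so a 3-D contour is always
produced.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `sigma` | 4 | px of the semi-axial grid | gradient smoothing scale |
| `k` | 1 | – | decay of the distance weight $R$ |
| `r` | 29 | px | total radial search length per contour point |
| `slice_spacing` | 2 × voxel | mm | anchor/slicing-plane density |
| `pixel_spacing` | voxel | mm | semi-axial grid resolution |
| `n_points` | 180 | – | contour samples per slice (1 per 2°) |
| `shrink_factor` | 1 | – | 1 = conforming loft, 0 = convex hull |

`sigma` and `r` are interpreted in pixels of the resampled planar grid,
whose spacing defaults to the volume's smallest voxel spacing (0.58 mm for
the scanner protocol this tool targets); at that spacing $r = 29$ px is a
±8.4 mm search range, commensurate with day-to-day uterine boundary motion.
`n_points = 180` makes the contour sampling (≈0.5–1 mm arc steps) finer
than the pixel grid, so the ellipse fit is never point-starved.

### The shrink factor

The 3-D assembly exposes a concavity parameter: `shrink_factor = 0` returns
the convex hull of all surface points, 1 returns the loft passing exactly
through the stacked ellipses, and intermediate values interpolate radially
between the two (each ring vertex slides along the ray from its ring
centroid toward its hull exit point). The package default is 1: because the
assembly lofts the rings directly, the stacked ellipses already define the
boundary, and any hull blending inflates the concave (posterior) side of an
anteverted organ. The hull end of the scale remains useful as a smoothing
fallback when individual slices misfit.

## Geometry conventions

All physical quantities are millimetres in a right-handed world frame with
axes (LR, AP, SI); grid indices are 1-based in R with voxel (1,1,1) centred
at the volume origin. In-plane coordinates on a slicing plane are
$(x, y) = (\text{LR component}, \text{anchor-line component})$, which keeps
$a$ attached to $x$ exactly as in the ellipse equation above. Ellipses are
canonicalised to $a \ge b$ with rotation $\phi$ reduced modulo $\pi$;
because $\phi$ is only defined modulo $\pi$ (and the parametric axes may
swap), `assemble_3d()` aligns rings *geometrically* — the first sample of
every ring is the one nearest the +LR direction from its centroid — so the
loft is never twisted by the parameterisation of an individual fit.

## The synthetic phantom: what it emulates, what it does not

Clinical volumes and contours cannot be redistributed, so the package
includes a generator (`phantom_spec()`, `phantom_case()`) that produces
speckled volumes with exact ground truth:

* an anteverted-uterus geometry: a quadratic mid-sagittal centerline whose
  body axis tips roughly 60–70° anteriorly from the superior–inferior
  direction, about 62 mm fundus-to-cervix;
* a minor-axis profile widest in the body (≈16 mm) tapering to ≈8 mm at the
  cervix, with major axes from $a = 1.01b + 11.3$ plus 1 mm per-slice
  Gaussian jitter so cross-sections are not perfectly collinear in $(b,a)$;
* hypoechoic interior ($\mu_{in}/\mu_{out} = 45/90 = 0.5$), a 1.2 mm
  Gaussian point-spread blur, and fully developed multiplicative unit-mean
  Rayleigh speckle (the standard fully-developed-speckle approximation for
  B-mode); optional angular shadow sectors emulate attenuation;
* 0.58 mm isotropic voxels, matching the resampled scanner output the tool
  targets;
* a simulated observer: the truth's exact mid-sagittal section, optionally
  perturbed by a smooth low-frequency displacement of bounded amplitude
  (`jitter`, mm) to emulate inter-observer contouring variability.

All randomness flows from one integer seed through scoped generators
(`withr::with_seed`), so every artefact is bit-reproducible.

What the phantom does *not* emulate: sector-scan geometry and scan
conversion, reverberation and mirror artefacts, tissue-dependent speckle
correlation lengths, neighbouring organs (bladder, rectum, bowel gas) and
genuinely non-elliptical cross-sections. Passing the phantom suite therefore
demonstrates that the implementation is correct and robust to speckle,
blur, field-of-view clipping and initialisation jitter — not that clinical
accuracy on patient data is reproduced. The built-in acceptance thresholds
(`scripts/acceptance.R`; noise-free DSC ≥ 0.95 and MSSD ≤ 1 mm, speckled
median DSC ≥ 0.80 and MSSD ≤ 3.5 mm over 20 seeds) are chosen to be
consistent in magnitude with the inter-observer agreement reported for
manual uterine contouring, and the clean-phantom results are expected to
sit well above them.

## Numerical choices

* **Ellipse fitting** is the numerically stable direct least-squares
  ellipse-specific fit (Halir–Flusser formulation): data are centred and
  scaled, the constrained eigenproblem is reduced to 3×3, and the
  ellipse-guaranteeing eigenvector is selected. Fewer than 5 points,
  collinear input, or a non-elliptical conic signal a distinct
  `se_fit_error` rather than returning garbage.
* **Out-of-volume pixels** are excluded from the Gaussian smoothing support
  by normalised convolution (blur the masked image, divide by the blurred
  mask) instead of being blurred in as a sentinel value; otherwise the edge
  of the field of view would manufacture boundaries. They also contribute
  zero to the edge map directly.
* **Noise floor:** the agreement term must exceed $10^{-10}\max|V_1|$
  before a pixel counts as an edge, so convolution round-off on a uniform
  image yields an exactly zero edge map.
* **Peaks** are strict local maxima with positive value; a plateau peaks at
  its centre sample; two peaks equidistant from the start break the tie
  *inward*, because overshooting into bright far tissue is the commoner
  failure and the prior centroid is interior.
* **Distance weighting** uses the initialisation ellipse (not the deformed
  provisional contour): $R$ must exist before any provisional contour does.
* **Per-slice fallbacks:** a degenerate or implausible regularised fit
  (axes off by more than 3× from the first guess, or centroid displaced by
  more than the larger first-guess semi-axis) reverts to the first-guess
  ellipse with a warning record.
* **Voxelization** marks voxel centres inside a watertight mesh by parity
  counting of ray crossings, with a sub-voxel jitter of the ray origins so
  rays cannot pass exactly through triangle edges.
* **Surface distances** (MSSD) sample both surfaces at ≤0.5 mm spacing via
  a deterministic barycentric lattice and use a uniform-grid
  nearest-neighbour search; the directed mean is asymmetric, and the
  default symmetric mode averages the two directions.
* **Quantiles** in cohort summaries are linear-interpolation (type 7).

## Problem sizes used in tests

The automated suite exercises full-size phantoms (0.58 mm voxels,
≈140×110×135 volumes, ≈65 slices per segmentation) in the end-to-end
acceptance checks — one noise-free case plus 20 speckled seeds segmented
from exact and from 2 mm-jittered initialisations — and a geometrically
smaller, coarser phantom (1 mm voxels, 2 mm ring spacing) in unit tests
where only plumbing or invariances are at stake. Simulated training
recovery uses 100 cohorts of 200 slices each.

## Known limitations

* The elliptical prior is strict: boundaries that genuinely deviate from an
  ellipse (bulky tumours, FIGO stage IV morphology) are smoothed over by
  design.
* Slices are processed independently; there is no 3-D regularisation along
  the stack beyond the axis model and the loft, so a single bad slice is
  damped only by its fallback and the ellipse fit.
* The semi-axial planes are fixed by the manual initialisation; the
  algorithm refines contours within planes but never re-orients the planes
  themselves.
* NIfTI/NRRD orientation handling assumes axis-aligned volumes in the
  (LR, AP, SI) frame; oblique acquisition matrices are not re-sliced.
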