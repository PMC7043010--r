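# stackedellipse

Semi-automatic 3-D segmentation of the uterus on B-mode ultrasound, for
image-guided adaptive radiotherapy of uterine cervix cancer.

The uterus moves and deforms daily during a course of radiotherapy, and
3-D transabdominal ultrasound can image it at the treatment couch — if the
organ can be segmented in minutes. This package implements the
**stacked-ellipse** approach: the uterus is hypoechoic (darker than its
surroundings) and its cross-sections orthogonal to the curved
fundus-to-cervix path are roughly elliptical, so the organ is modelled as a
stack of planar ellipses

```
(x - c1)^2 / a^2 + (y - c2)^2 / b^2 = 1
```

with the in-plane x axis along anatomical left–right (LR). One manually
contoured mid-sagittal slice with four landmark points supplies, for every
semi-axial slicing plane, the ellipse centroid `(c1, c2)` and minor
semi-axis `b`; the unseen LR semi-axis is predicted by a population model
`a = m·b + K` (default `a = 1.01·b + 11.3` mm) learned in a training phase
by parameterising gold-standard 3-D contours as ellipse stacks. Each
first-guess ellipse is then deformed to the uterine boundary using a
**directional edge map**

```
f = |∇V1 · J|² · R   where ∇V1·J > 0,  else 0
R = (1 − (d/max d)^k) · exp(−(d/max d)^k)
```

(`V1` the Gaussian-smoothed slice, `J` the outward unit gradient of the
initialisation contour's signed distance map, `d` the distance to that
contour), which keeps only dark-inside boundary polarity near the prior.
Contour points move along radial search windows of length `r` pixels to the
nearest edge-map peak, a direct least-squares ellipse regularises each
deformed contour, and the final ellipses are lofted into a watertight 3-D
surface. Defaults: `sigma = 4` px, `k = 1`, `r = 29` px.

Agreement between segmentations is measured with the Dice similarity
coefficient `DSC = 2|A∩B| / (|A|+|B|)` and the mean surface-to-surface
distance (MSSD, mm), reported as median [IQR] per patient and per cohort.

Because clinical volumes cannot be redistributed, the package includes a
synthetic phantom generator: a curved, hypoechoic, stacked-ellipse uterus
embedded in a brighter background with Gaussian point-spread blur and
fully developed multiplicative Rayleigh speckle, plus a simulated manual
initialisation with controllable observer jitter — every component of the
pipeline is testable against exact ground truth.

## Worked example

```r
library(stackedellipse)

spec <- phantom_spec(seed = 7)           # speckled anteverted-uterus phantom
case <- phantom_case(spec)
print(case$volume)
#> <volume3d> 140 x 111 x 136 voxels (LR/AP/SI), spacing 0.580 x 0.580 x 0.580 mm

seg <- segment_volume(case$volume, case$init)
print(seg)
#> <segmentation_result> 65 slices, mesh volume 53.8 cm^3, 0 warning(s)

ev <- evaluate_meshes(seg$mesh, case$truth_mesh)
cat(sprintf("DSC %.3f, MSSD %.2f mm\n", ev$dsc, ev$mssd_mm))
#> DSC 0.979, MSSD 0.34 mm

print(default_axis_model())
#> <axis_model> a = 1.010 * b + 11.300 mm (R^2 = 0.60, n = NA)
```

The phantom's manual initialisation is the truth's exact mid-sagittal
section here; the volume is fully speckled (interior/background intensity
ratio 0.5). A DSC of 0.979 with sub-millimetre mean surface distance says
the pipeline recovers a known stacked-ellipse target almost exactly under
heavy multiplicative noise; clinical images are harder (artefacts,
neighbouring organs, non-elliptical pathology), so accuracy there is bounded
by inter-observer contouring agreement rather than by these phantom
numbers.

A command-line front end mirrors the R API
(`inst/cli/se_tool.R`, subcommands `phantom`, `train`, `segment`,
`evaluate`, `batch`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","se_tool.R",package="stackedellipse"))')" \
    segment --volume vol.nii.gz --init init.json --out mesh.ply
```

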