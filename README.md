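# CortexMorph

3D morphometry and columnar spatial statistics for cortical neurons from
serial-section light microscopy.

Semi-thin serial sectioning turns a block of cortex into thousands of
sections on tape; scanned and aligned, they become an image stack in which
neuronal somata can be reconstructed in 3D. CortexMorph implements the
computational side of that workflow for people studying cortical
cytoarchitecture — biopsy placement, section detection, rigid stack
alignment, segmentation validation, 3D reconstruction with per-cell
morphometrics, pyramidal/non-pyramidal classification, nucleator
stereology, and a test for columnar organisation — together with a
synthetic-scene generator so the whole chain can be exercised and
calibrated without any external data.

The quantities at its core:

* **Sphericity** ψ = π^(1/3) (6V)^(2/3) / A for a cell of volume V and
  surface area A (1 for a sphere; elongated cells are lower).
* **Orientation** u = (d − c)/‖d − c‖ along the maximum Feret diameter with
  endpoints c, d, and θ = arccos |u·u₀| folded to [0°, 90°], where
  u₀ = (1, 0, 0) points toward the pial surface.
* **Nucleator estimates** from mean ray length l̄ between a profile's
  centroid and its boundary: Volume = (4/3)π l̄³, Diameter = 2 l̄.
* **Cylindrical K-function** K_u(r, t): ρ·K_u(r, t) is the expected number
  of further points within a cylinder of radius r and half-height t along
  direction u around a typical point; under complete spatial randomness
  K_u(r, t) = 2πr²t. Columnarity shows up as K̂ exceeding a 95%
  extreme-rank-length global envelope built from CSR simulations, most
  prominently for u along the pial axis.
* **Validation metrics** sensitivity = TP/(TP+FN),
  precision = TP/(TP+FP), F1 = their harmonic mean, applied pixelwise and
  objectwise (centroid-in-profile matching).

## Worked example

Simulate a cortex-like scene (pyramidal density 28,155 mm⁻³ arranged in
columns along x, mean volume 795 µm³, folded orientation ≈ 29°), run the
full pipeline, and test the recovered centroids for columnarity:

```r
library(CortexMorph)

p  <- sceneParams(seed = 11)        # 200 x 200 x 90 um window
sc <- simulateScene(p)
sc
#> SyntheticScene: 107 cells (87 pyramidal, 20 small round)
#> ImageStack 478 x 478 x 144 voxels, spacing (0.5, 0.5, 0.9) um
#>   intensity range [26.5, 243]

pl <- runPipeline(sc@stack, p$windowBox, seed = 1)
pyr <- subset(pl$cells, label == "pyramidal")
pl$pyramidalCount; pl$density
#> pyramidal cells: 85   density: 23611 mm^-3
mean(pyr$volume); mean(pyr$thetaDeg)
#> mean volume: 789 um^3   mean sphericity: 0.87   mean orientation: 28.7 deg

pat <- PointPattern3D(as.matrix(pyr[, c("cx", "cy", "cz")]), p$windowBox)
globalEnvelopeTest(pat, "x", r = seq(0, 25, length.out = 32), t = 80,
                   nsim = 199, seed = 2)
#> ERL global envelope test (95% level, 199 simulations)
#>   p = 0.01  (interval 0.01 - 0.01), observed ERL rank 2
#>   grid cells: 0 below, 19 inside, 13 above
```

The scene truly contained 87 pyramidal cells (24,167 mm⁻³ realised for this
seed); the pipeline recovers 85 of them as separate objects, their mean
measured volume is within 1% of the generated 795 µm³, the mean folded
orientation matches the generated ≈ 29°, and the envelope test flags
cylindrical clustering along the pial axis (p = 0.01, 13 grid cells above
the envelope) exactly where the generator put it.

The bundled published reference tallies reproduce through the same metric
code paths:

```r
reportMetrics(classificationMetrics(
  ConfusionCounts(TP = 128937, FN = 19923, FP = 11710)))
#> sensitivity   precision          f1
#>        0.87        0.92        0.89

formatSubjectSummary(subjectMorphometryTable()[, c("volume", "orientation",
                                                   "sphericity", "diaAll")])
#>      volume orientation sphericity diaAll
#> mean 795.00       29.00       0.35   7.03
#> sd    65.00        4.10       0.02   0.39
#> cv     0.08        0.14       0.06   0.06
```

See `vignettes/cortex-morphometry.Rmd` for the models, parameter choices
and numerical details.

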