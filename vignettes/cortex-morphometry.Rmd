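---
title: "Serial-section morphometry and columnar statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial-section morphometry and columnar statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CortexMorph)
```

CortexMorph reconstructs and measures neuronal somata from serial-section
light-microscopy stacks and tests their spatial arrangement for columnarity.
This vignette is the package's own account of the science: the models, the
parameters that matter, the numerical choices, and what the synthetic data
can and cannot show.

## The pipeline and its coordinate convention

The workflow mirrors a semi-thin-section study of layer III pyramidal cells
in human dorsolateral prefrontal cortex (Brodmann area 46): biopsy placement
on a tissue block, detection and rigid alignment of sections scanned from
tape, binary segmentation of somata, 3D reconstruction with morphometrics,
mixture-model separation of pyramidal from non-pyramidal objects, nucleator
stereology in 2D, and a cylindrical K-function analysis of the centroid
point pattern.

Throughout the package, dimension 1 of every voxel array is the in-plane
**x-axis pointing toward the pial surface**, dimension 2 the orthogonal
in-plane y-axis, and dimension 3 the sectioning (z) axis. All public
coordinates are micrometres; voxel (i, j, k) is centred at
`origin + ((i,j,k) - 0.5) * spacing`. Anisotropy is handled by physical
scaling: in-plane pixels are a few hundred nanometres (272 nm in the source
imaging setup) while the section interval is 800–900 nm, and every distance,
area and volume is computed in micrometres on that grid.

## The synthetic scene generator

Real stacks from the archival study are not redistributable, so every stage
is exercised on synthetic scenes whose ground truth is known exactly.
`sceneParams()` fixes the study conditions; `simulateScene()` draws a
columnar point pattern, attaches ellipsoidal cells, and renders an image
stack plus a voxel-exact truth labelling.

**Point process.** Cell centroids follow a Poisson cylinder-cluster
process: Poisson column centres in the y–z plane, a Poisson number of
points per column, x uniform over the window (columns traverse the full
height, as minicolumns traverse layer III), and Gaussian radial scatter of
scale `columnRadiusSD` wrapped periodically into the window. The default
column intensity is derived so the pyramidal intensity equals the target
density of 28,155 mm^-3; six cells per column with 10 µm radial scatter
gives ~40 µm column spacing in a 200 × 90 µm cross-section, consistent
with minicolumn geometry. An optional sequential hardcore thinning
(`hardcoreDistance`) is provided; the default relies on cell-level
exclusion instead (below).

**Cells.** Pyramidal cells are prolate spheroids. Volumes are log-normal
with mean 795 µm³ (`cellVolumeLogSD = 0.45`, a moderate spread; the very
large per-subject SDs of the source data partly reflect segmentation
artefacts that a clean generator should not imitate). The aspect ratio is
solved in closed form so the analytic spheroid sphericity matches a drawn
target, and the long axis makes a folded-normal angle with the x-axis
(scale 36°, so the mean folded angle is ≈ 28.7°, matching the observed
≈ 29°) with uniform azimuth. A quarter of the points are emitted as small
round cells (spheres, mean 120 µm³) so the downstream classifier has a
non-pyramidal class to find.

**Why the sphericity target is 0.85, not 0.35.** For a smooth spheroid,
sphericity 0.35 requires an aspect ratio near 50:1 — a 795 µm³ cell would
be ~156 µm long, incompatible with the stated volume, density, and any
plausible soma. The low published value arises from the surface roughness
of marching-cubes meshes of irregular real cells, a feature a smooth
ellipsoid cannot have. The generator therefore keeps the volume, density
and orientation marginals and uses a realistic soma elongation (aspect
≈ 3:1, ψ = 0.85, ~24 µm long). Passing tests consequently demonstrate
correct measurement of smooth somata; they say nothing about the sphericity
distribution of rough, irregular real cells.

**Impenetrability.** Somata cannot interpenetrate. Without a constraint,
~17% of cells at the default density and column geometry overlap a
neighbour, the segmenter fuses them, and the recovered density biases low
by ~20% — an artefact of the generator, not of the measurement chain. With
`excludeOverlaps = TRUE` (default) each cell is placed sequentially and
redrawn at another position in its own column if its ellipsoid would
intersect an already placed cell (a conservative bounding-extent test with
a 0.5 µm neuropil gap; the cell is dropped after 20 failed tries, which is
rare). Density recovery is then within a few percent.

**Rendering.** Truth labels are voxelised on the anisotropic grid (a voxel
belongs to the nearest cell whose ellipsoid contains its centre; ties to
the lower id). The intensity stack is a light background (200) with dark
cells (60) — toluidine-blue contrast — convolved with a Gaussian PSF
(σ = 0.4 µm) and degraded with additive Gaussian noise (SD 8, i.e. ~6% of
the contrast). The stack extends beyond the analysis window by a pad
covering every cell, so boundary cells are rendered whole;
`stackOrigin()` records the offset. What the generator does **not**
emulate: dendrites and axons, staining gradients, section-to-section
intensity variation, folds, or debris. Results on synthetic scenes
therefore bound the measurement error of the geometry pipeline, not the
difficulty of segmenting real tissue — which is why the bundled segmenter
is a reference implementation for controlled contrast and externally
produced masks are first-class inputs.

**Scale.** The default window is 200 × 200 × 90 µm at (0.5, 0.5, 0.9) µm
spacing: ~3 × 10⁷ voxels and ~135 cells per scene, chosen so a full
render–segment–measure cycle stays within tens of seconds and a few
gigabytes. The native 272 nm pixel is exercised in the voxelisation and
ball-morphometry tests; measurements are stable across this range because
everything is computed in physical units.

## Acquisition helpers

`planBiopsies()` thresholds the block image (Otsu) inside a user polygon,
erodes the sample area with a Euclidean-disk structuring element whose
diameter equals the biopsy diameter (so a punch cannot straddle the
boundary), splits the area into four quarters at the rows where the
cumulative white-pixel mass passes 25/50/75%, and draws one seeded uniform
position from each of two non-adjacent quarters.

`detectSections()` finds sections on a slide montage by local entropy:
sections carry fine texture, empty tape is flat. Gaussian blur (σ = 2 px)
suppresses noise-induced entropy; the entropy window (9 × 9 px) matches the
texture scale of stained tissue at the stated pixel size; both are
configurable. Components above a minimum area become sections, numbered
bottom-right to top-left (the tape-gluing order; configurable), with
optional every-k-th systematic sampling.

`alignStack()` registers consecutive sections rigidly: an exhaustive
coarse angle search with FFT cross-correlation for translation, then
Nelder-Mead refinement of (angle, dx, dy) against a 50-bin mutual
information with partial-volume (linear) bin spreading — an intensity
metric that tolerates differing intensity distributions between sections.
Registration runs on 4×-downscaled images for speed, with a
full-resolution refinement pass so the recovery tolerance (0.2°, 1 px) is
met; pairwise transforms are composed into the first image's frame and the
stack is resampled bilinearly, out-of-frame pixels filled with the median
background. The original environment's coarse-stage defaults are not
reproducible in the abstract, so the contract here is accuracy, verified on
known synthetic transforms, not a specific optimiser.

## Reconstruction and morphometrics

`labelAndFilter()` labels 26-connected 3D components and applies the
artifact rules: components under 8 voxels are noise; in validation mode,
objects spanning fewer than 4 consecutive sections (< ~3 µm tall) are
dropped; objects whose centroid lies in the first or last 3 sections are
*marked* (not deleted) because their centroids are unreliable where cells
are cut by the stack border.

`measureCells()` computes, per object:

* **volume** — voxel count × voxel volume (exact given the labelling);
* **surface area** — a marching-tetrahedra isosurface at level 0.5 of the
  binary field pre-smoothed with a σ = 1 voxel Gaussian, vertices on the
  physically scaled grid. Raw binary marching cubes overestimates a
  sphere's area by ~30% (staircase facets); σ = 1 voxel brings the ball
  error under 2% even at (0.272, 0.272, 0.9) µm spacing, at the price of
  rounding sharp corners (a cube's area reads ~4% low — the documented 5%
  "mesh tolerance" for polyhedra). Structures thinner than ~2 sections can
  have their area under-read, inflating sphericity; such objects are
  typically artifacts or merged cells and are screened downstream;
* **sphericity** — ψ = π^(1/3) (6V)^(2/3) / A, scale-invariant by
  construction (asserted numerically in the tests);
* **maximum Feret diameter (3D)** — the largest pairwise distance over
  boundary-voxel centres, with its endpoints; per-section profiles carry
  the 2D analogue over convex-hull vertices of the boundary polygon;
* **orientation** — u = (d − c)/‖d − c‖ from the Feret endpoints, and
  θ = arccos |u·(1,0,0)| folded to [0°, 90°]: the Feret axis has no sign,
  and folded angles are consistent with the observed 24–34° means.

## Classification

`selectLayer3()` finds the analysis window from the kernel-smoothed density
of centroid x-coordinates: layers II and IV are the two dominant peaks, and
the window is the interval between them shrunk by 10% of the inter-peak
distance on each side (keeping clear of the density shoulders); a manual
pass-through mirrors the click-based ROI of interactive workflows.

`gmmSplit()` fits a 2-component full-covariance Gaussian mixture to the raw
(volume, sphericity) pairs of the cells **below the mean volume** — the
small-round confusion (pyramidal top/bottom profiles resembling glia) lives
only at the small end of the volume scale, and restricting the fit keeps
the large-volume mass from dominating both components. The component with
the lower mean volume (ties: lower mean sphericity) is the non-pyramidal
class; its hard assignments are excluded and everything else, including all
above-mean cells, is pyramidal. The EM uses seeded k-means initialisation,
full covariances with a 10⁻⁶ ridge, and unstandardised features
(standardisation would change the fit); an installed reference fitter
(mclust) agrees with it on test mixtures to ≥ 98%.

`outlierFilter()` removes merged cells and vessels: anything whose
log 2D or log 3D maximum Feret exceeds the pyramidal mean by 3 SD. Only the
upper tail is screened — the targets are *big* objects — so removing the
step can only increase the pyramidal count. Under a pure log-normal the
false-flag rate is ~0.1–0.3%.

`numberDensity()` is count over window volume; densities are ratios, so
they conflate count changes with reference-volume changes (the classic
"reference trap") and should be compared with care.

## Nucleator stereology

`profileRayLengths()` casts 5 rays at 72° spacing from a random start angle
out of the profile centroid and measures the distance to the first boundary
intersection (exact ray–polygon arithmetic on the µm-coordinate boundary;
the nearest intersection wins, so non-convex profiles are handled;
profiles whose centroid falls outside their boundary are skipped).
`nucleatorEstimates()` converts the mean length l̄ into
Volume = (4/3)π l̄³ and Diameter = 2 l̄, either from the largest profile
(usually the equatorial section) or from all profiles pooled. The cube of
the *mean* is deliberate — it mirrors the tabulated workflow this package
reproduces — although classical nucleator theory cubes before averaging;
`classical = TRUE` provides (4/3)π·mean(l³) for comparison. For a perfect
sphere the largest-profile variant is exact and the all-profiles variant
strictly underestimates (off-equator chords are shorter), which is the
basis of the 2D-versus-3D size comparison: `sphereEquivalentDiameter()`
gives the 3D reference d = (6V/π)^(1/3).

## Cylindrical K and global envelopes

For a stationary point process with intensity ρ, ρ·K_u(r, t) is the
expected number of further points in a cylinder of radius r and half-height
t aligned with u, centred at a typical point; under complete spatial
randomness K_u(r, t) = 2πr²t. The estimator sums, over ordered pairs,
the indicator that the displacement falls in the cylinder, weighted by the
translation edge correction 1/|W ∩ W_h| (a product of 1D overlaps for a box
window), scaled by |W|²/(n(n−1)). Pair contributions are binned once on
the (r, t) grid and cumulated, so the full 64 × 64 surface costs one pass
over pairs. The estimator is checked against a hand-computed two-point
configuration (exactly) and the CSR expectation (in the mean over seeds).

`globalEnvelopeTest()` ranks the observed surface among `nsim` CSR
simulations (binomial: the observed n, uniform in the observed window) by
**extreme rank length**: pointwise two-sided depth ranks, each curve
summarised by its vector of sorted depths, curves ordered lexicographically
(ties share a rank). The 95% envelope is the pointwise hull of the curves
remaining after discarding the ⌊0.05(nsim+1)⌋ most extreme; the Monte-Carlo
p is the proportion of curves at least as extreme as the observed one, with
a tie interval. Grid cells where the observed surface exits above indicate
cylindrical clustering along u; below, repulsion (expected at small r:
somata exclude each other). The published designs — 64 × 64 over
r ∈ [0, 25], t ∈ [0, 80] with 4000 simulations, or fixed t = 80 with
2000 — are the defaults' upper end; tests run at nsim = 199, where the
nominal 5% level is exact by exchangeability (the type-I rate is verified
at 5% ± 2% over 500 replicates, and power against the strong columnar
fixture, σ_r = 5 µm and 20 points per column, is ≈ 1).

## Objectwise validation and summaries

`matchObjects3D()` implements centroid-in-profile matching: a reference
object is a true positive when its rounded centroid voxel lands inside a
predicted object's profile in the centroid's own section; false positives
are the reverse test on predicted centroids. Membership is tested in the
single section plane (a `membership = "column"` flag relaxes this to any
section, since published descriptions are ambiguous on the point).
Edge-flagged objects are excluded from the tallies, which is what turns the
original counts (472/19/33) into the filtered ones (368/6/29) in the
bundled reference data.

`aggregateSubjectStats()` uses the **population** SD (divisor n): the
printed summary rows are only reproducible that way (the sample SD of the
per-subject volumes is 79.8 against a printed 65). The reporting helper
`formatSubjectSummary()` additionally computes the displayed CV from the
*display-rounded* SD over the mean, rounded half-up — the one convention
that reproduces every printed CV cell, including Dia_All where the
full-precision CV would round to 0.05 instead of the printed 0.06. Note
the printed Dia_L mean (11.17) is itself not recoverable from the printed
per-subject values (they average to 11.177 → 11.18); it was evidently
computed from unrounded intermediates, and the package does not force
agreement.

`pointCountArea()` (A = ΣP × a/p) and `arealShrinkage()`
((before − after)/before, negative = swelling) support the tissue
deformation check; the bundled reference shrinkages (0.1%, 4.2%, 7.9%) are
small enough that no shrinkage correction is applied anywhere.

## Numerical choices and limitations

* Rounding for tabular reporting is half-up at 2 decimals (`roundHalfUp`),
  matching the printed tables; R's own `round()` is half-to-even.
* Connectivity is 26 in 3D and 8 in 2D, the defaults of the measurement
  environment the reference workflow used; both are configurable.
* The reference segmenter declares a stack empty when Otsu's split
  separates the class means by < 4 pooled within-class SDs; splitting pure
  Gaussian noise can reach at most ~2.7, while genuine two-level stacks sit
  far above.
* Degenerate inputs fail loudly: empty patterns, non-binary masks,
  zero-volume windows, undefined metrics (TP+FN = 0), sphericity targets
  above 1, coincident Feret endpoints.
* The pipeline does not split touching cells (no watershed); merged objects
  are handled by the downstream outlier screen, as in the workflow it
  mirrors. The generator's impenetrability constraint keeps true contacts
  rare, but on real tissue under-segmentation remains the dominant error
  mode and densities should be read accordingly.
* Tests and the acceptance script use scaled-down replicate counts
  (nsim = 199 envelopes, 5 scene seeds, 200 CSR replicates) chosen to keep
  a desk-scale run; all published-scale settings (2000/4000 simulations,
  native pixel size) remain available through arguments.
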