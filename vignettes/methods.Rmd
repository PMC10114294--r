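---
title: "Methods: morphometrics and spatial statistics for organoid volume EM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometrics and spatial statistics for organoid volume EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidvem)
```

This vignette is the package's own account of the measurements it implements,
the models behind its synthetic data generator, the numerical choices that
were genuinely open, and what the passing tests do and do not demonstrate
about real data.

## The measurement problem

A FIB-SEM acquisition of an organoid, after CNN segmentation, is a set of
co-registered 3D label volumes: one semantic mask per structure class (cell
bodies, nuclei, mitochondria, cell junctions, microvillar actin bundles,
lumen) on a voxel grid with physical spacing of tens of nanometres, usually
anisotropic (the axial step exceeds the lateral pixel size; a typical binned
acquisition has 30 × 30 nm pixels and 40 nm sections). The package treats
such a volume as a `labeled_volume`: a 3D integer array in `(z, y, x)` order
with its spacing in nanometres. Voxel `(k, j, i)` (0-based) has its center at
`((i + 0.5) s_x, (j + 0.5) s_y, (k + 0.5) s_z)`; all physical results are
reported in micrometres.

Five analyses are built on this substrate.

### Instance extraction

A semantic mask becomes a set of objects by 3D connected components:
two foreground voxels belong to the same object iff they are connected under
the chosen adjacency *and* carry the same semantic label. The default
adjacency is 26-neighbourhood (faces, edges, corners), the common convention
for foreground objects; 6-neighbourhood is available. The components code is
compiled (breadth-first search); the test suite checks it against an
independent implementation built from `igraph` components on the voxel
adjacency graph, exactly, over random volumes at both connectivities.
Objects touching the volume border are flagged so downstream statistics can
exclude them — whether to do so is left to the analyst, since border objects
have censored geometry but valid centroids.

### Volume, centroid, surface area, sphericity

Volume is exact: voxel count times the physical voxel volume. The centroid
is the unweighted mean of voxel centers (no intensity weighting). Sphericity
is Wadell's

$$\Psi = \frac{(6\sqrt{\pi}\,V_p)^{2/3}}{A_p},$$

the area of the volume-equivalent sphere over the particle's own surface
area: 1 for a sphere, $(\pi/6)^{1/3} \approx 0.806$ for a cube.

Surface area of a voxelised object is the one genuinely delicate
morphometric. Counting exposed voxel faces converges to the wrong answer —
for a smooth surface it overestimates by a factor of $3/2$ on average (the
mean of $|n_x|+|n_y|+|n_z|$ over uniformly oriented unit normals), and the
package keeps that estimator only as a flagged diagnostic. The default
estimator is a weighted 2×2×2 local-configuration sum: every cell of the
dual lattice (the cube spanned by 8 neighbouring voxel centers) is
classified into one of 256 in/out configurations, and the area is the
weighted configuration count. The weights are fit once per voxel spacing by
constrained least squares over digitized planes:

* For a plane with index-space normal $\hat m$ and uniform offset, the
  expected configuration mix per unit area has a closed form — sort the
  eight corner projections onto $\hat m$; the gaps between consecutive order
  statistics are the densities of the seven configurations the plane
  produces as it sweeps a cell.
* The regression target for orientation $\hat m$ is the physical area of
  that plane element, $\det(S)\,\lVert S^{-1}\hat m\rVert$ with
  $S = \mathrm{diag}(s_z, s_y, s_x)$, which makes the same fit valid on
  anisotropic grids.
* Two constraints are imposed exactly: the six face configurations carry
  their exact physical face areas (so axis-aligned surfaces — and hence
  boxes — are measured exactly up to edge effects), and the mean residual
  over orientations is zero (so smooth curved surfaces are asymptotically
  unbiased rather than carrying a small systematic offset).
* Configurations that never occur on planes (isolated corners, thin plates)
  fall back to the area of a marching-tetrahedra mesh of that configuration
  through a ridge prior, and the fitted weights are averaged over the
  symmetries of the grid.

Measured accuracy on digitized test bodies (isotropic grid): balls of radius
10/20/40 voxels are recovered within 0.3%/0.15%/0.01% with the error
decreasing monotonically in radius; a 10×20×30 box within 4%; a ball
sampled anisotropically at (400, 300, 300) nm within 0.5%. The estimator is
scale-exact: scaling the spacing by $\lambda$ scales areas by $\lambda^2$
and leaves $\Psi$ unchanged. The documented estimator tolerance for
sphericity on digitized convex bodies is 0.05, and the test geometry places
ball centers at a generic sub-voxel offset — at symmetric offsets the
voxelisation error of one radius can be accidentally near zero, which would
make the convergence comparison meaningless.

### Nearest neighbours with proximity exclusion

Inter-object distances are Euclidean 3D distances between centroids, in
physical units, computed by an exact pairwise scan (no spatial indexing
approximation touches any reported distance). Centroids are used instead of
boundary-to-boundary distances deliberately: they are robust to imperfect
segmentation of object outlines.

Before the distances are computed, the proximity-exclusion rule removes
objects that cannot be trusted to be genuinely separate: at ~40 nm axial
resolution, two same-class objects whose minimum gap is below 50 nm are as
likely one object split by a segmentation artifact. The gap is measured as
the minimum physical distance between voxel centers of the two objects,
within one structure class only. Both members of a close pair are removed by
default; whether one or both members of an unresolvable pair should go is a
genuinely open convention, settled here in favour of both, because keeping
either one silently fabricates geometry (an `exclude_one` mode that keeps
the larger member exists for comparison). Raising the threshold can only shrink the retained set, a
property the tests enforce.

Summaries report the fraction of objects within each queried distance
(1 µm by default) and percentiles by linear interpolation between order
statistics (R's quantile type 7) — the package fixes this single quantile
definition everywhere, including the box statistics, since published figures
rarely state one.

### Density maps

The local concentration of a structure is its volume fraction inside a
spherical sampling kernel scanned over a regular node grid. A voxel belongs
to the kernel iff its center lies within the kernel radius of the node —
a definition chosen because a brute-force voxel count can reproduce it
exactly, which is how the implementation is tested (equality to within
1e-9). Defaults: kernel radius 1.0 µm (sampling volume 4.19 µm³) and step
0.25 µm. The radius deserves a note: published methods for this analysis
describe "a sphere of 1 µm diameter (~4 µm³)", which is internally
inconsistent — a 1 µm *diameter* sphere holds 0.52 µm³, a 1 µm *radius*
sphere 4.19 µm³. The package honours the quantitatively operative volume
statement and defaults to radius 1.0 µm; passing `kernel_radius_um = 0.5`
selects the literal diameter reading. Neither reading is silently imposed.

At volume edges the kernel is clipped. The default policy renormalises by
the in-bounds kernel volume and marks nodes with under 50% kernel coverage
invalid; a strict policy invalidates any clipped node. The co-occurrence of
two maps (junctions vs actin bundles) is summarised by their Pearson
correlation over jointly valid nodes plus the Jaccard overlap of their
high-density node sets at a stated quantile (default 0.9) — a numerical
stand-in for what is usually assessed visually on rendered maps.

### Preservation and packing statistics

High-pressure frozen 3D cultures vary in how well their ultrastructure
survives vitrification. The package takes manually scored TEM tiles
(damaged / intact per tile, per organoid) as *input* — scoring is a visual
call and no automated damage detection is attempted — and computes
per-organoid preserved fractions, per-group box statistics (median, 25–75%
interval, min, max), packing density (organoid cross-sectional area divided
by cell count, µm² per cell) and the Pearson correlation between packing
density and preservation across organoids.

## The synthetic organoid generator

Real acquisitions are hundreds of gigabytes and their segmentations come
from commercial CNNs; neither is reproducible at desk scale. The generator
replaces them with seeded label volumes whose ground truth is known exactly,
so that every statistic above has a recovery test. It emulates:

* **Three packing morphologies.** `monolayer`: one shell of
  Voronoi-partitioned cells around a central ellipsoidal lumen, lumen
  fraction targeted at 60% of the organoid (the mature-organoid regime);
  `compact`: a Voronoi partition of the filled ellipsoid, no lumen;
  `mixed`: a compact body with 2–4 embedded lumina targeted at 15% total.
  The achieved lumen fraction is driven to within ±0.05 of target by
  bisection on the lumen scale against actual voxel counts.
* **Nuclei**, one per cell: an ellipsoid centered at the cell's interior,
  clipped to the cell, with its scale bisected so the achieved volume is the
  programmed fraction of the cell volume (default 0.25). Axis ratios control
  nuclear sphericity.
* **Mitochondria**: per-cell counts proportional to cell volume (0.03 per
  µm³), volumes log-normal (median 0.25 µm³, log-sd 0.6) — small organelles
  with a heavy right tail. Optional planted giants of a programmed multiple
  of the median volume (voxelised to the target via bisection inside the
  host cell) provide exact ground truth for outlier-flagging recovery.
* **Cell junctions**: a hard-core point process on cell–cell interface
  voxels — no two centers closer than twice the junction radius. When a
  target 90th-percentile NN distance is requested, the process is confined
  to a contiguous interface patch whose area fraction is tuned by bisection
  until the empirical 90th percentile matches; clustering by confinement
  with a hard-core minimum is a Matérn-type construction. If the request
  exceeds what the whole interface allows (too many points for the area),
  that is a feasibility error, not a silent compromise.
* **Actin bundles**: ~1-µm fibers seeded on lumen-facing cell surfaces,
  oriented along the outward surface-normal proxy, at a programmed surface
  density — the microvillar brush lining epithelial lumina.
* **Tile tables**: per-tile Bernoulli damage draws at per-organoid rates.
  Group means default to the preservation regimes of the systems the
  statistics are built for (compact colorectal organoids 0.83, breast-cancer
  spheroids 0.75, large-lumen mammary organoids 0.20, cryo-protected 0.77).
  Each organoid's packing density is coupled to its latent preservation
  propensity with a default observed correlation of 0.39. Because the
  finite number of scored tiles adds binomial noise to the observed
  fraction, the latent coupling is inflated by the classical attenuation
  factor $\sqrt{1 + \sigma^2_{\text{binom}}/\sigma^2_{\text{latent}}}$, so
  the *measured* correlation at the stated conditions matches the
  programmed one; degenerate rates (0 or 1) stay exactly degenerate.

All randomness derives from the seed in the spec; the same spec yields
bit-identical scenes. Containment invariants (nuclei and mitochondria inside
their cells, lumina disjoint from cells, junction centers on interfaces)
are tested across a sweep of 20 seeds.

**What the generator does not emulate** — and hence what passing recovery
tests do *not* show: grayscale EM texture, CNN segmentation errors, freezing
damage, curtaining artifacts, real junction clustering (the patch-confined
hard-core process is a stand-in; no quantitative clustering model for
junctions exists to copy), or realistic nuclear lobation and mitochondrial
network topology. Recovery tests demonstrate that the *measurement chain* is
correct, not that real organoids look like the phantoms.

## Numerical choices and problem sizes

* Quantiles: linear interpolation between order statistics, everywhere.
* Instance ids: assigned in raster scan order, so identical input gives
  identical ids.
* Degenerate inputs: empty volumes yield empty instance sets; outlier
  flagging requires ≥3 objects; NN requires ≥2 retained objects;
  correlation requires ≥3 pairs and nonzero variance — all hard errors, not
  NAs.
* The configuration-weight fit uses 12,000 quasi-uniform orientations
  (Fibonacci lattice) and is cached per spacing within a session; it takes
  about two seconds.
* Test and demonstration scenes use organoids of ~15–20 µm at 250–300 nm
  voxels (a few million voxels) and point processes up to n = 5,000; these
  sizes keep the full suite at a couple of minutes on one core while leaving
  every statistical tolerance attainable (the junction-scale recovery is
  checked at ±5%, which needs thousands of points). The same code paths are
  size-independent and have been run on 64³–500² grids in the suite; truly
  full-scale volumes are bounded by memory (a dense int array of a
  binned whole-organoid acquisition is several gigabytes), not algorithmic
  structure.

## Known limitations

* MRC output is limited to 16-bit labels (the format has no 32-bit integer
  mode among the modes implemented); TIFF to 16-bit. More than 65,535
  objects per volume therefore cannot round-trip through these files,
  though they are fine in memory.
* HDF5 is not currently among the supported on-disk formats.
* The surface-area estimator is unbiased for planes and spheres but still
  chamfers sharp edges slightly (boxes read ~2–4% low); sphericities of
  strongly concave or plate-like objects inherit the local-configuration
  estimator's limits at features a couple of voxels across.
* The proximity-exclusion gap is voxel-center based; at very coarse voxels
  it overstates the true boundary gap by up to one voxel diagonal.
* Nearest-neighbour analysis is per volume and single-class by design;
  cross-class distances (junction-to-actin) and pair-correlation functions
  are out of scope.
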