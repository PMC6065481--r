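---
title: "Methods: topology-preserving cortical segmentation and equivolumetric layering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology-preserving cortical segmentation and equivolumetric layering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cortexr)
```

This vignette documents the models, numerical choices and design decisions
behind `cortexr`, in the spirit of a methods section: what each stage
assumes, which parameters matter, and what the synthetic phantoms do and do
not establish about real data.

## Level sets as signed distance functions

Surfaces are carried implicitly: a level set is a volume `phi` of signed
Euclidean distances to the surface, negative inside, with the surface at
the zero crossing. Working on the voxel grid instead of triangular meshes
keeps every operation local and makes digital-topology control exact.

**Construction.** `probability_to_levelset` places the surface on the 0.5
isosurface of a probability map. Zero crossings are sampled on grid edges
(axis, face-diagonal and body-diagonal directions for continuous maps;
axis midpoints for binary masks, where no sub-voxel information exists)
and every voxel receives its distance to this interface sample: exactly,
via a bucketed nearest-point search, within 2.5 voxels of the surface, and
by Danielsson-style feature sweeps beyond. Within ~1.2 voxels of the
surface the point distance is replaced by a moving-least-squares average
of *oriented plane* distances (normals from the probability gradient),
which removes the tangential corrugation a discrete sample cloud imprints
on a min-distance and is what keeps the discrete Eikonal residual
`| |grad phi| - 1 |` at or below 0.1 throughout a 5-voxel band. Distances
are exact rather than PDE-propagated because local eikonal solvers
accumulate a few-percent bias at depth (focal regions), which matters for
the laminar stage.

**Reinitialization** re-derives the interface samples from the current
field by linear interpolation, so the zero crossing moves by less than
half a voxel. **Curvature** is the mean of the two principal curvatures,
computed from central second differences with an epsilon-guarded
normalization and clamped at the voxel resolution limit; a sphere of
radius r gives 1/r.

The *narrow band* (default half-width 5 voxels) is where values are kept
exact during evolution; the Eikonal contract is only meaningful for shapes
whose curvature radius exceeds the band, since the true distance function
of any shape is non-smooth on its medial axis. The random smooth phantoms
used in the validation are constrained accordingly (curvature radius
above ~6 voxels); sharper geometry is representable but its band will
contain genuine distance-function creases.

## Digital topology

A voxel is a **simple point** when flipping it changes neither the
foreground nor the background topology locally. We use the topological
number characterization: the number of connected components of the set
restricted to the geodesic neighborhood (N18 for 6-connectivity, N26 for
18/26) that touch the center must be one for both phases. The default
pair is (6,26) — 6-connected foreground against 26-connected background —
the standard choice that guarantees digital Jordan separation; (26,6),
(6,18) and (18,6) are accepted with the same order-2 geodesic
construction. The implementation is validated against an independent
component-labeling oracle on 10^5 random neighborhoods.

The **Euler characteristic** is `V - E + F - C` of the cubical complex of
closed voxel cubes (ball 1, hollow shell 2, solid torus 0). The complex of
closed cubes realises 26-adjacent foreground; for the well-composed masks
the pipeline produces, the admissible pairs agree, and the
`connectivity_pair` argument is validated for interface symmetry rather
than switching complexes.

**Evolution** (`evolve_levelset`) advects the front with normal speed
`F - 2 w kappa` (speed field plus mean-curvature regularization, weight
`w`), Godunov upwinding for the advection term, central differences for
the curvature term, and an adaptive time step capping front movement at
0.45 voxel per iteration (a fixed `dt` can be supplied). Sign flips are
the unit of topology control: when `preserve_topology` is on, a voxel may
change side only if it is a simple point, flips being attempted per
checkerboard parity class in scan order — a deterministic schedule in
which concurrently flipped voxels are never face-adjacent, so each
decision sees a consistent neighborhood. Rejected flips are parked just on
their old side of zero. The field is rebuilt to a signed distance every 5
iterations; convergence is declared when the largest per-iteration front
movement drops below `tol` (in voxels), and the result records which
condition fired.

## Skull stripping

The second-inversion image of an MP2RAGE acquisition has bright head
tissue on a dark background, so masking reduces to noise-floor
estimation: the histogram mode of the low-intensity range locates the
background level, the values at or below it form a half-normal sample
whose RMS gives `sigma_bg`, and the head is `intensity > k * sigma_bg`
(default k = 5, a conventional noise-floor multiple), closed with radius 2
voxels, reduced to the largest 6-connected component and hole-filled. Both
parameters are exposed. In the noiseless limit `sigma_bg = 0` and the mask
is exactly the nonzero support. The mask is computed from the second
inversion only; companions are multiplied by it, so zeroed (e.g. defaced)
regions inside the head survive as in-mask zeros.

## Tissue segmentation

Each registered contrast model maps structure names to Gaussian intensity
parameters; contrasts are treated as conditionally independent, so
log-likelihoods add. An optional per-structure prior stack enters as a
log-prior — this is also how mirror-symmetric structures (left/right
homologues with identical intensity models) are disambiguated, via
`hemisphere_priors`. The maximum-a-posteriori labeling initializes a
competitive boundary evolution: every voxel with a differently-labeled
6-neighbor may switch to its best-scoring neighboring label, the score
being the posterior log-gain plus a boundary-smoothness term
(`curvature_weight` per agreeing 26-neighbor, default 0.1 in log-posterior
units — small enough that intensity evidence dominates except at
boundaries). With topology preservation on, a switch must keep the voxel
simple for both the losing and the gaining structure, so every structure
retains the Euler characteristic and component count of its
initialization. Sweeps repeat until fewer than `tol` (fraction of voxels,
default 1e-4) change.

Outputs follow the ranked-membership convention: `segmentation` (winning
labels), `distance` (Euclidean distance to the nearest inter-structure
boundary, implemented as the EDT of the set of voxels with a
differently-labeled 6-neighbor — the "nearest boundary" reading),
`memberships`/`labels` (top-k posterior stacks, k = 4 by default, enough
for the downstream region grouping). Where the topology constraint keeps
a lower-posterior label in front, lower ranks are capped at the rank above
so the stacks stay descending; rank 1 always matches `segmentation`.

## Region extraction and cortical reconstruction

`extract_brain_region` groups ranked memberships by a plain-text recipe
table (region = cortical GM of the target; inside = its WM with filled
subcortex and ventricles; background = the rest), renormalizes the
triplet to sum to one, and derives masks as its argmax. The inside
compartment seeds the topologically spherical reconstruction, so it is
reduced to its largest 6-connected component and cavity-filled, with the
probabilities adjusted so the argmax contract survives; stray
intensity-ambiguous scraps (e.g. CSF voxels labeled as ventricle) are
demoted to background.

`cruise_cortex_extraction` then runs two topology-preserving evolutions:
the gray–white boundary from the inside mask under a `tanh`-squashed
white-vs-rest posterior balance, and the pial boundary outward from it
under the (white+gray)-vs-CSF balance, with curvature weight 0.2 (a
slightly stronger smoothing than the segmentation stage, since membership
maps are noisier than intensities at boundaries). Before the pial
evolution, thin sulci are protected: where two gray-matter banks approach
within a 2-voxel gap along a grid axis, the CSF probability on the gap
ridge is raised to at least the GM probability plus 0.05, so the pial
surface cannot bridge a buried fundus. Nesting `phi_cgb <= phi_gwb` is
enforced by clamping after every step, which preserves it exactly. The
evolutions preserve — not correct — the initialization's topology; a
non-spherical initialization triggers a warning.

## Equivolumetric layering

Between nested boundaries, the equidistant coordinate
`alpha = d_in / (d_in + d_out)` ignores folding: a layer at fixed `alpha`
is too thick on one side of a fold and too thin on the other. The
equivolume model instead assigns each voxel the fraction `rho` of the
local column volume below it. Under a linear variation of cross-sectional
area between `A_in` and `A_out`,

    rho(alpha) = (2 A_in alpha + (A_out - A_in) alpha^2) / (A_in + A_out),

whose inverse is the closed form in `equivolume_fraction`. The area ratio
comes from the tube formula `A_out/A_in = (1 + kappa t)^2` with `t` the
column thickness and `kappa` the inner-surface mean curvature, sampled
from the level set, corrected to the zero crossing through
`kappa_surf = kappa / (1 - kappa phi)`, box-smoothed (3^3) against
discretization noise, and averaged with the equivalent outer-surface
estimate. The quadratic form is exact for concentric spheres (area ratio
196/100 for radii 10 to 14), which is what places the mid-depth surface
within a fraction of a percent of the analytic equivolume radius
`((r_in^3 + r_out^3)/2)^(1/3) = 12.33`. Columns thinner than one voxel
keep the equidistant coordinate (the area estimate is unstable there);
their count is reported as attribute `n_thin`.

Depth runs from 0 at the gray–white boundary to 1 at the pial surface —
the orientation is a convention, and `invert = TRUE` flips the depth map
and laminae numbering (the boundary surfaces keep their geometric order).
Intracortical boundaries are built as level sets of `depth - rho_j`,
re-derived as signed distances, and clamped sequentially so nesting holds
voxelwise. Lamina volumes are measured sub-voxel by integrating a
piecewise-linear Heaviside of each boundary (`levelset_volume`): at
realistic thickness (a 4-voxel cortex cut into 4 laminae) raw voxel
counting has a quantization floor near 8%, which says nothing about the
surfaces themselves; the sub-voxel measure is the meaningful one and
agrees with the analytic shell volumes to ~3%.

## The phantom: what it emulates, and what it does not

`make_phantom` builds nested geometries (spheres, a radially perturbed
"folded" cortex whose inner boundary folds twice as strongly as the outer
one so thickness varies with the folds, a flat slab, and two connected
hemispheric shells with subcortical structures) and simulates the MP2RAGE
triplet on top: a second inversion with zero-mean background, a
T1-weighted image bright in white matter, and a quantitative T1 map with a
high-variance noise background, with per-class Gaussian noise scaled by a
global `noise_sd` multiplier (0.1 by default — i.e. spreads at 10% of
their nominal class values, the regime the recovery criteria are stated
at). Intensity levels are 7T-plausible class means; the defaults are in
`default_tissue_params`.

The phantoms establish correctness of the machinery — distance properties,
topology preservation, boundary placement, the equivolume geometry — under
known truth. They deliberately do not model B1 inhomogeneity, bias
fields, partial-volume mixing beyond nearest-label assignment, Rician
noise, or realistic folding statistics; passing them does not certify
segmentation accuracy on real 7T data, where contrast models would need
calibration and the atlas-driven priors of a full production pipeline.

## Validation problem sizes

The shipped test-suite and acceptance script run at sizes chosen to
exercise every code path while staying desk-scale: 41–48^3 grids for
level-set, topology and laminar geometry checks, 64^3 for segmentation
recovery and the end-to-end pipeline, 20 random smooth phantoms for the
Eikonal property, and 10^5 random neighborhoods for the simple-point
oracle. A full 64^3 pipeline run takes on the order of a minute on one
CPU.

## Known limitations

* Segmentation uses voxelwise relabeling on the discrete label map rather
  than continuous multi-phase level sets; sub-voxel boundary refinement
  happens only at the reconstruction stage.
* The (6,18)/(18,6) connectivity pairs reuse the order-2 geodesic
  neighborhoods; only (6,26)/(26,6) are exercised by the pipeline.
* The Euler characteristic is computed on the closed cubical complex for
  all pairs (values agree on well-composed masks).
* The thin-sulcus enhancement detects gaps along grid axes only; a deep
  fundus aligned with a body diagonal at exactly the gap limit may be
  missed.
* No mesh export: surfaces live and die as level sets.
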