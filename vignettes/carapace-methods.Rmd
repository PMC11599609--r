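---
title: "Quantifying boxfish carapace tessellations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying boxfish carapace tessellations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Boxfishes (Ostracioidea) are encased in a rigid carapace built from a few
hundred interlocking mineralized plates (scutes). Comparative work on this
system asks how a closed, doubly-curved surface is tiled: how scute size,
shape, thickness and local curvature covary, how they scale with body size
across species, and whether recurring scute types attach to particular
carapace regions (edges, flat flanks, the perforated head region). The
`carapace` package implements the full quantitative workflow from a labeled
3D segmentation (an integer label per scute, 0 for background) to the
statistical analyses, and ships a synthetic-carapace generator so every
stage can be validated against known ground truth.

## From label field to measurements

The measurement pipeline mirrors the workflow used with microCT
segmentations of real carapaces:

1. **Region-adjacency graph (RAG).** Each scute becomes a node at its voxel
   centroid; an edge connects two scutes whose labels share at least
   `min_contact` face-adjacent voxel pairs (6-connectivity; default 1 shared
   face). Face contact is the conservative choice for abutting,
   non-overlapping plates meeting along sutures; corner- or edge-touching
   voxels do not count. The scute's *number of neighbors* is its node
   degree: a six-neighbor scute is a hexagonal tile.
2. **Dual carapace surface.** The RAG is triangulated by enumerating
   mutually adjacent scute triples (four mutually touching scutes are split
   along the shorter center-to-center diagonal). After orientation repair,
   the dual mesh places one vertex in each triangle and forms one polygon
   around each fully surrounded node; the polygons are fan-triangulated,
   midpoint-subdivided three times, and Laplacian-smoothed (10 iterations,
   relaxation 0.7, umbrella operator, no shrinkage compensation). The sum of
   triangle areas of this surface is the carapace surface area **SA**, the
   body-size covariate of all scaling analyses. Because the dual surface is
   an inscribed, smoothed polyhedron, SA carries a small systematic
   underestimate relative to the true enclosing surface; the bias is
   scale-invariant for a fixed scute count and therefore cancels from
   scaling exponents.
3. **Per-scute variables.** Eight variables are computed per scute:
   neighbor count; volume (voxel count x voxel volume); *plane-based area*
   (area of the scute's dual-surface patch, set to the missing flag -1000
   when the scute borders an opening and its polygon does not close);
   thickness and maximum width (smallest and largest extents of the
   principal-axes bounding cuboid of the scute's voxels, plus one voxel for
   voxel extent); aspect ratio (thickness/width, a bending-resistance
   index, in (0, 1] by construction); and Gaussian (CGS) and mean (CMS)
   surface curvature, the product and mean of the two principal curvatures
   estimated at the surface point nearest the scute center.
4. **Carapace dimensions.** A PCA of the scute centers gives the
   anteroposterior axis as PC1; carapace length, height and width are the
   coordinate ranges along the components, with the dorsoventral world axis
   used to tell height from width.

### Curvature estimation

Principal curvatures are obtained by fitting a full quadric
(h = a u^2 + b uv + c v^2 + d u + e v + f) over surface vertices within a
geodesic-scale neighborhood of radius twice the median inter-center
spacing, in a local frame aligned with the area-weighted vertex normal.
The shape operator at the origin gives CGS and CMS; with outward normals,
convex regions have positive CMS. Quadric fitting was preferred over
cotangent-style discrete operators because the refined dual surface has
strongly non-uniform triangles. The neighborhood radius is configurable;
the default (2x spacing) trades noise suppression against spatial
smearing — curvature estimated one to two scute rings away from a sharp
edge is noticeably elevated, which matters when interpreting per-scute
curvature near edges.

## Scaling analyses

Interspecific scaling uses ordinary least squares on natural-log scales:
per-specimen values (or per-specimen *medians* of scute variables —
medians, not means, because horned or ornamented scutes produce extreme
values) are regressed on ln(SA), and the slope is the scaling exponent
with a t-based 95% confidence interval. Isometric references against an
area are 0.5 for lengths, 1 for areas, 1.5 for volumes, 0 for
dimensionless ratios, -1 for Gaussian and -0.5 for mean curvature. Scute
counts are modeled with a Poisson GLM (log link) on untransformed SA, and
the slope and profile-likelihood CI are exponentiated back to the response
scale; with counts unrelated to size this back-transformed slope is 1.00
with a vanishingly narrow interval. (A `log_sa` switch and a Wald CI
option are provided; profile is the default to match `confint`'s behavior
on GLMs.)

Size correction divides each value by SA^slope using the fitted exponent,
after which specimens of different size are directly comparable. Carapace
regions are compared by a graphical residual approach (residuals grouped
by simplified cross-sectional geometry class, which is always declared by
the user, never inferred), and the decision to pool flat-region and
edge-region exponents is backed by a region-interaction test: ln(median)
regressed on ln(SA) crossed with a region factor, with the interaction
p-value reported. No multiple-testing correction is applied anywhere in
the workflow.

## Regions, shape frequencies, clustering

Scutes are classified as *edge* when their size-normalized CGS reaches 5
(inclusive threshold, configurable) and *flat* otherwise. Shape
frequencies are per-specimen proportions of k-neighbor scutes with
opening-bordering scutes excluded from the denominator (their neighbor
count is censored by the opening); nine or more neighbors are pooled for
display but stored exactly.

The covariation analysis filters scutes whose area is missing (-1000) or
zero, normalizes each dimensioned variable by SA^slope, log-transforms all
variables except the neighbor count (the two curvature columns are first
shifted by their minimum plus 0.001 so the log is finite), removes extreme
outliers, standardizes, and runs a PCA whose loadings are reported as
variable-PC correlations (each component's sign is fixed so its
largest-magnitude loading is positive). Ward-linkage hierarchical
clustering on the PC scores (all components by default; an optional
k-means consolidation pass exists but is off) is cut at k = 5, the number
of recurring scute types. The outlier rule is operationalized as dropping
any row beyond median +/- 8 MAD in any transformed column; 8 MAD is an
extremely permissive fence that removes only isolated extremes of the kind
described for curvature and volume, and the dropped rows are always
reported with flags.

## The synthetic generator

`synthesize_carapace()` produces closed boxfish-like specimens with known
ground truth. Design choices, in the generator's own terms:

- **Shape family.** A rounded regular polygon (ellipse, rounded triangle
  with dorsal apex, or rounded square with axis-aligned flat sides) is
  swept along the anteroposterior axis under a longitudinal profile
  `(1 - |2u-1|^p)^(1/p)`. The rounded polygon is the Minkowski sum of a
  shrunk polygon with a disc, so `corner_rounding = 1` degenerates to an
  ellipse exactly, which makes the elliptic class analytically checkable
  against ellipsoid quadrature. The default taper exponent 1.6 gives a
  pointier nose/tail than an ellipsoid; this keeps the meridian curvature
  along the mid-body edges more uniform, which is what real keeled
  carapaces look like in profile.
- **Tessellation.** Lloyd-relaxed (centroidal) Voronoi tessellation of the
  mesh faces (default 80 sweeps), with Euclidean distances as a
  geodesic approximation valid at the one-scute-diameter scale, and a
  per-face density field under which regions shrink where density is high.
  Voronoi cell areas retain a natural log-scale spread of roughly 0.3 even
  after relaxation; this is an irreducible property of the tessellation,
  not a tunable noise parameter.
- **Openings.** Eye, mouth, gill and fin gaps are emulated by openings
  spread over the flatter flanks of the anterior third (away from the
  nose tip and the edges), implemented by relabeling the Voronoi regions
  nearest the chosen sites to background.
- **Planted scute types.** Five types mirror the regional organization of
  real carapaces: (1) highly curved edge scutes at the corner ends near the
  taper, small; (2) moderately curved edge scutes along the mid-body
  corners, thickest; (3) abdominal flats, largest and thinnest; (4)
  head/pectoral flats, intermediate; (5) opening-adjacent scutes, smallest
  with the highest aspect ratio among flats. Edge membership is graded by a
  discrete Gaussian-curvature proxy (angle deficit over vertex area);
  density multipliers make types 1, 4 and 5 locally smaller; thickness
  multiplies the base by a per-type ladder with a small lognormal jitter
  (sd 0.05). The generator also subtracts the predictable bounding-box
  inflation of curved shells (the sagitta of the cell arc) so the
  *measured* thickness ladder stays tight. `plant_contrast` scales the
  log-contrasts of the ladders; 1 is the realistic default, and values
  much above 1 saturate physically (shell thickness approaching cell
  width).
- **Voxelization.** Faces are sampled on a barycentric lattice at
  half-voxel spacing and grown inward along the normal over the scute's
  local thickness. The voxel size defaults to a third of the base
  thickness; the validator rejects anything coarser than two voxels per
  thickness. Measured thickness exceeds planted thickness by roughly one
  voxel plus the shell sagitta; this additive inflation compresses
  log-scale thickness contrasts by a factor around 0.55-0.7 and is the
  main reason measured aspect ratios sit above the planted ones.

`simulate_batch()` emulates a comparative sample: 13 specimens across the
three geometry classes (2 elliptic, 5 triangular, 6 tetragonal), carapace
lengths log-uniform over a four-fold span (35-140 mm), scute counts drawn
uniformly from 398-535, seven openings, and class-specific height/width
proportions (elliptic tall and narrow, tetragonal low and wide).
`simulate_isometric_batch()` scales one spec geometrically over a size
span (default x0.5 to x2) with fresh tessellation seeds, so that every
measured variable should recover its isometric reference exponent.

### What the generator does and does not emulate

It reproduces the statistical structure the analyses consume: closed
tessellated surfaces with hexagon-dominated neighbor distributions flanked
by pentagons and heptagons, curvature-correlated edge thickening,
size-graded regional scute types, and openings that censor plane-based
areas. It does not attempt horns or ornamentation, fin and eye anatomy,
concave cross-sections, measured outlines of real species, or
phylogenetic structure. Passing the validation suite therefore shows that
the pipeline recovers known structure of this kind; it does not certify
behavior on features the generator omits (for example, the extreme-value
tails that horned scutes contribute to real data, which the analyses
handle via medians and the outlier rule).

## Numerical choices and degenerate inputs

- Voxel world coordinates are voxel centers: `origin + (index - 0.5) *
  spacing`, mm everywhere; curvature is in mm^-1 / mm^-2.
- The missing-area flag is exactly -1000, kept bit-exact through CSV
  round-trips.
- Degenerate (planar or linear) voxel sets fall back to a one-voxel floor
  for the null dimension of the bounding cuboid, with a warning; scutes
  with fewer than 8 surface vertices in the curvature neighborhood get NA
  curvature with a warning.
- Zero-noise interaction tests (zero residual variance) return NA with a
  warning rather than a misleading p-value.
- Ties in Voronoi assignment are broken by seed order; all stochastic
  steps consume an explicit seed and restore the caller's RNG state, so
  identical spec + seed reproduces partitions, label fields and cluster
  assignments bit-exactly.
- Problem sizes used by the validation suite and the acceptance script
  were chosen to keep a full 13-specimen batch comfortably within a few
  minutes on one core: generation meshes of ~26k faces, ~450-540 scutes
  per specimen, voxel grids of one to three million cells.

## Known limitations

- SA from the smoothed dual surface underestimates the true enclosing
  area (inscribed polyhedron plus Laplacian shrinkage); absolute areas
  should not be compared across pipelines with different smoothing, though
  exponents are unaffected.
- Curvature smearing at the measurement scale blurs the edge/flat
  boundary by one to two scute rings; the normalized-CGS threshold of 5
  classifies the planted edge band well, but scutes immediately flanking
  an edge inherit elevated curvature.
- The planted five-type structure overlaps in measured feature space much
  as real scute types do; Ward recovery of the planted labels is good but
  not perfect, and sits near the recovery ceiling implied by the
  nearest-true-centroid assignment on the same data.
- Carapace height and width derive from the ranges along PC2/PC3 of the
  scute centers. For nearly square cross-sections this PCA is close to
  degenerate, and corner-dense scute distributions can rotate the
  transverse components toward the diagonals, inflating both ranges;
  dimensions of such specimens should be read as method-defined
  quantities rather than anatomical extents (scaling exponents are
  unaffected because the rotation is consistent across sizes).
- The Poisson count model treats specimens as independent; no
  phylogenetic correction is implemented anywhere.
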