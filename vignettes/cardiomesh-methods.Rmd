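---
title: "Methods: surface processing and mesh generation for cardiac models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface processing and mesh generation for cardiac models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomesh)
```

This vignette documents the models and numerical choices behind
`cardiomesh`: what each algorithm computes, which parameters matter, what
the synthetic fixtures do and do not emulate, and where the design was
genuinely open.

## Data model and conventions

A `tri_surface` is a triangulated 2-manifold: an `n x 3` coordinate matrix
in millimetres, an `m x 3` table of 1-based vertex indices, one integer
tag per triangle, and named per-point / per-cell fields. Closed surfaces
are stored with counter-clockwise winding seen from outside, so
right-hand-rule normals point outward and the divergence-theorem volume is
positive; `validate_surface()` enforces index ranges, positive areas,
edge-manifoldness and consistent winding. Boundary rings are extracted by
walking the directed boundary edges, so a ring's stored order keeps the
surface on its left; for determinism each ring is rotated to start at its
lowest vertex index. `tet_mesh` fixes the node order so every signed tet
volume is positive and keeps boundary faces (the faces used by exactly one
tet) wound outward; `hex_mesh` orders each cell as a counter-clockwise
bottom quad plus the matching top quad.

Millimetres are used throughout because every clinically meaningful
threshold in this domain (wall thicknesses near 1 mm, annulus widths near
0.75 mm) is naturally expressed in them.

Duplicate-point unification (in `merge_surfaces()` and the mesh mergers)
hashes coordinates on a grid of `1e-9` times the joint bounding-box
diagonal: far below any feature size, far above round-off.

## Distances

`surface_distance()` returns the exact euclidean distance from query
points to a triangulation — closest point on faces, edges or vertices, not
just vertices. The closest-feature scan is a compiled brute-force kernel;
at the package's problem sizes (at most a few thousand triangles) the scan
costs milliseconds and avoids the complexity of a hierarchy. The sign of
the signed variant comes from the angle-weighted pseudonormal of the
closest feature: the face normal inside a face, the sum of the two
incident face normals on an edge, the angle-weighted vertex normal at a
vertex. This rule is exact for closed meshes; signed queries against open
surfaces are refused because no interior is defined. `ring_distance()`
measures against the closed polyline through a ring's points (segments,
not samples) and optionally returns the closest-point displacement, which
is exactly the boundary datum the harmonic connection needs.

## The Laplace–Beltrami solver

All harmonic machinery rests on one solver: piecewise-linear finite
elements with the cotangent stiffness matrix
`L[i,j] = -(cot a + cot b)/2`, Dirichlet constraints eliminated
symmetrically, and a sparse direct solve (`Matrix`). Unconstrained
boundary points receive the natural (homogeneous Neumann) condition —
nothing needs to be assembled for them. Vector data is solved
componentwise, because the componentwise Laplacian is what the deformation
and extension problems state.

Obtuse triangles give negative off-diagonal weights; they are *not*
clamped, because clamping changes the operator. The price is that the
discrete maximum principle is only guaranteed on non-obtuse meshes, which
is how the property tests phrase it.

Three closed forms pin the solver down: constants are reproduced exactly;
the axial profile on a cylinder is linear (exactly so on a cylinder, which
unrolls isometrically to a plane where linear functions are in the P1
space — the observed error is round-off); and the flat annulus reproduces
the `log(R_out/r)/log(R_out/R_in)` profile with an error that shrinks
under refinement. One subtlety worth recording: for a *vector* boundary
datum `(cos θ, sin θ)` on a unit cylinder rim, the componentwise harmonic
solution decays like `sinh(z)/sinh(L)` along the axis, not linearly — only
the axisymmetric mode is linear. The tests assert the `sinh` form.

## Connections

**Zipper.** The band between rings Γ₁, Γ₂ is built greedily: start at a
point of Γ₁ (default: its first stored point, i.e. the lowest index — a
deterministic stand-in for the arbitrary start the construction permits)
and its closest Γ₂ point; at each step insert the candidate with the
shorter connecting edge (ties advance on Γ₁), form the triangle
`(P1, P2, P*)`, and stop after `n1 + n2 - 1` insertions plus one closing
triangle. Invariants: exactly `n1 + n2` triangles, `n1 + n2 + 1`
insertions with exactly one repeated point, every triangle has exactly one
edge on a parent ring. Because Γ₁ is traversed in its winding-consistent
stored order, the triangles `(P1, P2, P*)` are automatically
orientation-consistent with both parents whenever the geometry admits a
consistent band. Two choices are genuinely free — the start point and the
direction of travel on Γ₂ — and on strongly wobbly rings a poor pick can
self-overlap the band; `surface_connection()` therefore validates the
merged result and retries a fixed sequence of start offsets and
directions, so the output is deterministic and manifold or the call fails
loudly.

**Boolean connection.** Both closed inputs are cut at the zero level of
their mutual signed distances (linear interpolation along edges,
fan-triangulated polygons), the kept parts are clipped back a further
distance ε from the intersection rings, optionally remeshed in a 3h-wide
buffer, and zipper-joined ring-pair by ring-pair (nearest average distance
first). For the difference the second part bounds the result from inside
and is orientation-flipped so the output is closed and outward. ε defaults
to `2h`; larger ε gives a thicker, smoother "annulus" band and a smaller
enclosed volume (monotonically, which the tests check). The level-set
splitter treats vertices lying on the level as belonging to both sides,
which avoids zero-area slivers without perturbing the cut.

**Harmonic connection.** The ring displacement is extended over the
deformation domain (the input minus any excluded tags) with Dirichlet data
`d_ref` on the connection ring, zero on the interfaces of excluded tags,
natural conditions (or optional pinned zeros) on remaining rings. After
warping, the surface is clipped where the distance to the target ring is
below `h`, leaving a clean gap for the zipper. Registration is `none`,
`centroid` (translation of geometric centers) or `icp`: alternating
point-to-segment correspondence with a cross-covariance SVD fit (with
reflection guard) until the mean distance stalls. Point-to-segment ICP on
a rotationally symmetric ring has a flat valley in rotation, so exact
recovery of a rotation is only expected for asymmetric rings — the tests
use wobbly ones.

## Tagging

All array taggers evaluate the field at cell barycenters as the vertex
mean (P1-consistent). `tag_clip()` reuses the level-set splitter, so
inter-tag boundary points satisfy `|f - sigma| <= 1e-9 * range(f)` by
construction. `tag_harmonic()` first prunes the zig-zag ring with the
ordered scan that deletes a point of any three consecutive ring points
sharing one triangle (deleting `x_i` when `x_{i-1}` survives, else
`x_{i+1}`), which is precisely what prevents triangles from collapsing
onto the target ring; it then moves the pruned ring onto the clip ring and
blends the movement harmonically inside a buffer of radius ρ (default:
five mean edge lengths — the buffer must contain a few element layers for
the blend to have room). After the warp an unsigned-distance field can be
updated in place by `f + |phi|`; any other field must be recomputed by a
caller-supplied hook, because silently stale fields are worse than an
explicit refusal.

The geodesic patch tagger computes its distance field with the
triangle-based Eikonal update (planar two-point wavefront solution per
corner, edge updates as fallback) iterated with Jacobi sweeps, seeded with
exact euclidean distances in a small neighbourhood of the seed; on a
level-4 sphere fixture the tagged cap area is within ~2.5% of the analytic
spherical cap.

## Thickness, thickening, sizing

Wall thickness on the tagged walls is `tau = max(D_ext, D_int1)` — each
wall sees its distance to the other — and, when a second internal wall
(septum case) exists,
`tau = max( min( max(D_int1, D_int2), D_ext ), D_int )`: across the septum
the inter-cavity distance wins, elsewhere the cavity-to-outside distance.
On the remaining cells (a valvular annulus, say) τ is projected by nearest
neighbour; `harmonic_extension()` is the documented smoother alternative.
Thickening displaces the deficient points by `w = 0.5 * alpha *
(sigma - tau) * n` along angle-weighted outward normals, recomputed
immediately before warping; the half accounts for both walls moving.
Because the warp acts along normals, curved walls under-deliver slightly
and `alpha` is the documented manual correction; excluding one wall and
doubling `alpha` localizes the full correction on the other wall.

The mesh-size rule is `h = clamp(alpha * f^beta + gamma, m, M)` per field,
combined across fields by the pointwise minimum — the conservative choice
that gives local priority to the smallest requested element. The smoothed
companion `h-hat` comes from fixed-point neighbour averaging
(`v <- (1-lambda) v + lambda * mean(one-ring)`, default 10 sweeps,
`lambda = 1`), a convex combination that cannot leave the raw field's
range. Mean curvature is `|L x| / (2 A)` with mixed Voronoi areas, the
standard discrete estimate (`1/R` on spheres, `1/(2R)` on cylinders).

## Remeshing

Incremental isotropic remeshing: split edges longer than 4/3 of the local
target, collapse shorter than 4/5 (shortest first, with link-condition and
over-long-edge guards, whole pass rolled back if it would break
manifoldness), flip interior edges toward valence 6, relax tangentially
and project back to the input surface. Localization: cells outside the
target tags are never touched, their vertices are pinned, and the
polylines separating tags (and the surface boundary) are constraints whose
vertices only slide along the polyline; sharp constraint corners
(direction change above 30 degrees) and junctions are pinned, which is
what keeps a square's corners square and a tag boundary in place. With
`preserve_boundary = TRUE` boundary vertices and edges are kept verbatim —
required when the boundary must stay conforming with a neighbouring mesh,
as in the volumetric connection walls.

## Volume operations

The built-in tetrahedralizer cones every boundary triangle to the volume
centroid; it is valid exactly for star-shaped regions and refuses anything
else, and the boundary triangulation is preserved node for node. Any
constrained Delaunay mesher honouring that contract can be plugged in
through the `backend` argument. Disjoint closed components are coned
independently; a cavity component fails the star-shape test, as it should.

`mesh_connection()` flips the selected boundary patches (their normals
point into the gap), pairs rings by minimum average distance, builds each
wall with the zipper, optionally remeshes the walls at `h` with the patch
triangulations frozen, tetrahedralizes the closed connection surface and
merges the three meshes, unifying interface points so the result is
conforming; input volumes are conserved exactly.

`refine_mesh()` uses conforming longest-edge bisection: splitting an edge
splits every tet sharing it, so no hanging nodes can appear and the total
volume is exactly preserved. A tet is refined while its longest edge
exceeds `1.5 * h(barycenter)` with `h = max(m, alpha * f^beta)`; the local
pre-refinement size `h_in` of a cell is taken as its longest edge, and the
factor 1.5 balances termination against fidelity. Children inherit their
parent's tag, which coincides with the barycentric projection rule (each
child lies inside its parent); the boundary-face tags are projected by
nearest input face barycenter. `m = 0` is refused because it makes the
refinement unbounded.

`tet_to_hex()` splits each tet into four hexahedra around its edge
midpoints, face barycenters and cell barycenter (each boundary triangle
into three quads), an exact partition: hex volumes sum to the tet volume
to round-off, and all corner Jacobians are positive on non-degenerate
input. Refine-by-splitting iterations split each hex into eight and each
quad into four, halving the mesh-size; starting from a coarser tet mesh
with more RBS iterations yields less distorted hexahedra than the
converse.

## Synthetic fixtures: what they do and do not show

The generators produce closed smooth shells (epicardium/endocardium
analogs), nested two-cavity shells mimicking the biventricular topology,
open tubes with rim rings (atrium/vessel analogs), thin-wall shells, flat
patches, tetrahedral blocks, and a truncated prolate ellipsoid chamber —
the standard idealized left ventricle, in a capped "blood-pool" variant
(star-shaped, so the built-in tetrahedralizer applies) and a hollow wall
variant for thickness work. All generators are deterministic:
bit-identical output for identical parameters.

These fixtures have exact closed-form oracles (radii, volumes, cap areas,
subdivision counts), which is what makes the test suite sharp. What they
do not emulate: segmentation noise, trabeculae-scale high-curvature
detail, self-intersecting or non-manifold segmentation output, and
anatomical asymmetry. Passing tests therefore demonstrate correctness of
the algorithms' geometry and invariants, not robustness to arbitrarily
pathological clinical segmentations; the boolean and zipper retry guards
are the first line of defence there, and they fail loudly rather than
returning a broken mesh.

Problem sizes in the tests and the acceptance script (icospheres up to
subdivision level 4, about 5 000 triangles; refined cube meshes up to a
few tens of thousands of tets; 100 fuzzed ring pairs) were chosen so the
closed-form comparisons are comfortably inside their tolerances while the
whole suite runs in about a minute.

## Known limitations

* The tetrahedralization fallback is star-shaped only; general cavities
  and annular volumes need an external backend through the seam.
* The remesher targets isotropic sizing; no anisotropic tensors.
* Signed distances require closed references by construction.
* ICP registration aligns rings, not surfaces, and cannot fix the
  rotational gauge of symmetric rings.
* The thickening warp acts along normals and is first-order in the
  curvature; `alpha` exists to compensate.
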