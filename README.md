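# cardiomesh

Surface processing and mesh generation for cardiac computational models,
in R.

Patient-specific simulations of the heart — electrophysiology, mechanics,
hemodynamics — start from triangulated surfaces produced by medical-image
segmentation: an endocardium here, an epicardium there, each chamber
reconstructed separately, often intersecting or separated by gaps, and
never carrying the region labels a solver needs. `cardiomesh` turns such
raw surfaces into tagged, analysis-ready surface and volume meshes. It is
aimed at people building cardiac (or other biomedical) computational
pipelines who want every step scriptable and reproducible.

## What it provides

**Connecting surfaces.** Three complementary algorithms join two surfaces
into one watertight triangulation:

* *surface connection* — a greedy "zipper" between two boundary rings
  Γ₁ (n₁ points) and Γ₂ (n₂ points). Starting from a point on Γ₁ and its
  closest point on Γ₂ it appends, one at a time, the triangle with the
  shortest connecting edge; a final triangle closes the band. The band
  always has exactly n₁+n₂ triangles and is conforming with both inputs.
* *boolean connection* — difference/union/intersection of two closed
  surfaces computed via their signed distances d₁, d₂, with the kept parts
  clipped back a distance ε from the intersection curve and zipper-joined,
  so the output is smooth, tagged (part-1 / part-2 / connection ring) and
  ready for volume meshing instead of ending in razor-thin wedges.
* *harmonic connection* — deforms a template surface until one of its
  rings lands on a ring of a reference surface: the ring displacement
  **d**_ref becomes Dirichlet data for a Laplace–Beltrami problem
  Δφ = 0 solved with P1 finite elements (cotangent weights), the surface
  is warped by φ, clipped a distance h from the target ring and zipped to
  the reference. Optional rigid pre-registration by centroid alignment or
  ICP.

**Tagging.** `tag_simple()`, `tag_clip()` and `tag_harmonic()` turn a
scalar point field f (typically a distance from an anatomical landmark)
and a cut-off σ into cell tags: simple keeps the triangulation (zig-zag
boundary), clip cuts exactly at the f = σ level set, harmonic moves the
zig-zag ring onto the level set through a harmonically blended
deformation — precise tags *and* unchanged connectivity. Connectivity and
explicit-cell/geodesic-patch taggers complete the set.

**Fields and sizing.** Harmonic extension of scalar/vector fields from a
tagged subregion to the rest of a surface; wall thickness
τ = max(D_ext, D_int) (with a septum-aware two-cavity variant); thickening
by w = ½α(σ−τ)n; mesh-size functions h = clamp(α·f^β + γ, m, M) combined
across fields by pointwise minimum; discrete mean curvature; field
smoothing.

**Remeshing.** Tag-preserving isotropic remeshing (split / collapse /
flip / tangential relaxation with projection), localizable to a subset of
tags with frozen neighbours and constrained tag boundaries.

**Volume meshes.** Star-shaped tetrahedralization (with a pluggable
backend seam for constrained Delaunay meshers), connection of two
tetrahedral meshes through a generated wall volume, sizing-driven
conforming refinement by longest-edge bisection with barycentric tag
projection, and tet→hex conversion (4 hexahedra per tetrahedron, exact
volume, optional refine-by-splitting iterations).

**I/O and fixtures.** VTK legacy ASCII (tagged; the canonical format),
STL, OBJ, PLY; deterministic generators of idealized cardiac geometries
(spheres, wall shells, two-cavity "biventricular" shells, tubes, truncated
ellipsoid chambers, tetrahedral blocks).

## A worked example

Compute the thickness of a thin spherical wall, thicken it to a 1 mm
minimum, and derive a curvature- and thickness-aware mesh-size:

```r
library(cardiomesh)

sh <- shell(9.75, 10.25, level = 3)          # 0.5 mm wall, tags: 1 outer, 2 inner
sh <- surface_thickness(sh, internal_tags_1 = 2L, external_tags = 1L)
print(sh)
#> tri_surface: 1284 points, 2560 triangles, tags {1,2}, 0 boundary ring(s)
#>   point fields: thickness
mean(sh$point_data$thickness)
#> mean wall thickness: 0.499 mm

th <- surface_thicken(sh, sigma = 1)         # displace both walls by ~0.25 mm
th <- surface_thickness(th, 2L, 1L)
#> after thickening to sigma = 1: 0.999 mm

th <- mean_curvature(th)
th <- mesh_size(th, list(
  list(field = "curvature", alpha = 0.3, beta = -0.5, m = 0.3, M = 2),
  list(field = "thickness", alpha = 0.5, m = 0.3, M = 2)))
range(th$point_data$meshsize)
#> mesh-size range: [0.498, 0.501] mm
```

The thickness round-trips (0.5 mm wall → thicken to σ = 1 → recomputed
τ ≈ 1 mm), and the sizing rule `0.5 · τ` wins the pointwise minimum here,
guaranteeing at least two elements across the wall.

A command-line front end mirrors the R API and chains stages through VTK
files:

```sh
exec/cardiomesh fixture --kind two_cavity_shell --level 2 -o biv.vtk
exec/cardiomesh thickness --inner1 2 --inner2 3 --outer 1 -i biv.vtk -o biv_tau.vtk
exec/cardiomesh pipeline --config pipeline.yaml
```

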