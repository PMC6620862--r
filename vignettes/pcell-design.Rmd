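---
title: "Designing Schwarz Primitive scaffold cells: models, estimators and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing Schwarz Primitive scaffold cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcellkit)
```

## The model

Bone scaffolds built from triply periodic minimal surface (TPMS) unit cells
combine open, fully interconnected pore networks with tunable stiffness.
This package works with the Schwarz Primitive (P) surface in its nodal
(leading-Fourier-term) approximation,

$$ f(x, y, z) = \cos\frac{u}{s} + \cos\frac{v}{s} + \cos\frac{w}{s} = k, $$

where $(u, v, w) = \tfrac{2\pi}{L}(x, y, z)$ rescales the cubic cell
$[-L/2, L/2]^3$ (side $L$, default $2\pi$ mm) to the canonical
$[-\pi,\pi]^3$ domain. The level offset $k$ picks the extracted level
surface; the scale parameter $s$ acts like a uniform scaling of the surface
about the cell barycentre followed by truncation with the cube. The surface
splits the cell into a phase with $f < k$ and an internal phase with
$f > k$; the internal phase is the one that is later solidified.

Two facts shape the admissible parameter window. For $s = 1$ the cell keeps
a single connected surface with one open duct per cube face only for
$k \in (-1, 1)$: beyond $+1$ the lateral openings pinch shut at the face
centres, below $-1$ the surface loses its single-component structure. For
$k = 0$ the corresponding window is $s \in [0.75, 1.5]$: just above 1.5 the
surface starts crossing the cube edges (the nodal value at an edge midpoint,
$2\cos(\pi/s) + 1$, changes sign at $s = 1.5$), so boundary loops wrap
around edges and the one-loop-per-face structure is lost. Out-of-range
values are allowed for exploration but flagged by `pcellParams()`.

The nodal form is only approximately minimal. At $k = 0$ its mean curvature
$H$ vanishes in the cell average by symmetry, but not pointwise: evaluating
the exact level-set curvature formula over the surface gives an
area-weighted mean $|H| \cdot L \approx 0.44$ against a curvedness level
$R_{mean} \cdot L \approx 4.3$, i.e. $|H|$ is roughly a tenth of the local
curvature scale. Statements that the surface is "saddle-shaped with
$H \approx 0$" are accurate in this relative sense only, and the package's
tests assert exactly that: $\overline{|H|}/\bar R < 0.2$ for all admissible
$s$, and the signed mean $\bar H \cdot L < 0.05$ at $s = 1$ (for other $s$
the truncating cube clips the half-cell translation symmetry that drives
the cancellation, so even the signed mean no longer vanishes). No estimator
can push $\overline{|H|} \cdot L$ itself below 0.05 — the surface is simply
not that minimal.

## Tessellation

`sampleField()` samples $f$ on a node-centred $N^3$ grid (spacing
$L/(N-1)$, endpoints included; $N = 100$ by default, which reproduces the
reference area of the continuous standard cell, $S/L^2 = 2.3451$, to
0.33%). `extractIsosurface()` triangulates $\{f = k\}$ by marching
tetrahedra on the *body-centred 24-tetrahedron* decomposition: each grid
cell is split into 24 tets spanned by the cell centre, a face centre and a
face edge, with centre values obtained by averaging. Two properties drove
this choice over the more common 6-tet (Kuhn) split:

* it is invariant under the full cube symmetry group, so symmetric fields
  tessellate symmetrically — with the Kuhn split the two cells of the
  standard cell's eight curvature regions that sit on the main diagonal
  came out visibly different from the other six;
* shared cube faces are triangulated identically from both sides, so the
  mesh is watertight up to the domain boundary with exact vertex sharing
  (vertices are keyed by the grid edge they interpolate).

If $k$ coincides with a sampled value to within $10^{-12}$ of the field
scale it is shifted by $10^{-9}$, deterministically. The shift produces
near-coincident sliver vertices at the $10^{-9}$ scale; cleanup therefore
merges vertices at $10^{-7} L$ (five orders of magnitude below the grid
spacing) using two half-offset rounding grids, collapses the faces that
become degenerate, and cancels coincident face pairs. The result is
manifold: the standard cell has exactly one component and six boundary
loops, one per cube face, which is precisely the `checkIntegrity()`
criterion.

## Global properties

* **Volume fraction** $f_v$: the phase indicator is integrated column by
  column with linear interpolation of the crossing position inside each
  interval (second-order accurate). A second estimator applies the
  divergence theorem to the oriented isosurface plus the phase areas on two
  cube faces as caps; the two agree to a few parts in $10^3$ at $N = 100$
  and cross-validate each other.
* **Pore size** $p_s$: radius of the largest sphere inscribable in the
  internal phase. An exact Euclidean distance transform of the node mask
  seeds the search; the argmax is then refined continuously against the
  exact distance to the tessellated surface (vertices sample the surface at
  the grid scale, so the residual error is $O(h^2)$). For the standard cell
  this reproduces the closed form $p_s/L = \sqrt{3}/4$ (the nearest surface
  point to the cell centre is at $(\pi/2, \pi/2, \pi/2)$) to better than
  0.1%.
* **Surface ratio** $S/L^2$ and the dimensionless specific surface
  $(S/V_{\mathrm{internal}})\,L = (S/L^2)/f_v$.

All dimensionless properties are exactly invariant under `scaleParams()`
because sampling works in rescaled coordinates.

## Curvature analysis

`paraboloidCurvatures()` fits, at every vertex, a quadric height field
$h(u,v) = a u^2 + b uv + c v^2 + d u + e v$ over the ring neighbourhood in
the local tangent frame and takes the principal curvatures from the shape
operator of the fit. Conventions, none of which the nodal model itself
fixes, had to be chosen:

* **Normals** point along $-\nabla f$, away from the internal phase.
* **Sign**: positive curvature means bending towards the normal. A surface
  cap that forms a cup seen from outside the material then has two positive
  curvatures and is labelled *concave* by the sign rule
  ($\min(k_1,k_2) \ge 0$ and $\max(k_1,k_2) > 0$; *convex* is the mirror
  rule). With these conventions cells with $k < 0$ produce concave regions
  and $k > 0$ convex ones, and flipping all normals swaps the labels
  exactly.
* **Stencil**: three rings by default. On marching-tetrahedra meshes the
  two-ring stencil leaves enough noise in the smaller principal curvature
  to shatter the region masks into slivers; three rings restore eight
  clean regions while keeping the sphere-phantom median error at 1.1%
  (the package requires < 2% on sphere and cylinder phantoms, with errors
  decreasing under refinement).

`growRegions()` takes maximal connected components of same-label vertices
and discards regions below 0.1% of the total area as tessellation noise.
For $k = \pm 0.7$, $s = 1$ this yields exactly eight regions whose areas
agree to better than 1%, stable across $N \in \{60, 80, 100\}$. Region
statistics report the mean over regions of $R_{mean} L$ (the regions are
near-identical by cubic symmetry, so averaging over one or all eight is
equivalent) and of the area share $A_{r\%}$.

## Solidification and porosity

`solidify()` realises the inward offset on a distance field over a
cell-centred $M^3$ voxel grid rather than by CAD-style vertex-normal
offsetting, which self-intersects at saddle points. Within about 1.5
voxels of the surface the first-order estimate $(f-k)/|\nabla f|$ is used
(error $O(d^2 \kappa)$, which keeps sub-voxel shells accurate); further in,
the exact Euclidean distance transform corrected by the depth of the
nearest outside voxel takes over. The shell is
$\{f > k,\ \mathrm{dist} \le t\}$; porosity is $P = 1 - V_{solid}/L^3$ by
voxel counting. The thin-shell relation $P = 1 - (S/L^2)(t/L)$ is its
first-order limit: the package verifies agreement to 1% absolute at
$t/L = 0.005$ and 3% at $t/L = 0.02$, and linearity of $P(t)$ with
$R^2 > 0.999$. A thickness at or beyond the pore radius (with a one-voxel
resolution margin) raises a "shell closes the pore" error; thicknesses
under two voxels warn as under-resolved.

Three boundary representations are produced: the smooth outer isosurface,
the inner offset isosurface (level $t$ of the distance field), and a
watertight triangulated boundary of the voxel solid whose
divergence-theorem volume equals the voxel volume exactly — the mesh used
for closed-solid checks and STL export of the shell.

`designCell()` walks the design workflow in three steps: (1) pick $(k, s)$
by inverse interpolation of a sweep table so a dimensionless target (volume
fraction) is met, preferring the candidate closest to the standard cell;
(2) scale $L$ from a dimensional target (pore radius, e.g. the 300 µm
useful for cell ingrowth gives $L \approx 0.69$ mm at $p_s/L = 0.433$);
(3) set $t$ from a porosity target via the thin-shell relation, checked for
feasibility against the pore radius.

## Voxel finite elements

Every material voxel becomes an eight-node trilinear brick with the
isotropic elasticity matrix from $(E_s, \nu_s)$; defaults are the Ti-6Al-4V
constants $E_s = 110$ GPa, $G_s = 40$ GPa, $\nu_s = 0.3$, cell size 5 mm,
applied strain 0.1%. The global system is solved matrix-free by
Jacobi-preconditioned conjugate gradients to a relative residual of
$10^{-8}$ (deterministic; iteration cap 50 000). Floating components that
do not connect the two constraint faces are removed first, with a logged
count.

Boundary conditions follow the two loading cases: compression prescribes
the top-face displacement in $y$ with the bottom face fully clamped;
shear drives the $+x$ face in $y$, clamps the $-x$ face and constrains the
$\pm y$ faces in $x$. Both therefore measure *apparent* moduli,
$E = (F_R/A)/\epsilon_A$ from the reaction force $F_R$ on the driven face.
For patch tests a `support = "rolling"` variant (normal-only constraints
plus symmetry planes) reproduces the uniform-strain solution exactly —
the clamped variant overshoots $E_s$ by about 3.5% on a homogeneous cube
through the Poisson constraint, which is physical for clamped platens, so
the dense-limit check uses the rolling variant. Von Mises stress is
evaluated per element at the centroid, in MPa.

Because the solid here is a voxelised shell while the reference workflow
meshed a CAD solid with a commercial code whose moduli are shown only in
figures, the stiffness results are validated qualitatively: stiffness
grows with thickness, falls with $s$, grows with $k$, the apparent shear
modulus peaks at the standard cell, and at fixed thickness the
variable-$k$ family lies above the variable-$s$ family in the
stiffness-porosity plane. One caveat is resolved explicitly: in the voxel
model the shear peak sits at $s = 1$ in the thin-shell regime
($t = 0.3$ mm on the 5 mm cell, the scaffold-typical high-porosity
condition, and the regime in which the package tests the claim), while for
$t \gtrsim 0.4$ mm the peak drifts to $s \approx 1.15$ — a property of the
voxelised shell that persists under mesh refinement down to 0.05 mm
elements.

## Problem sizes and runtime choices

Default production resolutions are $N = 100$ for field sampling and
element size 0.05 mm ($M = 100$ on the 5 mm cell) for solids. The test
suite and the acceptance script run the geometric anchors at $N = 100$ and
the FEM property checks at element size 0.1 mm ($M = 50$) with the field at
$N = 60$, sizes at which every stiffness solve completes in seconds while
the monotone relations are already resolved well beyond their margins;
module tests use $N$ between 30 and 80. All sweeps are deterministic and
emit rows sorted by parameter tuples so reruns diff cleanly.

## What the checks do and do not show

The analytic anchors (area ratio, $f_v = 1/2$, $\sqrt{3}/4$ pore radius,
phantom curvatures, patch test) pin the estimators against closed forms.
The trend checks mirror the qualitative behaviour reported for this cell
family. None of this validates manufacturing effects (strut-level
roughness, print anisotropy), multi-cell scaffolds with $s \ne 1$ cells
(whose shared boundaries are not $C^1$), or absolute stiffness of
CAD-smooth shells — the voxel representation converges to those only as
the element size shrinks.
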