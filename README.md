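# pcellkit

Design and assessment of Schwarz Primitive (P-surface) unit cells for bone
tissue scaffolds.

Porous scaffolds for bone regeneration are commonly assembled from triply
periodic minimal surface (TPMS) unit cells: their pore networks are fully
interconnected, their surface-to-volume ratio is high, and their stiffness
can be tuned towards that of the surrounding bone to limit stress
shielding. This package implements the complete single-cell workflow for
the Schwarz Primitive surface in its nodal approximation

    f(x, y, z) = cos(u/s) + cos(v/s) + cos(w/s) = k,
    (u, v, w) = (2*pi/L) * (x, y, z)  on the cubic cell [-L/2, L/2]^3

for users — biomedical engineers and scaffold designers — who need to go
from the two analytical parameters `(k, s)` and the two dimensions `(L, t)`
to a manufacturable solid cell with known geometric and mechanical
properties:

* **Tessellation** of the level surface by marching tetrahedra on a
  symmetric body-centred cell decomposition, with STL input/output and an
  integrity check (one surface component, one open duct per cube face —
  the requirement that bounds `k` to ]-1, 1[ and `s` to [0.75, 1.5]).
* **Global properties**: volume fraction `f_v` (sub-grid-corrected voxel
  counting, cross-validated by a divergence-theorem mesh estimator), pore
  size `p_s` (maximum inscribed sphere via exact Euclidean distance
  transform with continuous refinement), surface ratio `S/L^2`, and
  dimensionless surface area per unit volume.
* **Local curvature properties**: per-vertex principal curvatures by the
  paraboloid method, the sign-rule classification into concave / convex /
  saddle vertices, region growing, and the region statistics `R_mean * L`
  (curvedness) and `A_r%` (area share).
* **Shell solidification**: inward offset of thickness `t` on a Euclidean
  distance field, porosity `P = 1 - V_solid / L^3`, the thin-shell
  relation `P = 1 - (S/L^2) (t/L)` and its inversion for design, plus a
  requirements-to-parameters design routine.
* **Voxel finite elements**: eight-node brick elements on the voxel shell,
  matrix-free preconditioned conjugate gradients, apparent compressive and
  shear moduli `E = (F_R/A)/eps_A` under prescribed-displacement loading,
  von Mises stress fields, and stiffness-porosity sweeps (Ti-6Al-4V
  constants by default).

## Worked example

```r
library(pcellkit)

params <- pcellParams(k = 0, s = 1)      # standard cell, L = 2*pi mm, N = 100
field  <- sampleField(params)
mesh   <- extractIsosurface(field)

surfaceRatio(mesh)                       # 2.352828
volumeFraction(field)                    # 0.5000323
poreSize(field, mesh = mesh)$p_s_over_L  # 0.4330138  (= sqrt(3)/4)
checkIntegrity(mesh)
#> Integrity: PASS (1 component(s), 6 boundary loop(s))
#>   loops per face: x-=1 x+=1 y-=1 y+=1 z-=1 z+=1
```

The surface ratio of the tessellated standard cell, 2.3528, sits 0.33%
above the continuous-surface reference value 2.3451; the volume fraction is
one half because the `k = 0` surface splits the cell into two congruent
phases; and the largest inscribed pore sphere has radius `sqrt(3)/4 * L`
(its centre is the cell centre, its contact points the
`(±pi/2, ±pi/2, ±pi/2)` surface points).

Curvature regions and a solid shell:

```r
ca <- curvatureAnalysis(pcellParams(k = -0.7, s = 1))
length(ca$regions)                       # 8 concave regions
ca$stats$A_r_pct                         # ~ 0.63 (% of S, each)

sol <- solidify(field, t = 0.4, M = 100)
porosity(sol)                            # 0.8539
writeSTL(sol$boundary_mesh, "shell.stl")

fld5 <- sampleField(pcellParams(k = 0, s = 1, L = 5, N = 60))
sol5 <- solidify(fld5, t = 0.4, M = 50)
femCompression(sol5, pcellMaterial())
#> Compression: E = 2.432 GPa (E/E_s = 0.0221), F_R = 60.79 N, 982 CG iters
```

A command-line driver with `generate`, `props`, `sweep`, `curvature`,
`solidify`, `design`, `fem` and `reproduce-figures` subcommands is
installed at `inst/cli/pcell.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pcell.R", package="pcellkit"))')" \
  generate --k 0 --s 1 --N 100 --out cell.stl
```

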