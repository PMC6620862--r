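Package: pcellkit
Title: Design and Assessment of Schwarz Primitive Unit Cells for Bone Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for parameterizing, tessellating and assessing Schwarz
    Primitive (P-surface) unit cells used as building blocks of bone tissue
    scaffolds. The nodal implicit representation cos(x/s)+cos(y/s)+cos(z/s)=k
    is sampled on a regular grid and triangulated by marching tetrahedra;
    global cell properties (volume fraction, maximum inscribed pore size,
    surface area per unit volume, surface ratio) and local curvature
    properties (paraboloid-method principal curvatures, concave/convex region
    detection with curvedness statistics) are computed from the tessellation.
    Solid shell cells of prescribed thickness are generated by inward
    distance-field offsetting with porosity control, and their apparent
    compressive and shear stiffness is evaluated with a voxel finite-element
    solver using eight-node brick elements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
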