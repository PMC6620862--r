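test_that("sphere-void phantom isosurface area matches 4*pi*r^2", {
  ph <- makePhantom("sphere-void", r = 1, L = 4, n = 5)
  m <- extractIsosurface(ph$field, 0, normals = "none")
  expect_lt(abs(meshArea(m) - ph$oracle$area) / ph$oracle$area, 0.01)
})

test_that("mid-plane level set of a linear field has area L^2", {
  L <- 3
  fld <- fieldFromFunction(function(x, y, z) -z, L = L, N = 30)
  m <- extractIsosurface(fld, 0, normals = "none")
  expect_equal(meshArea(m), L^2, tolerance = 1e-9)
})

test_that("isovalues outside the field range are rejected", {
  fld <- std_field(40)
  expect_error(extractIsosurface(fld, 3.5), "outside")
  expect_warning(m <- extractIsosurface(fld, max(fld$values)), "empty")
  expect_equal(nrow(m$faces), 0L)
})

test_that("surface ratio is symmetric in k", {
  for (k in c(0.3, 0.7)) {
    mp <- extractIsosurface(sampleField(pcellParams(k = k, N = 60)),
                            normals = "none")
    mm <- extractIsosurface(sampleField(pcellParams(k = -k, N = 60)),
                            normals = "none")
    expect_lt(abs(surfaceRatio(mp) - surfaceRatio(mm)) / surfaceRatio(mm),
              0.005)
  }
})

test_that("mesh area is invariant under grid axis permutations", {
  fld <- sampleField(pcellParams(k = 0.4, s = 1.1, N = 50))
  a0 <- meshArea(extractIsosurface(fld, normals = "none"))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    fp <- fld
    fp$values <- aperm(fld$values, perm)
    ap <- meshArea(extractIsosurface(fp, normals = "none"))
    expect_lt(abs(ap - a0) / a0, 0.001)
  }
})

test_that("mesh area converges under grid refinement", {
  a100 <- surfaceRatio(std_mesh(100))
  a140 <- surfaceRatio(extractIsosurface(sampleField(pcellParams(N = 140)),
                                         normals = "none"))
  expect_lt(abs(a100 - a140) / a140, 0.01)
})

test_that("extracted meshes are clean: valid indices, no degenerate faces", {
  m <- std_mesh(60)
  expect_true(all(m$faces >= 1 & m$faces <= nrow(m$vertices)))
  expect_true(all(m$faces[, 1] != m$faces[, 2] &
                    m$faces[, 2] != m$faces[, 3] &
                    m$faces[, 1] != m$faces[, 3]))
  areas <- pcellkit:::triangleAreas(m$vertices, m$faces)
  expect_true(all(areas > 0))
  # boundary vertices lie on the cube surface
  bl <- boundaryLoops(m)
  bv <- unique(unlist(bl$loops))
  on_cube <- apply(abs(abs(m$vertices[bv, , drop = FALSE]) - pi) <
                     1e-6 * m$L, 1, any)
  expect_true(all(on_cube))
})
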