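test_that("standard cell is a single surface with one duct per cube face", {
  r <- checkIntegrity(std_mesh(60))
  expect_true(r$passes)
  expect_equal(r$n_components, 1L)
  expect_equal(r$n_boundary_loops, 6L)
  expect_true(all(r$loops_per_face == 1L))
  expect_equal(r$n_nonmanifold, 0L)
})

test_that("integrity fails beyond the admissible s range and holds inside", {
  for (s in seq(0.75, 1.5, by = 0.15)) {
    fld <- sampleField(pcellParams(k = 0, s = s, N = 50))
    expect_true(checkIntegrity(extractIsosurface(fld))$passes,
                label = sprintf("s = %.2f", s))
  }
  for (s in c(1.55, 1.6)) {
    fld <- sampleField(pcellParams(k = 0, s = s, N = 50))
    expect_false(checkIntegrity(extractIsosurface(fld))$passes,
                 label = sprintf("s = %.2f", s))
  }
})

test_that("integrity holds across the admissible k range and fails outside", {
  for (k in seq(-0.9, 0.9, by = 0.3)) {
    fld <- sampleField(pcellParams(k = k, s = 1, N = 50))
    expect_true(checkIntegrity(extractIsosurface(fld))$passes,
                label = sprintf("k = %.1f", k))
  }
  # k = 2: the level set closes into a blob without lateral openings
  fld <- sampleField(pcellParams(k = 2, s = 1, N = 50))
  r <- checkIntegrity(extractIsosurface(fld))
  expect_false(r$passes)
  # k = -2: complement case, also no one-loop-per-face structure
  fld <- sampleField(pcellParams(k = -2, s = 1, N = 50))
  expect_false(checkIntegrity(extractIsosurface(fld))$passes)
})

test_that("empty meshes are rejected by the integrity check", {
  fld <- std_field(40)
  suppressWarnings(m <- extractIsosurface(fld, max(fld$values)))
  expect_error(checkIntegrity(m), "empty")
})
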