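test_that("volume fraction of the standard cell is one half", {
  fld <- std_field(60)
  expect_equal(volumeFraction(fld), 0.5, tolerance = 2e-3)
  expect_equal(volumeFraction(fld, method = "mesh", mesh = std_mesh(60)),
               0.5, tolerance = 5e-3)
})

test_that("volume fraction respects level-set complement symmetry", {
  f1 <- sampleField(pcellParams(k = 0.5, N = 50))
  f2 <- sampleField(pcellParams(k = -0.5, N = 50))
  expect_equal(volumeFraction(f1) + volumeFraction(f2), 1, tolerance = 2e-3)
})

test_that("extreme isovalues saturate the volume fraction", {
  fld <- std_field(40)
  expect_gt(volumeFraction(fld, k = -2.9), 0.99)
  expect_lt(volumeFraction(fld, k = 2.9), 0.01)
  expect_warning(v <- volumeFraction(fld, k = 3.2), "empty")
  expect_identical(v, 0)
  expect_warning(v <- volumeFraction(fld, k = -3.2), "fills")
  expect_identical(v, 1)
})

test_that("grid and capped-mesh volume estimators agree within 0.5%", {
  for (k in c(-0.5, 0, 0.5)) {
    fld <- sampleField(pcellParams(k = k, N = 60))
    v_grid <- volumeFraction(fld)
    v_mesh <- volumeFraction(fld, method = "mesh")
    expect_lt(abs(v_grid - v_mesh) / v_grid, 0.005,
              label = sprintf("k = %.1f", k))
  }
})

test_that("pore radius of a spherical void equals the sphere radius", {
  ph <- makePhantom("sphere-void", r = 1.2, L = 4, n = 4)
  ps <- poreSize(ph$field, 0)
  expect_equal(ps$p_s, 1.2, tolerance = ph$field$spacing / 1.2)
  expect_equal(ps$center, c(0, 0, 0), tolerance = 0.1)
})

test_that("standard-cell pore radius matches the closed form sqrt(3)/4 * L", {
  fld <- std_field(100)
  m <- std_mesh(100)
  ps <- poreSize(fld, mesh = m)
  expect_equal(ps$p_s_over_L, sqrt(3) / 4, tolerance = 0.005)
  # independent oracle: brute-force nearest distance from candidate centres
  # to a dense sampling of the surface (vertices plus face centroids)
  cent <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
             m$vertices[m$faces[, 3], ]) / 3
  samp <- rbind(m$vertices, cent)
  h <- fld$spacing
  cand <- as.matrix(expand.grid(x = c(-h, 0, h), y = c(-h, 0, h),
                                z = c(-h, 0, h)))
  dists <- apply(cand, 1, function(p) {
    sqrt(min((samp[, 1] - p[1])^2 + (samp[, 2] - p[2])^2 +
               (samp[, 3] - p[3])^2))
  })
  p_s_brute <- max(dists)
  expect_equal(p_s_brute / fld$params$L, sqrt(3) / 4, tolerance = 0.005)
  expect_lt(abs(ps$p_s - p_s_brute) / p_s_brute, 0.005)
})

test_that("degenerate phases are rejected by the pore-size estimator", {
  fld <- std_field(40)
  f2 <- fld
  f2$values <- fld$values * 0 + 1
  expect_error(poreSize(f2, k = 2), "empty")
  expect_error(poreSize(f2, k = 0), "fills")
})

test_that("plane and sphere identities for the derived ratios hold", {
  L <- 3
  plane <- fieldFromFunction(function(x, y, z) -z, L = L, N = 30)
  m <- extractIsosurface(plane, 0, normals = "none")
  expect_equal(surfaceRatio(m, L), 1, tolerance = 1e-9)
  f_v <- volumeFraction(plane, 0)
  expect_equal(f_v, 0.5, tolerance = 1e-9)
  expect_equal(areaVolumeRatio(m, f_v, L), 2, tolerance = 1e-9)
  ph <- makePhantom("sphere-void", r = 1, L = 4, n = 5)
  ms <- extractIsosurface(ph$field, 0, normals = "none")
  fv_s <- volumeFraction(ph$field, 0)
  # (S/V) * L for a sphere is 3L/r
  expect_equal(meshArea(ms) / (fv_s * 4^3) * 4, 3 * 4 / 1, tolerance = 0.02)
  expect_error(areaVolumeRatio(ms, 0), "positive")
})

test_that("global properties are monotone in k and s as the trends require", {
  kt <- propertyTable(k = c(-0.6, -0.3, 0, 0.3, 0.6), s = 1, N = 50)
  expect_true(all(diff(kt$f_v) < 0))
  expect_true(all(diff(kt$p_s_over_L) < 0))
  expect_true(all(diff(kt$area_volume_ratio) > 0))
  st <- propertyTable(k = 0, s = c(0.8, 1, 1.2, 1.4), N = 50)
  expect_true(all(diff(st$f_v) > 0))
  expect_true(all(diff(st$p_s_over_L) > 0))
  expect_true(all(diff(st$area_volume_ratio) < 0))
})

test_that("area-volume ratio equals surface ratio over volume fraction", {
  g <- globalProperties(pcellParams(k = 0.3, N = 50))
  expect_equal(g$area_volume_ratio, g$surface_ratio / g$f_v,
               tolerance = 1e-12)
  expect_equal(g$V_P_surface, g$f_v * g$V_unit_cell, tolerance = 1e-12)
})

test_that("property sweeps record per-row failures and keep going", {
  tab <- propertyTable(k = seq(-0.9, 0.9, by = 0.1), s = 1, N = 40)
  expect_equal(nrow(tab), 19L)
  expect_true(all(is.na(tab$error)))
  # a sweep containing an impossible isovalue still returns all rows
  tab2 <- propertyTable(pairs = data.frame(k = c(0, 3.5), s = c(1, 1)),
                        N = 30)
  expect_equal(nrow(tab2), 2L)
  expect_true(any(!is.na(tab2$error)))
  expect_true(any(is.na(tab2$error)))
})

test_that("property tables export as CSV with six significant digits", {
  tab <- propertyTable(k = 0, s = 1, N = 30,
                       file = file.path(tempdir(), "props.csv"))
  got <- utils::read.csv(file.path(tempdir(), "props.csv"))
  expect_equal(nrow(got), 1L)
  expect_equal(got$f_v, signif(tab$f_v, 6))
})
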