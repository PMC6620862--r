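test_that("porosity identities on handmade voxel solids", {
  M <- 10
  L <- 2
  expect_equal(porosity(manual_solid(array(TRUE, c(M, M, M)), L)), 0)
  expect_equal(porosity(manual_solid(array(FALSE, c(M, M, M)), L)), 1)
  occ <- array(FALSE, c(M, M, M))
  occ[1:5, , ] <- TRUE
  expect_equal(porosity(manual_solid(occ, L)), 0.5)
})

test_that("zero thickness yields an empty solid with porosity one", {
  fld <- std_field(40)
  sol <- solidify(fld, t = 0, M = 30)
  expect_equal(sum(sol$occupancy), 0L)
  expect_equal(porosity(sol), 1)
})

test_that("solid occupancy stays within the internal phase", {
  fld <- std_field(40)
  sol <- suppressWarnings(solidify(fld, t = 0.4, M = 40))
  L <- sol$L
  hv <- sol$voxel_size
  centers <- seq(-L / 2 + hv / 2, L / 2 - hv / 2, length.out = sol$M)
  g <- expand.grid(x = centers, y = centers, z = centers)
  inside <- array(fld$fun(g$x, g$y, g$z) > 0, dim = dim(sol$occupancy))
  expect_true(all(!sol$occupancy | inside))
  expect_equal(sol$material_volume, sum(sol$occupancy) * hv^3)
})

test_that("thin-shell porosity approaches the analytic relation", {
  fld <- std_field(60)
  L <- fld$params$L
  gaps <- sapply(c(0.005, 0.02), function(tL) {
    t <- tL * L
    sol <- suppressWarnings(solidify(fld, t = t, M = 100))
    abs(porosity(sol) - (1 - surfaceRatio(sol$outer_mesh) * t / L))
  })
  expect_lt(gaps[1], 0.01)
  expect_lt(gaps[2], 0.03)
})

test_that("porosity is linear in thickness", {
  fld <- std_field(60)
  ts <- c(0.2, 0.4, 0.6)
  Ps <- vapply(ts, function(t) porosity(solidify(fld, t = t, M = 100)),
               numeric(1))
  expect_true(all(diff(Ps) < 0))
  fit <- stats::lm(Ps ~ ts)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("porosity weakly depends on k and s at fixed thickness", {
  Ps <- vapply(list(c(-0.5, 1), c(0, 1), c(0.5, 1), c(0, 0.9), c(0, 1.1)),
               function(p) {
    fld <- sampleField(pcellParams(k = p[1], s = p[2], N = 40))
    porosity(solidify(fld, t = 0.4, M = 50))
  }, numeric(1))
  expect_lt(max(Ps) - min(Ps), 0.05)
})

test_that("a shell as thick as the pore fills the whole internal phase", {
  fld <- std_field(50)
  ps <- poreSize(fld)$p_s
  sol <- solidify(fld, t = ps * 0.99, M = 50)
  expect_equal(porosity(sol), 1 - volumeFraction(fld), tolerance = 0.01)
  expect_error(solidify(fld, t = ps * 1.3, M = 50), "closes the pore")
  expect_warning(solidify(fld, t = 0.1, M = 40), "under-resolved")
})

test_that("the voxel shell boundary mesh is watertight and bounds the volume", {
  fld <- std_field(40)
  sol <- suppressWarnings(solidify(fld, t = 0.5, M = 40))
  bm <- sol$boundary_mesh
  ed <- pcellkit:::meshEdges(bm$faces)
  expect_equal(sum(ed$count == 1), 0L) # no open edges
  expect_equal(sum(ed$count > 2), 0L)  # manifold
  # outward orientation: divergence-theorem volume equals the voxel volume
  v <- bm$vertices
  f <- bm$faces
  a <- v[f[, 1], ]; b <- v[f[, 2], ]; cc <- v[f[, 3], ]
  vol <- sum((a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
                a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
                a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6)
  expect_equal(vol, sol$material_volume, tolerance = 1e-9)
})

test_that("thickness inverts the thin-shell porosity relation", {
  t1 <- thicknessForPorosity(0.9, 2.3451, 2 * pi)
  expect_equal(t1, 0.1 * 2 * pi / 2.3451, tolerance = 1e-12)
  expect_equal(t1, 0.2679, tolerance = 1e-3)
  t2 <- thicknessForPorosity(0.5, 2.3451, 2 * pi)
  expect_equal(t2, 1.3397, tolerance = 1e-3)
  # P -> 1 gives t -> 0
  expect_lt(thicknessForPorosity(0.999, 2.3451, 2 * pi), 0.003)
  expect_error(thicknessForPorosity(0.5, 2.3451, 2 * pi, p_s = 1.0),
               "infeasible")
  expect_error(thicknessForPorosity(1.2, 2.3451, 2 * pi), "between")
  expect_error(thicknessForPorosity(0.9, -1, 2 * pi), "positive")
})

test_that("roundtrip: thickness from target porosity reproduces it", {
  fld <- std_field(60)
  sr <- surfaceRatio(std_mesh(60))
  t <- thicknessForPorosity(0.9, sr, fld$params$L)
  sol <- solidify(fld, t = t, M = 100)
  expect_equal(porosity(sol), 0.9, tolerance = 0.02 * 0.9)
})

test_that("cell design meets targets by inverse lookup", {
  tab <- rbind(propertyTable(k = seq(-0.6, 0.6, by = 0.3), s = 1, N = 40),
               propertyTable(k = 0, s = c(0.8, 1, 1.2, 1.4), N = 40))
  spec <- designCell(f_v = 0.5, table = tab)
  expect_lt(abs(spec$params$k), 0.05)
  expect_lt(abs(spec$params$s - 1), 0.05)
  # pore-size target sets the cell side: L = p_s_target / (p_s/L)
  spec2 <- designCell(f_v = 0.5, p_s_target = 0.3, table = tab)
  expect_equal(spec2$params$L, 0.3 / spec2$p_s_over_L, tolerance = 1e-9)
  expect_equal(spec2$params$L, 0.693, tolerance = 0.02)
  # porosity target sets the thickness
  spec3 <- designCell(f_v = 0.5, P_target = 0.9, table = tab)
  expect_equal(spec3$t, (1 - 0.9) * spec3$params$L / spec3$surface_ratio,
               tolerance = 1e-9)
  expect_error(designCell(f_v = 0.99, table = tab), "unreachable")
  expect_error(designCell(f_v = 0.5, p_s_target = 0.3, L = 5, table = tab),
               "conflict")
  expect_error(designCell(P_target = 0.9, table = tab), "dimensionless")
})
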