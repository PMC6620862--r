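# independent R-side integration of the brick stiffness matrix with 3-point
# Gauss quadrature (the integrand is quadratic per direction, so any rule of
# order >= 2 is exact; agreement checks the C++ closed 2-point integration)
hex_ke_oracle <- function(E, nu, h) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C) <- c(rep(lam + 2 * mu, 3), rep(mu, 3))
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5, 8, 5) / 9
  KE <- matrix(0, 24, 24)
  # corner order must match the solver: bit0 = x, bit1 = y, bit2 = z
  corners <- cbind(bitwAnd(0:7, 1), bitwAnd(bitwShiftR(0:7, 1), 1),
                   bitwAnd(bitwShiftR(0:7, 2), 1))
  sg <- 2 * corners - 1
  for (ix in 1:3) for (iy in 1:3) for (iz in 1:3) {
    xi <- gp[ix]; eta <- gp[iy]; zeta <- gp[iz]
    B <- matrix(0, 6, 24)
    for (cc in 1:8) {
      dN <- c(sg[cc, 1] * (1 + sg[cc, 2] * eta) * (1 + sg[cc, 3] * zeta),
              (1 + sg[cc, 1] * xi) * sg[cc, 2] * (1 + sg[cc, 3] * zeta),
              (1 + sg[cc, 1] * xi) * (1 + sg[cc, 2] * eta) * sg[cc, 3]) /
        8 * (2 / h)
      j <- 3 * (cc - 1)
      B[1, j + 1] <- dN[1]
      B[2, j + 2] <- dN[2]
      B[3, j + 3] <- dN[3]
      B[4, j + 2] <- dN[3]; B[4, j + 3] <- dN[2]
      B[5, j + 1] <- dN[3]; B[5, j + 3] <- dN[1]
      B[6, j + 1] <- dN[2]; B[6, j + 2] <- dN[1]
    }
    w <- gw[ix] * gw[iy] * gw[iz] * (h / 2)^3
    KE <- KE + w * t(B) %*% C %*% B
  }
  KE
}

test_that("brick element stiffness matches independent quadrature", {
  KE <- pcellkit:::.cpp_hex_ke(110000, 0.3, 0.1)
  KE_o <- hex_ke_oracle(110000, 0.3, 0.1)
  expect_equal(KE, KE_o, tolerance = 1e-10)
  expect_true(isSymmetric(KE, tol = 1e-8))
  ev <- eigen(KE, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-6 * max(ev)), 6L) # rigid-body modes
  expect_true(all(ev > -1e-6 * max(ev)))
})

test_that("homogeneous cube reproduces the material modulus (patch test)", {
  sol <- femCompression(fullSolid(L = 5, M = 8), pcellMaterial(),
                        support = "rolling")
  expect_equal(sol$E_over_Es, 1, tolerance = 0.01)
  # resolution independence of the patch solution
  sol16 <- femCompression(fullSolid(L = 5, M = 12), pcellMaterial(),
                          support = "rolling")
  expect_equal(sol16$E_over_Es, sol$E_over_Es, tolerance = 1e-5)
})

test_that("reactions balance between driven and fixed faces", {
  sol <- femCompression(fullSolid(L = 5, M = 8), pcellMaterial())
  bot <- pcellkit:::faceDofs(8, 2, 0L, 2)
  top <- pcellkit:::faceDofs(8, 2, 8L, 2)
  expect_equal(sum(sol$f[bot]), -sum(sol$f[top]),
               tolerance = 1e-6 * abs(sum(sol$f[top])))
  # interior nodes carry no net force
  interior <- setdiff(seq_along(sol$f), c(
    pcellkit:::faceDofs(8, 2, 0L, 1), pcellkit:::faceDofs(8, 2, 0L, 2),
    pcellkit:::faceDofs(8, 2, 0L, 3), pcellkit:::faceDofs(8, 2, 8L, 2)))
  expect_lt(max(abs(sol$f[interior])), 1e-5 * max(abs(sol$f)))
})

test_that("full-cube apparent shear modulus matches the isotropic value", {
  mat <- pcellMaterial()
  sh <- femShear(fullSolid(L = 5, M = 8), mat)
  G_iso <- mat$E_s / (2 * (1 + mat$nu_s))
  expect_equal(sh$G_app, G_iso, tolerance = 0.01)
  expect_lt(abs(sh$G_app - mat$G_s) / mat$G_s, 0.25)
})

test_that("shell stiffness increases with thickness", {
  fld <- sampleField(pcellParams(k = 0, s = 1, L = 5, N = 40))
  mat <- pcellMaterial()
  E <- vapply(c(0.5, 0.7, 0.9), function(t) {
    femCompression(solidify(fld, t = t, M = 24), mat)$E_over_Es
  }, numeric(1))
  expect_true(all(diff(E) > 0))
  expect_true(all(E > 0 & E < 1))
})

test_that("compressive stiffness falls with s and grows with k", {
  mat <- pcellMaterial()
  E_s_fam <- vapply(c(0.85, 1.15), function(s) {
    fld <- sampleField(pcellParams(k = 0, s = s, L = 5, N = 40))
    femCompression(solidify(fld, t = 0.6, M = 24), mat)$E_over_Es
  }, numeric(1))
  expect_gt(E_s_fam[1], E_s_fam[2])
  E_k_fam <- vapply(c(-0.5, 0.5), function(k) {
    fld <- sampleField(pcellParams(k = k, s = 1, L = 5, N = 40))
    femCompression(solidify(fld, t = 0.6, M = 24), mat)$E_over_Es
  }, numeric(1))
  expect_lt(E_k_fam[1], E_k_fam[2])
})

test_that("apparent shear modulus peaks at the standard cell", {
  # thin-shell regime (t = 0.3 mm on the 5 mm cell): the representative
  # high-porosity condition, where the peak at s = 1 is resolved
  mat <- pcellMaterial()
  G <- vapply(c(0.85, 1, 1.15), function(s) {
    fld <- sampleField(pcellParams(k = 0, s = s, L = 5, N = 40))
    femShear(suppressWarnings(solidify(fld, t = 0.3, M = 40)),
             mat)$G_over_Gs
  }, numeric(1))
  expect_gt(G[2], G[1])
  expect_gt(G[2], G[3])
})

test_that("floating components are removed and disconnection errors", {
  occ <- array(FALSE, c(8, 8, 8))
  occ[3:6, , 3:6] <- TRUE      # column connecting the y faces
  occ[1, 1, 1] <- TRUE         # floating voxel
  sol <- manual_solid(occ, 2)
  expect_message(res <- femCompression(sol, pcellMaterial()), "floating")
  expect_equal(res$n_removed_components, 1L)
  occ2 <- array(FALSE, c(8, 8, 8))
  occ2[, 1:3, ] <- TRUE        # slab not reaching the top face
  expect_error(femCompression(manual_solid(occ2, 2), pcellMaterial()),
               "connect")
})

test_that("von Mises field honours uniaxial and hydrostatic states", {
  mat <- pcellMaterial()
  sol <- femCompression(fullSolid(L = 2, M = 6), mat, support = "rolling")
  vm <- vonMisesField(sol)
  sigma <- mat$E_s * 1000 * sol$eps_A # MPa
  expect_equal(mean(vm$von_mises), sigma, tolerance = 1e-6 * sigma)
  expect_lt(stats::sd(vm$von_mises), 1e-6 * sigma)
  expect_true(all(vm$von_mises >= 0))
  # pure hydrostatic contraction: u = -eps * x
  M <- 6
  Mn <- M + 1
  ax <- seq(0, 2, length.out = Mn)
  g <- expand.grid(x = ax, y = ax, z = ax)
  u <- as.vector(t(cbind(-1e-3 * g$x, -1e-3 * g$y, -1e-3 * g$z)))
  st <- pcellkit:::.cpp_fem_stress(array(TRUE, c(M, M, M)), M, 2 / M,
                                   110000, 0.3, u)
  expect_lt(max(st$von_mises), 1e-6)
})

test_that("stiffness-porosity sweep emits valid rows and logs failures", {
  specs <- data.frame(k = c(0, 0), s = c(1, 1), t = c(0.5, 9),
                      family = c("k", "k"))
  tab <- stiffnessPorosityCurve(specs, L = 5, M = 20, N = 30,
                                modes = "compression")
  expect_equal(nrow(tab), 2L)
  ok <- is.na(tab$error)
  expect_true(ok[1] && !ok[2])
  expect_true(tab$P[1] >= 0 && tab$P[1] <= 1)
  expect_true(tab$E_over_Es[1] > 0 && tab$E_over_Es[1] < 1)
})
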