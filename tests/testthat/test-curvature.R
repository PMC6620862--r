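test_that("paraboloid estimator recovers phantom curvatures", {
  ph <- makePhantom("sphere", r = 1, n = 4)
  cv <- paraboloidCurvatures(ph$mesh)
  ok <- cv$fit_ok
  expect_lt(median(abs(cv$k1[ok] - 1)), 0.02)
  expect_lt(median(abs(cv$k2[ok] - 1)), 0.02)
  # error decreases under refinement
  ph3 <- makePhantom("sphere", r = 1, n = 3)
  cv3 <- paraboloidCurvatures(ph3$mesh)
  expect_lt(median(abs(cv$k1[ok] - 1)),
            median(abs(cv3$k1[cv3$fit_ok] - 1)) + 1e-6)

  cyl <- makePhantom("cylinder", r = 1, height = 2, n = 4)
  cvc <- paraboloidCurvatures(cyl$mesh)
  okc <- cvc$fit_ok
  expect_lt(median(abs(cvc$k1[okc] - 1)), 0.02)
  expect_lt(median(abs(cvc$k2[okc])), 0.02)

  sad <- makePhantom("saddle", L = 1, n = 4)
  cvs <- paraboloidCurvatures(sad$mesh)
  ctr <- which.min(rowSums(sad$mesh$vertices[, 1:2]^2))
  expect_equal(cvs$k1[ctr], 1, tolerance = 0.02)
  expect_equal(cvs$k2[ctr], -1, tolerance = 0.02)
  expect_equal(cvs$H[ctr], 0, tolerance = 0.02)
})

test_that("derived curvature quantities satisfy their identities", {
  m <- std_mesh(60)
  cv <- paraboloidCurvatures(m)
  ok <- cv$fit_ok
  expect_true(all(cv$k1[ok] >= cv$k2[ok]))
  expect_equal(cv$G[ok], cv$k1[ok] * cv$k2[ok], tolerance = 1e-12)
  expect_equal(cv$H[ok], (cv$k1[ok] + cv$k2[ok]) / 2, tolerance = 1e-12)
  expect_equal(cv$R[ok], sqrt(cv$k1[ok]^2 + cv$k2[ok]^2), tolerance = 1e-12)
  expect_true(all(cv$R[ok] >= abs(cv$k1[ok]) - 1e-12))
  expect_true(all(cv$R[ok] >= abs(cv$k2[ok]) - 1e-12))
})

test_that("the sign rule labels vertices exactly as stated", {
  cv <- fake_curvature(k1 = c(0.3, 0.3, 0, 0.1, -0.1, 0),
                       k2 = c(0.1, -0.1, 0, 0, -0.3, -0.2))
  lab <- classifyVertices(cv)
  expect_equal(as.character(lab),
               c("concave", "saddle_flat", "saddle_flat", "concave",
                 "convex", "convex"))
  # failed fits never classify
  cv2 <- fake_curvature(k1 = 0.3, k2 = 0.1, fit_ok = FALSE)
  expect_equal(as.character(classifyVertices(cv2)), "saddle_flat")
})

test_that("flipping all normals swaps concave and convex labels", {
  fld <- sampleField(pcellParams(k = -0.5, N = 50))
  m <- extractIsosurface(fld)
  cv <- paraboloidCurvatures(m)
  m2 <- m
  m2$normals <- -m$normals
  cv2 <- paraboloidCurvatures(m2)
  lab <- classifyVertices(cv)
  lab2 <- classifyVertices(cv2)
  expect_equal(sum(lab == "concave"), sum(lab2 == "convex"))
  expect_equal(sum(lab == "convex"), sum(lab2 == "concave"))
  ok <- cv$fit_ok & cv2$fit_ok
  expect_equal(cv$k1[ok], -cv2$k2[ok], tolerance = 1e-8)
})

test_that("standard k=0 cells are saddle-shaped with near-zero mean curvature", {
  for (s in c(0.8, 1, 1.4)) {
    ca <- curvatureAnalysis(pcellParams(k = 0, s = s, N = 60))
    expect_equal(length(ca$regions), 0L, label = sprintf("s = %.1f", s))
    ok <- ca$curvature$fit_ok
    expect_gt(mean(ca$curvature$G[ok] <= 0), 0.95)
    # the nodal surface is only approximately minimal: |H| is small relative
    # to the curvedness everywhere; the signed mean cancels by the half-cell
    # translation symmetry only at s = 1 (clipping breaks it otherwise)
    expect_lt(mean(abs(ca$curvature$H[ok])) / mean(ca$curvature$R[ok]), 0.2)
    if (s == 1) {
      expect_lt(abs(mean(ca$curvature$H[ok])) * ca$mesh$L, 0.05)
    }
  }
})

test_that("eight near-identical regions appear for k = ±0.7", {
  for (kk in c(-0.7, 0.7)) {
    ca <- curvatureAnalysis(pcellParams(k = kk, s = 1, N = 80))
    expect_equal(length(ca$regions), 8L, label = sprintf("k = %.1f", kk))
    want <- if (kk < 0) "concave" else "convex"
    expect_true(all(vapply(ca$regions, function(r) r$label, "") == want))
    ar <- vapply(ca$regions, function(r) r$A_r_pct, numeric(1))
    expect_lt((max(ar) - min(ar)) / max(ar), 0.05)
    expect_true(all(ar > 0 & ar <= 100))
    expect_lte(sum(ar), 100)
  }
})

test_that("region count is stable across grid resolutions", {
  for (N in c(60, 80)) {
    ca <- curvatureAnalysis(pcellParams(k = 0.7, s = 1, N = N))
    expect_equal(length(ca$regions), 8L, label = sprintf("N = %d", N))
  }
})

test_that("region curvedness grows with |k| and with decreasing s", {
  rml <- vapply(c(0.3, 0.5, 0.7), function(kk) {
    curvatureAnalysis(pcellParams(k = kk, s = 1, N = 60))$stats$R_mean_L
  }, numeric(1))
  expect_true(all(diff(rml) > 0))
  lo <- curvatureAnalysis(pcellParams(k = -0.5, s = 0.85, N = 60))$stats
  hi <- curvatureAnalysis(pcellParams(k = -0.5, s = 1.15, N = 60))$stats
  expect_gt(lo$R_mean_L, hi$R_mean_L)
  expect_lt(lo$A_r_pct, hi$A_r_pct)
})

test_that("regions are connected sets of same-label vertices", {
  ca <- curvatureAnalysis(pcellParams(k = 0.6, s = 1, N = 50))
  lab <- ca$labels
  for (r in ca$regions) {
    expect_true(all(lab[r$vertex_ids] == r$label))
  }
  csv <- file.path(tempdir(), "curv.csv")
  writeCurvatureCSV(ca$mesh, ca$curvature, csv)
  got <- utils::read.csv(csv)
  expect_equal(nrow(got), nrow(ca$mesh$vertices))
})
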