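test_that("nodal field evaluates the cosine sum with the scale parameter", {
  p1 <- pcellParams(k = 0, s = 1)
  expect_equal(evalField(0, 0, 0, p1), 3)
  expect_equal(evalField(pi, pi, pi, p1), -3)
  p2 <- pcellParams(k = 0, s = 2)
  expect_equal(evalField(pi, pi, pi, p2), 0, tolerance = 1e-12)
  # general L: coordinates are rescaled to the canonical domain
  p3 <- pcellParams(k = 0, s = 1, L = 5)
  expect_equal(evalField(2.5, 2.5, 2.5, p3), -3)
  expect_error(evalField(Inf, 0, 0, p1), "finite")
})

test_that("parameter validity flags follow the admissible ranges", {
  expect_true(pcellParams(k = 0.9)$valid_k)
  expect_false(pcellParams(k = 1.0)$valid_k)
  expect_false(pcellParams(k = -1.0)$valid_k)
  expect_true(pcellParams(s = 0.75)$valid_s)
  expect_true(pcellParams(s = 1.5)$valid_s)
  expect_false(pcellParams(s = 1.55)$valid_s)
  expect_false(pcellParams(s = 0.7)$valid_s)
  expect_error(pcellParams(N = 2), "N")
  expect_error(pcellParams(L = -1), "L")
  expect_error(pcellParams(s = 0), "s")
})

test_that("uniform scaling multiplies L and preserves dimensionless ratios", {
  p <- pcellParams(k = 0.3, s = 1.1, L = 2 * pi, N = 40)
  q <- scaleParams(p, 2)
  expect_equal(q$L, 4 * pi)
  expect_equal(q$k, p$k)
  expect_equal(q$s, p$s)
  expect_identical(scaleParams(p, 1)$L, p$L)
  expect_error(scaleParams(p, 0), "positive")
  expect_error(scaleParams(p, -2), "positive")
})

test_that("dimensionless properties are invariant under scaling to 1e-12", {
  p <- pcellParams(k = 0.2, s = 1, N = 40)
  q <- scaleParams(p, 3)
  gp <- globalProperties(p)
  gq <- globalProperties(q)
  expect_equal(gq$f_v, gp$f_v, tolerance = 1e-12)
  expect_equal(gq$surface_ratio, gp$surface_ratio, tolerance = 1e-12)
  expect_equal(gq$p_s_over_L, gp$p_s_over_L, tolerance = 1e-8)
  # dimensional quantities scale
  expect_equal(gq$S, gp$S * 9, tolerance = 1e-12)
  expect_equal(gq$p_s, gp$p_s * 3, tolerance = 1e-8)
})
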