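graded <- function(...) gm(matrix(c(...), 1))

test_that("rainfall erosivity matches hand evaluation and is affine", {
  mk <- function(p) lapply(rep(p, 12), function(x) gm(matrix(x, 2, 2)))
  r100 <- rainfall_erosivity(mk(100))
  expect_equal(r100$values[1, 1], 12 * (-2.6398 + 0.3046 * 100))
  r0 <- rainfall_erosivity(mk(0))
  expect_equal(r0$values[1, 1], -31.6776)
  # affine: R(2P) - R(P) = 0.3046 * sum(P)
  r200 <- rainfall_erosivity(mk(200))
  expect_equal(r200$values[1, 1] - r100$values[1, 1], 0.3046 * 1200)
  expect_error(rainfall_erosivity(mk(100)[1:11]), "12")
})

test_that("factor grading reproduces the band table", {
  expect_equal(grade_factor(graded(550), "R")$grid$values[1, 1], 3)
  expect_equal(grade_factor(graded(0.96), "C")$grid$values[1, 1], 1)
  expect_equal(grade_factor(graded(300), "LS")$grid$values[1, 1], 9)
  expect_equal(grade_factor(graded(0.5), "C")$grid$values[1, 1], 9)
  expect_equal(grade_factor(graded(0.95), "C")$grid$values[1, 1], 3)  # boundary
  expect_equal(grade_factor(graded(0.6), "I")$grid$values[1, 1], 3)
  expect_equal(grade_factor(graded(260), "W")$grid$values[1, 1], 9)
  expect_equal(grade_factor(graded(6), "soil_texture")$grid$values[1, 1], 1)
  expect_error(grade_factor(graded(99), "soil_texture"), "99")
  g <- grade_factor(gm(matrix(runif(25, 400, 700), 5)), "R")
  expect_true(all(g$grid$values %in% c(1, 3, 5, 7, 9)))
})

test_that("sensitivity indices match hand-evaluated examples", {
  g1 <- graded(1); g3 <- graded(3); g5 <- graded(5)
  g7 <- graded(7); g9 <- graded(9)
  expect_equal(sswl(g1, g1, g1, g1)$values[1, 1], 1)
  expect_equal(sswl(g9, g9, g9, g9)$values[1, 1], 9)
  expect_equal(sswl(g1, g3, g5, g7)$values[1, 1], 105^(1 / 4))
  expect_equal(sse(g1, g3, g5, g7)$values[1, 1], 4)
  expect_equal(sse(g9, g9, g9, g9)$values[1, 1], 9)
  expect_equal(sld(g3, g3, g3, g3)$values[1, 1], 3)
  expect_equal(sld(g9, g7, g5, g3)$values[1, 1], 945^(1 / 4))
  expect_error(sswl(g1, g1, g1, graded(2)), "1,3,5,7,9")
})

test_that("geometric-mean indices are bounded and below the mean (AM-GM)", {
  set.seed(9)
  mk <- function() gm(matrix(sample(c(1, 3, 5, 7, 9), 36, TRUE), 6))
  for (i in 1:5) {
    a <- mk(); b <- mk(); cg <- mk(); d <- mk()
    gmx <- sswl(a, b, cg, d)$values
    amx <- sse(a, b, cg, d)$values
    mn <- pmin(a$values, b$values, cg$values, d$values)
    mx <- pmax(a$values, b$values, cg$values, d$values)
    expect_true(all(gmx >= mn - 1e-12 & gmx <= mx + 1e-12))
    expect_true(all(gmx <= amx + 1e-12))
    expect_true(all(amx >= 1 & amx <= 9))
  }
})

test_that("composite sensitivity is the weighted sum with printed weights", {
  x <- gm(matrix(2, 2, 2))
  expect_equal(composite_sensitivity(x, x, x)$values, matrix(2, 2, 2))
  v <- composite_sensitivity(gm(matrix(9, 1, 1)), gm(matrix(1, 1, 1)),
                             gm(matrix(1, 1, 1)))$values[1, 1]
  expect_equal(v, 0.43 * 9 + 0.39 + 0.18)
  expect_warning(composite_sensitivity(x, x, x, weights = c(0.5, 0.4, 0.3)),
                 "sum")
})

test_that("service indices match hand evaluation and stay in [0,1]", {
  u <- function(x) gm(matrix(x, 1))
  expect_equal(water_retention(u(0), u(1), u(1), u(0))$values[1, 1], 0)
  expect_equal(water_retention(u(1), u(1), u(1), u(0))$values[1, 1], 1)
  expect_equal(water_retention(u(0.5), u(6 / 13), u(0.8), u(0.25))$values[1, 1],
               0.5 * 6 / 13 * 0.8 * 0.75, tolerance = 1e-6)
  expect_equal(soil_conservation(u(1), u(1), u(0))$values[1, 1], 0)
  expect_equal(soil_conservation(u(1), u(0), u(0))$values[1, 1], 1)
  expect_equal(soil_conservation(u(0.6), u(0.3), u(0.2))$values[1, 1], 0.336)
  expect_equal(biodiversity_service(u(1), u(1), u(1), u(1))$values[1, 1], 0)
  expect_equal(biodiversity_service(u(1), u(1), u(1), u(0))$values[1, 1], 1)
  expect_equal(biodiversity_service(u(0.5), u(0.5), u(0.5), u(0.5))$values[1, 1],
               0.0625)
  expect_error(water_retention(u(1.2), u(1), u(1), u(0)), "normalized")
})

test_that("composite importance is a bounded convex combination", {
  u <- function(x) gm(matrix(x, 1))
  expect_equal(composite_importance(u(0.3), u(0.3), u(0.3))$values[1, 1], 0.3)
  expect_equal(composite_importance(u(1), u(0), u(0))$values[1, 1], 0.45)
  set.seed(2)
  a <- gm(matrix(runif(16), 4)); b <- gm(matrix(runif(16), 4))
  cg <- gm(matrix(runif(16), 4))
  comp <- composite_importance(a, b, cg)$values
  expect_true(all(comp >= pmin(a$values, b$values, cg$values) - 1e-12))
  expect_true(all(comp <= pmax(a$values, b$values, cg$values) + 1e-12))
})

test_that("environment superposition is symmetric and classifies to 5 classes", {
  set.seed(4)
  sens <- gm(matrix(runif(400, 1, 9), 20))
  imp <- gm(matrix(runif(400), 20))
  a <- superpose_environment(sens, imp)
  b <- superpose_environment(imp, sens)
  expect_equal(a$environment_class$values, b$environment_class$values)
  expect_setequal(unique(as.vector(a$environment_class$values)), 1:5)
  # identical layers: environment classes equal the sensitivity classes
  s2 <- superpose_environment(sens, sens)
  expect_equal(s2$environment_class$values, s2$sensitivity_class$values)
  expect_error(superpose_environment(sens, gm(matrix(1, 20, 20))), "constant")
})

test_that("slope from a tilted plane recovers the analytic angle", {
  nr <- 12
  z <- outer(seq_len(nr), seq_len(nr), function(r, c) 100 * c)  # 100 m / cell
  s <- slope_from_dem(esp_grid(z, cellsize = 1000))
  expect_equal(s$values[6, 6], atan(0.1) * 180 / pi, tolerance = 1e-6)
})
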