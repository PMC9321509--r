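test_that("ASCII grid round-trips values, metadata and nodata", {
  m <- matrix(1:9, 3, 3, byrow = TRUE)
  m[2, 3] <- NA
  g <- esp_grid(m, cellsize = 50, origin = c(1000, 2000), nodata = -9999)
  p <- tempfile(fileext = ".asc")
  write_grid(g, p)
  g2 <- read_grid(p)
  expect_equal(g2$values, g$values)
  expect_equal(g2$cellsize, g$cellsize)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$nodata, g$nodata)
  # class-code grids are written as integers
  expect_false(any(grepl("\\.", readLines(p)[-(1:6)])))
  unlink(p)
})

test_that("nodata sentinel cells are flagged on read", {
  p <- tempfile(fileext = ".asc")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCORNER 0", "YLLCORNER 0",
               "CELLSIZE 10", "NODATA_value -9999",
               "1 -9999", "3 4"), p)
  g <- read_grid(p)
  expect_true(is.na(g$values[1, 2]))
  expect_equal(g$values[2, 2], 4)
  unlink(p)
})

test_that("malformed ASCII grids are rejected", {
  p <- tempfile(fileext = ".asc")
  writeLines(c("NCOLS 3", "NROWS 2", "XLLCORNER 0", "YLLCORNER 0",
               "CELLSIZE 10", "1 2 3", "4 5"), p)
  expect_error(read_grid(p), "body")
  writeLines(c("NCOLS 3", "XLLCORNER 0", "YLLCORNER 0", "CELLSIZE 10",
               "1 2 3"), p)
  expect_error(read_grid(p), "missing")
  unlink(p)
  expect_error(read_grid(tempfile()), "not found")
})

test_that("grid arithmetic propagates nodata and checks alignment", {
  a <- gm(matrix(c(1, NA, 3, 4), 2))
  b <- gm(matrix(c(10, 20, 30, 40), 2))
  s <- a + b
  expect_true(is.na(s$values[2, 1]))
  expect_equal(s$values[1, 1], 11)
  off <- esp_grid(matrix(0, 2, 2), cellsize = 100, origin = c(5, 5))
  expect_error(a + off, "aligned")
})

test_that("focal range matches hand values and the brute-force oracle", {
  expect_equal(focal_range(gm(matrix(7, 4, 4)), 3)$values,
               matrix(0, 4, 4))
  g <- gm(matrix(1:9, 3, 3, byrow = TRUE))
  expect_equal(focal_range(g, 3)$values[2, 2], 8)
  set.seed(11)
  m <- matrix(runif(64), 8, 8)
  fr <- focal_range(gm(m), 5)$values
  h <- 2
  for (r in 1:8) for (c in 1:8) {
    w <- m[max(1, r - h):min(8, r + h), max(1, c - h):min(8, c + h)]
    expect_equal(fr[r, c], max(w) - min(w))
  }
  expect_error(focal_range(g, 4), "odd")
})

test_that("euclidean distance matches the all-pairs oracle and is Lipschitz", {
  g <- gm(matrix(0, 10, 10), cellsize = 100)
  one <- euclidean_distance(g, matrix(c(5L, 5L), 1))
  expect_equal(one$values[5, 5], 0)
  expect_equal(one$values[4, 5], 100)
  expect_equal(one$values[5, 6], 100)
  set.seed(3)
  cells <- which(matrix(runif(100) < 0.08, 10, 10), arr.ind = TRUE)
  d <- euclidean_distance(g, cells)$values
  for (r in 1:10) for (c in 1:10)
    expect_equal(d[r, c],
                 min(sqrt((cells[, 1] - r)^2 + (cells[, 2] - c)^2)) * 100)
  # 1-Lipschitz per metre: neighbours differ by at most cellsize * sqrt(2)
  dif <- c(abs(diff(d)), abs(t(diff(t(d)))))
  expect_true(all(dif <= 100 * sqrt(2) + 1e-9))
  expect_error(euclidean_distance(g, cells[0, , drop = FALSE]), "empty")
})

test_that("segments are rasterized before the distance transform", {
  g <- esp_grid(matrix(0, 10, 10), cellsize = 100, origin = c(0, 1000))
  seg <- data.frame(x1 = 0, y1 = 550, x2 = 1000, y2 = 550)  # row 5
  d <- euclidean_distance(g, seg)
  expect_equal(d$values[5, ], rep(0, 10))
  expect_equal(d$values[8, 3], 300)
})

test_that("minmax normalization is affine onto [0,1] and keeps nodata", {
  g <- gm(matrix(c(2, 4, 6, NA), 2))
  n <- minmax_normalize(g)
  expect_equal(sort(n$values[!is.na(n$values)]), c(0, 0.5, 1))
  expect_true(is.na(n$values[2, 2]))
  expect_error(minmax_normalize(gm(matrix(5, 2, 2))), "constant")
  # order preservation on random values
  set.seed(8)
  v <- matrix(rnorm(36), 6)
  expect_equal(order(minmax_normalize(gm(v))$values), order(v))
})

test_that("jenks breaks find the optimal partition", {
  b <- jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)
  expect_gte(b$breaks, 3)
  expect_lt(b$breaks, 10)
  expect_equal(jenks_breaks(1:5, 1)$breaks, numeric(0))
  b3 <- jenks_breaks(c(1, 5, 9), 3)
  expect_equal(partition_ssd(c(1, 5, 9), classify(c(1, 5, 9), b3)), 0)
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
  # optimality vs exhaustive enumeration over random cases
  set.seed(21)
  for (i in 1:12) {
    n <- sample(6:12, 1); k <- sample(2:4, 1)
    x <- round(runif(n, 0, 50), 2)
    if (length(unique(x)) < k) next
    br <- jenks_breaks(x, k)
    expect_equal(partition_ssd(x, classify(x, br)), oracle_jenks_ssd(x, k),
                 tolerance = 1e-10)
  }
})

test_that("classification thresholds are left-open/right-closed", {
  g <- gm(matrix(c(1, 2, 3, 10), 2))
  cls <- classify(g, 3.5)
  expect_equal(sort(as.vector(cls$values)), c(1, 1, 1, 2))
  expect_equal(classify(c(0.1, 0.2), 5), c(1, 1))       # all below first break
  expect_equal(classify(3.5, 3.5), 1)                   # boundary -> lower
  # idempotence on labels
  lab <- c(1, 2, 3, 4)
  br <- jenks_breaks(lab, 4)
  expect_equal(classify(lab, br), lab)
})

test_that("large-raster breaks use the deterministic subsample", {
  set.seed(5)
  v <- rnorm(30000)
  expect_identical(jenks_breaks(v, 5), jenks_breaks(v, 5))
})
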