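test_that("patch labelling honours the connectivity definition", {
  m <- matrix(1, 4, 4)
  m[1, 1] <- 5; m[2, 2] <- 5
  expect_equal(nrow(label_patches(gm(m), 5, connectivity = 8)$patches), 1)
  expect_equal(nrow(label_patches(gm(m), 5, connectivity = 4)$patches), 2)
  full <- label_patches(gm(matrix(5, 3, 3)), 5)
  expect_equal(nrow(full$patches), 1)
  expect_equal(full$patches$cells, 9)
  none <- label_patches(gm(matrix(1, 3, 3)), 5)
  expect_equal(nrow(none$patches), 0)
})

test_that("component counts match the flood-fill oracle", {
  set.seed(17)
  for (i in 1:8) {
    m <- matrix(as.numeric(runif(144) < 0.4), 12, 12)
    for (conn in c(4, 8)) {
      ps <- label_patches(gm(m), 1, connectivity = conn)
      expect_equal(nrow(ps$patches),
                   oracle_component_count(m == 1, conn))
    }
  }
})

test_that("patches separated by under 500 m merge; farther ones do not", {
  near <- label_patches(make_fixture("two_patches_300m"), 5)
  expect_equal(nrow(near$patches), 2)
  merged <- merge_nearby(near, 500)
  expect_equal(nrow(merged$patches), 1)
  # area is the sum of member areas, gap cells stay background
  expect_equal(merged$patches$cells, sum(near$patches$cells))
  far <- label_patches(make_fixture("two_patches_600m"), 5)
  expect_equal(nrow(merge_nearby(far, 500)$patches), 2)
})

test_that("merging is transitive, idempotent and monotone in the gap", {
  m <- matrix(1, 5, 14)
  m[3, 2] <- 5; m[3, 6] <- 5; m[3, 10] <- 5   # A-B 400 m, B-C 400 m, A-C 800 m
  ps <- label_patches(gm(m), 5)
  expect_equal(nrow(ps$patches), 3)
  all3 <- merge_nearby(ps, 500)
  expect_equal(nrow(all3$patches), 1)
  twice <- merge_nearby(all3, 500)
  expect_equal(twice$label_grid$values, all3$label_grid$values)
  counts <- vapply(c(100, 300, 450, 900),
                   function(gap) nrow(merge_nearby(ps, gap)$patches),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("edge-to-edge patch distances equal the brute-force pair minimum", {
  set.seed(23)
  m <- matrix(as.numeric(runif(100) < 0.2), 10, 10)
  ps <- label_patches(esp_grid(m, cellsize = 10), 1)
  if (nrow(ps$patches) >= 2) {
    D <- espmcr:::patch_pair_distances(ps$label_grid)
    lab <- ps$label_grid$values
    for (a in 1:(nrow(ps$patches) - 1)) for (b in (a + 1):nrow(ps$patches)) {
      ca <- which(lab == a, arr.ind = TRUE)
      cb <- which(lab == b, arr.ind = TRUE)
      bf <- min(sqrt(outer(ca[, 1], cb[, 1], "-")^2 +
                       outer(ca[, 2], cb[, 2], "-")^2)) * 10
      expect_equal(D[a, b], bf)
    }
  }
})

test_that("the area filter is strict and relabels by descending area", {
  m <- matrix(1, 10, 10)
  m[1:3, 1:3] <- 5      # 9 cells = 9 km2 at 1000 m
  m[6:7, 6:9] <- 5      # 8 cells = 8 km2 (excluded: strict >)
  ps <- label_patches(esp_grid(m, cellsize = 1000), 5)
  src <- filter_by_area(ps, 8)
  expect_equal(nrow(src$patches), 1)
  expect_equal(src$patches$area_km2, 9)
  all_kept <- filter_by_area(ps, 0)
  expect_equal(nrow(all_kept$patches), 2)
  expect_true(all(diff(all_kept$patches$area_km2) <= 0))
  expect_warning(empty <- filter_by_area(ps, 1000), "empty")
  expect_equal(nrow(empty$patches), 0)
  expect_lte(sum(src$patches$area_km2), sum(ps$patches$area_km2))
})

test_that("land-use composition counts cells and sums to 100 percent", {
  m <- matrix(1, 6, 6); m[2:4, 2:4] <- 5
  ps <- filter_by_area(label_patches(esp_grid(m, 1000), 5), 0)
  lu <- esp_grid(matrix(1, 6, 6), 1000)
  comp1 <- landuse_composition(ps, lu)
  expect_equal(comp1$percent, 100)
  lu$values[2:4, 2] <- 3     # 3 of the 9 source cells cultivated
  comp2 <- landuse_composition(ps, lu)
  expect_equal(sum(comp2$percent), 100)
  expect_equal(comp2$area_km2[comp2$class == 3], 3)
  expect_equal(comp2$percent[comp2$class == 1], 100 * 6 / 9)
})
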