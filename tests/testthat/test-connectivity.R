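test_that("single-step costs follow the mean-resistance convention", {
  g <- esp_grid(matrix(3, 5, 5), cellsize = 100)
  cd <- cost_distance(g, matrix(c(3L, 3L), 1))
  expect_equal(cd$cost$values[3, 3], 0)
  expect_equal(cd$cost$values[3, 4], 3 * 100)
  expect_equal(cd$cost$values[2, 2], 3 * 100 * sqrt(2))
  expect_true(all(cd$allocation$values == 1))
})

test_that("cost distance matches the relaxation oracle on random surfaces", {
  set.seed(31)
  for (i in 1:10) {
    nr <- sample(5:8, 1); nc <- sample(5:8, 1)
    resist <- matrix(runif(nr * nc, 0.5, 10), nr, nc)
    resist[runif(nr * nc) < 0.1] <- NA
    src <- matrix(FALSE, nr, nc)
    src[sample(which(!is.na(resist)), 2)] <- TRUE
    cd <- cost_distance(esp_grid(resist, 50), src)
    expect_equal(cd$cost$values, oracle_cost(resist, 50, src),
                 tolerance = 1e-9)
  }
})

test_that("cost satisfies the Bellman condition everywhere", {
  set.seed(32)
  resist <- matrix(runif(49, 1, 5), 7, 7)
  cd <- cost_distance(esp_grid(resist, 100), matrix(c(1L, 1L), 1))
  cost <- cd$cost$values
  for (r in 1:7) for (c in 1:7)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > 7 || c2 < 1 || c2 > 7) next
      step <- (resist[r, c] + resist[r2, c2]) / 2 * 100 * sqrt(dr^2 + dc^2)
      expect_lte(cost[r, c], cost[r2, c2] + step + 1e-9)
    }
})

test_that("least-cost paths match oracle costs and handle edge cases", {
  fx <- make_fixture("uniform_surface")
  co <- least_cost_path(fx$surface, fx$a, fx$b)
  expect_equal(co$cost, fx$expected_cost)
  expect_equal(nrow(co$path), 8)                    # straight orthogonal path
  expect_true(all(co$path[, 1] == 6))
  expect_equal(co$length_m, 700)
  # overlapping sources: zero-cost empty path
  same <- least_cost_path(fx$surface, fx$a, fx$a)
  expect_equal(same$cost, 0)
  expect_equal(nrow(same$path), 0)
  # unreachable pair: explicit disconnected result, not an error
  wall <- matrix(1, 5, 5); wall[, 3] <- NA
  dis <- least_cost_path(esp_grid(wall, 100), matrix(c(3L, 1L), 1),
                         matrix(c(3L, 5L), 1))
  expect_true(dis$disconnected)
  # random surfaces vs oracle
  set.seed(33)
  for (i in 1:8) {
    resist <- matrix(runif(64, 0.5, 8), 8, 8)
    a <- matrix(c(1L, 1L), 1); b <- matrix(c(8L, 8L), 1)
    co <- least_cost_path(esp_grid(resist, 10), a, b)
    amask <- matrix(FALSE, 8, 8); amask[1, 1] <- TRUE
    expect_equal(co$cost, oracle_cost(resist, 10, amask)[8, 8],
                 tolerance = 1e-9)
  }
})

test_that("corridor cost is symmetric and scales with the surface", {
  set.seed(34)
  resist <- matrix(runif(81, 1, 6), 9, 9)
  a <- matrix(c(2L, 2L), 1); b <- matrix(c(8L, 7L), 1)
  co_ab <- least_cost_path(esp_grid(resist, 100), a, b)
  co_ba <- least_cost_path(esp_grid(resist, 100), b, a)
  expect_equal(co_ab$cost, co_ba$cost, tolerance = 1e-9)
  co_scaled <- least_cost_path(esp_grid(3 * resist, 100), a, b)
  expect_equal(co_scaled$cost, 3 * co_ab$cost, tolerance = 1e-9)
  expect_equal(co_scaled$path, co_ab$path)
  # straight-line lower bound
  expect_gte(co_ab$cost, min(resist) * 100 * sqrt(6^2 + 5^2))
})

test_that("adjacent-pairs networks link only allocation neighbours", {
  g <- esp_grid(matrix(1, 5, 21), cellsize = 100)
  lab <- matrix(0L, 5, 21)
  lab[3, 2] <- 1L; lab[3, 11] <- 2L; lab[3, 20] <- 3L
  net <- corridor_network(g, grid_like(g, lab), mode = "adjacent_pairs")
  expect_equal(net$n_corridors, 2)
  pairs <- t(vapply(net$corridors, function(co) c(co$a, co$b), numeric(2)))
  expect_false(any(pairs[, 1] == 1 & pairs[, 2] == 3))
  all_net <- corridor_network(g, grid_like(g, lab), mode = "all_pairs")
  expect_equal(all_net$n_corridors, 3)
  expect_warning(one <- corridor_network(g, grid_like(g, lab == 1)),
                 "fewer than two")
  expect_equal(one$n_corridors, 0)
})

test_that("series and parallel circuits carry the textbook currents", {
  # single-file chain: every interior cell carries the full unit current
  chain <- matrix(NA_real_, 3, 7); chain[2, ] <- 1
  cf <- current_flow(esp_grid(chain, 100), matrix(c(2L, 1L), 1),
                     matrix(c(2L, 7L), 1), swath_percentile = 10)
  expect_equal(cf$values[2, 2:6], rep(1, 5), tolerance = 1e-10)
  # two equal parallel chains: half the current in each
  par <- matrix(NA_real_, 5, 6)
  par[1, ] <- 1; par[5, ] <- 1; par[, 1] <- 1; par[, 6] <- 1
  cfp <- current_flow(esp_grid(par, 100), matrix(c(3L, 1L), 1),
                      matrix(c(3L, 6L), 1), swath_percentile = 10)
  expect_equal(cfp$values[1, 3], 0.5, tolerance = 1e-10)
  expect_equal(cfp$values[5, 3], 0.5, tolerance = 1e-10)
})

test_that("current flow matches the dense Laplacian oracle", {
  set.seed(35)
  for (i in 1:5) {
    resist <- matrix(runif(49, 0.5, 5), 7, 7)
    amask <- matrix(FALSE, 7, 7); amask[4, 1] <- TRUE
    bmask <- matrix(FALSE, 7, 7); bmask[4, 7] <- TRUE
    cf <- current_flow(esp_grid(resist, 100), amask, bmask,
                       swath_percentile = 1e9)  # swath = whole grid
    expect_equal(cf$values, oracle_current(resist, 100, amask, bmask),
                 tolerance = 1e-8)
  }
})

test_that("current is conserved and insensitive to resistance scaling", {
  set.seed(36)
  resist <- matrix(runif(64, 1, 4), 8, 8)
  amask <- matrix(FALSE, 8, 8); amask[1, 1] <- TRUE
  bmask <- matrix(FALSE, 8, 8); bmask[8, 8] <- TRUE
  cf1 <- current_flow(esp_grid(resist, 100), amask, bmask,
                      swath_percentile = 1e9)
  # unit current enters at the source cell
  expect_equal(cf1$values[1, 1], 0.5, tolerance = 1e-8)  # half-sum convention
  cf3 <- current_flow(esp_grid(5 * resist, 100), amask, bmask,
                      swath_percentile = 1e9)
  expect_equal(cf1$values, cf3$values, tolerance = 1e-8)
})

test_that("nodes concentrate at a planted bottleneck", {
  fx <- make_fixture("bottleneck_neck")
  cf <- current_flow(fx$surface, fx$a, fx$b, swath_percentile = 10)
  mx <- which(cf$values == max(cf$values, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(unname(mx[1, ]), as.integer(fx$neck))
  nodes <- extract_nodes(list(cf), min_area_km2 = 0)
  imp_lab <- nodes$important_nodes$label_grid$values
  expect_gt(imp_lab[fx$neck[1], fx$neck[2]], 0)
  # threshold larger than any patch: no important nodes survive
  none <- extract_nodes(list(cf), min_area_km2 = 1e6)
  expect_equal(nrow(none$important_nodes$patches), 0)
})

test_that("a constant current field admits no importance split", {
  chain <- matrix(NA_real_, 3, 7); chain[2, ] <- 1
  cf <- current_flow(esp_grid(chain, 100), matrix(c(2L, 1L), 1),
                     matrix(c(2L, 7L), 1), swath_percentile = 10)
  cfc <- cf
  cfc$values[2, ] <- 1   # idealized uniform corridor
  nodes <- extract_nodes(list(cfc), min_area_km2 = 1)
  expect_equal(nrow(nodes$important_nodes$patches), 0)
  expect_gt(nrow(nodes$general_nodes$patches), 0)
})
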