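test_that("cost distance on a uniform surface follows king-move geometry", {
  r <- grid(matrix(1, 7, 7), cellsize = 1000)   # 1 km cells, R = 1
  seed <- matrix(FALSE, 7, 7); seed[4, 2] <- TRUE
  cf <- cost_distance(r, seed)
  expect_equal(cf$cost$values[4, 2], 0)
  expect_equal(cf$cost$values[4, 5], 3)              # three cells east
  expect_equal(cf$cost$values[3, 3], sqrt(2), tolerance = 1e-12)
  expect_equal(cf$cost$values[2, 4], 2 * sqrt(2), tolerance = 1e-12)
  expect_error(cost_distance(r, matrix(FALSE, 7, 7)), "empty")
  r0 <- r; r0$values[1, 1] <- 0
  expect_error(cost_distance(r0, seed), "positive")
})

test_that("cost distance equals the exhaustive relaxation oracle on random grids", {
  set.seed(314)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    res <- matrix(runif(n * n, 0.5, 10), n, n)
    seed <- matrix(FALSE, n, n); seed[sample(n, 1), sample(n, 1)] <- TRUE
    cf <- cost_distance(grid(res, cellsize = 1000), seed)
    expect_equal(cf$cost$values, oracle_cost_distance(res, seed, 1),
                 tolerance = 1e-9)
  }
})

test_that("cost distance equals exhaustive simple-path enumeration on a 3x3 grid", {
  set.seed(271)
  for (i in 1:5) {
    res <- matrix(runif(9, 0.5, 5), 3, 3)
    seed <- matrix(FALSE, 3, 3); seed[1, 1] <- TRUE
    cf <- cost_distance(grid(res, cellsize = 1000), seed)
    expect_equal(cf$cost$values[3, 3],
                 oracle_enumerate_min_cost(res, c(1, 1), c(3, 3), 1),
                 tolerance = 1e-9)
  }
})

test_that("missing resistance cells are impassable barriers", {
  res <- matrix(1, 5, 5); res[, 3] <- NA
  seed <- matrix(FALSE, 5, 5); seed[3, 1] <- TRUE
  cf <- cost_distance(grid(res, cellsize = 1000), seed)
  expect_true(all(is.na(cf$cost$values[, 3])))
  expect_true(all(is.na(cf$cost$values[, 4:5])))     # unreachable side
  tgt <- matrix(FALSE, 5, 5); tgt[3, 5] <- TRUE
  expect_error(least_cost_path(cf, tgt), "unreachable")
})

test_that("path tracing reports the cost-field value and correct step lengths", {
  r <- grid(matrix(1, 5, 9), cellsize = 1000)
  seed <- matrix(FALSE, 5, 9); seed[3, 1] <- TRUE
  cf <- cost_distance(r, seed)
  tgt <- matrix(FALSE, 5, 9); tgt[3, 9] <- TRUE
  p <- least_cost_path(cf, tgt)
  expect_equal(p$cost, cf$cost$values[3, 9])
  expect_equal(p$cost, 8)                  # straight east, analytic minimum
  expect_equal(p$length_km, 8)
  expect_equal(nrow(p$cells), 9)
  # seed adjacent to target: a single step
  tgt2 <- matrix(FALSE, 5, 9); tgt2[3, 2] <- TRUE
  expect_equal(nrow(least_cost_path(cf, tgt2)$cells), 2)
})

test_that("corridors connect every patch pair, deduplicated and deterministic", {
  lab <- matrix(0, 15, 15)
  lab[2:3, 2:3] <- 1; lab[2:3, 13:14] <- 2; lab[13:14, 7:8] <- 3
  mask <- grid(matrix(as.numeric(lab > 0), 15, 15), cellsize = 30)
  src <- espkit:::source_set_from_mask(mask, 0, "ESP1")
  res <- grid(matrix(1, 15, 15), cellsize = 30)
  co <- extract_corridors(src, res)
  expect_equal(co$raw_count, 3)            # three unordered pairs
  expect_lte(co$count, 3)
  expect_gte(co$count, 1)
  # dedup: total length never exceeds the sum of individual lengths
  expect_lte(co$total_length_km,
             sum(vapply(co$corridors, `[[`, numeric(1), "length_km")) + 1e-9)
  # two-patch case: exactly one corridor
  lab2 <- matrix(0, 8, 8); lab2[2, 2] <- 1; lab2[7, 7] <- 2
  src2 <- espkit:::source_set_from_mask(
    grid(matrix(as.numeric(lab2 > 0), 8, 8), cellsize = 30), 0, "ESP1")
  co2 <- extract_corridors(src2, grid(matrix(1, 8, 8), cellsize = 30))
  expect_equal(co2$count, 1)
  # determinism under equal-cost alternatives: identical reruns
  co2b <- extract_corridors(src2, grid(matrix(1, 8, 8), cellsize = 30))
  expect_identical(co2$corridors[[1]]$cells, co2b$corridors[[1]]$cells)
  expect_error(extract_corridors(src2, res), "co-registered")
  one <- espkit:::source_set_from_mask(
    grid(matrix(c(1, rep(0, 63)), 8, 8), cellsize = 30), 0, "ESP1")
  expect_error(extract_corridors(one, grid(matrix(1, 8, 8), cellsize = 30)),
               "at least 2")
})

test_that("a symmetric fixture with two equal-cost routes yields one deterministic path", {
  # two patches on a line, an impassable block in between, equal detours
  res <- matrix(1, 9, 9); res[4:6, 5] <- NA
  lab <- matrix(0, 9, 9); lab[5, 1:2] <- 1; lab[5, 8:9] <- 2
  src <- espkit:::source_set_from_mask(
    grid(matrix(as.numeric(lab > 0), 9, 9), cellsize = 30), 0, "ESP1")
  co <- extract_corridors(src, grid(res, cellsize = 30))
  expect_equal(co$count, 1)
  co2 <- extract_corridors(src, grid(res, cellsize = 30))
  expect_identical(co$corridors[[1]]$cells, co2$corridors[[1]]$cells)
})

test_that("the cost triangle property holds across sampled patch triples", {
  b <- small_landscape(seed = 5, n = 64)
  res <- grid(matrix(runif(64 * 64, 1, 100), 64, 64), cellsize = 30)
  set.seed(41)
  pts <- cbind(sample(64, 3), sample(64, 3))
  cfs <- lapply(1:3, function(i) {
    s <- matrix(FALSE, 64, 64); s[pts[i, 1], pts[i, 2]] <- TRUE
    cost_distance(res, s)
  })
  cAB <- cfs[[1]]$cost$values[pts[2, 1], pts[2, 2]]
  cBC <- cfs[[2]]$cost$values[pts[3, 1], pts[3, 2]]
  cAC <- cfs[[1]]$cost$values[pts[3, 1], pts[3, 2]]
  expect_lte(cAC, cAB + cBC + 1e-9)
})
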