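test_that("proximity distances are exact Euclidean in metres", {
  tpl <- grid(matrix(0, 10, 10), cellsize = 30)
  road <- grid_like(tpl, 0); road$values[, 4] <- 1   # north-south road
  d <- proximity_grid(road, tpl)
  expect_equal(d$values[5, 4], 0)                    # on the road
  expect_equal(d$values[5, 7], 90)                   # three cells due east
  set.seed(99)
  for (i in 1:3) {
    m <- matrix(runif(32 * 32) < 0.05, 32, 32)
    if (!any(m)) m[17, 12] <- TRUE
    feat <- grid(matrix(as.numeric(m), 32, 32), cellsize = 30)
    tpl32 <- grid(matrix(0, 32, 32), cellsize = 30)
    expect_equal(proximity_grid(feat, tpl32)$values,
                 oracle_proximity(m, 30), tolerance = 1e-9)
  }
  expect_error(proximity_grid(grid_like(tpl, 0), tpl), "empty")
})

test_that("the weighted resistance surface reproduces hand arithmetic", {
  tpl <- grid(matrix(0, 2, 2), cellsize = 30)
  cfg <- resistance_config()
  mk <- function(x) grid_like(tpl, x)
  # most permeable printed combination: classes 10/10/10/10 and 20/20/20
  f_lo <- list(mspa = mk(10), landuse = mk(10), elevation = mk(10),
               slope = mk(10), road = mk(20), water = mk(20),
               nightlight = mk(20))
  expect_equal(build_resistance(f_lo, cfg)$values[1, 1], 11.9)
  # a hostile combination: 90/90/90 and 80/80/80/80
  f_hi <- list(mspa = mk(90), landuse = mk(90), elevation = mk(90),
               slope = mk(80), road = mk(80), water = mk(80),
               nightlight = mk(80))
  expect_equal(build_resistance(f_hi, cfg)$values[1, 1], 86.7)
  # a uniform class value passes through (convex combination)
  f_50 <- lapply(f_lo, function(g) mk(50))
  expect_equal(build_resistance(f_50, cfg)$values[1, 1], 50)
  f_missing <- f_lo; f_missing$slope <- NULL
  expect_error(build_resistance(f_missing, cfg), "slope")
})

test_that("resistance is convex, order-invariant and monotone in each factor", {
  set.seed(111)
  tpl <- grid(matrix(0, 8, 8), cellsize = 30)
  cfg <- resistance_config()
  classes <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  fac <- lapply(setNames(names(cfg$weights), names(cfg$weights)),
                function(nm) grid_like(tpl, matrix(sample(classes, 64,
                                                          TRUE), 8, 8)))
  r <- build_resistance(fac, cfg)
  lo <- Reduce(pmin, lapply(fac, function(g) g$values))
  hi <- Reduce(pmax, lapply(fac, function(g) g$values))
  expect_true(all(r$values >= lo - 1e-9 & r$values <= hi + 1e-9))
  # permuting the factor list leaves the surface unchanged
  r2 <- build_resistance(rev(fac), cfg)
  expect_equal(r2$values, r$values)
  # raising one factor's class raises the surface
  fac2 <- fac
  fac2$landuse$values[3, 3] <- fac2$landuse$values[3, 3] + 10
  expect_gt(build_resistance(fac2, cfg)$values[3, 3], r$values[3, 3])
})

test_that("the printed class tables are encoded faithfully", {
  cfg <- resistance_config()
  expect_equal(sum(cfg$weights), 1)
  g <- function(x) grid(matrix(x, 1), cellsize = 30)
  expect_equal(as.vector(reclassify(g(c(373, 374, 666, 667, 959, 960,
                                        1275, 1276)),
                                    cfg$elevation_bins)$values),
               c(10, 30, 30, 50, 50, 70, 70, 90))
  expect_equal(as.vector(reclassify(g(c(8, 8.1, 15, 25, 40, 41)),
                                    cfg$slope_bins)$values),
               c(10, 20, 20, 40, 60, 80))
  expect_equal(as.vector(reclassify(g(c(100, 450, 1200, 1600)),
                                    cfg$road_bins)$values),
               c(80, 80, 40, 20))
  expect_equal(as.vector(reclassify(g(c(50, 150, 500, 900)),
                                    cfg$water_bins)$values),
               c(20, 40, 60, 80))
  expect_equal(as.vector(reclassify(g(c(5, 20, 50, 60)),
                                    cfg$nightlight_bins)$values),
               c(20, 40, 60, 80))
  # MSPA lookup: core/bridge most permeable, background hostile
  cls <- mspa_classes()
  expect_equal(unname(cfg$mspa_lookup[as.character(cls[["core"]])]), 10)
  expect_equal(unname(cfg$mspa_lookup[as.character(cls[["bridge"]])]), 10)
  expect_equal(unname(cfg$mspa_lookup[as.character(cls[["background"]])]), 90)
})

test_that("factor derivation from a bundle yields complete classified grids", {
  b <- small_landscape(seed = 23, n = 64)
  mc <- classify_mspa(grid_like(b$landuse,
    matrix(as.numeric(b$landuse$values %in% ecological_classes()), 64, 64)))
  fac <- resistance_factors(b, mc)
  expect_setequal(names(fac), names(resistance_config()$weights))
  r <- build_resistance(fac)
  expect_true(all(r$values >= 10 & r$values <= 100))
})

test_that("Horn slope is zero on a flat plane and matches an inclined plane", {
  flat <- grid(matrix(5, 6, 6), cellsize = 30)
  expect_true(all(slope_horn(flat)$values == 0))
  # plane dropping 1 m per cell eastward: slope = atan(1/30)
  v <- matrix(rep(seq(0, -5), each = 6), 6, 6)
  s <- slope_horn(grid(v, cellsize = 30))
  expect_equal(s$values[3, 3], atan(1 / 30) * 180 / pi, tolerance = 1e-9)
})
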