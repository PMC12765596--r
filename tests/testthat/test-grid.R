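test_that("ASCII grid round trips are bit-exact, including nodata", {
  set.seed(101)
  for (i in 1:5) {
    nr <- sample(3:20, 1); nc <- sample(3:20, 1)
    v <- matrix(rnorm(nr * nc) * 1000, nr, nc)
    v[runif(nr * nc) < 0.1] <- NA
    g <- grid(v, cellsize = runif(1, 5, 100), origin_x = rnorm(1) * 1e5)
    p <- withr::local_tempfile(fileext = ".asc")
    write_grid(g, p)
    g2 <- read_grid(p)
    expect_identical(dim(g2$values), dim(g$values))
    expect_equal(g2$values, g$values, tolerance = 0)
    expect_equal(g2$cellsize, g$cellsize, tolerance = 0)
    expect_equal(g2$origin_x, g$origin_x, tolerance = 1e-9)
  }
})

test_that("a constant 3x3 grid survives write-then-read and the nodata sentinel is honoured", {
  g <- grid(matrix(1, 3, 3), cellsize = 30)
  p <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, p)
  expect_equal(read_grid(p)$values, g$values)
  # a -9999 cell in the file comes back as missing
  lines <- readLines(p)
  lines[7] <- "1 -9999 1"
  writeLines(lines, p)
  g3 <- read_grid(p)
  expect_true(is.na(g3$values[1, 2]))
  expect_equal(sum(is.na(g3$values)), 1)
})

test_that("malformed headers and ragged rows raise errors naming the field", {
  g <- grid(matrix(1:12, 3, 4), cellsize = 10)
  p <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, p)
  lines <- readLines(p)
  bad <- lines
  bad[1] <- "ncols 7"  # header claims more columns than the rows hold
  writeLines(bad, p)
  expect_error(read_grid(p), "ncols")
  bad <- lines[-2]
  writeLines(bad, p)
  expect_error(read_grid(p), "malformed")
  expect_error(write_grid(g, p, format = "geotiff"), "unsupported")
})

test_that("reclassify follows the lower-exclusive/upper-inclusive rule of the printed tables", {
  cfg <- resistance_config()
  g <- grid(matrix(c(100, 373, 373.0001, 666, 959.5, 1275, 1276, 2200),
                   2, 4), cellsize = 30)
  out <- reclassify(g, cfg$elevation_bins)
  expect_equal(as.vector(out$values), c(10, 10, 30, 30, 70, 70, 90, 90))
  # a single total bin maps everything
  tot <- reclassify(g, bin_table(-Inf, Inf, 7))
  expect_true(all(tot$values == 7))
  # the identity bin table composed with itself is the identity
  ident <- bin_table(c(-Inf, 500), c(500, Inf), c(10, 20))
  once <- reclassify(g, ident)
  expect_equal(reclassify(once, bin_table(c(9, 19), c(11, 21), c(10, 20)))$values,
               once$values)
  # a value covered by no bin is a coverage error naming the value
  expect_error(reclassify(g, bin_table(0, 500, 1)), "covered by no bin")
})

test_that("nodata propagates through reclassify and normalize", {
  v <- matrix(c(1, NA, 3, 4), 2, 2)
  g <- grid(v, cellsize = 30)
  rc <- reclassify(g, bin_table(-Inf, Inf, 5))
  expect_true(is.na(rc$values[2, 1]))
  nm <- minmax_normalize(g, 0, 1)
  expect_true(is.na(nm$values[2, 1]))
})

test_that("min-max normalization maps endpoints affinely", {
  g <- grid(matrix(c(0, 5, 10), 1, 3), cellsize = 1)
  expect_equal(as.vector(minmax_normalize(g, 0, 100)$values), c(0, 50, 100))
  g2 <- grid(matrix(c(2, 4), 1, 2), cellsize = 1)
  expect_equal(as.vector(minmax_normalize(g2, 0, 1)$values), c(0, 1))
  g3 <- grid(matrix(1:3, 1, 3), cellsize = 1)
  expect_equal(as.vector(minmax_normalize(g3, 0, 1)$values), c(0, 0.5, 1))
  expect_error(minmax_normalize(grid(matrix(7, 2, 2), cellsize = 1)),
               "constant")
})

test_that("patch labelling respects connectivity and matches a flood-fill oracle", {
  diagd <- grid(matrix(c(1, 0, 0, 1), 2, 2), cellsize = 30)
  expect_equal(length(label_patches(diagd, 4)$patch_ids), 2)
  expect_equal(length(label_patches(diagd, 8)$patch_ids), 1)
  set.seed(202)
  for (i in 1:8) {
    g <- random_binary_grid(20, 20, p = runif(1, 0.2, 0.7))
    for (conn in c(4, 8)) {
      ps <- label_patches(g, conn)
      expect_equal(length(ps$patch_ids),
                   max(oracle_label(g$values == 1, conn)))
      # label count is invariant under transposition
      gt <- grid(t(g$values), cellsize = 30)
      expect_equal(length(label_patches(gt, conn)$patch_ids),
                   length(ps$patch_ids))
    }
  }
})

test_that("patch areas follow cellcount times cell area", {
  g <- grid(matrix(rep(c(1, 0), each = 50), 10, 10), cellsize = 30)
  ps <- label_patches(g, 8)
  expect_equal(sum(ps$cellcount), 50)
  expect_equal(sum(ps$area_km2), 50 * 0.0009)
  expect_error(label_patches(grid(matrix(2, 2, 2), cellsize = 30)), "binary")
})

test_that("grid registration mismatches are rejected, not resampled", {
  a <- grid(matrix(0, 4, 4), cellsize = 30)
  b <- grid(matrix(0, 4, 4), cellsize = 60)
  expect_error(espkit:::assert_same_geometry(a, b), "cellsize")
  d <- grid(matrix(0, 5, 4), cellsize = 30)
  expect_error(espkit:::assert_same_geometry(a, d), "dimensions")
})

test_that("GeoJSON feature sets round trip", {
  ln <- features(list(cbind(x = c(0, 90, 90), y = c(0, 0, 60))), "line",
                 data.frame(id = 1))
  pg <- features(list(cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))),
                 "polygon", data.frame(category = "reserve"))
  pt <- features(list(matrix(c(15, 45), 1, 2)), "point",
                 data.frame(type = "strategic"))
  for (f in list(ln, pg, pt)) {
    p <- withr::local_tempfile(fileext = ".geojson")
    write_features(f, p)
    f2 <- read_features(p)
    expect_equal(f2$type, f$type)
    expect_equal(length(f2$geoms), length(f$geoms))
    expect_equal(f2$geoms[[1]][, "x"][1], f$geoms[[1]][, "x"][1])
  }
})
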