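test_that("flow on an east-tilted plane drains east with chain accumulation", {
  v <- matrix(rep(seq(10, 5), each = 4), 4, 6)  # drops eastward
  fd <- flow_direction(grid(v, cellsize = 30))
  expect_true(all(fd$values[, -6] == 1))        # scan-order code 1 = east
  fa <- flow_accumulation(fd)
  # single east-draining row of 5: accumulations 1..5
  row5 <- matrix(seq(5, 1), 1, 5)
  fa5 <- flow_accumulation(flow_direction(grid(row5, cellsize = 30)))
  expect_equal(as.vector(fa5$values), 1:5)
})

test_that("pits terminate flow and a constant surface is all pits", {
  bowl <- matrix(5, 5, 5); bowl[3, 3] <- 1
  fd <- flow_direction(grid(bowl, cellsize = 30))
  expect_equal(fd$values[3, 3], 0)
  flat <- flow_direction(grid(matrix(2, 4, 4), cellsize = 30))
  expect_true(all(flat$values == 0))
  fa <- flow_accumulation(flat)
  expect_true(all(fa$values == 1))
})

test_that("directions and accumulations match brute-force oracles on random surfaces", {
  set.seed(515)
  for (i in 1:50) {
    z <- matrix(runif(25, 0, 100), 5, 5)
    fd <- flow_direction(grid(z, cellsize = 30))
    expect_identical(matrix(as.integer(fd$values), 5, 5),
                     oracle_flow_dir_strict(z))
    fa <- flow_accumulation(fd)
    expect_equal(fa$values, oracle_flow_acc(fd$values))
  }
})

test_that("accumulation is conservative: pit totals equal the cell count", {
  set.seed(616)
  z <- matrix(runif(400), 20, 20)
  fd <- flow_direction(grid(z, cellsize = 30))
  fa <- flow_accumulation(fd)
  expect_true(all(fa$values >= 1))
  pits <- fd$values == 0
  expect_equal(sum(fa$values[pits]), 400)
})

test_that("channel masks are nested in the percentile and inversion is an involution", {
  b <- small_landscape(seed = 3, n = 64)
  s <- b$dem
  m97 <- extract_channels(s, FALSE, 97)
  m90 <- extract_channels(s, FALSE, 90)
  expect_true(all(m97$values <= m90$values))   # higher threshold, fewer cells
  # the valley mask of S is the ridge mask of (max - S)
  inv <- grid_like(s, max(s$values) - s$values)
  expect_equal(extract_channels(s, FALSE, 95)$values,
               extract_channels(inv, TRUE, 95)$values)
  expect_error(extract_channels(s, FALSE, 40), "percentile")
  # degenerate constant surface: no channels
  const <- grid(matrix(3, 10, 10), cellsize = 30)
  expect_true(all(extract_channels(const, FALSE, 95)$values == 0))
})

test_that("a tent surface concentrates its ridge mask on the crest", {
  nr <- 21; nc <- 21
  v <- outer(seq_len(nr), seq_len(nc),
             function(r, c) 100 - 5 * abs(c - 11)) + 0.01 *
    outer(seq_len(nr), seq_len(nc), function(r, c) r)
  ridge <- extract_channels(grid(v, cellsize = 30), invert = TRUE,
                            accumulation_percentile = 97)
  crest_hits <- sum(ridge$values[, 11])
  expect_gt(crest_hits, 0)
  expect_gt(crest_hits / sum(ridge$values), 0.9)
})

test_that("node location finds crossings, ignores disjoint masks, collapses runs", {
  tpl <- grid(matrix(0, 15, 15), cellsize = 30)
  ridge <- grid_like(tpl, 0); ridge$values[8, ] <- 1     # east-west ridge
  corr <- grid_like(tpl, 0); corr$values[, 8] <- 1       # north-south corridor
  valley <- grid_like(tpl, 0); valley$values[2, ] <- 1
  roads <- grid_like(tpl, 0)                             # no roads
  nodes <- locate_nodes(corr, ridge, roads, valley, 2)
  expect_equal(sum(nodes$type == "strategic"), 1)
  expect_equal(sum(nodes$type == "artificial"), 0)
  expect_equal(nodes$row[1], 8); expect_equal(nodes$col[1], 8)
  # a corridor running along the ridge for 10 cells is one node
  corr2 <- grid_like(tpl, 0); corr2$values[8, 3:12] <- 1
  n2 <- locate_nodes(corr2, ridge, roads, valley, 2)
  expect_equal(sum(n2$type == "strategic"), 1)
  # roads crossing the valley line give an artificial node
  roads2 <- grid_like(tpl, 0); roads2$values[, 5] <- 1
  n3 <- locate_nodes(corr, ridge, roads2, valley, 2)
  expect_equal(sum(n3$type == "artificial"), 1)
})

test_that("node counts are invariant to corridor orientation reversal", {
  tpl <- grid(matrix(0, 12, 12), cellsize = 30)
  ridge <- grid_like(tpl, 0); ridge$values[6, ] <- 1
  corr <- grid_like(tpl, 0); corr$values[, 4] <- 1; corr$values[, 9] <- 1
  roads <- grid_like(tpl, 0); valley <- grid_like(tpl, 0)
  n1 <- locate_nodes(corr, ridge, roads, valley, 1)
  corr_rev <- grid_like(tpl, corr$values[nrow(corr$values):1, ])
  ridge_rev <- grid_like(tpl, ridge$values[nrow(ridge$values):1, ])
  n2 <- locate_nodes(corr_rev, ridge_rev, roads, valley, 1)
  expect_equal(nrow(n1), nrow(n2))
})
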