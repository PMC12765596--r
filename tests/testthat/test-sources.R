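cls <- mspa_classes()

# build an MSPA-class grid directly from a core mask
class_grid_from_core <- function(core, cellsize = 30) {
  v <- matrix(cls[["background"]], nrow(core), ncol(core))
  v[core] <- cls[["core"]]
  grid(v, cellsize = cellsize)
}

test_that("connectivity sources respect the area threshold", {
  core <- matrix(FALSE, 20, 20); core[3:12, 3:12] <- TRUE  # 100 cells
  cg <- class_grid_from_core(core)                          # 0.09 km^2
  expect_equal(length(sources_connectivity(cg, 0.05)$patch_ids), 1)
  expect_equal(sources_connectivity(cg, 0.05)$total_area_km2, 0.09)
  expect_equal(length(sources_connectivity(cg, 0.1)$patch_ids), 0)
  empty <- class_grid_from_core(matrix(FALSE, 5, 5))
  expect_equal(length(sources_connectivity(empty, 0)$patch_ids), 0)
})

test_that("reserve rasterization follows the cell-centre rule and merges overlaps", {
  tpl <- grid(matrix(0, 10, 10), cellsize = 30)
  # square covering exactly the centres of cells (2:3, 2:3)
  sq <- features(list(cbind(x = c(40, 100, 100, 40), y = c(200, 200, 260, 260))),
                 "polygon")
  s <- sources_reserves(sq, tpl)
  expect_equal(sum(s$cellcount), 4)
  # two disjoint polygons -> two patches
  two <- features(list(
    cbind(x = c(10, 80, 80, 10), y = c(10, 10, 80, 80)),
    cbind(x = c(160, 230, 230, 160), y = c(160, 160, 230, 230))), "polygon")
  expect_equal(length(sources_reserves(two, tpl)$patch_ids), 2)
  # overlapping polygons merge and cover less than the sum of parts
  ov <- features(list(
    cbind(x = c(10, 150, 150, 10), y = c(10, 10, 150, 150)),
    cbind(x = c(80, 220, 220, 80), y = c(80, 80, 220, 220))), "polygon")
  so <- sources_reserves(ov, tpl)
  expect_equal(length(so$patch_ids), 1)
  a1 <- sources_reserves(features(ov$geoms[1], "polygon"), tpl)$total_area_km2
  a2 <- sources_reserves(features(ov$geoms[2], "polygon"), tpl)$total_area_km2
  expect_lt(so$total_area_km2, a1 + a2)
  expect_warning(sources_reserves(features(list(), "polygon"), tpl), "empty")
})

test_that("integration is union-then-filter and counts match a constructed fixture", {
  tpl <- grid(matrix(0, 24, 24), cellsize = 30)
  core <- matrix(FALSE, 24, 24); core[2:11, 2:11] <- TRUE        # 100 cells
  e1 <- sources_connectivity(class_grid_from_core(core), 0)
  rmask <- grid_like(tpl, 0)
  rmask$values[2:11, 12:21] <- 1                   # adjacent 100-cell block
  e2 <- espkit:::source_set_from_mask(rmask, 0, "ESP2")
  u <- (e1$label_grid$values > 0) | (rmask$values > 0)
  expect_equal(sum(u), 200)                        # candidate cells
  fv <- matrix(0, 24, 24); fv[2:11, 6:17] <- 1     # 120 of them pass F > 0.4
  niche <- list(niche = grid_like(tpl, fv),
                mask = grid_like(tpl, fv),
                config = niche_config())
  class(niche) <- "esp_niche_result"
  e3 <- sources_integrated(e1, e2, niche, min_area_km2 = 0)
  expect_equal(sum(e3$cellcount), 120)
  expect_equal(length(e3$patch_ids), 1)
  # F = 1 everywhere keeps the whole union; F = 0 empties it
  niche1 <- niche; niche1$mask <- grid_like(tpl, 1)
  expect_equal(sum(sources_integrated(e1, e2, niche1, 0)$cellcount), sum(u))
  niche0 <- niche; niche0$mask <- grid_like(tpl, 0)
  expect_equal(length(sources_integrated(e1, e2, niche0, 0)$patch_ids), 0)
  # intersection mode never exceeds union mode
  e3i <- sources_integrated(e1, e2, niche1, 0, combine = "intersection")
  expect_lte(sum(e3i$cellcount), sum(u))
})

test_that("integrated sources are always a subset of the union, monotone in the threshold", {
  b <- small_landscape(seed = 15, n = 96)
  lu <- b$landuse$values
  fg <- grid_like(b$landuse,
                  matrix(as.numeric(lu %in% ecological_classes()),
                         nrow(lu), ncol(lu)))
  mc <- classify_mspa(fg)
  e1 <- sources_connectivity(mc, 0.2)
  e2 <- sources_reserves(b$reserves, b$dem)
  ind <- compute_indicators(b)
  areas <- c()
  for (thr in c(0.3, 0.45, 0.6)) {
    ni <- comprehensive_niche(ind, niche_config(threshold = thr))
    e3 <- sources_integrated(e1, e2, ni, 0)
    m3 <- e3$label_grid$values > 0
    mu <- (e1$label_grid$values > 0) | (e2$label_grid$values > 0)
    expect_true(all(!m3 | mu))
    areas <- c(areas, e3$total_area_km2)
  }
  expect_true(all(diff(areas) <= 0))
})

test_that("land-use composition fractions sum to one and match constructions", {
  tpl <- grid(matrix(0, 10, 10), cellsize = 30)
  lab <- grid_like(tpl, 0); lab$values[1:10, 1:4] <- 1
  src <- list(strategy = "ESP1", label_grid = lab, patch_ids = 1,
              cellcount = 40, area_km2 = 40 * 9e-4,
              total_area_km2 = 40 * 9e-4)
  class(src) <- "esp_sources"
  lu <- grid_like(tpl, landuse_classes()[["closed_forest"]])
  comp <- source_composition(src, lu)
  expect_equal(comp$overall$fraction[comp$overall$class == "closed_forest"], 1)
  # a 50/50 split fixture
  lu$values[1:5, ] <- landuse_classes()[["grassland"]]
  comp2 <- source_composition(src, lu)
  expect_equal(sum(comp2$overall$fraction), 1)
  expect_equal(comp2$overall$fraction[comp2$overall$class == "grassland"], 0.5)
  expect_equal(rowSums(comp2$per_patch), 1, ignore_attr = TRUE)
})
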