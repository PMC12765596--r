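#' Resistance-surface configuration
#'
#' Classification tables and AHP-derived weights for the seven factors of
#' the minimum-cumulative-resistance (MCR) surface: MSPA landscape element,
#' land use, elevation, slope, road proximity, water proximity and the
#' normalized nighttime-light index. Class values live on the 10-100 scale;
#' bins follow the lower-exclusive / upper-inclusive convention, so
#' elevation 373 m falls in the "<= 373" class and 373.1 m in the next one.
#'
#' Categorical lookups: MSPA core and bridge 10, edge and islet 20 (the
#' perforation boundary class is grouped with edge), branch and loop 30,
#' background 90; land use scores closed forestland 10, shrub, sparse
#' forestland and grassland 20, water 30, paddy field 40, dryland and
#' unused land 50, construction land 90.
#'
#' @param weights named factor weights, summing to 1.
#' @return an object of class `esp_resistance_config`.
#' @export
resistance_config <- function(weights = c(mspa = 0.23, landuse = 0.25,
                                          elevation = 0.19, slope = 0.14,
                                          road = 0.07, water = 0.04,
                                          nightlight = 0.08)) {
  if (abs(sum(weights) - 1) > 1e-9)
    stop("resistance factor weights must sum to 1")
  cls <- mspa_classes()
  lu <- landuse_classes()
  structure(list(
    weights = weights,
    mspa_lookup = setNames(
      c(90, 10, 20, 20, 20, 10, 30, 30),
      as.character(cls[c("background", "core", "islet", "edge", "perforation",
                         "bridge", "loop", "branch")])),
    landuse_lookup = setNames(
      c(40, 50, 10, 20, 20, 20, 30, 90, 50),
      as.character(lu[c("paddy", "dryland", "closed_forest", "shrub",
                        "sparse_forest", "grassland", "water",
                        "construction", "unused")])),
    elevation_bins = bin_table(c(-Inf, 373, 666, 959, 1275),
                               c(373, 666, 959, 1275, Inf),
                               c(10, 30, 50, 70, 90)),
    slope_bins = bin_table(c(-Inf, 8, 15, 25, 40),
                           c(8, 15, 25, 40, Inf),
                           c(10, 20, 40, 60, 80)),
    road_bins = bin_table(c(-Inf, 500, 1000, 1500),
                          c(500, 1000, 1500, Inf),
                          c(80, 60, 40, 20)),
    water_bins = bin_table(c(-Inf, 100, 400, 800),
                           c(100, 400, 800, Inf),
                           c(20, 40, 60, 80)),
    nightlight_bins = bin_table(c(-Inf, 10, 35, 55),
                                c(10, 35, 55, Inf),
                                c(20, 40, 60, 80))),
    class = "esp_resistance_config")
}

# categorical lookup reclassification (class code -> resistance value)
lookup_reclass <- function(g, lookup) {
  v <- g$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  key <- as.character(v[ok])
  hit <- lookup[key]
  if (anyNA(hit))
    stop("lookup_reclass: class code ", key[which(is.na(hit))[1]],
         " has no resistance value")
  out[ok] <- hit
  grid_like(g, out)
}

#' Euclidean proximity to features
#'
#' Distance (metres) from every cell centre to the nearest feature cell.
#' Line features are first burnt onto the grid (every cell a segment
#' passes through); a binary grid marks feature cells directly. The
#' distance transform is exact Euclidean (via `EBImage::distmap`).
#'
#' @param feats line `esp_features` or a binary `esp_grid` of feature
#'   cells.
#' @param template an `esp_grid` supplying geometry.
#' @return an `esp_grid` of distances (m).
#' @export
proximity_grid <- function(feats, template) {
  stopifnot(is_grid(template))
  mask <- if (is_features(feats)) {
    burn_lines(feats, template)
  } else if (is_grid(feats)) {
    assert_same_geometry(feats, template)
    !is.na(feats$values) & feats$values == 1
  } else stop("proximity_grid needs esp_features or a binary esp_grid")
  if (!any(mask))
    stop("proximity_grid: empty feature set, distance undefined")
  img <- EBImage::Image(1 - matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  d <- EBImage::imageData(EBImage::distmap(img, metric = "euclidean"))
  grid_like(template, d * template$cellsize)
}

# burn polylines into a logical cell mask by dense sampling along segments
burn_lines <- function(feats, template) {
  if (feats$type != "line") stop("burn_lines needs line features")
  nr <- nrow(template$values); nc <- ncol(template$values)
  mask <- matrix(FALSE, nr, nc)
  step <- template$cellsize / 2
  for (m in feats$geoms) {
    if (nrow(m) < 2) next
    for (i in seq_len(nrow(m) - 1)) {
      p0 <- m[i, ]; p1 <- m[i + 1, ]
      len <- sqrt(sum((p1 - p0)^2))
      t <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
      xs <- p0[1] + t * (p1[1] - p0[1]); ys <- p0[2] + t * (p1[2] - p0[2])
      idx <- xy_cell(template, xs, ys)
      ok <- idx$r >= 1 & idx$r <= nr & idx$c >= 1 & idx$c <= nc
      mask[cbind(idx$r[ok], idx$c[ok])] <- TRUE
    }
  }
  mask
}

#' Build the weighted MCR resistance surface
#'
#' `R(cell) = sum_i w_i * class_i(cell)` over the seven classified factor
#' grids; any cell missing in any factor is missing in the result. Values
#' stay within the convex hull of the class values (10-100).
#'
#' @param factors named list of seven class-value grids: `mspa`, `landuse`,
#'   `elevation`, `slope`, `road`, `water`, `nightlight`.
#' @param config an [resistance_config()] object.
#' @return an `esp_grid` resistance surface.
#' @export
build_resistance <- function(factors, config = resistance_config()) {
  need <- names(config$weights)
  for (nm in need)
    if (is.null(factors[[nm]]))
      stop("build_resistance: factor '", nm, "' is missing")
  do.call(assert_same_geometry, factors[need])
  acc <- 0
  for (nm in need) acc <- acc + config$weights[[nm]] * factors[[nm]]$values
  grid_like(factors[[need[1]]], acc)
}

#' Classified factor grids for the MCR surface
#'
#' Derives the seven classified factors from a landscape bundle and an MSPA
#' classification: slope by Horn's method from the DEM, road and water
#' proximity as exact Euclidean distances (water cells taken from the
#' land-use water class), nightlight min-max normalized to 0-100 before
#' binning.
#'
#' @param bundle landscape bundle.
#' @param mspa_class grid from [classify_mspa()].
#' @param config an [resistance_config()] object.
#' @return named list of seven class-value grids for [build_resistance()].
#' @export
resistance_factors <- function(bundle, mspa_class,
                               config = resistance_config()) {
  dem <- bundle$dem
  water_mask <- grid_like(bundle$landuse,
                          matrix(as.numeric(!is.na(bundle$landuse$values) &
                                              bundle$landuse$values ==
                                              landuse_classes()[["water"]]),
                                 nrow(dem$values), ncol(dem$values)))
  list(
    mspa = lookup_reclass(mspa_class, config$mspa_lookup),
    landuse = lookup_reclass(bundle$landuse, config$landuse_lookup),
    elevation = reclassify(dem, config$elevation_bins),
    slope = reclassify(slope_horn(dem), config$slope_bins),
    road = reclassify(proximity_grid(bundle$roads, dem), config$road_bins),
    water = reclassify(proximity_grid(water_mask, dem), config$water_bins),
    nightlight = reclassify(minmax_normalize(bundle$nightlight, 0, 100),
                            config$nightlight_bins))
}
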