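#' Land-use class codes
#'
#' The nine land-use classes carried by landscape bundles.
#' @return named integer vector.
#' @export
landuse_classes <- function() {
  c(paddy = 1L, dryland = 2L, closed_forest = 3L, shrub = 4L,
    sparse_forest = 5L, grassland = 6L, water = 7L, construction = 8L,
    unused = 9L)
}

#' Ecological-land foreground classes
#'
#' Default foreground for MSPA: woodland, grassland and water.
#' @return integer vector of class codes.
#' @export
ecological_classes <- function() {
  landuse_classes()[c("closed_forest", "shrub", "sparse_forest",
                      "grassland", "water")]
}

default_landuse_prob <- function() {
  # rows: elevation bands; cols: the nine classes. Low elevations are
  # dominated by cropland and construction, the 800-1200 m belt by closed
  # forest and grassland, high elevations by shrub/sparse forest/unused.
  m <- rbind(
    `0`    = c(0.15, 0.35, 0.05, 0.03, 0.05, 0.10, 0.02, 0.22, 0.03),
    `400`  = c(0.10, 0.40, 0.10, 0.04, 0.06, 0.10, 0.01, 0.16, 0.03),
    `800`  = c(0.01, 0.12, 0.40, 0.06, 0.08, 0.16, 0.01, 0.05, 0.11),
    `1200` = c(0.00, 0.05, 0.20, 0.14, 0.12, 0.09, 0.00, 0.01, 0.39),
    `1600` = c(0.00, 0.01, 0.10, 0.28, 0.22, 0.10, 0.00, 0.00, 0.29))
  colnames(m) <- names(landuse_classes())
  m
}

#' Synthetic-landscape configuration
#'
#' Parameters of the seeded mountain-landscape generator. The defaults
#' describe a vertically zoned mid-latitude massif on a 256 x 256 grid of
#' 30 m cells (about 59 km^2): relief spanning 0-2200 m; a temperature
#' lapse of 0.006 degC/m from an 18 degC valley base (so the 800-1000 m
#' belt averages near 12.6 degC); precipitation rising with elevation to a
#' mid-mountain maximum (about 720 mm at 900 m); NPP and NDVI unimodal in
#' elevation, peaking in the 800-1200 m forest belt; land use drawn per
#' 400-m elevation band from a probability table; nightlight decaying
#' exponentially with elevation; valley-following roads; and reserve
#' polygons centred at mid-to-high elevations.
#'
#' @param seed master seed; every layer derives its own stream from it by a
#'   fixed labelled offset, so adding a layer never perturbs existing ones.
#' @param nrows,ncols,cellsize grid shape and metric resolution.
#' @param relief_m total elevation span (m).
#' @param n_ridges number of ridge lines composing the massif.
#' @param noise_amp fractal-noise amplitude relative to the ridge field.
#' @param lapse_rate temperature lapse (degC per m).
#' @param t0 valley-floor mean annual temperature (degC).
#' @param temp_noise_sd,precip_noise_sd additive noise (degC, mm).
#' @param precip0,precip_slope,precip_curv precipitation-elevation profile
#'   `p0 + slope*h - curv*h^2` (mm).
#' @param npp_max,npp_peak_elev,npp_width NPP peak (g C/m^2), its elevation
#'   and Gaussian width (m).
#' @param landuse_prob elevation-band class-probability table (rows named
#'   by band lower edge, each row summing to 1).
#' @param n_roads valley road count.
#' @param n_reserves,reserve_radius_m reserve polygon count and mean radius.
#' @param nightlight0,nightlight_decay_m valley radiance and e-folding
#'   elevation of the nightlight field.
#' @param water_percentile flow-accumulation percentile carved into water.
#' @return an object of class `esp_landscape_config`.
#' @export
landscape_config <- function(seed = 42, nrows = 256, ncols = 256,
                             cellsize = 30, relief_m = 2200, n_ridges = 9,
                             noise_amp = 0.35, lapse_rate = 0.006, t0 = 18,
                             temp_noise_sd = 0.3, precip_noise_sd = 15,
                             precip0 = 600, precip_slope = 0.1936,
                             precip_curv = 6.455e-5,
                             npp_max = 680, npp_peak_elev = 1000,
                             npp_width = 700,
                             landuse_prob = default_landuse_prob(),
                             n_roads = 6, n_reserves = 7,
                             reserve_radius_m = 700,
                             nightlight0 = 0.95, nightlight_decay_m = 290,
                             water_percentile = 99) {
  if (any(abs(rowSums(landuse_prob) - 1) > 1e-9))
    stop("land-use probability rows must each sum to 1")
  if (ncol(landuse_prob) != length(landuse_classes()))
    stop("land-use probability table needs one column per class")
  for (v in c(nrows, ncols, cellsize, relief_m, npp_width))
    if (v <= 0) stop("landscape scales must be positive")
  structure(as.list(environment()), class = "esp_landscape_config")
}

# layer-specific deterministic seed; offsets are fixed labels so layers
# stay reproducible when new layers are added
layer_seed <- function(seed, offset) {
  as.integer((abs(seed) %% 20000000) * 100 + offset)
}

# spectral-synthesis fractal field, sd 1, deterministic under set.seed
gaussian_field <- function(nr, nc, beta = 1.8) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  fr <- c(seq(0, floor(nr / 2)), seq(-(ceiling(nr / 2) - 1), -1)) / nr
  fc <- c(seq(0, floor(nc / 2)), seq(-(ceiling(nc / 2) - 1), -1)) / nc
  f <- sqrt(outer(fr^2, fc^2, `+`))
  f[1, 1] <- f[1, 2]
  filt <- f^(-beta / 2)
  out <- Re(fft(fft(w) * filt, inverse = TRUE))
  (out - mean(out)) / stats::sd(out)
}

#' Generate a synthetic mountain landscape
#'
#' Builds the full co-registered bundle the ESP pipeline consumes: DEM from
#' smoothed ridge fields plus fractal noise (min-max anchored to the
#' configured relief), temperature by lapse, precipitation as a humped
#' function of elevation, unimodal NPP/NDVI, band-probability land use with
#' spatially clustered classes (the per-band class proportions match the
#' probability table), water carved along the highest-flow-accumulation
#' cells, nightlight decaying with elevation, least-elevation valley roads,
#' reserve polygons in the mid-to-high belt, and the soil/climate layers
#' feeding the sensitivity indicators. Bit-identical for a fixed config.
#'
#' @param config an [landscape_config()] object.
#' @return an `esp_landscape` bundle (list of grids plus `roads` and
#'   `reserves` feature sets).
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "esp_landscape_config"))
  nr <- config$nrows; nc <- config$ncols; cs <- config$cellsize
  tpl <- grid(matrix(0, nr, nc), cellsize = cs)

  # --- DEM: ridges + dome + fractal noise, anchored to [0, relief]
  set.seed(layer_seed(config$seed, 1))
  xs <- (col(matrix(0, nr, nc)) - 0.5) / nc
  ys <- (row(matrix(0, nr, nc)) - 0.5) / nr
  # several distinct massifs separated by low valleys, so the mid-elevation
  # forest belt breaks into multiple habitat patches
  base <- 0.12 * exp(-((xs - 0.5)^2 + (ys - 0.5)^2) / (2 * 0.35^2))
  amps <- 1 / seq_len(config$n_ridges)^0.4
  # centres on a jittered lattice: massifs stay separated by low saddles
  # instead of collapsing into one highland block
  side <- ceiling(sqrt(config$n_ridges))
  lat <- expand.grid(x = seq(0.18, 0.82, length.out = side),
                     y = seq(0.18, 0.82, length.out = side))
  lat <- lat[sample(nrow(lat), config$n_ridges), , drop = FALSE]
  massif_max <- matrix(0, nr, nc)
  for (k in seq_len(config$n_ridges)) {
    cxy <- c(lat$x[k], lat$y[k]) + runif(2, -0.05, 0.05)
    th <- runif(1, 0, pi)
    dperp <- abs((xs - cxy[1]) * sin(th) - (ys - cxy[2]) * cos(th))
    dalong <- (xs - cxy[1]) * cos(th) + (ys - cxy[2]) * sin(th)
    mk <- exp(-dperp^2 / (2 * 0.055^2)) * exp(-dalong^2 / (2 * 0.13^2))
    base <- base + amps[k] * mk
    massif_max <- pmax(massif_max, mk)
  }
  base <- base + config$noise_amp * gaussian_field(nr, nc, beta = 2.2)
  dem_vals <- (base - min(base)) / (max(base) - min(base)) * config$relief_m
  dem <- grid_like(tpl, dem_vals)

  # --- climate
  set.seed(layer_seed(config$seed, 3))
  temp <- grid_like(tpl, config$t0 - config$lapse_rate * dem_vals +
                      if (config$temp_noise_sd > 0)
                        config$temp_noise_sd * gaussian_field(nr, nc, 1.5)
                      else 0)
  set.seed(layer_seed(config$seed, 4))
  precip <- grid_like(tpl, config$precip0 +
                        config$precip_slope * dem_vals -
                        config$precip_curv * dem_vals^2 +
                        if (config$precip_noise_sd > 0)
                          config$precip_noise_sd * gaussian_field(nr, nc, 1.5)
                        else 0)

  # --- vegetation: unimodal in elevation
  set.seed(layer_seed(config$seed, 5))
  npp <- grid_like(tpl, pmax(config$npp_max *
    exp(-((dem_vals - config$npp_peak_elev) / config$npp_width)^2) *
    (1 + 0.05 * gaussian_field(nr, nc, 1.5)), 0))
  set.seed(layer_seed(config$seed, 6))
  ndvi <- grid_like(tpl, pmin(pmax(
    0.15 + 0.74 * exp(-((dem_vals - config$npp_peak_elev) / 900)^2) +
      0.03 * gaussian_field(nr, nc, 1.5), 0), 1))

  # --- land use: band probabilities realized through a clustered
  # suitability field. The field mixes autocorrelated noise with massif
  # proximity, and classes are ordered human-use first, ecological last, so
  # each massif carries its own woodland block while the band's class
  # proportions still match the probability table exactly.
  set.seed(layer_seed(config$seed, 2))
  clus <- gaussian_field(nr, nc, 2.2)
  suit <- 0.5 * (clus - min(clus)) / (max(clus) - min(clus)) +
    0.5 * massif_max
  class_order <- c("paddy", "dryland", "construction", "unused",
                   "grassland", "sparse_forest", "shrub", "closed_forest",
                   "water")
  ord_codes <- landuse_classes()[class_order]
  band_edges <- as.numeric(rownames(config$landuse_prob))
  band_idx <- findInterval(dem_vals, band_edges)
  lu <- matrix(NA_real_, nr, nc)
  for (b in seq_len(nrow(config$landuse_prob))) {
    cells <- which(band_idx == b)
    if (!length(cells)) next
    # rank-uniform transform keeps classes spatially coherent while
    # matching the band's class proportions
    u <- rank(suit[cells], ties.method = "first") / (length(cells) + 1)
    cuts <- cumsum(config$landuse_prob[b, class_order])
    lu[cells] <- ord_codes[findInterval(u, c(0, cuts),
                                        rightmost.closed = TRUE)]
  }
  lu <- pmin(lu, length(landuse_classes()))

  # --- water along top flow-accumulation channels of the DEM
  acc <- flow_accumulation(flow_direction(dem))
  thr <- quantile(acc$values, config$water_percentile / 100, names = FALSE)
  lu[acc$values >= thr & dem_vals < 0.6 * config$relief_m] <-
    landuse_classes()[["water"]]
  landuse <- grid_like(tpl, lu)

  # --- nightlight: human activity concentrated in valleys
  set.seed(layer_seed(config$seed, 7))
  nl <- config$nightlight0 * exp(-dem_vals / config$nightlight_decay_m) *
    pmax(1 + 0.3 * gaussian_field(nr, nc, 1.5), 0.2) + 0.005
  nightlight <- grid_like(tpl, nl)

  # --- soils and erosion drivers
  set.seed(layer_seed(config$seed, 8))
  f1 <- gaussian_field(nr, nc, 2.0)
  f2 <- gaussian_field(nr, nc, 2.0)
  soil_k <- grid_like(tpl, 0.1 + 0.4 * pnorm(f1))
  soil_texture <- grid_like(tpl, matrix(findInterval(pnorm(f2),
                                                     c(0, 1/3, 2/3)), nr, nc))
  pre_n <- (precip$values - min(precip$values)) /
    max(1e-9, diff(range(precip$values)))
  rainfall_erosivity <- grid_like(tpl, 0.18 * precip$values *
                                    (1 + 0.1 * f1))
  sandstorm_days <- grid_like(tpl, pmax(12 * (1 - pre_n) *
                                          (1 + 0.3 * pnorm(f2)), 0))
  dryness <- grid_like(tpl, 1.6 - pre_n + 0.1 * f1)

  # --- valley roads: least-elevation paths between low-elevation endpoints
  set.seed(layer_seed(config$seed, 9))
  low <- which(dem_vals <= quantile(dem_vals, 0.25, names = FALSE))
  road_geoms <- list()
  if (config$n_roads > 0 && length(low) >= 2) {
    walkres <- grid_like(tpl, dem_vals - min(dem_vals) + 10)
    for (i in seq_len(config$n_roads)) {
      ends <- sample(low, 2)
      seed_m <- matrix(FALSE, nr, nc); seed_m[ends[1]] <- TRUE
      tgt_m <- matrix(FALSE, nr, nc); tgt_m[ends[2]] <- TRUE
      cf <- cost_distance(walkres, seed_m)
      p <- tryCatch(least_cost_path(cf, tgt_m), error = function(e) NULL)
      if (is.null(p)) next
      xy <- cell_xy(tpl, p$cells[, 1], p$cells[, 2])
      road_geoms[[length(road_geoms) + 1]] <- cbind(x = xy$x, y = xy$y)
    }
  }
  roads <- features(road_geoms, "line",
                    data.frame(id = seq_along(road_geoms)))

  # --- reserves: irregular polygons centred in the mid-to-high belt
  set.seed(layer_seed(config$seed, 10))
  mid <- which(dem_vals >= 800 & dem_vals <= 1800)
  res_geoms <- list()
  if (config$n_reserves > 0 && length(mid)) {
    centers <- sample(mid, min(config$n_reserves, length(mid)))
    for (idx in centers) {
      r0 <- ((idx - 1) %% nr) + 1; c0 <- ((idx - 1) %/% nr) + 1
      ctr <- cell_xy(tpl, r0, c0)
      rad <- config$reserve_radius_m * runif(1, 0.6, 1.4)
      ang <- seq(0, 2 * pi, length.out = 13)[-13]
      rr <- rad * (1 + 0.25 * runif(12, -1, 1))
      px <- pmin(pmax(ctr$x + rr * cos(ang), 0.5 * cs), (nc - 0.5) * cs)
      py <- pmin(pmax(ctr$y + rr * sin(ang), 0.5 * cs), (nr - 0.5) * cs)
      res_geoms[[length(res_geoms) + 1]] <- cbind(x = px, y = py)
    }
  }
  categories <- rep(c("forest ecological system", "inland wetland",
                      "wildlife", "ancient biological trace"),
                    length.out = length(res_geoms))
  reserves <- features(res_geoms, "polygon",
                       data.frame(id = seq_along(res_geoms),
                                  category = categories))

  structure(list(dem = dem, landuse = landuse, ndvi = ndvi, npp = npp,
                 temperature = temp, precipitation = precip,
                 soil_k = soil_k, soil_texture = soil_texture,
                 nightlight = nightlight, roads = roads,
                 reserves = reserves,
                 rainfall_erosivity = rainfall_erosivity,
                 sandstorm_days = sandstorm_days, dryness = dryness,
                 config = config),
            class = "esp_landscape")
}

#' @export
print.esp_landscape <- function(x, ...) {
  cat(sprintf("<esp_landscape> %d x %d cells at %g m, relief %.0f-%.0f m\n",
              nrow(x$dem$values), ncol(x$dem$values), x$dem$cellsize,
              min(x$dem$values), max(x$dem$values)))
  cat(sprintf("  %d road(s), %d reserve(s)\n", length(x$roads$geoms),
              length(x$reserves$geoms)))
  invisible(x)
}

#' Per-band diagnostic report of a landscape bundle
#'
#' Summarizes climate, vegetation, nightlight and land-use composition per
#' altitudinal band — the standard diagnostic view of a vertically zoned
#' landscape. Means ignore missing cells; band cell counts sum to the
#' non-missing total.
#'
#' @param bundle an `esp_landscape`.
#' @param band_width band width (m).
#' @return data.frame, one row per band.
#' @export
landscape_report <- function(bundle, band_width = 200) {
  z <- bundle$dem$values
  if (band_width <= 0) stop("band_width must be positive")
  lo <- floor(min(z, na.rm = TRUE) / band_width)
  hi <- max(lo, ceiling(max(z, na.rm = TRUE) / band_width) - 1)
  bands <- seq(lo, hi)
  bidx <- pmin(pmax(floor(z / band_width), lo), hi) - lo + 1
  mean_by <- function(g) vapply(seq_along(bands), function(i)
    mean(g$values[bidx == i & !is.na(z)], na.rm = TRUE), numeric(1))
  out <- data.frame(
    band_lower = bands * band_width, band_upper = (bands + 1) * band_width,
    cells = vapply(seq_along(bands), function(i)
      sum(bidx == i & !is.na(z)), numeric(1)),
    mean_temperature = mean_by(bundle$temperature),
    mean_precipitation = mean_by(bundle$precipitation),
    mean_ndvi = mean_by(bundle$ndvi),
    mean_npp = mean_by(bundle$npp),
    mean_nightlight = mean_by(bundle$nightlight))
  lu <- bundle$landuse$values
  for (nm in names(landuse_classes())) {
    code <- landuse_classes()[[nm]]
    out[[paste0("frac_", nm)]] <- vapply(seq_along(bands), function(i) {
      n <- sum(bidx == i & !is.na(lu))
      if (n == 0) return(0)
      sum(lu[bidx == i] == code, na.rm = TRUE) / n
    }, numeric(1))
  }
  out
}
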