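#' Niche-suitability configuration
#'
#' Weights for the six indicators of the comprehensive ecological niche:
#' three ecosystem-service indicators (biodiversity maintenance 0.25, water
#' supply 0.45, soil and water conservation 0.30) and three
#' ecological-sensitivity indicators (soil and water loss 0.26, land
#' desertification 0.55, human activity intensity 0.19), combined across the
#' two dimensions with configurable dimension weights. The ideal niche
#' `D_opt` and minimum niche `D_min` of each indicator are set as percentiles
#' of its observed distribution, a scale-free choice robust to outliers.
#' Cells whose comprehensive niche exceeds `threshold` qualify as optimal
#' ecological sources.
#'
#' @param service_weights weights of the three service indicators (sum 1).
#' @param sensitivity_weights weights of the three sensitivity indicators
#'   (sum 1).
#' @param dimension_weights weights of (service, sensitivity) (sum 1).
#' @param d_opt_percentile,d_min_percentile percentile levels (0-100)
#'   defining the ideal and minimum niche of each indicator.
#' @param threshold comprehensive-niche cutoff for optimal sources.
#' @return an object of class `esp_niche_config`.
#' @export
niche_config <- function(service_weights = c(biodiversity = 0.25,
                                             water_supply = 0.45,
                                             conservation = 0.30),
                         sensitivity_weights = c(soil_water_loss = 0.26,
                                                 desertification = 0.55,
                                                 human_activity = 0.19),
                         dimension_weights = c(service = 0.5,
                                               sensitivity = 0.5),
                         d_opt_percentile = 90, d_min_percentile = 10,
                         threshold = 0.4) {
  chk <- function(w, lab) {
    if (abs(sum(w) - 1) > 1e-9)
      stop(lab, " weights must sum to 1 (got ", sum(w), ")")
  }
  chk(service_weights, "service"); chk(sensitivity_weights, "sensitivity")
  chk(dimension_weights, "dimension")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (d_min_percentile >= d_opt_percentile)
    stop("d_min_percentile must be below d_opt_percentile")
  structure(list(service_weights = service_weights,
                 sensitivity_weights = sensitivity_weights,
                 dimension_weights = dimension_weights,
                 d_opt_percentile = d_opt_percentile,
                 d_min_percentile = d_min_percentile,
                 threshold = threshold),
            class = "esp_niche_config")
}

# normalize a layer to [0,1]; constant layers collapse to 0 so that a flat
# factor never drives a product
norm01 <- function(g) {
  rng <- range(g$values, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0)
    return(grid_like(g, ifelse(is.na(g$values), NA_real_, 0)))
  minmax_normalize(g, 0, 1)
}

#' Compute the six niche indicators from a landscape bundle
#'
#' Ecosystem services: biodiversity maintenance
#' `NPP * F_pre * F_tmp * (1 - F_ele)`, water supply
#' `NPP * F_sic * F_pre * (1 - F_slo)`, soil and water conservation
#' `NPP * (1 - K) * (1 - F_slo)`. Ecological sensitivities: soil and water
#' loss `(R * K * LS * C)^(1/4)`, land desertification
#' `(I * W * D * C)^(1/4)`, and human activity intensity, the
#' construction-land share (%) in a moving circular window. Every factor is
#' min-max normalized to [0, 1] before entering its product, since the raw
#' layers mix units; slope comes from the DEM by Horn's method, the soil
#' infiltration factor from the soil-texture class, the vegetation-cover
#' erosion factor from NDVI (denser cover, lower erodibility).
#'
#' @param bundle a landscape bundle from [generate_landscape()].
#' @param human_window_m radius (metres) of the circular window for the
#'   construction-land share.
#' @return a named list of six indicator grids (class `esp_indicators`).
#' @export
compute_indicators <- function(bundle, human_window_m = 500) {
  need <- c("dem", "landuse", "ndvi", "npp", "temperature", "precipitation",
            "soil_k", "soil_texture", "rainfall_erosivity", "sandstorm_days",
            "dryness")
  for (nm in need)
    if (is.null(bundle[[nm]]))
      stop("compute_indicators: required layer '", nm, "' is missing")
  do.call(assert_same_geometry, bundle[need])

  dem <- bundle$dem
  slope <- slope_horn(dem)
  n_npp <- norm01(bundle$npp)
  n_pre <- norm01(bundle$precipitation)
  n_tmp <- norm01(bundle$temperature)
  n_ele <- norm01(dem)
  n_slo <- norm01(slope)
  n_k <- norm01(bundle$soil_k)
  # soil infiltration from texture class: coarser texture infiltrates better
  sic <- grid_like(dem, infiltration_lookup(bundle$soil_texture$values))
  n_sic <- norm01(sic)
  n_r <- norm01(bundle$rainfall_erosivity)
  # slope-length proxy rises with slope steepness
  n_ls <- n_slo
  # vegetation-cover erosion factor: low under dense cover
  cfac <- grid_like(dem, 1 - norm01(bundle$ndvi)$values)
  n_i <- norm01(bundle$dryness)
  n_w <- norm01(bundle$sandstorm_days)
  n_d <- norm01(bundle$soil_texture)

  vals <- function(g) g$values
  biodiversity <- grid_like(dem, vals(n_npp) * vals(n_pre) * vals(n_tmp) *
                              (1 - vals(n_ele)))
  water_supply <- grid_like(dem, vals(n_npp) * vals(n_sic) * vals(n_pre) *
                              (1 - vals(n_slo)))
  conservation <- grid_like(dem, vals(n_npp) * (1 - vals(n_k)) *
                              (1 - vals(n_slo)))
  soil_water_loss <- grid_like(dem, (vals(n_r) * vals(n_k) * vals(n_ls) *
                                       vals(cfac))^(1 / 4))
  desertification <- grid_like(dem, (vals(n_i) * vals(n_w) * vals(n_d) *
                                       vals(cfac))^(1 / 4))
  constr <- !is.na(bundle$landuse$values) &
    bundle$landuse$values == landuse_classes()[["construction"]]
  radius_cells <- max(1, round(human_window_m / dem$cellsize))
  human_activity <- grid_like(dem, 100 * focal_fraction(constr, radius_cells))
  human_activity$values[is.na(bundle$landuse$values)] <- NA_real_

  structure(list(biodiversity = biodiversity, water_supply = water_supply,
                 conservation = conservation,
                 soil_water_loss = soil_water_loss,
                 desertification = desertification,
                 human_activity = human_activity),
            class = "esp_indicators")
}

#' Piecewise niche membership
#'
#' Maps an actual-niche layer `X` to membership: 0 where `X < D_min`,
#' `X / D_opt` where `D_min <= X < D_opt`, and 1 where `X >= D_opt`. The
#' jump from 0 to `D_min / D_opt` at `X = D_min` is intentional and kept
#' exactly as defined.
#'
#' @param x an `esp_grid` of actual niche values.
#' @param d_opt ideal niche (scalar, > `d_min`).
#' @param d_min minimum niche (scalar, >= 0).
#' @return an `esp_grid` of memberships in [0, 1].
#' @export
niche_membership <- function(x, d_opt, d_min) {
  stopifnot(is_grid(x))
  if (d_min < 0 || d_min >= d_opt)
    stop("need 0 <= d_min < d_opt")
  v <- x$values
  out <- ifelse(v >= d_opt, 1, ifelse(v >= d_min, v / d_opt, 0))
  grid_like(x, out)
}

#' Comprehensive ecological niche
#'
#' Weighted overlay of the six indicator memberships. Sensitivity indicators
#' (including human-activity intensity) measure badness and are inverted
#' (`1 - normalized value`) before membership, so high suitability reads
#' uniformly high; the two dimension scores are combined with the
#' configured dimension weights. Cells with comprehensive niche above the
#' threshold form the optimal-source mask.
#'
#' @param indicators an `esp_indicators` list from [compute_indicators()].
#' @param config an [niche_config()] object.
#' @return an `esp_niche_result`: per-indicator membership grids, the
#'   comprehensive-niche grid `F` in [0, 1] and the optimal-source mask.
#' @export
comprehensive_niche <- function(indicators, config = niche_config()) {
  sv <- names(config$service_weights)
  ss <- names(config$sensitivity_weights)
  stack <- list(biodiversity = indicators$biodiversity,
                water_supply = indicators$water_supply,
                conservation = indicators$conservation,
                soil_water_loss = indicators$soil_water_loss,
                desertification = indicators$desertification,
                human_activity = indicators$human_activity)
  if (length(sv) != 3 || length(ss) != 3 || any(is.na(match(
    c("biodiversity", "water_supply", "conservation"), names(stack)))))
    stop("niche configuration does not match the six indicators")
  # polarity: sensitivities are inverted so that larger = more suitable
  actual <- list(
    biodiversity = norm01(stack$biodiversity),
    water_supply = norm01(stack$water_supply),
    conservation = norm01(stack$conservation),
    soil_water_loss = grid_like(stack$soil_water_loss,
                                1 - norm01(stack$soil_water_loss)$values),
    desertification = grid_like(stack$desertification,
                                1 - norm01(stack$desertification)$values),
    human_activity = grid_like(stack$human_activity,
                               1 - norm01(stack$human_activity)$values))
  memberships <- lapply(actual, function(g) {
    qs <- quantile(g$values,
                   probs = c(config$d_min_percentile,
                             config$d_opt_percentile) / 100,
                   na.rm = TRUE, names = FALSE)
    if (qs[2] <= qs[1]) qs[2] <- qs[1] + 1e-12
    if (qs[2] <= 0) return(grid_like(g, ifelse(is.na(g$values), NA_real_, 1)))
    niche_membership(g, qs[2], max(qs[1], 0))
  })
  weights <- c(config$dimension_weights[["service"]] * config$service_weights,
               config$dimension_weights[["sensitivity"]] *
                 config$sensitivity_weights)
  names(weights) <- names(actual)
  acc <- 0
  for (nm in names(actual)) acc <- acc + weights[[nm]] * memberships[[nm]]$values
  fgrid <- grid_like(indicators$biodiversity, acc)
  mask <- grid_like(fgrid, ifelse(is.na(acc), NA_real_,
                                  as.numeric(acc > config$threshold)))
  structure(list(memberships = memberships, niche = fgrid, mask = mask,
                 config = config),
            class = "esp_niche_result")
}

#' Aggregate weighted memberships directly
#'
#' Convenience overlay for externally supplied membership grids (values in
#' [0, 1]): `F = w_service * sum(W_k F_k) + w_sensitivity * sum(W_k F_k)`.
#'
#' @param service list of 3 membership grids (order matches
#'   `service_weights`).
#' @param sensitivity list of 3 membership grids.
#' @param config an [niche_config()] object.
#' @return comprehensive-niche `esp_grid`.
#' @export
weighted_niche <- function(service, sensitivity, config = niche_config()) {
  if (length(service) != length(config$service_weights) ||
      length(sensitivity) != length(config$sensitivity_weights))
    stop("membership lists do not match the configured weights")
  acc <- 0
  for (i in seq_along(service))
    acc <- acc + config$dimension_weights[["service"]] *
      config$service_weights[[i]] * service[[i]]$values
  for (i in seq_along(sensitivity))
    acc <- acc + config$dimension_weights[["sensitivity"]] *
      config$sensitivity_weights[[i]] * sensitivity[[i]]$values
  grid_like(service[[1]], acc)
}

# moving circular-window fraction of a logical mask, FFT convolution with
# edge correction (window area = in-grid cells only)
focal_fraction <- function(mask, radius_cells) {
  nr <- nrow(mask); nc <- ncol(mask)
  k <- 2 * radius_cells + 1
  off <- seq(-radius_cells, radius_cells)
  kern <- outer(off, off, function(a, b) as.numeric(a^2 + b^2 <=
                                                      radius_cells^2))
  pr <- stats::nextn(nr + k - 1, 2); pc <- stats::nextn(nc + k - 1, 2)
  pad <- function(m) {
    out <- matrix(0, pr, pc)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  conv <- function(a, b) {
    re <- Re(fft(fft(pad(a)) * fft(pad(b)), inverse = TRUE)) / (pr * pc)
    re[radius_cells + seq_len(nr), radius_cells + seq_len(nc)]
  }
  num <- conv(matrix(as.numeric(mask), nr, nc), kern)
  den <- conv(matrix(1, nr, nc), kern)
  pmin(pmax(num / den, 0), 1)
}

#' Slope from a DEM by Horn's method
#'
#' Third-order finite differences over the 3x3 neighbourhood (edges padded
#' by replication), returned in degrees.
#'
#' @param dem an `esp_grid` of elevations (m).
#' @return an `esp_grid` of slopes (degrees).
#' @export
slope_horn <- function(dem) {
  stopifnot(is_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  # replicate-pad so border cells get a defined slope
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sub <- function(dr, dc) zp[dr + seq_len(nr), dc + seq_len(nc)]
  dzdx <- ((sub(0, 2) + 2 * sub(1, 2) + sub(2, 2)) -
             (sub(0, 0) + 2 * sub(1, 0) + sub(2, 0))) / (8 * dem$cellsize)
  dzdy <- ((sub(2, 0) + 2 * sub(2, 1) + sub(2, 2)) -
             (sub(0, 0) + 2 * sub(0, 1) + sub(0, 2))) / (8 * dem$cellsize)
  grid_like(dem, atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi)
}

infiltration_lookup <- function(texture_class) {
  # texture classes 1 (fine) .. 3 (coarse): coarser soils infiltrate faster
  lut <- c(0.3, 0.6, 0.9)
  out <- matrix(NA_real_, nrow(texture_class), ncol(texture_class))
  ok <- !is.na(texture_class)
  out[ok] <- lut[pmin(pmax(round(texture_class[ok]), 1), 3)]
  out
}
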