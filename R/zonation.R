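#' Altitudinal band profile of an ecological security pattern
#'
#' Distributes source area, corridor length, node counts and the land-use
#' composition of sources across altitudinal bands anchored at 0 m
#' (`[0, 200)`, `[200, 400)`, ... by default). Source cells are assigned by
#' their DEM value; each corridor step by the elevation of its midpoint
#' (mean of the two cell elevations); nodes by the DEM at the node cell.
#' Corridor steps are the deduplicated network steps, so band lengths sum
#' to the corridor set's total length.
#'
#' @param dem elevation `esp_grid` (m).
#' @param sources an `esp_sources` (or `NULL`).
#' @param corridors an `esp_corridorset` (or `NULL`).
#' @param nodes an `esp_nodes` data.frame (or `NULL`).
#' @param landuse optional land-use grid for per-band source composition.
#' @param band_width band width in metres (> 0), default 200.
#' @return an `esp_profile` data.frame: one row per band with `band_lower`,
#'   `band_upper`, `source_area_km2`, `corridor_length_km`, `node_count`,
#'   and (with `landuse`) one `area_<class>_km2` column per class.
#' @export
band_profile <- function(dem, sources = NULL, corridors = NULL,
                         nodes = NULL, landuse = NULL, band_width = 200) {
  stopifnot(is_grid(dem))
  if (band_width <= 0) stop("band_width must be positive")
  z <- dem$values
  zr <- range(z, na.rm = TRUE)
  lo <- floor(zr[1] / band_width)
  hi <- max(lo, ceiling(zr[2] / band_width) - 1)
  bands <- seq(lo, hi)
  band_of <- function(e) pmin(pmax(floor(e / band_width), lo), hi) - lo + 1
  nb <- length(bands)
  out <- data.frame(band_lower = bands * band_width,
                    band_upper = (bands + 1) * band_width,
                    source_area_km2 = 0, corridor_length_km = 0,
                    node_count = 0L)
  cell_km2 <- (dem$cellsize / 1000)^2
  if (!is.null(sources)) {
    assert_same_geometry(dem, sources$label_grid)
    sel <- !is.na(sources$label_grid$values) &
      sources$label_grid$values > 0 & !is.na(z)
    if (any(sel)) {
      tb <- tabulate(band_of(z[sel]), nbins = nb)
      out$source_area_km2 <- tb * cell_km2
    }
    if (!is.null(landuse)) {
      assert_same_geometry(dem, landuse)
      for (nm in names(landuse_classes())) {
        code <- landuse_classes()[[nm]]
        s2 <- sel & !is.na(landuse$values) & landuse$values == code
        out[[paste0("area_", nm, "_km2")]] <-
          tabulate(band_of(z[s2]), nbins = nb) * cell_km2
      }
    }
  }
  if (!is.null(corridors) && length(corridors$corridors)) {
    nr <- nrow(z)
    steps <- corridor_steps(corridors$corridors, nr)
    e1 <- z[cbind(((steps$from - 1) %% nr) + 1, ((steps$from - 1) %/% nr) + 1)]
    e2 <- z[cbind(((steps$to - 1) %% nr) + 1, ((steps$to - 1) %/% nr) + 1)]
    mid <- (e1 + e2) / 2
    lens <- steps$dist * dem$cellsize / 1000
    ok <- !is.na(mid)
    bl <- band_of(mid[ok])
    out$corridor_length_km <- vapply(seq_len(nb), function(i)
      sum(lens[ok][bl == i]), numeric(1))
  }
  if (!is.null(nodes) && nrow(nodes)) {
    e <- z[cbind(nodes$row, nodes$col)]
    ok <- !is.na(e)
    out$node_count <- tabulate(band_of(e[ok]), nbins = nb)
  }
  class(out) <- c("esp_profile", "data.frame")
  attr(out, "band_width") <- band_width
  out
}

#' Peak band of a profiled quantity
#'
#' Returns the band holding the maximum of the chosen quantity; on a tie
#' the lowest band wins (with a message).
#'
#' @param profile an `esp_profile` from [band_profile()].
#' @param quantity profile column name (e.g. `"source_area_km2"`).
#' @return list with `band_lower`, `band_upper`, `value`; `NULL` (with a
#'   message) if the profile is all zero.
#' @export
peak_band <- function(profile, quantity = "source_area_km2") {
  v <- profile[[quantity]]
  if (is.null(v)) stop("unknown profile quantity '", quantity, "'")
  if (all(v == 0)) {
    message("peak_band: profile is all zero, no peak")
    return(NULL)
  }
  idx <- which(v == max(v))
  if (length(idx) > 1)
    message("peak_band: tie across ", length(idx),
            " bands, reporting the lowest")
  i <- idx[1]
  list(band_lower = profile$band_lower[i], band_upper = profile$band_upper[i],
       value = v[i])
}

#' Unimodality check with a deviation score
#'
#' A band sequence is unimodal when it rises to its maximum and then falls,
#' plateaus allowed. The deviation score is the residual of the best
#' up-then-down isotonic fit (minimum over peak positions of the summed
#' absolute deviation), 0 exactly when the sequence is unimodal.
#'
#' @param profile an `esp_profile` or a plain numeric vector.
#' @param quantity profile column name (ignored for a vector input).
#' @return list with `unimodal` (logical) and `deviation` (>= 0).
#' @export
unimodality_check <- function(profile, quantity = "source_area_km2") {
  v <- if (is.numeric(profile)) profile else profile[[quantity]]
  if (is.null(v)) stop("unknown profile quantity '", quantity, "'")
  n <- length(v)
  if (n < 3) stop("unimodality_check needs at least 3 bands")
  up_ok <- c(TRUE, cumsum(diff(v) < 0) == 0)
  down_ok <- rev(c(TRUE, cumsum(rev(diff(v)) > 0) == 0))
  unimodal <- any(up_ok & down_ok)
  dev <- min(vapply(seq_len(n), function(p) {
    up <- isoreg(seq_len(p), v[seq_len(p)])$yf
    dn <- if (p < n) rev(isoreg(seq_len(n - p + 1),
                                rev(v[p:n]))$yf) else v[n]
    fit <- c(up, dn[-1])
    sum(abs(fit - v))
  }, numeric(1)))
  list(unimodal = unimodal, deviation = dev)
}
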