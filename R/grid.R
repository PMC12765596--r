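#' Create a grid
#'
#' A grid is the single-band raster carrier used throughout espkit: a numeric
#' matrix with square cells, row 1 northernmost and column 1 westernmost.
#' Missing cells are stored as `NA`; `nodata` is only the sentinel used when
#' the grid is written to disk. The origin is the outer (north-west) corner
#' of cell `[1, 1]`, in projected metric coordinates.
#'
#' @param values numeric matrix (rows north to south).
#' @param cellsize cell edge length in metres.
#' @param origin_x,origin_y coordinates of the north-west corner of the grid.
#'   `origin_y` defaults to `nrow(values) * cellsize` so that the lower-left
#'   corner sits at (0, 0).
#' @param nodata sentinel value used in files; `NA` in memory.
#' @return an object of class `esp_grid`.
#' @export
grid <- function(values, cellsize = 30, origin_x = 0, origin_y = NULL,
                 nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0)
    stop("cellsize must be a single positive number")
  if (is.null(origin_y)) origin_y <- nrow(values) * cellsize
  structure(
    list(values = values, cellsize = as.numeric(cellsize),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         nodata = as.numeric(nodata)),
    class = "esp_grid")
}

#' @export
print.esp_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<esp_grid> %d x %d cells, %g m resolution\n",
              nrow(x$values), ncol(x$values), x$cellsize))
  cat(sprintf("  origin (NW): %.1f, %.1f; nodata cells: %d\n",
              x$origin_x, x$origin_y, sum(is.na(x$values))))
  if (length(v))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g\n",
                min(v), mean(v), max(v)))
  invisible(x)
}

#' @rdname grid
#' @param x object to test.
#' @export
is_grid <- function(x) inherits(x, "esp_grid")

#' @export
dim.esp_grid <- function(x) dim(x$values)

#' Build a grid sharing another grid's geometry
#' @param template an `esp_grid` supplying geometry.
#' @param values replacement matrix (or scalar, recycled).
#' @return an `esp_grid`.
#' @export
grid_like <- function(template, values) {
  stopifnot(is_grid(template))
  if (is.null(dim(values)) &&
      length(values) %in% c(1, length(template$values)))
    values <- matrix(values, nrow(template$values), ncol(template$values))
  if (!identical(dim(values), dim(template$values)))
    stop("replacement values do not match template dimensions")
  g <- template
  v <- as.matrix(values)
  storage.mode(v) <- "double"
  g$values <- v
  g
}

# Registration check: all grids passed together must share shape, cellsize
# and origin. Enforced, never resampled.
assert_same_geometry <- function(...) {
  gs <- list(...)
  gs <- Filter(is_grid, gs)
  if (length(gs) < 2) return(invisible(TRUE))
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!identical(dim(g$values), dim(ref$values)))
      stop("grids are not co-registered: dimensions differ")
    if (abs(g$cellsize - ref$cellsize) > 1e-9)
      stop("grids are not co-registered: cellsize differs")
    if (abs(g$origin_x - ref$origin_x) > 1e-6 ||
        abs(g$origin_y - ref$origin_y) > 1e-6)
      stop("grids are not co-registered: origin differs")
  }
  invisible(TRUE)
}

# Cell centre coordinates (r, c are 1-based matrix indices).
cell_xy <- function(g, r, c) {
  list(x = g$origin_x + (c - 0.5) * g$cellsize,
       y = g$origin_y - (r - 0.5) * g$cellsize)
}

# Map coordinates to 1-based cell indices (half-open cells: a point on a
# shared edge belongs to the lower-index cell).
xy_cell <- function(g, x, y) {
  c0 <- floor((x - g$origin_x) / g$cellsize) + 1
  r0 <- floor((g$origin_y - y) / g$cellsize) + 1
  list(r = as.integer(r0), c = as.integer(c0))
}

#' Read and write grids
#'
#' Grids are exchanged as ESRI ASCII rasters (plain-text, single band): a
#' six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values from north to south. Values are
#' written at full double precision so a write-then-read round trip is
#' bit-exact.
#'
#' @param path file path.
#' @param format raster format; only `"ascii"` (ESRI ASCII grid) is
#'   supported.
#' @return `read_grid` returns an `esp_grid`; `write_grid` returns `path`
#'   invisibly.
#' @export
read_grid <- function(path, format = c("ascii", "geotiff")) {
  format <- match.arg(format)
  if (format != "ascii")
    stop("unsupported raster format '", format,
         "': espkit exchanges rasters as ESRI ASCII grids")
  lines <- readLines(path)
  if (length(lines) < 7) stop("malformed ESRI ASCII grid: truncated file")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("malformed ESRI ASCII grid header at line ", i)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  for (f in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
              "nodata_value"))
    if (is.null(hdr[[f]]) || is.na(hdr[[f]]))
      stop("malformed ESRI ASCII grid: missing or bad header field '", f, "'")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop("malformed ESRI ASCII grid: nrows header is ", nr,
         " but file has ", length(body), " data rows")
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  widths <- lengths(vals)
  if (any(widths != nc))
    stop("malformed ESRI ASCII grid: ncols header is ", nc,
         " but a data row has ", widths[widths != nc][1], " values")
  m <- do.call(rbind, vals)
  m[m == hdr$nodata_value] <- NA_real_
  grid(m, cellsize = hdr$cellsize, origin_x = hdr$xllcorner,
       origin_y = hdr$yllcorner + nr * hdr$cellsize,
       nodata = hdr$nodata_value)
}

#' @rdname read_grid
#' @param g an `esp_grid`.
#' @export
write_grid <- function(g, path, format = c("ascii", "geotiff")) {
  format <- match.arg(format)
  if (format != "ascii")
    stop("unsupported raster format '", format,
         "': espkit exchanges rasters as ESRI ASCII grids")
  stopifnot(is_grid(g))
  v <- g$values
  v[is.na(v)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %s", formatC(g$origin_x, format = "g", digits = 17)),
    sprintf("yllcorner %s", formatC(g$origin_y - nrow(v) * g$cellsize,
                                    format = "g", digits = 17)),
    sprintf("cellsize %s", formatC(g$cellsize, format = "g", digits = 17)),
    sprintf("NODATA_value %s", formatC(g$nodata, format = "g", digits = 17)))
  rows <- apply(v, 1, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Build a reclassification bin table
#'
#' Bins follow the lower-exclusive / upper-inclusive convention: a value `v`
#' falls in bin `(lower, upper]`. Use `-Inf` / `Inf` for open ends, so a
#' first bin `(-Inf, 373]` captures "<= 373" and a last bin `(1275, Inf]`
#' captures "> 1275".
#'
#' @param lower,upper numeric bin bounds (equal length).
#' @param value output class value per bin.
#' @return a `data.frame` usable by [reclassify()].
#' @export
bin_table <- function(lower, upper, value) {
  stopifnot(length(lower) == length(upper), length(lower) == length(value))
  if (any(upper <= lower)) stop("bin upper bounds must exceed lower bounds")
  o <- order(lower)
  lower <- lower[o]; upper <- upper[o]; value <- value[o]
  if (length(lower) > 1 && any(lower[-1] < upper[-length(upper)] - 1e-12))
    stop("bins overlap")
  data.frame(lower = lower, upper = upper, value = value)
}

#' Reclassify a grid through a bin table
#'
#' Every non-missing cell must fall in exactly one bin `(lower, upper]`;
#' missing cells propagate. A value covered by no bin raises a coverage
#' error naming the value.
#'
#' @param g an `esp_grid`.
#' @param bins a bin table from [bin_table()].
#' @return an `esp_grid` of class values.
#' @export
reclassify <- function(g, bins) {
  stopifnot(is_grid(g))
  v <- g$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (i in seq_len(nrow(bins))) {
    sel <- !is.na(v) & v > bins$lower[i] & v <= bins$upper[i]
    out[sel] <- bins$value[i]
  }
  miss <- !is.na(v) & is.na(out)
  if (any(miss))
    stop("reclassify: value ", v[which(miss)[1]], " is covered by no bin")
  grid_like(g, out)
}

#' Min-max normalize a grid
#'
#' Affine rescaling so the grid minimum maps to `target_lo` and the maximum
#' to `target_hi`; missing cells are preserved. A constant grid cannot be
#' normalized and raises an error.
#'
#' @param g an `esp_grid`.
#' @param target_lo,target_hi target range endpoints.
#' @return an `esp_grid`.
#' @export
minmax_normalize <- function(g, target_lo = 0, target_hi = 1) {
  stopifnot(is_grid(g))
  v <- g$values
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0)
    stop("cannot min-max normalize a constant (or empty) grid")
  grid_like(g, target_lo + (v - rng[1]) / (rng[2] - rng[1]) *
              (target_hi - target_lo))
}

#' Label connected patches in a binary grid
#'
#' Connected-component labelling under 4- or 8-connectivity. Labels are
#' consecutive positive integers assigned in row-major first-cell order, so
#' labelling is deterministic. Cell values must be 0, 1 or `NA` (`NA` counts
#' as background).
#'
#' @param g an `esp_grid` with values in `{0, 1, NA}`.
#' @param connectivity 4 or 8.
#' @return an `esp_patchset`: the label grid plus per-patch cell counts and
#'   areas in km^2.
#' @export
label_patches <- function(g, connectivity = 8) {
  stopifnot(is_grid(g), connectivity %in% c(4, 8))
  v <- g$values
  bad <- !is.na(v) & !(v %in% c(0, 1))
  if (any(bad)) stop("label_patches expects a binary grid (0/1/NA)")
  fg <- !is.na(v) & v == 1
  lab <- cpp_label_components(fg, as.integer(connectivity))
  n <- max(lab)
  counts <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else integer(0)
  structure(
    list(label_grid = grid_like(g, lab),
         patch_ids = seq_len(n),
         cellcount = counts,
         area_km2 = counts * (g$cellsize / 1000)^2,
         connectivity = connectivity),
    class = "esp_patchset")
}

#' @export
print.esp_patchset <- function(x, ...) {
  cat(sprintf("<esp_patchset> %d patches, %.3f km^2 total (%d-connected)\n",
              length(x$patch_ids), sum(x$area_km2), x$connectivity))
  invisible(x)
}

# Shift a matrix by (dr, dc), padding with `fill`. Workhorse for vectorized
# neighbourhood operations.
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Scan order shared with the C++ core: E, N, W, S, NE, NW, SW, SE.
neighbor_offsets <- function() {
  data.frame(dr = c(0, -1, 0, 1, -1, -1, 1, 1),
             dc = c(1, 0, -1, 0, 1, -1, -1, 1),
             dist = c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2)))
}
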