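#' Simple vector feature sets
#'
#' espkit carries roads, reserve outlines, corridors and nodes as flat
#' feature sets: a geometry type, a list of coordinate matrices (one per
#' feature, columns x and y) and a property table. They serialize to and
#' from GeoJSON `FeatureCollection`s.
#'
#' @param geoms list of numeric matrices with columns x, y (points: one row).
#' @param type `"point"`, `"line"` or `"polygon"` (single outer ring).
#' @param props data.frame of per-feature properties (or `NULL`).
#' @return an object of class `esp_features`.
#' @export
features <- function(geoms, type = c("line", "polygon", "point"),
                     props = NULL) {
  type <- match.arg(type)
  geoms <- lapply(geoms, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2) stop("feature coordinates need two columns (x, y)")
    colnames(m) <- c("x", "y")
    m
  })
  if (is.null(props)) props <- data.frame(row.names = seq_along(geoms))
  if (nrow(props) != length(geoms))
    stop("property table rows must match feature count")
  structure(list(type = type, geoms = geoms, props = props),
            class = "esp_features")
}

#' @export
print.esp_features <- function(x, ...) {
  cat(sprintf("<esp_features> %d %s feature(s), %d propert(ies)\n",
              length(x$geoms), x$type, ncol(x$props)))
  invisible(x)
}

#' @rdname features
#' @param x object to test.
#' @export
is_features <- function(x) inherits(x, "esp_features")

geojson_type <- function(type) {
  switch(type, point = "Point", line = "LineString", polygon = "Polygon")
}

#' Read and write feature sets as GeoJSON
#'
#' @param f an `esp_features` object.
#' @param path file path.
#' @return `read_features` returns an `esp_features`; `write_features`
#'   returns `path` invisibly.
#' @export
write_features <- function(f, path) {
  stopifnot(is_features(f))
  feats <- lapply(seq_along(f$geoms), function(i) {
    m <- f$geoms[[i]]
    coords <- switch(f$type,
      point = as.numeric(m[1, ]),
      line = unname(lapply(seq_len(nrow(m)), function(j) as.numeric(m[j, ]))),
      polygon = {
        if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])  # close ring
        list(unname(lapply(seq_len(nrow(m)), function(j) as.numeric(m[j, ]))))
      })
    props <- if (ncol(f$props)) as.list(f$props[i, , drop = FALSE])
             else setNames(list(), character(0))
    list(type = "Feature",
         geometry = list(type = geojson_type(f$type), coordinates = coords),
         properties = props)
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$type) || obj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  feats <- obj$features
  if (!length(feats)) return(features(list(), "point"))
  gtypes <- vapply(feats, function(ft) ft$geometry$type, character(1))
  type <- switch(gtypes[1], Point = "point", LineString = "line",
                 Polygon = "polygon",
                 stop("unsupported GeoJSON geometry: ", gtypes[1]))
  geoms <- lapply(feats, function(ft) {
    cc <- ft$geometry$coordinates
    m <- switch(type,
      point = matrix(as.numeric(unlist(cc)), 1, 2),
      line = do.call(rbind, lapply(cc, function(p) as.numeric(unlist(p)))),
      polygon = do.call(rbind, lapply(cc[[1]],
                                      function(p) as.numeric(unlist(p)))))
    colnames(m) <- c("x", "y")
    m
  })
  plists <- lapply(feats, function(ft) ft$properties)
  keys <- unique(unlist(lapply(plists, names)))
  props <- if (length(keys)) {
    as.data.frame(lapply(setNames(keys, keys), function(k)
      unlist(lapply(plists, function(p)
        if (is.null(p[[k]])) NA else p[[k]]))), stringsAsFactors = FALSE)
  } else NULL
  features(geoms, type, props)
}

#' Rasterize polygons onto a grid template
#'
#' A cell belongs to a polygon when its centre falls inside the outer ring
#' (cell-centre-in-polygon rule). Overlapping polygons merge in the output
#' mask.
#'
#' @param f polygon `esp_features`.
#' @param template an `esp_grid` supplying geometry.
#' @return a binary `esp_grid` (1 inside any polygon, 0 elsewhere).
#' @export
rasterize_polygons <- function(f, template) {
  stopifnot(is_features(f), is_grid(template))
  if (f$type != "polygon") stop("rasterize_polygons needs polygon features")
  nr <- nrow(template$values); nc <- ncol(template$values)
  ctr <- cell_xy(template, rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  pts <- cbind(ctr$x, ctr$y)
  inside <- rep(FALSE, nrow(pts))
  for (m in f$geoms) {
    ring <- m
    if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), ]
    inside <- inside | mgcv::in.out(rbind(ring, ring[1, ]), pts)
  }
  grid_like(template, matrix(as.numeric(inside), nr, nc))
}
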