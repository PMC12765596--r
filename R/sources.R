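#' Ecological sources from MSPA connectivity
#'
#' ESP1 strategy: source patches are the connected core-class components of
#' an MSPA classification whose area reaches `min_area_km2`.
#'
#' @param class_grid grid from [classify_mspa()].
#' @param min_area_km2 minimum patch area (km^2).
#' @return an `esp_sources` object (strategy `"ESP1"`).
#' @export
sources_connectivity <- function(class_grid, min_area_km2 = 0.5) {
  stopifnot(is_grid(class_grid))
  core <- grid_like(class_grid,
                    as.numeric(!is.na(class_grid$values) &
                                 class_grid$values == mspa_classes()[["core"]]))
  source_set_from_mask(core, min_area_km2, "ESP1")
}

#' Ecological sources from nature reserves
#'
#' ESP2 strategy: reserve polygons rasterized onto the grid template
#' (cell-centre rule); overlapping or touching reserves merge into one
#' patch.
#'
#' @param reserves polygon `esp_features`.
#' @param template an `esp_grid` supplying geometry.
#' @param min_area_km2 minimum patch area (km^2); defaults to 0 so every
#'   legally designated reserve is kept.
#' @return an `esp_sources` object (strategy `"ESP2"`).
#' @export
sources_reserves <- function(reserves, template, min_area_km2 = 0) {
  stopifnot(is_grid(template))
  if (!is_features(reserves) || length(reserves$geoms) == 0) {
    warning("empty reserve set: ESP2 sources are empty")
    mask <- grid_like(template, 0)
  } else {
    mask <- rasterize_polygons(reserves, template)
  }
  mask$values[is.na(template$values)] <- NA_real_
  source_set_from_mask(mask, min_area_km2, "ESP2")
}

#' Integrated ecological sources with a niche filter
#'
#' ESP3 strategy: candidate cells are the union of the connectivity (ESP1)
#' and reserve (ESP2) source cells; cells whose comprehensive niche exceeds
#' the configured threshold are retained, relabelled, and patches below
#' `min_area_km2` dropped. The union-then-filter rule (rather than
#' intersection) keeps reserves that fall outside MSPA cores in play, which
#' is the point of combining the two strategies; set `combine =
#' "intersection"` for sensitivity analysis.
#'
#' @param mspa_sources,reserve_sources `esp_sources` from the two base
#'   strategies.
#' @param niche an `esp_niche_result` from [comprehensive_niche()].
#' @param min_area_km2 minimum patch area (km^2).
#' @param combine `"union"` (default) or `"intersection"`.
#' @return an `esp_sources` object (strategy `"ESP3"`).
#' @export
sources_integrated <- function(mspa_sources, reserve_sources, niche,
                               min_area_km2 = 0.5,
                               combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  m1 <- source_mask(mspa_sources)
  m2 <- source_mask(reserve_sources)
  assert_same_geometry(m1, m2, niche$niche)
  cand <- if (combine == "union") {
    (m1$values == 1) | (m2$values == 1)
  } else {
    (m1$values == 1) & (m2$values == 1)
  }
  cand[is.na(cand)] <- FALSE
  keep <- cand & !is.na(niche$mask$values) & niche$mask$values == 1
  mask <- grid_like(m1, matrix(as.numeric(keep), nrow(keep), ncol(keep)))
  source_set_from_mask(mask, min_area_km2, "ESP3")
}

# shared labelling + area filter behind the three strategies
source_set_from_mask <- function(mask, min_area_km2, strategy) {
  ps <- label_patches(mask, connectivity = 8)
  keep_ids <- ps$patch_ids[ps$area_km2 >= min_area_km2]
  lab <- ps$label_grid$values
  lab[!(lab %in% keep_ids)] <- 0
  # relabel consecutively, preserving row-major discovery order
  if (length(keep_ids)) {
    remap <- integer(max(ps$patch_ids))
    remap[keep_ids] <- seq_along(keep_ids)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  counts <- if (length(keep_ids)) tabulate(lab[lab > 0],
                                           nbins = length(keep_ids))
            else integer(0)
  structure(
    list(strategy = strategy,
         label_grid = grid_like(mask, lab),
         patch_ids = seq_along(keep_ids),
         cellcount = counts,
         area_km2 = counts * (mask$cellsize / 1000)^2,
         total_area_km2 = sum(counts) * (mask$cellsize / 1000)^2,
         min_area_km2 = min_area_km2),
    class = "esp_sources")
}

#' @export
print.esp_sources <- function(x, ...) {
  cat(sprintf("<esp_sources %s> %d patches, %.2f km^2\n", x$strategy,
              length(x$patch_ids), x$total_area_km2))
  invisible(x)
}

# binary grid of source cells
source_mask <- function(sources) {
  grid_like(sources$label_grid,
            matrix(as.numeric(!is.na(sources$label_grid$values) &
                                sources$label_grid$values > 0),
                   nrow(sources$label_grid$values),
                   ncol(sources$label_grid$values)))
}

#' Land-use composition of a source set
#'
#' Per-class cell counts and area fractions over all source cells and per
#' patch; fractions sum to 1.
#'
#' @param sources an `esp_sources` object.
#' @param landuse land-use class `esp_grid`.
#' @return list with `overall` (data.frame of class, cells, fraction) and
#'   `per_patch` (matrix of fractions, patches x classes).
#' @export
source_composition <- function(sources, landuse) {
  stopifnot(is_grid(landuse))
  assert_same_geometry(sources$label_grid, landuse)
  lab <- sources$label_grid$values
  lu <- landuse$values
  classes <- landuse_classes()
  sel <- !is.na(lab) & lab > 0 & !is.na(lu)
  overall_counts <- vapply(classes, function(code) sum(lu[sel] == code),
                           numeric(1))
  tot <- sum(overall_counts)
  overall <- data.frame(class = names(classes), code = unname(classes),
                        cells = unname(overall_counts),
                        fraction = if (tot > 0) unname(overall_counts) / tot
                                   else rep(0, length(classes)),
                        row.names = NULL)
  np <- length(sources$patch_ids)
  per_patch <- matrix(0, np, length(classes),
                      dimnames = list(NULL, names(classes)))
  for (p in seq_len(np)) {
    s <- sel & lab == p
    n <- sum(s)
    if (n > 0)
      per_patch[p, ] <- vapply(classes, function(code) sum(lu[s] == code),
                               numeric(1)) / n
  }
  list(overall = overall, per_patch = per_patch)
}
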