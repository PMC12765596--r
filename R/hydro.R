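#' D8 flow direction
#'
#' Each cell drains to its steepest-descent 8-neighbour (drop divided by
#' distance, diagonal distance `sqrt(2)`); ties break by the fixed
#' neighbour scan order (E, N, W, S, NE, NW, SW, SE). Flats are resolved
#' iteratively: a flat cell drains to an equal-elevation neighbour that
#' already has a direction, which keeps the drainage graph acyclic;
#' unresolvable flats (and true pits) become terminal pits, coded 0. No
#' depression filling is applied — the surfaces routed here are resistance
#' fields whose basins are meaningful, not terrain artefacts.
#'
#' @param surface an `esp_grid`.
#' @return an `esp_grid` of direction codes (1-8 in scan order, 0 = pit).
#' @export
flow_direction <- function(surface) {
  stopifnot(is_grid(surface))
  z <- surface$values
  nr <- nrow(z); nc <- ncol(z)
  off <- neighbor_offsets()
  best <- matrix(-Inf, nr, nc)
  dir <- matrix(0L, nr, nc)
  nbz <- vector("list", 8)
  for (k in 1:8) {
    nb <- shift_mat(z, -off$dr[k], -off$dc[k], fill = NA)
    nbz[[k]] <- nb
    drop <- (z - nb) / off$dist[k]
    upd <- !is.na(drop) & drop > 0 & drop > best + 1e-12
    dir[upd] <- k
    best[upd] <- drop[upd]
  }
  # iterative flat resolution: drain toward already-resolved equal cells
  flat <- dir == 0 & !is.na(z)
  if (any(flat)) {
    repeat {
      resolved <- dir > 0
      assigned <- matrix(FALSE, nr, nc)
      newdir <- dir
      for (k in 1:8) {
        nb_res <- shift_mat(resolved, -off$dr[k], -off$dc[k], fill = FALSE)
        eq <- !is.na(nbz[[k]]) & nbz[[k]] == z
        sel <- flat & !assigned & eq & nb_res
        newdir[sel] <- k
        assigned <- assigned | sel
      }
      if (!any(assigned)) break
      dir <- newdir
      flat <- flat & !assigned
      if (!any(flat)) break
    }
  }
  dir[is.na(z)] <- 0L
  grid_like(surface, dir)
}

#' D8 flow accumulation
#'
#' Counts, for every cell, the cells draining through it (self-inclusive,
#' minimum 1) by topological-order propagation along the direction grid.
#' The accumulations of the terminal pit cells sum to the total cell count.
#'
#' @param directions direction grid from [flow_direction()].
#' @return an `esp_grid` of accumulation counts.
#' @export
flow_accumulation <- function(directions) {
  stopifnot(is_grid(directions))
  d <- directions$values
  d[is.na(d)] <- 0
  grid_like(directions, cpp_flow_accumulation(matrix(as.integer(d),
                                                     nrow(d), ncol(d))))
}

#' Extract ridge or valley lines from a surface
#'
#' Valley lines (`invert = FALSE`) are the high-flow-accumulation channels
#' of D8 routing on the surface itself; ridge lines (`invert = TRUE`) are
#' the channels of the inverted surface (`max - surface`), i.e. the crest
#' network. On an MCR resistance surface the ridge lines of the inverted
#' field are the low-resistance channels organisms favour, and the valley
#' lines the high-resistance divides.
#'
#' @param surface an `esp_grid`.
#' @param invert route on `max(surface) - surface` instead of `surface`.
#' @param accumulation_percentile channel threshold: cells whose
#'   accumulation reaches this percentile (in (50, 100)) are channel cells.
#' @return a binary `esp_grid` channel mask.
#' @export
extract_channels <- function(surface, invert = FALSE,
                             accumulation_percentile = 95) {
  stopifnot(is_grid(surface))
  if (accumulation_percentile <= 50 || accumulation_percentile >= 100)
    stop("accumulation_percentile must lie in (50, 100)")
  z <- surface
  if (invert) {
    mx <- max(surface$values, na.rm = TRUE)
    z <- grid_like(surface, mx - surface$values)
  }
  acc <- flow_accumulation(flow_direction(z))
  av <- acc$values
  thr <- quantile(av, accumulation_percentile / 100, na.rm = TRUE,
                  names = FALSE)
  if (!is.finite(thr) || thr <= 1) {
    # degenerate surface: everything is a pit, no channels
    return(grid_like(surface, matrix(0, nrow(av), ncol(av))))
  }
  mask <- matrix(as.numeric(!is.na(av) & av >= thr), nrow(av), ncol(av))
  mask[is.na(surface$values)] <- NA_real_
  grid_like(surface, mask)
}

#' Locate strategic and artificial ecological nodes
#'
#' Strategic nodes sit where ecological corridors cross ridge lines of the
#' resistance surface (migration hubs); artificial nodes sit where roads
#' cross valley lines (pressure points needing protection). An intersection
#' is a cell-level conjunction with a one-cell 8-neighbour dilation
#' tolerance; each connected intersection cluster collapses to the cell
#' nearest its centroid, and nodes of the same type within `merge_radius`
#' cells merge.
#'
#' @param corridors an `esp_corridorset` (or a binary corridor grid).
#' @param ridge_mask,valley_mask binary channel grids from
#'   [extract_channels()].
#' @param roads_mask binary road-cell grid (or line `esp_features`).
#' @param merge_radius_cells merge radius, in cells.
#' @return an `esp_nodes` data.frame: row, col, x, y, type.
#' @export
locate_nodes <- function(corridors, ridge_mask, roads_mask, valley_mask,
                         merge_radius_cells = 2) {
  tpl <- ridge_mask
  stopifnot(is_grid(tpl))
  corr <- if (inherits(corridors, "esp_corridorset")) corridor_mask(corridors)
          else as_mask(corridors)
  roads <- if (is_features(roads_mask)) burn_lines(roads_mask, tpl)
           else as_mask(roads_mask)
  strategic <- intersection_nodes(corr, as_mask(ridge_mask), tpl,
                                  merge_radius_cells)
  artificial <- intersection_nodes(roads, as_mask(valley_mask), tpl,
                                   merge_radius_cells)
  out <- rbind(
    if (nrow(strategic)) cbind(strategic, type = "strategic"),
    if (nrow(artificial)) cbind(artificial, type = "artificial"))
  if (is.null(out))
    out <- data.frame(row = integer(0), col = integer(0), x = numeric(0),
                      y = numeric(0), type = character(0))
  class(out) <- c("esp_nodes", "data.frame")
  out
}

as_mask <- function(x) {
  if (is_grid(x)) !is.na(x$values) & x$values == 1
  else as.matrix(x) & !is.na(as.matrix(x))
}

intersection_nodes <- function(mask_a, mask_b, tpl, merge_radius) {
  inter <- (mask_a & cpp_dilate(mask_b, 8L)) | (mask_b & cpp_dilate(mask_a, 8L))
  empty <- data.frame(row = integer(0), col = integer(0), x = numeric(0),
                      y = numeric(0))
  if (!any(inter)) return(empty)
  lab <- cpp_label_components(inter, 8L)
  reps <- lapply(seq_len(max(lab)), function(id) {
    cells <- which(lab == id, arr.ind = TRUE)
    ctr <- colMeans(cells)
    d <- (cells[, 1] - ctr[1])^2 + (cells[, 2] - ctr[2])^2
    cells[order(d, cells[, 1], cells[, 2])[1], ]
  })
  pts <- do.call(rbind, reps)
  # single-linkage merge of representatives within the merge radius
  n <- nrow(pts)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          sqrt(sum((pts[i, ] - pts[j, ])^2)) <= merge_radius) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  merged <- do.call(rbind, lapply(unique(comp), function(cid) {
    sub <- pts[comp == cid, , drop = FALSE]
    round(colMeans(sub))
  }))
  xy <- cell_xy(tpl, merged[, 1], merged[, 2])
  data.frame(row = as.integer(merged[, 1]), col = as.integer(merged[, 2]),
             x = xy$x, y = xy$y)
}

#' Nodes as point features
#'
#' @param nodes an `esp_nodes` data.frame from [locate_nodes()].
#' @return point `esp_features` with a `type` property.
#' @export
nodes_to_features <- function(nodes) {
  geoms <- lapply(seq_len(nrow(nodes)), function(i)
    matrix(c(nodes$x[i], nodes$y[i]), 1, 2))
  features(geoms, "point", data.frame(type = nodes$type))
}
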