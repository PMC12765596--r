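#' Accumulated cost distance over a resistance surface
#'
#' Exact single-source (multi-cell seed) shortest-path costs under
#' 8-neighbour moves. The cost of a step between adjacent cells is
#' `cellsize_km * (R(a) + R(b)) / 2`, times `sqrt(2)` for diagonal moves —
#' the standard cost-distance convention. Missing resistance cells are
#' impassable. The returned backlink grid codes, for every reached cell,
#' the scan-order direction (E, N, W, S, NE, NW, SW, SE) of its
#' predecessor; ties break deterministically.
#'
#' @param resistance an `esp_grid` of positive resistance values.
#' @param seed_mask binary `esp_grid` (or logical matrix) of seed cells.
#' @return an `esp_costfield`: `cost` grid (km-weighted cost units),
#'   `backlink` grid, and the seed mask.
#' @export
cost_distance <- function(resistance, seed_mask) {
  stopifnot(is_grid(resistance))
  seed <- if (is_grid(seed_mask)) {
    assert_same_geometry(resistance, seed_mask)
    !is.na(seed_mask$values) & seed_mask$values == 1
  } else {
    m <- as.matrix(seed_mask)
    if (!identical(dim(m), dim(resistance$values)))
      stop("seed mask does not match the resistance surface")
    m & !is.na(m)
  }
  if (!any(seed)) stop("cost_distance: empty seed mask")
  if (any(resistance$values <= 0, na.rm = TRUE))
    stop("cost_distance: resistance must be positive")
  res <- cpp_cost_distance(resistance$values, seed,
                           resistance$cellsize / 1000)
  cost <- res$cost
  cost[is.infinite(cost)] <- NA_real_
  structure(list(cost = grid_like(resistance, cost),
                 backlink = grid_like(resistance, res$backlink),
                 seed = seed),
            class = "esp_costfield")
}

#' Trace the least-cost path to a target
#'
#' Picks the minimum-cost cell of the target mask (ties broken by row-major
#' cell order) and traces backlinks to the seed. The reported cost equals
#' the cost field at that cell.
#'
#' @param cost_field an `esp_costfield` from [cost_distance()].
#' @param target_mask binary `esp_grid` or logical matrix.
#' @return list with `cells` (two-column matrix of row/col indices, target
#'   first cell to seed last), `cost`, and `length_km`.
#' @export
least_cost_path <- function(cost_field, target_mask) {
  cost <- cost_field$cost$values
  tgt <- if (is_grid(target_mask)) {
    !is.na(target_mask$values) & target_mask$values == 1
  } else as.matrix(target_mask) & !is.na(as.matrix(target_mask))
  if (!any(tgt)) stop("least_cost_path: empty target mask")
  reach <- tgt & !is.na(cost)
  if (!any(reach))
    stop("least_cost_path: target unreachable from the seed")
  nr <- nrow(cost); nc <- ncol(cost)
  cand <- which(reach)
  # row-major tie-break on equal costs
  rowmajor <- ((cand - 1) %% nr) * nc + ((cand - 1) %/% nr)
  o <- order(cost[cand], rowmajor)
  start <- cand[o[1]]
  off <- neighbor_offsets()
  back <- cost_field$backlink$values
  r <- ((start - 1) %% nr) + 1
  c <- ((start - 1) %/% nr) + 1
  cells <- matrix(NA_integer_, nr * nc, 2)
  n <- 0
  len <- 0
  repeat {
    n <- n + 1
    cells[n, ] <- c(r, c)
    d <- back[r, c]
    if (d == 0) break
    len <- len + off$dist[d]
    r <- r + off$dr[d]
    c <- c + off$dc[d]
  }
  list(cells = cells[seq_len(n), , drop = FALSE],
       cost = cost[start],
       length_km = len * cost_field$cost$cellsize / 1000)
}

#' Extract least-cost ecological corridors between source patches
#'
#' One least-cost path per unordered pair of source patches, computed by
#' seeding the cost distance on one patch and tracing from the other.
#' Integration and deduplication: the total network length `C` counts every
#' cell-to-cell step once even when several corridors share it, and a
#' corridor whose cells are (at least `containment`) contained in another
#' corridor's cells is dropped from the corridor count.
#'
#' @param sources an `esp_sources` object with >= 2 patches.
#' @param resistance an `esp_grid` resistance surface.
#' @param containment overlap fraction above which the smaller corridor of
#'   a pair is considered a duplicate (default 0.95).
#' @return an `esp_corridorset`: list of corridors (cells, endpoint patch
#'   ids, cost, length_km), the deduplicated total length `total_length_km`,
#'   and the retained corridor count `count`.
#' @export
extract_corridors <- function(sources, resistance, containment = 0.95) {
  stopifnot(is_grid(resistance))
  assert_same_geometry(sources$label_grid, resistance)
  lab <- sources$label_grid$values
  ids <- sources$patch_ids
  if (length(ids) < 2)
    stop("extract_corridors needs at least 2 source patches")
  nr <- nrow(lab); nc <- ncol(lab)
  corridors <- list()
  for (i in ids[-length(ids)]) {
    seed <- !is.na(lab) & lab == i
    cf <- cost_distance(resistance, seed)
    for (j in ids[ids > i]) {
      tgt <- !is.na(lab) & lab == j
      path <- tryCatch(least_cost_path(cf, tgt), error = function(e) NULL)
      if (is.null(path)) next
      corridors[[length(corridors) + 1]] <-
        list(from = i, to = j, cells = path$cells, cost = path$cost,
             length_km = path$length_km)
    }
  }
  if (!length(corridors))
    stop("extract_corridors: no patch pair is mutually reachable")
  # containment pruning: drop the smaller corridor of a highly nested pair
  cellsets <- lapply(corridors, function(co)
    unique((co$cells[, 2] - 1) * nr + co$cells[, 1]))
  drop <- rep(FALSE, length(corridors))
  for (a in seq_along(corridors)) {
    if (drop[a]) next
    for (b in seq_along(corridors)) {
      if (a == b || drop[b]) next
      na <- length(cellsets[[a]]); nb <- length(cellsets[[b]])
      small <- if (na <= nb) a else b
      big <- if (na <= nb) b else a
      ov <- sum(cellsets[[small]] %in% cellsets[[big]])
      if (ov / length(cellsets[[small]]) >= containment) drop[small] <- TRUE
      if (drop[a]) break
    }
  }
  kept <- corridors[!drop]
  # deduplicated length: unique undirected steps across kept corridors
  steps <- corridor_steps(kept, nr)
  cellsize_km <- resistance$cellsize / 1000
  total <- sum(steps$dist) * cellsize_km
  structure(list(corridors = kept, count = length(kept),
                 raw_count = length(corridors),
                 total_length_km = total,
                 cellsize = resistance$cellsize,
                 template = sources$label_grid),
            class = "esp_corridorset")
}

# unique undirected steps (pairs of linear cell indices) over corridors
corridor_steps <- function(corridors, nr) {
  a <- integer(0); b <- integer(0)
  for (co in corridors) {
    cl <- co$cells
    if (nrow(cl) < 2) next
    idx <- (cl[, 2] - 1) * nr + cl[, 1]
    a <- c(a, idx[-length(idx)])
    b <- c(b, idx[-1])
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  r1 <- ((lo - 1) %% nr) + 1; c1 <- ((lo - 1) %/% nr) + 1
  r2 <- ((hi - 1) %% nr) + 1; c2 <- ((hi - 1) %/% nr) + 1
  dist <- ifelse(r1 != r2 & c1 != c2, sqrt(2), 1)
  list(from = lo, to = hi, dist = dist)
}

#' @export
print.esp_corridorset <- function(x, ...) {
  cat(sprintf(
    "<esp_corridorset> %d corridor(s) (%d raw), %.2f km deduplicated\n",
    x$count, x$raw_count, x$total_length_km))
  invisible(x)
}

#' Corridors as line features
#'
#' @param corridorset an `esp_corridorset`.
#' @return line `esp_features` with endpoint patch ids, cost and length
#'   properties.
#' @export
corridors_to_features <- function(corridorset) {
  tpl <- corridorset$template
  geoms <- lapply(corridorset$corridors, function(co) {
    xy <- cell_xy(tpl, co$cells[, 1], co$cells[, 2])
    cbind(x = xy$x, y = xy$y)
  })
  props <- data.frame(
    from = vapply(corridorset$corridors, `[[`, numeric(1), "from"),
    to = vapply(corridorset$corridors, `[[`, numeric(1), "to"),
    cost = vapply(corridorset$corridors, `[[`, numeric(1), "cost"),
    length_km = vapply(corridorset$corridors, `[[`, numeric(1), "length_km"))
  features(geoms, "line", props)
}

# binary matrix of all corridor cells
corridor_mask <- function(corridorset) {
  tpl <- corridorset$template
  m <- matrix(FALSE, nrow(tpl$values), ncol(tpl$values))
  for (co in corridorset$corridors) m[co$cells] <- TRUE
  m
}
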