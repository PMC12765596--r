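# Independent oracles used to cross-check the package's algorithms. They
# implement the operation definitions directly (flood fill, brute-force
# distance scans, exhaustive relaxation) and share no code with the
# implementations they test.

# scan order shared with the package's definitions
ORACLE_OFF <- data.frame(dr = c(0, -1, 0, 1, -1, -1, 1, 1),
                         dc = c(1, 0, -1, 0, 1, -1, -1, 1),
                         dist = c(1, 1, 1, 1, rep(sqrt(2), 4)))

# flood-fill connected components of a logical matrix
oracle_label <- function(fg, connectivity = 4) {
  nr <- nrow(fg); nc <- ncol(fg)
  nn <- if (connectivity == 8) 8 else 4
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!fg[r0, c0] || lab[r0, c0] > 0) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nn)) {
        r <- p[1] + ORACLE_OFF$dr[k]; c <- p[2] + ORACLE_OFF$dc[k]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && fg[r, c] &&
            lab[r, c] == 0) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Chebyshev distance from each cell to the nearest TRUE cell of `mask`,
# including (optionally) the off-grid region at the given boundary distance
oracle_cheb_dist <- function(mask, include_offgrid = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d <- if (nrow(idx)) min(pmax(abs(idx[, 1] - r), abs(idx[, 2] - c))) else Inf
    if (include_offgrid) d <- min(d, r, nr + 1 - r, c, nc + 1 - c)
    out[r, c] <- d
  }
  out
}

# Per-definition MSPA oracle for foreground connectivity 4 (box structuring
# element, background connectivity 8), edge width w. Returns the class-code
# matrix using espkit's coding.
oracle_mspa <- function(fg, w = 1) {
  cls <- mspa_classes()
  cls[] <- cls  # keep codes; output is double to match grids
  nr <- nrow(fg); nc <- ncol(fg)
  out <- matrix(as.numeric(cls[["background"]]), nr, nc)
  if (!any(fg)) return(out)
  dbg <- oracle_cheb_dist(!fg, include_offgrid = TRUE)
  core <- fg & dbg > w
  lab_fg <- oracle_label(fg, 4)
  core_comps <- unique(lab_fg[core])
  islet <- fg & !(lab_fg %in% core_comps)
  dim(islet) <- dim(fg)
  lab_core <- oracle_label(core, 4)
  ncore <- max(lab_core)
  # distance to each core component
  dcomp <- lapply(seq_len(ncore), function(id)
    oracle_cheb_dist(lab_core == id))
  near_core_ids <- function(r, c)
    which(vapply(dcomp, function(d) d[r, c] <= w, logical(1)))
  zone <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if (fg[r, c] && !core[r, c] && !islet[r, c] &&
        length(near_core_ids(r, c))) zone[r, c] <- TRUE
  # outer vs hole background
  lab_bg <- oracle_label(!fg, 8)
  touches_border <- unique(c(lab_bg[1, ], lab_bg[nr, ], lab_bg[, 1],
                             lab_bg[, nc]))
  outer_bg <- !fg & (lab_bg %in% setdiff(touches_border, 0))
  dim(outer_bg) <- dim(fg)
  hole_bg <- !fg & !outer_bg
  d_outer <- oracle_cheb_dist(outer_bg, include_offgrid = TRUE)
  d_hole <- oracle_cheb_dist(hole_bg)
  out[core] <- cls[["core"]]
  out[islet] <- cls[["islet"]]
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!zone[r, c]) next
    out[r, c] <- if (d_outer[r, c] <= w) cls[["edge"]]
                 else if (d_hole[r, c] <= w) cls[["perforation"]]
                 else cls[["edge"]]
  }
  connector <- fg & !core & !islet & !zone
  if (any(connector)) {
    lab_conn <- oracle_label(connector, 4)
    anchored_id <- matrix(0L, nr, nc)  # zone/core cells labelled by comp
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (core[r, c]) anchored_id[r, c] <- lab_core[r, c]
      else if (zone[r, c]) anchored_id[r, c] <- near_core_ids(r, c)[1]
    }
    for (id in seq_len(max(lab_conn))) {
      cells <- which(lab_conn == id, arr.ind = TRUE)
      touched <- integer(0)
      contact <- matrix(FALSE, nr, nc)
      for (i in seq_len(nrow(cells))) {
        for (k in 1:4) {
          r <- cells[i, 1] + ORACLE_OFF$dr[k]
          c <- cells[i, 2] + ORACLE_OFF$dc[k]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              anchored_id[r, c] > 0) {
            touched <- union(touched, anchored_id[r, c])
            contact[cells[i, 1], cells[i, 2]] <- TRUE
          }
        }
      }
      code <- if (length(touched) >= 2) cls[["bridge"]]
      else if (length(touched) == 1) {
        if (max(oracle_label(contact, 8)) >= 2) cls[["loop"]]
        else cls[["branch"]]
      } else cls[["branch"]]
      out[lab_conn == id] <- code
    }
  }
  storage.mode(out) <- "double"
  out
}

# exhaustive-relaxation (Bellman-Ford) shortest-path oracle for the
# cost-distance operation
oracle_cost_distance <- function(res, seed, cell_km) {
  nr <- nrow(res); nc <- ncol(res)
  cost <- matrix(Inf, nr, nc)
  cost[seed & !is.na(res)] <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(res[r, c])) next
      for (k in 1:8) {
        r2 <- r + ORACLE_OFF$dr[k]; c2 <- c + ORACLE_OFF$dc[k]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(res[r2, c2])) next
        w <- cell_km * (res[r, c] + res[r2, c2]) / 2 * ORACLE_OFF$dist[k]
        if (cost[r2, c2] + w < cost[r, c] - 1e-12) {
          cost[r, c] <- cost[r2, c2] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  cost
}

# exhaustive simple-path enumeration oracle (tiny grids only)
oracle_enumerate_min_cost <- function(res, from, to, cell_km) {
  nr <- nrow(res); nc <- ncol(res)
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  recurse <- function(r, c, acc) {
    if (acc >= best) return()
    if (r == to[1] && c == to[2]) { best <<- acc; return() }
    visited[r, c] <<- TRUE
    for (k in 1:8) {
      r2 <- r + ORACLE_OFF$dr[k]; c2 <- c + ORACLE_OFF$dc[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || visited[r2, c2]) next
      w <- cell_km * (res[r, c] + res[r2, c2]) / 2 * ORACLE_OFF$dist[k]
      recurse(r2, c2, acc + w)
    }
    visited[r, c] <<- FALSE
  }
  recurse(from[1], from[2], 0)
  best
}

# brute-force steepest-descent D8 direction oracle (scan-order tie-break;
# flats left unresolved as 0 — compare only on strict-descent cells)
oracle_flow_dir_strict <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  dir <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    best <- 0; bk <- 0L
    for (k in 1:8) {
      r2 <- r + ORACLE_OFF$dr[k]; c2 <- c + ORACLE_OFF$dc[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      drop <- (z[r, c] - z[r2, c2]) / ORACLE_OFF$dist[k]
      if (drop > best + 1e-12) { best <- drop; bk <- k }
    }
    dir[r, c] <- bk
  }
  dir
}

# path-tracing accumulation oracle: count, for every cell, the cells whose
# drainage path passes through it (self-inclusive)
oracle_flow_acc <- function(dir) {
  nr <- nrow(dir); nc <- ncol(dir)
  acc <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    cr <- r; cc <- c
    repeat {
      acc[cr, cc] <- acc[cr, cc] + 1
      d <- dir[cr, cc]
      if (d == 0) break
      cr <- cr + ORACLE_OFF$dr[d]; cc <- cc + ORACLE_OFF$dc[d]
    }
  }
  acc
}

# all-pairs minimum Euclidean distance oracle
oracle_proximity <- function(mask, cellsize) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    out[r, c] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - c)^2)) * cellsize
  out
}

# small random binary grid helper
random_binary_grid <- function(nr, nc, p = 0.5, cellsize = 30) {
  grid(matrix(as.numeric(runif(nr * nc) < p), nr, nc), cellsize = cellsize)
}

# tiny landscape bundle for fast pipeline-level tests
small_landscape <- function(seed = 7, n = 96) {
  generate_landscape(landscape_config(seed = seed, nrows = n, ncols = n))
}
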