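#' Build the corridor-vertex ecological network
#'
#' Graph abstraction consumed by the connectivity indices: vertices are one
#' per source patch (all corridor attachment cells of a patch collapse to a
#' single vertex) plus every junction cell where three or more corridor
#' segments meet; links are the maximal corridor segments between
#' consecutive vertices; `C` is the deduplicated total corridor length.
#' This structural vertex definition — terminals plus junctions, not the
#' conservation-planning node set of [locate_nodes()] — is what the index
#' formulas operate on.
#'
#' @param corridorset an `esp_corridorset`.
#' @param sources the `esp_sources` the corridors connect.
#' @return an `esp_network`: `V`, `L`, `C_km` and a link table.
#' @export
build_network <- function(corridorset, sources) {
  if (!length(corridorset$corridors))
    stop("build_network: empty corridor set")
  lab <- sources$label_grid$values
  nr <- nrow(lab)
  steps <- corridor_steps(corridorset$corridors, nr)
  # node identity: patch cells collapse to one node per patch
  node_of <- function(idx) {
    r <- ((idx - 1) %% nr) + 1; c <- ((idx - 1) %/% nr) + 1
    p <- lab[cbind(r, c)]
    ifelse(!is.na(p) & p > 0, -p, idx)  # negative ids = patch nodes
  }
  a <- node_of(steps$from); b <- node_of(steps$to)
  keep <- a != b  # steps inside one patch are not graph edges
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(cbind(lo, hi)) & (lo < 0 & hi < 0)
  # parallel unit steps between two cells cannot occur (dedup upstream);
  # multiple direct patch-patch contacts collapse to one link
  a <- a[!dup]; b <- b[!dup]
  nodes <- sort(unique(c(a, b)))
  deg <- table(factor(c(a, b), levels = nodes))
  is_patch <- nodes < 0
  is_vertex <- is_patch | deg >= 3
  # walk maximal segments between vertices, suppressing degree-2 cells
  adj <- split(seq_along(a), factor(a, levels = nodes))
  adj2 <- split(seq_along(b), factor(b, levels = nodes))
  inc <- mapply(function(x, y) c(x, y), adj, adj2, SIMPLIFY = FALSE)
  names(inc) <- as.character(nodes)
  other <- function(eid, nd) if (a[eid] == nd) b[eid] else a[eid]
  visited <- rep(FALSE, length(a))
  links <- 0
  link_rows <- list()
  vtx_ids <- nodes[is_vertex]
  for (v in vtx_ids) {
    for (eid in inc[[as.character(v)]]) {
      if (visited[eid]) next
      visited[eid] <- TRUE
      prev <- v
      cur <- other(eid, v)
      while (!(cur %in% vtx_ids)) {
        eids <- inc[[as.character(cur)]]
        nxt <- eids[!visited[eids]]
        if (!length(nxt)) break  # dangling chain end (degree-1 non-patch)
        visited[nxt[1]] <- TRUE
        prev <- cur
        cur <- other(nxt[1], cur)
      }
      # an out-and-back excursion from a patch boundary is not a link:
      # links join two distinct vertices
      if (!identical(v, cur)) {
        links <- links + 1
        link_rows[[links]] <- data.frame(from = v, to = cur)
      }
    }
  }
  # isolated cycles with no vertex on them would be missed; count them
  while (any(!visited)) {
    eid <- which(!visited)[1]
    visited[eid] <- TRUE
    startn <- a[eid]; cur <- b[eid]
    while (cur != startn) {
      eids <- inc[[as.character(cur)]]
      nxt <- eids[!visited[eids]]
      if (!length(nxt)) break
      visited[nxt[1]] <- TRUE
      cur <- other(nxt[1], cur)
    }
    # isolated cycles without a vertex on them carry no pairwise linkage
  }
  V <- sum(is_vertex)
  structure(list(V = as.integer(V), L = as.integer(links),
                 C_km = corridorset$total_length_km,
                 links = do.call(rbind, link_rows)),
            class = "esp_network")
}

#' @export
print.esp_network <- function(x, ...) {
  cat(sprintf("<esp_network> V = %d, L = %d, C = %.2f km\n",
              x$V, x$L, x$C_km))
  invisible(x)
}

#' Network closure index (alpha)
#'
#' `alpha = (L - V + 1) / (2V - 5)`: the ratio of independent loops to the
#' maximum possible. Requires `V >= 3`. A tree (`L = V - 1`) scores 0.
#'
#' @param L link count.
#' @param V vertex count.
#' @return dimensionless real.
#' @export
alpha_index <- function(L, V) {
  if (V < 3) stop("alpha_index requires V >= 3")
  (L - V + 1) / (2 * V - 5)
}

#' Network complexity index (beta)
#'
#' `beta = L / V`, the mean links per vertex. Requires `V >= 1`.
#'
#' @inheritParams alpha_index
#' @return dimensionless real.
#' @export
beta_index <- function(L, V) {
  if (V < 1) stop("beta_index requires V >= 1")
  L / V
}

#' Network connectivity index (gamma)
#'
#' `gamma = L / (3 (V - 2))`: realized links over the maximal-planar
#' possibility; 1 for a maximal planar graph. Requires `V >= 3`.
#'
#' @inheritParams alpha_index
#' @return dimensionless real.
#' @export
gamma_index <- function(L, V) {
  if (V < 3) stop("gamma_index requires V >= 3")
  L / (3 * (V - 2))
}

#' Corridor-network cost ratio
#'
#' `cost ratio = 1 - L / C`, with `L` the corridor count and `C` the total
#' corridor length in km (the mixed dimensions are the convention of this
#' index). Requires `C > 0`.
#'
#' @param L corridor (link) count.
#' @param C total corridor length (km).
#' @return dimensionless real.
#' @export
cost_ratio <- function(L, C) {
  if (C <= 0) stop("cost_ratio requires C > 0")
  1 - L / C
}

#' All four connectivity indices of a network
#'
#' @param network an `esp_network` (or a list with `L`, `V`, `C_km`).
#' @param digits rounding applied for reporting (4 decimals, the customary
#'   precision); use `NULL` for unrounded values.
#' @return data.frame with L, V, C_km, alpha, beta, gamma, cost_ratio.
#' @export
connectivity_indices <- function(network, digits = 4) {
  L <- network$L; V <- network$V; C <- network$C_km
  out <- data.frame(
    L = L, V = V, C_km = C,
    alpha = if (V >= 3) alpha_index(L, V) else NA_real_,
    beta = if (V >= 1) beta_index(L, V) else NA_real_,
    gamma = if (V >= 3) gamma_index(L, V) else NA_real_,
    cost_ratio = if (!is.null(C) && is.finite(C) && C > 0) cost_ratio(L, C)
                 else NA_real_)
  if (!is.null(digits)) {
    idx <- c("alpha", "beta", "gamma", "cost_ratio")
    out[idx] <- lapply(out[idx], round, digits = digits)
  }
  out
}
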