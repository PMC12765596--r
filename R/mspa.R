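#' MSPA parameters
#'
#' Defaults mirror the common connectivity-analysis setup: foreground
#' connectivity 4, edge width 1 cell. The `transition` and `intext` flags
#' are accepted for interface completeness; the classifier implements
#' transition-on semantics and does not subdivide classes into internal and
#' external variants.
#'
#' @param foreground_connectivity 4 or 8; background connectivity is the
#'   geometric complement (4 pairs with 8 and vice versa).
#' @param edge_width boundary width in cells (>= 1).
#' @param transition,intext compatibility flags (see Details).
#' @return an object of class `esp_mspa_params`.
#' @export
mspa_params <- function(foreground_connectivity = 4, edge_width = 1,
                        transition = TRUE, intext = TRUE) {
  if (!foreground_connectivity %in% c(4, 8))
    stop("foreground_connectivity must be 4 or 8")
  if (edge_width < 1) stop("edge_width must be >= 1")
  structure(list(foreground_connectivity = as.integer(foreground_connectivity),
                 edge_width = as.integer(edge_width),
                 transition = isTRUE(transition), intext = isTRUE(intext)),
            class = "esp_mspa_params")
}

#' MSPA class codes
#'
#' Integer codes of the seven foreground classes plus background used in
#' classified grids.
#' @return named integer vector.
#' @export
mspa_classes <- function() {
  c(background = 0L, core = 1L, islet = 2L, edge = 3L, perforation = 4L,
    bridge = 5L, loop = 6L, branch = 7L)
}

#' Morphological spatial pattern analysis
#'
#' Classifies a binary foreground raster into core, islet, edge,
#' perforation, bridge, loop and branch, the structural classes used for
#' connectivity-based ecological-source identification. The classification
#' partitions the foreground: every foreground cell receives exactly one
#' class; background (and off-grid, which counts as background) stays
#' background.
#'
#' Definitions: core cells survive `edge_width` erosions with the
#' structuring element complementary to the foreground connectivity
#' (foreground 4-connectivity pairs with the 8-neighbour box element);
#' islets are foreground components containing no core; edge and
#' perforation are the non-core cells within `edge_width` of a core
#' component, split by whether they border the outer background or an
#' enclosed hole; the remaining connector cells form bridges (touching >= 2
#' distinct core components through their boundary zones), loops (touching
#' one core component at >= 2 mutually non-adjacent contact cells) or
#' branches (all other connectors).
#'
#' @param g binary `esp_grid` (values 0, 1 or `NA`).
#' @param params an [mspa_params()] object.
#' @return an `esp_grid` of [mspa_classes()] codes (`NA` propagates).
#' @export
classify_mspa <- function(g, params = mspa_params()) {
  stopifnot(is_grid(g))
  v <- g$values
  if (any(!is.na(v) & !(v %in% c(0, 1))))
    stop("classify_mspa expects a binary grid (0/1/NA)")
  fg <- !is.na(v) & v == 1
  conn <- params$foreground_connectivity
  se <- if (conn == 4) 8L else 4L        # complementary structuring element
  bg_conn <- if (conn == 4) 8L else 4L   # Jordan-consistent background conn
  w <- params$edge_width
  cls <- mspa_classes()
  out <- matrix(cls[["background"]], nrow(v), ncol(v))

  if (any(fg)) {
    # core: survives w erosions (off-grid is background)
    core <- fg
    for (i in seq_len(w)) core <- cpp_erode(core, se)

    # islet: foreground components without core
    lab_fg <- cpp_label_components(fg, conn)
    core_comps <- unique(lab_fg[core])
    islet <- fg & !(lab_fg %in% core_comps)
    dim(islet) <- dim(fg)

    # boundary zone: non-core, non-islet cells geodesically within w steps
    # of a core component; carries that component's label
    lab_core <- cpp_label_components(core, conn)
    allowed <- fg & !core & !islet
    ext <- cpp_dilate_labels(lab_core, allowed, w, se)
    zone <- ext > 0 & !core
    dim(zone) <- dim(fg)

    # outer vs hole background via a padded background labelling
    nr <- nrow(fg); nc <- ncol(fg)
    padbg <- matrix(TRUE, nr + 2, nc + 2)
    padbg[2:(nr + 1), 2:(nc + 1)] <- !fg
    lab_bg <- cpp_label_components(padbg, bg_conn)
    outer_id <- lab_bg[1, 1]
    outer_bg <- matrix(FALSE, nr, nc)
    outer_bg[] <- (lab_bg[2:(nr + 1), 2:(nc + 1)] == outer_id) & !fg
    hole_bg <- !fg & !outer_bg
    # pad the outer mask so border foreground cells see off-grid background
    pad_outer <- matrix(TRUE, nr + 2, nc + 2)
    pad_outer[2:(nr + 1), 2:(nc + 1)] <- outer_bg
    near_outer <- reach_within(pad_outer, rbind(FALSE, cbind(FALSE, fg, FALSE), FALSE), w, se)
    near_outer <- near_outer[2:(nr + 1), 2:(nc + 1)]
    near_hole <- reach_within(hole_bg, fg, w, se)

    connector <- fg & !core & !islet & !zone

    out[core] <- cls[["core"]]
    out[islet] <- cls[["islet"]]
    out[zone & near_outer] <- cls[["edge"]]
    out[zone & !near_outer & near_hole] <- cls[["perforation"]]
    # zone cells near neither (possible only for w > 1 with exotic
    # geometry) default to edge
    out[zone & !near_outer & !near_hole] <- cls[["edge"]]

    if (any(connector)) {
      lab_conn <- cpp_label_components(connector, conn)
      # cells carrying a core-component identity: core itself + its zone
      anchor <- matrix(0L, nr, nc)
      anchor[lab_core > 0] <- lab_core[lab_core > 0]
      anchor[zone] <- ext[zone]
      off <- neighbor_offsets()[seq_len(conn), ]
      for (id in seq_len(max(lab_conn))) {
        cells <- which(lab_conn == id, arr.ind = TRUE)
        touched <- integer(0)
        contact <- logical(nrow(cells))
        for (k in seq_len(nrow(off))) {
          r2 <- cells[, 1] + off$dr[k]; c2 <- cells[, 2] + off$dc[k]
          ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
          ids <- rep(0L, nrow(cells))
          ids[ok] <- anchor[cbind(r2[ok], c2[ok])]
          touched <- union(touched, ids[ids > 0])
          contact <- contact | ids > 0
        }
        code <- if (length(touched) >= 2) {
          cls[["bridge"]]
        } else if (length(touched) == 1) {
          # loop needs >= 2 contact cells mutually non-adjacent under 8-conn
          cmask <- matrix(FALSE, nr, nc)
          cmask[cells[contact, , drop = FALSE]] <- TRUE
          ncc <- max(cpp_label_components(cmask, 8L))
          if (ncc >= 2) cls[["loop"]] else cls[["branch"]]
        } else {
          cls[["branch"]]  # attached only through other connectors
        }
        out[lab_conn == id] <- code
      }
    }
  }
  out[is.na(v)] <- NA_real_
  grid_like(g, out)
}

# Can a fg cell reach a target-mask cell within `steps` dilations of the
# target under structuring element `se`? (plain dilation, not geodesic)
reach_within <- function(target, fg, steps, se) {
  m <- target
  for (i in seq_len(steps)) m <- cpp_dilate(m, se)
  m & fg
}

#' Summarize an MSPA classification
#'
#' @param class_grid grid returned by [classify_mspa()].
#' @return data.frame with per-class cell counts and areas (km^2); class
#'   counts over the seven foreground classes sum to the foreground count.
#' @export
mspa_summary <- function(class_grid) {
  stopifnot(is_grid(class_grid))
  cls <- mspa_classes()
  v <- class_grid$values
  counts <- vapply(cls, function(code) sum(!is.na(v) & v == code), numeric(1))
  data.frame(class = names(cls), code = unname(cls),
             cells = unname(counts),
             area_km2 = unname(counts) * (class_grid$cellsize / 1000)^2,
             row.names = NULL)
}
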