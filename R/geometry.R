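#' Segment cells from the skeletonized junction network
#'
#' Cells are the 4-connected components of the skeleton's complement.
#' Components touching the image border are flagged and excluded from
#' monolayer summaries by default.
#'
#' @param skel logical skeleton matrix (or a `tj_graph`, whose stored
#'   skeleton is used).
#' @return object of class `tj_cells`: `table` (id, area_px, centroid,
#'   border, AR and per-region perimeter estimate) and `labels` (label
#'   matrix, 0 on the skeleton).
#' @export
segment_cells <- function(skel) {
  if (inherits(skel, "tj_graph")) skel <- skel$skeleton
  skel <- skel != 0
  H <- nrow(skel); W <- ncol(skel)
  lab <- label_components(!skel, connectivity = 4)
  n <- max(lab)
  if (n == 0) stopf("no interior components found in the skeleton complement")
  area <- tabulate(lab, nbins = n)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  lv <- as.vector(lab)
  keep <- lv > 0
  sr <- rowsum(as.vector(rows)[keep], lv[keep])[, 1]
  sc <- rowsum(as.vector(cols)[keep], lv[keep])[, 1]
  border_ids <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  border_ids <- border_ids[border_ids > 0]
  tab <- data.frame(id = seq_len(n), area_px = area,
                    centroid_row = sr / area, centroid_col = sc / area,
                    border = seq_len(n) %in% border_ids)
  if (all(tab$border)) stopf("no interior cell found (all touch the border)")
  tab$AR <- region_aspect_ratio(lab, n)
  tab$perim_px <- region_perimeter(lab, n)
  structure(list(table = tab, labels = lab), class = "tj_cells")
}

# Aspect ratio per labeled region from the second-central-moment ellipse,
# with the 1/12 pixel-extent correction so exact rectangles come out exact.
region_aspect_ratio <- function(lab, n = max(lab)) {
  H <- nrow(lab)
  idx <- which(lab > 0)
  l <- lab[idx]
  rc <- rc_from_idx(idx, H)
  area <- tabulate(l, nbins = n)
  mr <- rowsum(rc[, 1], l)[, 1] / area[sort(unique(l))]
  out <- rep(NA_real_, n)
  sl <- sort(unique(l))
  mr <- rowsum(as.numeric(rc[, 1]), l)[, 1] / area[sl]
  mc <- rowsum(as.numeric(rc[, 2]), l)[, 1] / area[sl]
  names(mr) <- names(mc) <- sl
  dr <- rc[, 1] - mr[as.character(l)]
  dc <- rc[, 2] - mc[as.character(l)]
  srr <- rowsum(dr * dr, l)[, 1] / area[sl] + 1 / 12
  scc <- rowsum(dc * dc, l)[, 1] / area[sl] + 1 / 12
  src <- rowsum(dr * dc, l)[, 1] / area[sl]
  tr <- srr + scc
  det <- srr * scc - src^2
  disc <- pmax(tr^2 / 4 - det, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr / 2 - sqrt(disc)
  ar <- ifelse(l2 <= 0, Inf, sqrt(l1 / l2))
  out[sl] <- ar
  out
}

# Perimeter per labeled region from the traced outer contour: weighted
# chain length (1 per axial step, sqrt(2) per diagonal) scaled by the
# classical 0.948 staircase-bias factor, plus pi for the half-pixel
# Minkowski dilation from pixel centers to pixel edges. Calibrated for
# convex, isotropically oriented regions (epithelial cell profiles);
# axis-aligned rectangles are underestimated by a few percent.
region_perimeter <- function(lab, n = max(lab)) {
  out <- rep(NA_real_, n)
  oc <- EBImage::ocontour(EBImage::Image(lab))
  for (nm in seq_along(oc)) {
    ct <- oc[[nm]]
    if (is.null(ct) || nrow(ct) < 2) { out[nm] <- 4; next }
    ct2 <- rbind(ct, ct[1, ])
    dr <- abs(diff(ct2[, 1])); dc <- abs(diff(ct2[, 2]))
    chain <- sum(ifelse(dr + dc == 2, sqrt(2), pmax(dr + dc, 0)))
    out[nm] <- 0.948 * chain + pi
  }
  out
}

#' Attach cell incidence to a junction graph
#'
#' Links every edge to the (at most two) cells flanking its pixel path and
#' every vertex to the union of its incident edges' cells, and records the
#' cell-adjacency pairs implied by shared edges.
#'
#' @param graph a `tj_graph`.
#' @param cells a `tj_cells` segmentation from the same skeleton.
#' @return the graph, with `edges[[i]]$cells`, `vertex_cells` (list) and
#'   `cell_adjacency` (two-column matrix) filled in.
#' @export
link_cells <- function(graph, cells) {
  lab <- cells$labels
  H <- nrow(lab); W <- ncol(lab)
  for (i in seq_along(graph$edges)) {
    e <- graph$edges[[i]]
    labs <- integer(0)
    p <- e$path
    pr <- rep(p[, 1], each = 4) + rep(OFFS4[, 1], nrow(p))
    pc <- rep(p[, 2], each = 4) + rep(OFFS4[, 2], nrow(p))
    ok <- pr >= 1 & pr <= H & pc >= 1 & pc <= W
    labs <- lab[cbind(pr[ok], pc[ok])]
    labs <- labs[labs > 0]
    if (length(labs)) {
      tt <- sort(table(labs), decreasing = TRUE)
      graph$edges[[i]]$cells <- as.integer(names(tt))[seq_len(min(2, length(tt)))]
    }
  }
  nv <- nrow(graph$vertices)
  vc <- vector("list", nv)
  for (e in graph$edges) {
    for (v in c(e$v1, e$v2)) {
      if (!is.na(v)) vc[[v]] <- union(vc[[v]], e$cells)
    }
  }
  # include labels directly around the vertex cluster (covers tiny edges)
  for (v in seq_len(nv)) {
    px <- graph$vertex_pixels[[v]]
    if (is.null(px)) next
    rc <- rc_from_idx(px, H)
    pr <- rep(rc[, 1], each = 8) + rep(OFFS8[, 1], nrow(rc))
    pc <- rep(rc[, 2], each = 8) + rep(OFFS8[, 2], nrow(rc))
    ok <- pr >= 1 & pr <= H & pc >= 1 & pc <= W
    labs <- lab[cbind(pr[ok], pc[ok])]
    vc[[v]] <- sort(union(vc[[v]], labs[labs > 0]))
  }
  graph$vertex_cells <- vc
  prs <- do.call(rbind, lapply(graph$edges, function(e)
    if (length(e$cells) == 2) sort(e$cells) else NULL))
  graph$cell_adjacency <- if (is.null(prs)) matrix(integer(0), 0, 2) else
    unique(prs)
  graph
}

#' Polygonal representation of segmented cells
#'
#' Each interior cell's incident vertices (relocated coordinates, plus any
#' auxiliary points added by an edit script) are ordered by angle about the
#' region centroid. Polygons that self-intersect (strongly concave cells)
#' are flagged `non_polygonal`; their shape metrics fall back to the
#' pixel-region estimates.
#'
#' @param cells a `tj_cells`.
#' @param graph a `tj_graph` after [link_cells()].
#' @return `cells` with columns `A_poly`, `p_poly`, `n_vertices`,
#'   `non_polygonal` added to the table and a `polygons` list (vertex id
#'   vectors, auxiliary points as negative indices into `graph$aux_points`).
#' @export
polygonize <- function(cells, graph) {
  if (is.null(graph$vertex_cells))
    stopf("graph has no cell incidence; call link_cells() first")
  tab <- cells$table
  n <- nrow(tab)
  member <- vector("list", n)
  for (v in seq_along(graph$vertex_cells))
    for (cid in graph$vertex_cells[[v]])
      if (cid >= 1 && cid <= n) member[[cid]] <- c(member[[cid]], v)
  aux_by_cell <- list()
  for (ai in seq_along(graph$aux_points)) {
    cid <- as.character(graph$aux_points[[ai]]$cell_id)
    aux_by_cell[[cid]] <- c(aux_by_cell[[cid]], ai)
  }
  tab$A_poly <- NA_real_; tab$p_poly <- NA_real_
  tab$n_vertices <- 0L; tab$non_polygonal <- FALSE
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    vs <- unique(member[[i]])
    aux <- aux_by_cell[[as.character(i)]]
    pts <- NULL
    ids <- integer(0)
    if (length(vs)) {
      pts <- cbind(graph$vertices$relocated_row[vs],
                   graph$vertices$relocated_col[vs])
      ids <- vs
    }
    if (length(aux)) {
      apts <- do.call(rbind, lapply(graph$aux_points[aux], function(a)
        c(a$row, a$col)))
      pts <- rbind(pts, apts)
      ids <- c(ids, -aux)
    }
    tab$n_vertices[i] <- length(ids)
    if (tab$border[i] || length(ids) < 3) {
      tab$non_polygonal[i] <- !tab$border[i]
      next
    }
    ang <- atan2(pts[, 1] - tab$centroid_row[i], pts[, 2] - tab$centroid_col[i])
    o <- order(ang)
    pts <- pts[o, , drop = FALSE]
    ids <- ids[o]
    if (.polygon_self_intersects(pts)) {
      tab$non_polygonal[i] <- TRUE
      next
    }
    tab$A_poly[i] <- polygon_area(pts)
    tab$p_poly[i] <- polygon_perimeter(pts)
    polys[[i]] <- ids
  }
  cells$table <- tab
  cells$polygons <- polys
  cells
}

#' Shoelace area of a polygon given as (row, col) points
#' @param pts two-column matrix of ordered polygon points.
#' @export
polygon_area <- function(pts) {
  x <- pts[, 2]; y <- pts[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Euclidean perimeter of a polygon given as (row, col) points
#' @param pts two-column matrix of ordered polygon points.
#' @export
polygon_perimeter <- function(pts) {
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
  sum(d)
}

.polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  if (n < 4) return(FALSE)
  seg <- function(i) rbind(pts[i, ], pts[if (i == n) 1 else i + 1, ])
  inter <- function(p1, p2, p3, p4) {
    d1 <- (p4[2] - p3[2]) * (p1[1] - p3[1]) - (p4[1] - p3[1]) * (p1[2] - p3[2])
    d2 <- (p4[2] - p3[2]) * (p2[1] - p3[1]) - (p4[1] - p3[1]) * (p2[2] - p3[2])
    d3 <- (p2[2] - p1[2]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[2] - p1[2])
    d4 <- (p2[2] - p1[2]) * (p4[1] - p1[1]) - (p2[1] - p1[1]) * (p4[2] - p1[2])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    si <- seg(i)
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent via wraparound
      sj <- seg(j)
      if (inter(si[1, ], si[2, ], sj[1, ], sj[2, ])) return(TRUE)
    }
  }
  FALSE
}

#' Apical shape index
#'
#' `q_a = p_a / sqrt(A_a)`: dimensionless, scale-invariant; lower and more
#' uniform values indicate jammed (regular, compact) cells. The
#' isoperimetric bound is `2 * sqrt(pi) ~ 3.545` (disk); a regular hexagon
#' gives ~3.722, a square 4.
#'
#' @param perimeter,area numeric vectors (same units of length and
#'   length^2).
#' @return numeric vector of shape indices.
#' @export
#' @examples
#' shape_index(4, 1)                 # unit square: 4
#' shape_index(6, 3 * sqrt(3) / 2)   # regular hexagon, side 1
shape_index <- function(perimeter, area) {
  if (any(area <= 0, na.rm = TRUE)) stopf("area must be positive")
  perimeter / sqrt(area)
}

#' Cell-level geometry table
#'
#' Combines polygon and pixel-region measures into the per-cell record:
#' areas and perimeters (polygon where available, else pixel region),
#' apical shape index, aspect ratio, and physical units.
#'
#' @param cells a `tj_cells` after [polygonize()] (plain segmentations are
#'   accepted; all metrics then use pixel-region estimates).
#' @param pixel_size micrometres per pixel.
#' @return data frame, one row per cell.
#' @export
cell_geometry <- function(cells, pixel_size = 1) {
  tab <- cells$table
  if (is.null(tab$A_poly)) {
    tab$A_poly <- NA_real_; tab$p_poly <- NA_real_
    tab$non_polygonal <- FALSE
  }
  use_poly <- !is.na(tab$A_poly) & !tab$non_polygonal
  A_px <- ifelse(use_poly, tab$A_poly, tab$area_px)
  p_px <- ifelse(use_poly, tab$p_poly, tab$perim_px)
  data.frame(id = tab$id,
             centroid_row = tab$centroid_row,
             centroid_col = tab$centroid_col,
             A_px = A_px, p_px = p_px,
             A_um2 = A_px * pixel_size^2, p_um = p_px * pixel_size,
             q_a = shape_index(p_px, A_px),
             AR = tab$AR,
             polygonal = use_poly,
             border = tab$border)
}

#' Monolayer summary of the jamming descriptors
#'
#' Means and dispersion of the shape descriptors over (by default) interior
#' cells, and the cell density `sigma` in cells per mm^2. The density
#' denominator is the imaged area minus border-cell pixels, so `sigma`
#' reflects interior packing; with `include_border = TRUE` all cells are
#' counted over the full imaged area.
#'
#' @param cells a `tj_cells` (after [polygonize()] for polygon metrics).
#' @param pixel_size micrometres per pixel.
#' @param image_dim image extent `c(H, W)`; defaults to the label matrix
#'   extent.
#' @param include_border count border cells and the full image area.
#' @return one-row data frame: n_cells, sigma (cells/mm^2), mean_q_a,
#'   mean_AR, sd_AR, mean_area_um2.
#' @export
summarize_monolayer <- function(cells, pixel_size = 1, image_dim = NULL,
                                include_border = FALSE) {
  geo <- cell_geometry(cells, pixel_size)
  if (is.null(image_dim)) image_dim <- dim(cells$labels)
  total_px <- prod(image_dim)
  if (include_border) {
    sel <- rep(TRUE, nrow(geo))
    denom_px <- total_px
  } else {
    sel <- !geo$border
    denom_px <- total_px - sum(cells$table$area_px[cells$table$border])
  }
  if (!any(sel)) stopf("no cells to summarize")
  area_mm2 <- denom_px * (pixel_size / 1000)^2
  data.frame(n_cells = sum(sel),
             sigma = sum(sel) / area_mm2,
             mean_q_a = mean(geo$q_a[sel], na.rm = TRUE),
             mean_AR = mean(geo$AR[sel & is.finite(geo$AR)]),
             sd_AR = stats::sd(geo$AR[sel & is.finite(geo$AR)]),
             mean_area_um2 = mean(geo$A_um2[sel]))
}
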