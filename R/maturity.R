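#' Score tricellulin localization at every vertex
#'
#' For each vertex, the tricellular mask is a disc of radius `r_tri` at the
#' relocated coordinates intersected with a dilation of the junction
#' skeleton; the bicellular mask is the incident edges' pixel paths dilated
#' by `w_bi`, intersected with the binarized junction foreground, excluding
#' every tricellular disc. The localization score is the normalized ratio
#'
#'   `T_L = I_tri / (I_tri + I_bi)`
#'
#' of the mean contrast-adjusted tricellular intensities over the two masks:
#' 0.5 when the marker is evenly spread along junctions, -> 1 under pure
#' vertex enrichment, -> 0 under exclusion from the vertex, and 0 when both
#' means vanish. `tl_form = "raw-clipped"` instead computes
#' `min(I_tri / I_bi, 1)` for sensitivity analysis. Vertices with an empty
#' mask are flagged `unscorable` and carry `NA`, never silently dropped.
#'
#' @param graph a `tj_graph` (after [relocate_vertices()]; unrelocated
#'   vertices are scored at their skeleton coordinates).
#' @param tric_adjusted contrast-adjusted tricellular image.
#' @param boundary logical boundary map from [binarize_junctions()].
#' @param r_tri tricellular disc radius (px).
#' @param w_bi bicellular ribbon half-width (px).
#' @param tl_form `"normalized"` (default) or `"raw-clipped"`.
#' @return data frame (one row per vertex): vertex_id, coordinates, I_tri,
#'   I_bi, T_L, mask areas, unscorable flag.
#' @export
score_vertices <- function(graph, tric_adjusted, boundary, r_tri = 4,
                           w_bi = 2, tl_form = c("normalized", "raw-clipped")) {
  tl_form <- match.arg(tl_form)
  img <- as_intensity_matrix(tric_adjusted, "tric")
  H <- graph$dim[1]
  vt <- graph$vertices
  coords <- cbind(vt$relocated_row, vt$relocated_col)
  edge_px <- vector("list", nrow(vt))
  for (e in graph$edges) {
    px <- idx_from_rc(e$path, H)
    for (v in c(e$v1, e$v2))
      if (!is.na(v)) edge_px[[v]] <- c(edge_px[[v]], px)
  }
  sc <- tl_score_engine(coords, edge_px, graph$skeleton, boundary != 0, img,
                        r_tri = r_tri, w_bi = w_bi, tl_form = tl_form)
  data.frame(vertex_id = vt$id, row = coords[, 1], col = coords[, 2],
             degree = vt$degree, border = vt$border,
             unrelocated = vt$unrelocated,
             I_tri = sc$I_tri, I_bi = sc$I_bi, T_L = sc$T_L,
             n_tri_px = sc$n_tri, n_bi_px = sc$n_bi,
             unscorable = sc$unscorable)
}

#' Aggregate vertex scores per cell
#'
#' The cell-level score is the unweighted mean of the localization score
#' over the cell's incident scored vertices; cells with none get `NA`.
#'
#' @param graph a `tj_graph` after [link_cells()].
#' @param vertex_scores result of [score_vertices()].
#' @return data frame: cell_id, T_L_cell, n_vertices_scored.
#' @export
score_cells <- function(graph, vertex_scores) {
  if (is.null(graph$vertex_cells))
    stopf("graph has no cell incidence; call link_cells() first")
  n <- max(c(0L, unlist(graph$vertex_cells)))
  acc <- rep(0, n); cnt <- integer(n)
  for (v in seq_along(graph$vertex_cells)) {
    tl <- vertex_scores$T_L[vertex_scores$vertex_id == v]
    if (!length(tl) || is.na(tl)) next
    for (cid in graph$vertex_cells[[v]]) {
      acc[cid] <- acc[cid] + tl
      cnt[cid] <- cnt[cid] + 1L
    }
  }
  data.frame(cell_id = seq_len(n),
             T_L_cell = ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_),
             n_vertices_scored = cnt)
}

#' Assign wound-front rows by adjacency distance from the leader
#'
#' The leader cell is row 1, its immediate followers row 2, and so on: the
#' row is `1 +` the breadth-first distance in the cell-adjacency graph
#' (cells adjacent iff they share a junction edge). Multiple leader ids are
#' accepted (several migration fingers in one field); distances are then
#' taken to the nearest leader. Unreachable cells get `NA`.
#'
#' @param adjacency two-column matrix of adjacent cell-id pairs (e.g.
#'   `graph$cell_adjacency` after [link_cells()], or the ground-truth
#'   adjacency).
#' @param leader_cell_id one or more leader cell ids.
#' @return data frame: cell_id, row.
#' @export
assign_rows <- function(adjacency, leader_cell_id) {
  adjacency <- as.matrix(adjacency)
  ids <- sort(unique(c(as.integer(adjacency), as.integer(leader_cell_id))))
  g <- igraph::graph_from_edgelist(matrix(as.character(adjacency), ncol = 2),
                                   directed = FALSE)
  missing <- setdiff(as.character(ids), igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                 name = missing)
  dd <- igraph::distances(g, v = as.character(leader_cell_id))
  d <- apply(dd, 2, min)
  row <- d[as.character(ids)] + 1
  row[is.infinite(row)] <- NA_real_
  data.frame(cell_id = ids, row = as.numeric(row))
}

#' Row-resolved profile of cell area and localization score
#'
#' Per-row means with their standard errors, plus an interior reference
#' (mean over cells at least `interior_reference_row` rows from the
#' leader).
#'
#' @param rows data frame from [assign_rows()].
#' @param cell_tl data frame from [score_cells()].
#' @param cell_areas data frame with `id` and an area column (`A_um2` or
#'   `A_px`), e.g. from [cell_geometry()].
#' @param interior_reference_row rows >= this form the interior reference.
#' @return list: `profile` (row, n, mean_area, sem_area, mean_TL, sem_TL)
#'   and `reference` (means over the interior region, `NA` when absent).
#' @export
rowwise_profile <- function(rows, cell_tl, cell_areas,
                            interior_reference_row = 15) {
  area_col <- intersect(c("A_um2", "A_px", "area_px"), names(cell_areas))[1]
  if (is.na(area_col)) stopf("cell_areas must contain an area column")
  m <- merge(rows, cell_tl, by = "cell_id", all.x = TRUE)
  m <- merge(m, data.frame(cell_id = cell_areas$id,
                           area = cell_areas[[area_col]]),
             by = "cell_id", all.x = TRUE)
  m <- m[!is.na(m$row), ]
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  prof <- do.call(rbind, lapply(split(m, m$row), function(d) data.frame(
    row = d$row[1], n = nrow(d),
    mean_area = mean(d$area, na.rm = TRUE), sem_area = sem(d$area),
    mean_TL = mean(d$T_L_cell, na.rm = TRUE), sem_TL = sem(d$T_L_cell))))
  rownames(prof) <- NULL
  ref <- m[m$row >= interior_reference_row, ]
  list(profile = prof[order(prof$row), ],
       reference = data.frame(
         n = nrow(ref),
         mean_area = if (nrow(ref)) mean(ref$area, na.rm = TRUE) else NA_real_,
         mean_TL = if (nrow(ref)) mean(ref$T_L_cell, na.rm = TRUE) else NA_real_))
}

#' Partition vertices by the cell-cycle label of their incident cells
#'
#' A vertex is label-homogeneous (synchronized) when all incident cells
#' carry the same label, including degree-4 vertices, which must agree over
#' all four cells; it is `"mixed"` otherwise. Vertices with any unlabeled
#' incident cell are excluded (`NA`).
#'
#' @param graph a `tj_graph` after [link_cells()].
#' @param cell_labels data frame with columns `cell_id` and `label`.
#' @return data frame: vertex_id, group (label, `"mixed"`, or `NA`).
#' @export
triplet_by_label <- function(graph, cell_labels) {
  if (is.null(graph$vertex_cells))
    stopf("graph has no cell incidence; call link_cells() first")
  lut <- stats::setNames(as.character(cell_labels$label),
                         as.character(cell_labels$cell_id))
  grp <- vapply(seq_along(graph$vertex_cells), function(v) {
    cs <- graph$vertex_cells[[v]]
    if (length(cs) < 3) return(NA_character_)
    ls <- lut[as.character(cs)]
    if (any(is.na(ls))) return(NA_character_)
    if (length(unique(ls)) == 1) ls[1] else "mixed"
  }, character(1))
  data.frame(vertex_id = seq_along(grp), group = grp)
}

#' Two-sample two-sided Kolmogorov-Smirnov comparison
#'
#' Compares two sets of localization scores (or any samples) with the
#' two-sided two-sample KS test: sensitive to both location and shape of
#' the distributions. Exact p-values are used when `n_a * n_b <= 10^4`,
#' the asymptotic approximation otherwise.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with `D` (the ECDF sup-difference) and `p.value`.
#' @export
compare_groups <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stopf("both groups need at least 2 non-missing values")
  exact <- length(a) * length(b) <= 1e4
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                        exact = exact))
  list(D = unname(kt$statistic), p.value = kt$p.value)
}

#' Normalize grouped scores to a control group
#'
#' Divides every group's values by the mean of the control group, so the
#' control's normalized mean is exactly 1. Rank-based comparisons (KS) are
#' unchanged by this common positive rescaling.
#'
#' @param values numeric vector of scores.
#' @param groups vector of group labels aligned with `values`.
#' @param control_label label of the reference group.
#' @return data frame: value, normalized, group.
#' @export
normalize_to_control <- function(values, groups, control_label) {
  sel <- groups == control_label & !is.na(values)
  if (!any(sel)) stopf("control group '%s' is empty", control_label)
  m <- mean(values[sel])
  if (m <= 0) stopf("control group mean must be positive")
  data.frame(value = values, normalized = values / m, group = groups)
}
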