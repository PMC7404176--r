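#' Binarize the junctional channel
#'
#' Junction (ZO-1-like) signal forms thin bright lines over a dark
#' background whose intensity varies across the field, so the default is a
#' local adaptive threshold (pixel > local mean + offset) with a global Otsu
#' fallback. Gaps are closed morphologically and isolated specks below
#' `min_object_area` removed.
#'
#' @param zo1 projected junctional image (matrix or `tj_projection`).
#' @param sensitivity offset above the local mean, as a fraction of the
#'   image maximum (adaptive method) — smaller values detect fainter lines.
#' @param min_object_area connected foreground objects smaller than this
#'   (px^2) are discarded.
#' @param close_radius radius (px) of the disc used for morphological
#'   closing; 0 disables closing.
#' @param window half-width (px) of the local-mean window for the adaptive
#'   threshold.
#' @param method `"adaptive"` (default) or `"otsu"`.
#' @return logical matrix (boundary map).
#' @export
binarize_junctions <- function(zo1, sensitivity = 0.1, min_object_area = 64,
                               close_radius = 2, window = 15,
                               method = c("adaptive", "otsu")) {
  method <- match.arg(method)
  img <- as_intensity_matrix(zo1, "zo1")
  mx <- max(img)
  if (mx <= 0)
    stopf("junction image has no signal; adjust sensitivity or check input")
  norm <- img / mx
  mask <- if (method == "adaptive") {
    EBImage::imageData(EBImage::thresh(norm, w = window, h = window,
                                       offset = sensitivity)) > 0
  } else {
    norm > EBImage::otsu(EBImage::Image(norm))
  }
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2 * close_radius + 1, "disc")
    mask <- EBImage::imageData(EBImage::closing(mask * 1, brush)) > 0
  }
  lab <- label_components(mask, connectivity = 8)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_object_area)
  mask <- matrix(lab %in% keep, nrow(img), ncol(img))
  if (!any(mask))
    stopf("binarization produced an empty foreground; lower sensitivity")
  mask
}

# One Zhang-Suen subiteration, vectorised over the whole image.
.zs_pass <- function(m, sub) {
  P2 <- shift_mat(m, 1, 0); P3 <- shift_mat(m, 1, -1)
  P4 <- shift_mat(m, 0, -1); P5 <- shift_mat(m, -1, -1)
  P6 <- shift_mat(m, -1, 0); P7 <- shift_mat(m, -1, 1)
  P8 <- shift_mat(m, 0, 1); P9 <- shift_mat(m, 1, 1)
  # P2 = north neighbor: value of the pixel above, i.e. matrix shifted down
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
    (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
    (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
  cond <- m == 1 & B >= 2 & B <= 6 & A == 1
  if (sub == 1) {
    cond <- cond & (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
  } else {
    cond <- cond & (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
  }
  cond
}

# Crossing number (0->1 transitions around the 8-neighborhood) of one pixel.
.crossing_number <- function(m, r, c) {
  seq8 <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  v <- m[cbind(r + seq8[, 1], c + seq8[, 2])]
  sum(v == 1 & c(v[-1], v[1]) == 0)
}

#' Topology-preserving skeletonization (thinning)
#'
#' Reduces a binary boundary network to single-pixel-wide, 8-connected
#' lines using Zhang-Suen thinning, followed by a cleanup pass that removes
#' redundant pixels from any remaining fully-foreground 2x2 block when
#' deletion does not change local connectivity. The operation preserves the
#' number of connected components and holes and is idempotent.
#'
#' @param boundary logical or 0/1 matrix (from [binarize_junctions()]).
#' @return logical matrix: the skeleton.
#' @export
skeletonize <- function(boundary) {
  m0 <- (as_intensity_matrix(boundary * 1, "boundary") != 0) * 1L
  if (!any(m0 == 1)) stopf("boundary map is empty")
  H <- nrow(m0); W <- ncol(m0)
  # pad so border pixels have full neighborhoods
  m <- matrix(0L, H + 2, W + 2)
  m[2:(H + 1), 2:(W + 1)] <- m0
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      del <- .zs_pass(m, sub)
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  # cleanup: dissolve remaining 2x2 solid blocks one simple pixel at a time
  repeat {
    solid <- m[-nrow(m), -ncol(m)] & m[-nrow(m), -1] &
      m[-1, -ncol(m)] & m[-1, -1]
    idx <- which(solid)
    if (!length(idx)) break
    removed <- FALSE
    rc <- rc_from_idx(idx, nrow(m) - 1L)
    for (i in seq_len(nrow(rc))) {
      for (off in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
        r <- rc[i, 1] + off[1]; c <- rc[i, 2] + off[2]
        if (m[r, c] == 1 && .crossing_number(m, r, c) == 1) {
          m[r, c] <- 0L
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) break  # no simple pixel available; keep topology
  }
  m[2:(H + 1), 2:(W + 1)] == 1
}

#' Detect candidate tricellular vertices by pixel counting
#'
#' A skeleton pixel whose 8-neighborhood holds three or more separate
#' skeleton branches marks a nodal point where lines cross. Branches are
#' counted with the crossing number (0-to-1 transitions around the
#' neighborhood ring), which ignores the staircase turns a thinned diagonal
#' line produces. Adjacent vertex pixels (thinning can yield 2-pixel
#' junction clusters) are merged into a single vertex whose position is the
#' cluster centroid snapped to the nearest skeleton pixel of the cluster.
#'
#' @param skel logical skeleton matrix from [skeletonize()].
#' @return object of class `tj_vertices`: data frame `table` (id, row, col,
#'   n_pixels) plus the per-vertex cluster pixel indices in `pixels`.
#' @export
detect_vertices <- function(skel) {
  skel <- skel != 0
  # count branches with the path-adjacency of the skeleton: all axial
  # neighbors, plus diagonal neighbors only when the step is not a shortcut
  # past an orthogonal skeleton pixel. A pixel where >= 3 such branches
  # meet is a nodal point; this also catches junctions whose plain
  # 8-neighborhood ring shows fewer than 3 transitions (the stem of a T
  # joining between two bar pixels).
  adj <- .segment_adjacency(skel, skel)
  deg <- lengths(adj$nbrs)
  vpix <- matrix(FALSE, nrow(skel), ncol(skel))
  vpix[adj$idx[deg >= 3]] <- TRUE
  H <- nrow(skel)
  if (!any(vpix)) {
    return(structure(list(table = data.frame(id = integer(0), row = numeric(0),
                                             col = numeric(0),
                                             n_pixels = integer(0)),
                          pixels = list()), class = "tj_vertices"))
  }
  lab <- label_components(vpix, connectivity = 8)
  k <- max(lab)
  idx <- which(lab > 0)
  by_cl <- split(idx, lab[idx])
  # merge clusters closer than 2 px (Chebyshev): a near-degenerate four-way
  # contact thins into two branch-pixel clusters separated by a single path
  # pixel; they are one nodal point (retained with its full degree)
  if (k > 1) {
    ctr <- t(vapply(by_cl, function(px) colMeans(rc_from_idx(px, H)),
                    numeric(2)))
    gp <- igraph::make_empty_graph(k, directed = FALSE)
    prx <- which(outer(ctr[, 1], ctr[, 1], function(a, b) abs(a - b)) <= 3 &
                   outer(ctr[, 2], ctr[, 2], function(a, b) abs(a - b)) <= 3 &
                   upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    if (nrow(prx)) {
      near <- vapply(seq_len(nrow(prx)), function(i) {
        a <- rc_from_idx(by_cl[[prx[i, 1]]], H)
        b <- rc_from_idx(by_cl[[prx[i, 2]]], H)
        min(pmax(abs(outer(a[, 1], b[, 1], "-")),
                 abs(outer(a[, 2], b[, 2], "-")))) <= 2
      }, logical(1))
      if (any(near)) gp <- igraph::add_edges(gp, t(prx[near, , drop = FALSE]))
    }
    memb <- igraph::components(gp)$membership
    by_cl <- lapply(seq_len(max(memb)), function(m)
      unlist(by_cl[memb == m], use.names = FALSE))
    k <- length(by_cl)
  }
  names(by_cl) <- as.character(seq_len(k))
  tab <- data.frame(id = seq_len(k), row = 0, col = 0,
                    n_pixels = lengths(by_cl))
  pixels <- vector("list", k)
  for (m in seq_len(k)) {
    px <- by_cl[[as.character(m)]]
    rc <- rc_from_idx(px, H)
    ctr <- colMeans(rc)
    j <- which.min((rc[, 1] - ctr[1])^2 + (rc[, 2] - ctr[2])^2)
    tab$row[m] <- rc[j, 1]; tab$col[m] <- rc[j, 2]
    pixels[[m]] <- px
  }
  structure(list(table = tab, pixels = pixels), class = "tj_vertices")
}

# Path-adjacency among non-vertex skeleton pixels: axial neighbors always,
# diagonal neighbors only when neither shared orthogonal neighbor lies on
# the full skeleton (otherwise the path runs through that pixel, and the
# diagonal is a shortcut that would bridge distinct branches around a
# removed junction pixel).
.segment_adjacency <- function(segmask, fullskel) {
  H <- nrow(segmask); W <- ncol(segmask)
  idx <- which(segmask)
  id <- matrix(0L, H, W)
  id[idx] <- seq_along(idx)
  pair_list <- list()
  add_pairs <- function(dr, dc, ok_extra = NULL) {
    nb <- shift_mat(id, -dr, -dc, fill = 0L)  # neighbor id seen from p
    sel <- segmask & nb > 0
    if (!is.null(ok_extra)) sel <- sel & ok_extra
    if (any(sel)) pair_list[[length(pair_list) + 1L]] <<- cbind(id[sel], nb[sel])
  }
  add_pairs(0, 1); add_pairs(1, 0)
  fs <- fullskel
  # diagonal (dr=1, dc=1): common orthogonal neighbors (r+1, c) and (r, c+1)
  blocked <- shift_mat(fs, -1, 0, fill = FALSE) | shift_mat(fs, 0, -1, fill = FALSE)
  add_pairs(1, 1, ok_extra = !blocked)
  blocked <- shift_mat(fs, -1, 0, fill = FALSE) | shift_mat(fs, 0, 1, fill = FALSE)
  add_pairs(1, -1, ok_extra = !blocked)
  pairs <- if (length(pair_list)) do.call(rbind, pair_list) else
    matrix(integer(0), 0, 2)
  nbrs <- vector("list", length(idx))
  if (nrow(pairs)) {
    both <- rbind(pairs, pairs[, 2:1])
    sp <- split(both[, 2], both[, 1])
    nbrs[as.integer(names(sp))] <- sp
  }
  list(idx = idx, nbrs = nbrs)
}

# Order one segment's pixels into a path: shortest path between the two
# most distant endpoint candidates. Robust to 1-px side nubs and small
# triangle cycles a thinning can leave: such redundant pixels simply do not
# appear on the path (they remain part of the skeleton mask).
.order_path <- function(members, adj, H) {
  n <- length(members)
  rc <- rc_from_idx(adj$idx[members], H)
  if (n == 1) return(rc)
  local <- integer(max(members))
  local[members] <- seq_len(n)
  prs <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- local[adj$nbrs[[members[i]]]]
    nb <- nb[nb > i]
    if (length(nb)) cbind(i, nb) else NULL
  }))
  gl <- igraph::make_empty_graph(n, directed = FALSE)
  w <- numeric(0)
  if (!is.null(prs) && nrow(prs)) {
    gl <- igraph::add_edges(gl, t(prs))
    d <- abs(rc[prs[, 1], 1] - rc[prs[, 2], 1]) +
      abs(rc[prs[, 1], 2] - rc[prs[, 2], 2])
    w <- ifelse(d == 2, sqrt(2), 1)
  }
  deg <- igraph::degree(gl)
  cand <- which(deg <= 1)
  if (length(cand) == 0) cand <- 1L  # cycle: start anywhere
  dd <- igraph::distances(gl, v = cand, weights = w)
  if (length(cand) >= 2) {
    dc <- dd[, cand, drop = FALSE]
    dc[!is.finite(dc)] <- -1
    ij <- which(dc == max(dc), arr.ind = TRUE)[1, ]
    a <- cand[ij[1]]; b <- cand[ij[2]]
  } else {
    a <- cand[1]
    fin <- which(is.finite(dd[1, ]))
    b <- fin[which.max(dd[1, fin])]
  }
  if (a == b) return(rc[a, , drop = FALSE])
  sp <- igraph::shortest_paths(gl, from = a, to = b, weights = w)$vpath[[1]]
  rc[as.integer(sp), , drop = FALSE]
}

#' Build the junction graph from a skeleton and its vertices
#'
#' Traces the skeleton paths between vertex clusters into edges, prunes
#' short spur branches with a free end (iterated to a fixpoint), dissolves
#' vertices left with degree 2 by concatenating their two edges, and flags
#' branches touching the image border.
#'
#' @param skel logical skeleton matrix.
#' @param vertices result of [detect_vertices()] on the same skeleton.
#' @param min_branch_len spur branches with one free end shorter than this
#'   (px path length) are removed.
#' @return object of class `tj_graph` with elements `vertices` (data frame:
#'   id, row, col, relocated row/col, degree, border, unrelocated), `edges`
#'   (list: id, path matrix, v1, v2, length, border), `skeleton`, `dim`.
#' @export
build_graph <- function(skel, vertices, min_branch_len = 10) {
  skel <- skel != 0
  H <- nrow(skel); W <- ncol(skel)
  vmask <- matrix(FALSE, H, W)
  vid <- matrix(0L, H, W)
  for (v in seq_along(vertices$pixels)) {
    vmask[vertices$pixels[[v]]] <- TRUE
    vid[vertices$pixels[[v]]] <- v
  }
  segmask <- skel & !vmask
  adj <- .segment_adjacency(segmask, skel)
  edges <- list()
  nseg <- 0L
  if (length(adj$idx)) {
    gseg <- igraph::make_empty_graph(length(adj$idx), directed = FALSE)
    prs <- do.call(rbind, lapply(seq_along(adj$nbrs), function(i) {
      nb <- adj$nbrs[[i]]
      nb <- nb[nb > i]
      if (length(nb)) cbind(i, nb) else NULL
    }))
    if (!is.null(prs) && nrow(prs))
      gseg <- igraph::add_edges(gseg, t(prs))
    memb <- igraph::components(gseg)$membership
    by_seg <- split(seq_along(adj$idx), memb)
    nseg <- length(by_seg)
    eid <- 0L
    for (s in seq_len(nseg)) {
      path <- .order_path(by_seg[[s]], adj, H)
      ends <- path[c(1, nrow(path)), , drop = FALSE]
      att <- integer(0)
      vatt <- c(NA_integer_, NA_integer_)
      for (e in 1:2) {
        nb <- cbind(ends[e, 1] + OFFS8[, 1], ends[e, 2] + OFFS8[, 2])
        ok <- nb[, 1] >= 1 & nb[, 1] <= H & nb[, 2] >= 1 & nb[, 2] <= W
        ids <- unique(vid[nb[ok, , drop = FALSE]])
        ids <- ids[ids > 0]
        if (length(ids)) vatt[e] <- ids[1]
      }
      # a 1-2 px fragment touching one cluster at both ends is junction
      # debris left over from thinning; absorb it into the cluster
      if (!is.na(vatt[1]) && identical(vatt[1], vatt[2]) &&
          path_length(path) < 3) {
        vertices$pixels[[vatt[1]]] <-
          union(vertices$pixels[[vatt[1]]], idx_from_rc(path, H))
        next
      }
      border <- any(path[, 1] <= 1 | path[, 1] >= H |
                      path[, 2] <= 1 | path[, 2] >= W)
      eid <- eid + 1L
      edges[[eid]] <- list(id = eid, path = path, v1 = vatt[1], v2 = vatt[2],
                           length = path_length(path), border = border,
                           cells = integer(0))
    }
  }
  vt <- vertices$table
  vt$degree <- 0L
  vt$border <- vt$row <= 2 | vt$row >= H - 1 | vt$col <= 2 | vt$col >= W - 1
  vt$relocated_row <- as.numeric(vt$row)
  vt$relocated_col <- as.numeric(vt$col)
  vt$unrelocated <- TRUE
  g <- structure(list(vertices = vt, edges = edges, dim = c(H, W),
                      skeleton = skel, vertex_pixels = vertices$pixels,
                      aux_points = list(), min_branch_len = min_branch_len),
                 class = "tj_graph")
  g <- .attach_free_ends(g, min_branch_len)
  g <- .prune_graph(g, min_branch_len)
  .extend_border_stubs(g)
}

# Thinning occasionally renders a three-way junction without any pixel of
# crossing number >= 3 (the stem meets the bar between two of its pixels),
# so one wall ends free against the flank of another wall's path. Repair:
# a long free end adjacent to another edge's path marks the missed nodal
# point; that path pixel is promoted to a new vertex and the covering edge
# split there. Short free ends are left for spur pruning.
.attach_free_ends <- function(g, min_branch_len) {
  H <- g$dim[1]; W <- g$dim[2]
  # pixel -> (edge index, path position) for all edge paths
  owner_e <- integer(H * W); owner_p <- integer(H * W)
  for (i in seq_along(g$edges)) {
    px <- idx_from_rc(g$edges[[i]]$path, H)
    owner_e[px] <- i
    owner_p[px] <- seq_along(px)
  }
  vat <- matrix(0L, H, W)
  for (v in seq_along(g$vertex_pixels)) vat[g$vertex_pixels[[v]]] <- v
  i <- 1L
  while (i <= length(g$edges)) {
    e <- g$edges[[i]]
    for (end in c(1L, 2L)) {
      free <- if (end == 1L) is.na(e$v1) else is.na(e$v2)
      if (!free || e$length < min_branch_len || e$border) next
      tip <- if (end == 1L) e$path[1, ] else e$path[nrow(e$path), ]
      tipidx <- (tip[2] - 1L) * H + tip[1]
      nb_r <- tip[1] + OFFS8[, 1]; nb_c <- tip[2] + OFFS8[, 2]
      ok <- nb_r >= 1 & nb_r <= H & nb_c >= 1 & nb_c <= W
      nidx <- (nb_c[ok] - 1L) * H + nb_r[ok]
      # existing vertex cluster next to the tip: just attach
      vhit <- vat[nidx]
      vhit <- vhit[vhit > 0]
      if (length(vhit)) {
        if (end == 1L) e$v1 <- vhit[1] else e$v2 <- vhit[1]
        g$edges[[i]] <- e
        next
      }
      hits <- which(owner_e[nidx] > 0 & owner_e[nidx] != i)
      if (!length(hits)) next
      hidx <- nidx[hits[1]]
      j <- owner_e[hidx]; pos <- owner_p[hidx]
      ej <- g$edges[[j]]
      # new vertex at the junction pixel
      nv <- nrow(g$vertices) + 1L
      rc <- rc_from_idx(hidx, H)
      g$vertices <- rbind(g$vertices,
                          data.frame(id = nv, row = rc[1, 1], col = rc[1, 2],
                                     n_pixels = 1L, degree = 0L,
                                     border = FALSE,
                                     relocated_row = as.numeric(rc[1, 1]),
                                     relocated_col = as.numeric(rc[1, 2]),
                                     unrelocated = TRUE))
      g$vertex_pixels[[nv]] <- hidx
      vat[hidx] <- nv
      owner_e[hidx] <- 0L
      if (end == 1L) e$v1 <- nv else e$v2 <- nv
      g$edges[[i]] <- e
      # split the covering edge at the junction pixel
      p1 <- ej$path[seq_len(max(pos - 1L, 0L)), , drop = FALSE]
      p2 <- ej$path[seq_len(nrow(ej$path)) > pos, , drop = FALSE]
      mkborder <- function(p) nrow(p) > 0 &&
        any(p[, 1] <= 1 | p[, 1] >= H | p[, 2] <= 1 | p[, 2] >= W)
      rep1 <- list(id = ej$id, path = p1, v1 = ej$v1, v2 = nv,
                   length = path_length(p1), border = mkborder(p1),
                   cells = integer(0))
      rep2 <- list(id = length(g$edges) + 1L, path = p2, v1 = nv, v2 = ej$v2,
                   length = path_length(p2), border = mkborder(p2),
                   cells = integer(0))
      if (nrow(p1) == 0) {
        # junction pixel was the first path pixel; keep only the far part
        rep2$id <- ej$id
        g$edges[[j]] <- rep2
      } else if (nrow(p2) == 0) {
        g$edges[[j]] <- rep1
      } else {
        g$edges[[j]] <- rep1
        g$edges[[length(g$edges) + 1L]] <- rep2
        px2 <- idx_from_rc(p2, H)
        owner_e[px2] <- length(g$edges)
        owner_p[px2] <- seq_along(px2)
      }
      e <- g$edges[[i]]
    }
    i <- i + 1L
  }
  g
}

# Free-ended branches whose tip lies within `margin` px of the image border
# are walls cut by the field of view whose binarized trace stops just short
# of the edge (anti-aliasing and closing retract line ends slightly). Left
# as is, the two cells such a wall separates would leak around the tip and
# merge, so the stub is extended straight to the border and border-flagged.
.extend_border_stubs <- function(g, margin = 4) {
  H <- g$dim[1]; W <- g$dim[2]
  for (i in seq_along(g$edges)) {
    e <- g$edges[[i]]
    for (end in c(1L, 2L)) {
      if (end == 1L && !is.na(e$v1)) next
      if (end == 2L && !is.na(e$v2)) next
      tip <- if (end == 1L) e$path[1, ] else e$path[nrow(e$path), ]
      dists <- c(tip[1] - 1, H - tip[1], tip[2] - 1, W - tip[2])
      if (min(dists) == 0 || min(dists) > margin) next
      target <- switch(which.min(dists),
                       c(1, tip[2]), c(H, tip[2]),
                       c(tip[1], 1), c(tip[1], W))
      n <- max(abs(target - tip)) + 1
      ext <- cbind(round(seq(tip[1], target[1], length.out = n)),
                   round(seq(tip[2], target[2], length.out = n)))
      ext <- ext[-1, , drop = FALSE]
      g$skeleton[ext] <- TRUE
      e$path <- if (end == 1L) rbind(ext[rev(seq_len(nrow(ext))), , drop = FALSE],
                                     e$path) else rbind(e$path, ext)
      e$length <- path_length(e$path)
      e$border <- TRUE
    }
    g$edges[[i]] <- e
  }
  g
}

# Iterated spur pruning + dissolution of vertices left with degree < 3,
# run to a fixpoint: deleting a spur can demote its vertex to degree 2,
# which merges two edges, which can expose a new spur, and so on.
.prune_graph <- function(g, min_branch_len) {
  degrees <- function(g) {
    deg <- integer(nrow(g$vertices))
    for (e in g$edges) {
      if (!is.na(e$v1)) deg[e$v1] <- deg[e$v1] + 1L
      if (!is.na(e$v2)) deg[e$v2] <- deg[e$v2] + 1L
    }
    deg
  }
  repeat {
    changed <- FALSE
    # drop short branches with a free end, unless they touch the border
    keep <- vapply(g$edges, function(e) {
      n_free <- is.na(e$v1) + is.na(e$v2)
      !(n_free >= 1 && !e$border && e$length < min_branch_len)
    }, logical(1))
    if (!all(keep)) { g$edges <- g$edges[keep]; changed <- TRUE }
    deg <- degrees(g)
    g$vertices$degree <- deg
    low <- which(deg > 0 & deg < 3 & !g$vertices$border)
    if (length(low)) {
      v <- low[1]
      eids <- which(vapply(g$edges, function(e)
        (!is.na(e$v1) && e$v1 == v) || (!is.na(e$v2) && e$v2 == v),
        logical(1)))
      vpx <- rc_from_idx(g$vertex_pixels[[v]], g$dim[1])
      if (deg[v] == 1) {
        # absorb the vertex into its only edge; that end becomes free
        e <- g$edges[[eids[1]]]
        if (!is.na(e$v1) && e$v1 == v) {
          e$path <- rbind(vpx, e$path); e$v1 <- NA_integer_
        } else {
          e$path <- rbind(e$path, vpx); e$v2 <- NA_integer_
        }
        e$length <- path_length(e$path)
        g$edges[[eids[1]]] <- e
      } else if (length(eids) == 1) {
        # degree 2 via a loop edge: detach it
        e <- g$edges[[eids[1]]]
        e$v1 <- NA_integer_; e$v2 <- NA_integer_
        g$edges[[eids[1]]] <- e
      } else {
        # degree 2: concatenate the two edges across the vertex
        e1 <- g$edges[[eids[1]]]; e2 <- g$edges[[eids[2]]]
        p1 <- if (!is.na(e1$v2) && e1$v2 == v) e1$path else
          e1$path[rev(seq_len(nrow(e1$path))), , drop = FALSE]
        o1 <- if (!is.na(e1$v2) && e1$v2 == v) e1$v1 else e1$v2
        p2 <- if (!is.na(e2$v1) && e2$v1 == v) e2$path else
          e2$path[rev(seq_len(nrow(e2$path))), , drop = FALSE]
        o2 <- if (!is.na(e2$v1) && e2$v1 == v) e2$v2 else e2$v1
        path <- rbind(p1, vpx, p2)
        g$edges[[eids[1]]] <- list(id = e1$id, path = path, v1 = o1, v2 = o2,
                                   length = path_length(path),
                                   border = e1$border || e2$border,
                                   cells = unique(c(e1$cells, e2$cells)))
        g$edges <- g$edges[-eids[2]]
      }
      changed <- TRUE
    }
    if (!changed) break
  }
  # final degrees and edge renumbering
  deg <- integer(nrow(g$vertices))
  for (i in seq_along(g$edges)) {
    g$edges[[i]]$id <- i
    e <- g$edges[[i]]
    if (!is.na(e$v1)) deg[e$v1] <- deg[e$v1] + 1L
    if (!is.na(e$v2)) deg[e$v2] <- deg[e$v2] + 1L
  }
  g$vertices$degree <- deg
  g
}

#' Relocate vertices onto tricellular point sources
#'
#' Skeleton crossings mark where three cells meet, but the true tricellular
#' structure sits at the nearby maximum of the tricellular-marker image.
#' Candidate point sources are strict local maxima of the Gaussian-smoothed
#' image whose local prominence (value minus the median network intensity in
#' a surrounding annulus) exceeds a threshold; each vertex moves to the
#' nearest accepted candidate within `search_radius`, or stays put flagged
#' `unrelocated` when none exists.
#'
#' The prominence threshold is `max(k * mad, rel_min * median)` where mad and
#' median are computed over the dilated junction network, so flat boundary
#' signal without punctae (no enrichment) yields no accepted candidates.
#'
#' @param graph a `tj_graph`.
#' @param tric contrast-adjusted tricellular image.
#' @param search_radius maximum relocation distance (px).
#' @param sigma Gaussian smoothing sigma before maxima detection (px).
#' @param k robust-SD multiplier of the prominence threshold.
#' @param rel_min floor of the prominence threshold as a fraction of the
#'   median network intensity.
#' @return the graph with updated `relocated_row/col` and `unrelocated`.
#' @export
relocate_vertices <- function(graph, tric, search_radius = 5, sigma = 1,
                              k = 2, rel_min = 0.1) {
  img <- as_intensity_matrix(tric, "tric")
  H <- nrow(img); W <- ncol(img)
  if (!all(graph$dim == c(H, W)))
    stopf("tricellular image extent does not match the graph")
  S <- EBImage::imageData(EBImage::gblur(img, sigma = sigma))
  net <- EBImage::imageData(EBImage::dilate(graph$skeleton * 1,
                                            EBImage::makeBrush(5, "disc"))) > 0
  netvals <- S[net]
  med <- stats::median(netvals)
  thr <- max(k * stats::mad(netvals), rel_min * med)
  # strict local maxima
  ismax <- matrix(TRUE, H, W)
  for (o in seq_len(nrow(OFFS8)))
    ismax <- ismax & (S > shift_mat(S, OFFS8[o, 1], OFFS8[o, 2], fill = -Inf))
  cand <- which(ismax)
  crc <- rc_from_idx(cand, H)
  ann <- disc_offsets(8)
  ann <- ann[ann[, "dist"] >= 4, , drop = FALSE]
  vt <- graph$vertices
  accepted <- rep(NA, length(cand))  # lazily evaluated prominence
  for (v in seq_len(nrow(vt))) {
    d2 <- (crc[, 1] - vt$row[v])^2 + (crc[, 2] - vt$col[v])^2
    near <- which(d2 <= search_radius^2)
    if (!length(near)) next
    near <- near[order(d2[near])]
    moved <- FALSE
    for (ci in near) {
      if (is.na(accepted[ci])) {
        ar <- crc[ci, 1] + ann[, "dr"]; ac <- crc[ci, 2] + ann[, "dc"]
        ok <- ar >= 1 & ar <= H & ac >= 1 & ac <= W
        aidx <- (ac[ok] - 1L) * H + ar[ok]
        aidx <- aidx[net[aidx]]
        base <- if (length(aidx)) stats::median(S[aidx]) else med
        accepted[ci] <- (S[cand[ci]] - base) >= thr
      }
      if (isTRUE(as.logical(accepted[ci]))) {
        vt$relocated_row[v] <- crc[ci, 1]
        vt$relocated_col[v] <- crc[ci, 2]
        vt$unrelocated[v] <- FALSE
        moved <- TRUE
        break
      }
    }
    if (!moved) {
      vt$relocated_row[v] <- vt$row[v]
      vt$relocated_col[v] <- vt$col[v]
      vt$unrelocated[v] <- TRUE
    }
  }
  graph$vertices <- vt
  graph
}

#' Apply a declarative edit script to a junction graph
#'
#' Replaces interactive manual correction: an edit script is an ordered list
#' of commands, each a list with an `op` field and arguments. Supported ops:
#'
#' * `add_auxiliary_point(coords, cell_id)` — adds an extra polygon point
#'   for a cell (used by polygonization).
#' * `move_vertex(id, coords)` — sets the relocated coordinates.
#' * `delete_vertex(id)` — removes a vertex; when exactly two incident edges
#'   remain they are joined across the removed vertex, otherwise its edges
#'   are dropped.
#' * `merge_vertices(id_a, id_b)` — reattaches b's edges to a and removes b.
#' * `split_cell(cell_id, coords)` — draws the polyline into the stored
#'   skeleton; cell segmentation must be recomputed afterwards.
#'
#' @param graph a `tj_graph`.
#' @param edits list of commands (or a path to a JSON file containing them).
#' @return the edited graph, with an `audit` attribute listing applied
#'   commands.
#' @export
apply_edits <- function(graph, edits) {
  if (is.character(edits) && length(edits) == 1)
    edits <- jsonlite::read_json(edits, simplifyVector = FALSE)
  audit <- character(0)
  for (i in seq_along(edits)) {
    cmd <- edits[[i]]
    op <- cmd$op
    ok_vertex <- function(id) {
      if (is.null(id) || length(id) != 1 || is.na(id) ||
          id < 1 || id > nrow(graph$vertices) ||
          graph$vertices$degree[id] < 0)
        stopf("edit %d (%s): vertex id %s does not exist", i, op,
              deparse(id))
    }
    if (is.null(op)) stopf("edit %d has no 'op' field", i)
    if (op == "add_auxiliary_point") {
      coords <- unlist(cmd$coords)
      graph$aux_points[[length(graph$aux_points) + 1]] <-
        list(row = coords[1], col = coords[2], cell_id = cmd$cell_id)
      audit <- c(audit, sprintf("add_auxiliary_point cell=%s (%.1f, %.1f)",
                                cmd$cell_id, coords[1], coords[2]))
    } else if (op == "move_vertex") {
      ok_vertex(cmd$id)
      coords <- unlist(cmd$coords)
      graph$vertices$relocated_row[cmd$id] <- coords[1]
      graph$vertices$relocated_col[cmd$id] <- coords[2]
      audit <- c(audit, sprintf("move_vertex %d -> (%.1f, %.1f)", cmd$id,
                                coords[1], coords[2]))
    } else if (op == "delete_vertex") {
      ok_vertex(cmd$id)
      graph <- .delete_vertex(graph, cmd$id)
      audit <- c(audit, sprintf("delete_vertex %d", cmd$id))
    } else if (op == "merge_vertices") {
      ok_vertex(cmd$id_a); ok_vertex(cmd$id_b)
      a <- cmd$id_a; b <- cmd$id_b
      for (j in seq_along(graph$edges)) {
        e <- graph$edges[[j]]
        if (!is.na(e$v1) && e$v1 == b) e$v1 <- a
        if (!is.na(e$v2) && e$v2 == b) e$v2 <- a
        graph$edges[[j]] <- e
      }
      keep <- vapply(graph$edges, function(e)
        !(!is.na(e$v1) && !is.na(e$v2) && e$v1 == e$v2 && e$length < 3),
        logical(1))
      graph$edges <- graph$edges[keep]
      graph$vertices$degree[b] <- 0L
      graph <- .prune_graph(graph, graph$min_branch_len)
      audit <- c(audit, sprintf("merge_vertices %d <- %d", a, b))
    } else if (op == "split_cell") {
      coords <- do.call(rbind, lapply(cmd$coords, unlist))
      graph$skeleton <- .draw_polyline(graph$skeleton, coords)
      graph$needs_resegmentation <- TRUE
      audit <- c(audit, sprintf("split_cell %s (%d points)", cmd$cell_id,
                                nrow(coords)))
    } else {
      stopf("edit %d: unknown op '%s'", i, op)
    }
  }
  attr(graph, "audit") <- audit
  graph
}

.delete_vertex <- function(g, id) {
  inc <- which(vapply(g$edges, function(e)
    (!is.na(e$v1) && e$v1 == id) || (!is.na(e$v2) && e$v2 == id),
    logical(1)))
  if (length(inc) == 2) {
    e1 <- g$edges[[inc[1]]]; e2 <- g$edges[[inc[2]]]
    p1 <- if (!is.na(e1$v2) && e1$v2 == id) e1$path else
      e1$path[rev(seq_len(nrow(e1$path))), , drop = FALSE]
    o1 <- if (!is.na(e1$v2) && e1$v2 == id) e1$v1 else e1$v2
    p2 <- if (!is.na(e2$v1) && e2$v1 == id) e2$path else
      e2$path[rev(seq_len(nrow(e2$path))), , drop = FALSE]
    o2 <- if (!is.na(e2$v1) && e2$v1 == id) e2$v2 else e2$v1
    path <- rbind(p1, p2)
    g$edges[[inc[1]]] <- list(id = e1$id, path = path, v1 = o1, v2 = o2,
                              length = path_length(path),
                              border = e1$border || e2$border,
                              cells = unique(c(e1$cells, e2$cells)))
    g$edges <- g$edges[-inc[2]]
  } else if (length(inc) > 0) {
    g$edges <- g$edges[-inc]
  }
  g$vertices$degree[id] <- 0L
  .prune_graph(g, g$min_branch_len)
}

.draw_polyline <- function(mask, coords) {
  for (i in seq_len(nrow(coords) - 1)) {
    a <- coords[i, ]; b <- coords[i + 1, ]
    n <- max(abs(b - a)) + 1
    rr <- round(seq(a[1], b[1], length.out = n))
    cc <- round(seq(a[2], b[2], length.out = n))
    ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

#' Check the planar Euler relation on the interior subdivision
#'
#' For the subgraph bounding a connected patch of interior (non-border)
#' cells, the planar Euler formula gives `V - E + C = 1` where `C` is the
#' number of cells in the patch. Interior cells can fall into several
#' disconnected patches (when border cells separate them), in which case
#' the totals satisfy `V - E + C = n_patches`.
#'
#' @param graph a `tj_graph` whose edges carry incident cells (see
#'   [link_cells()]).
#' @param cells a `tj_cells` segmentation.
#' @return list with totals `V`, `E`, `C`, `euler = V - E + C`,
#'   `n_patches`, and `patches`, a data frame of per-patch counts and
#'   per-patch Euler numbers.
#' @export
euler_summary <- function(graph, cells) {
  interior <- cells$table$id[!cells$table$border]
  # connected patches of interior cells under shared-edge adjacency
  adj <- graph$cell_adjacency
  adj <- adj[adj[, 1] %in% interior & adj[, 2] %in% interior, , drop = FALSE]
  gi <- igraph::make_empty_graph(length(interior), directed = FALSE)
  lut <- stats::setNames(seq_along(interior), interior)
  if (nrow(adj))
    gi <- igraph::add_edges(gi, t(cbind(lut[as.character(adj[, 1])],
                                        lut[as.character(adj[, 2])])))
  memb <- igraph::components(gi)$membership
  patches <- do.call(rbind, lapply(seq_len(max(memb)), function(p) {
    cellsp <- interior[memb == p]
    es <- Filter(function(e) length(intersect(e$cells, cellsp)) >= 1,
                 graph$edges)
    vs <- unique(unlist(lapply(es, function(e) c(e$v1, e$v2))))
    vs <- vs[!is.na(vs)]
    data.frame(patch = p, V = length(vs), E = length(es), C = length(cellsp),
               euler = length(vs) - length(es) + length(cellsp))
  }))
  es <- Filter(function(e) length(intersect(e$cells, interior)) >= 1,
               graph$edges)
  vs <- unique(unlist(lapply(es, function(e) c(e$v1, e$v2))))
  vs <- vs[!is.na(vs)]
  list(V = length(vs), E = length(es), C = length(interior),
       euler = length(vs) - length(es) + length(interior),
       n_patches = max(memb), patches = patches)
}

#' Serialize a junction graph to JSON
#'
#' Coordinates are exported 0-based (row, col); pixel paths are run-length
#' encoded per coordinate column.
#'
#' @param graph a `tj_graph`.
#' @param path output file.
#' @param params optional named list recorded as provenance.
#' @export
write_graph_json <- function(graph, path, params = list()) {
  vt <- graph$vertices
  rle_pack <- function(x) {
    r <- rle(x)
    list(lengths = r$lengths, values = r$values)
  }
  obj <- list(
    provenance = c(list(package = "trijunct",
                        version = as.character(utils::packageVersion("trijunct"))),
                   params),
    dim = graph$dim,
    vertices = lapply(seq_len(nrow(vt)), function(i) list(
      id = vt$id[i], coords = c(vt$row[i], vt$col[i]) - 1,
      relocated = c(vt$relocated_row[i], vt$relocated_col[i]) - 1,
      degree = vt$degree[i], border = vt$border[i],
      unrelocated = vt$unrelocated[i])),
    edges = lapply(graph$edges, function(e) list(
      id = e$id, v1 = e$v1, v2 = e$v2, length = e$length,
      border = e$border, cells = e$cells,
      path_rows = rle_pack(e$path[, 1] - 1L),
      path_cols = rle_pack(e$path[, 2] - 1L))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
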