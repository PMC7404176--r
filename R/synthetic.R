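#' Specify a synthetic epithelial monolayer
#'
#' Builds the parameter set for the synthetic-image generator. The generator
#' emulates a confluent epithelial monolayer imaged in three fluorescence
#' channels: a junctional channel (ZO-1-like thin bright boundary lines), a
#' tricellular-marker channel (tricellulin-like, boundary lines plus punctae
#' at the vertices where three cells meet), and a nuclear channel (one blob
#' per cell). Geometry comes from a centroidal-relaxed random-point Voronoi
#' tessellation, which mimics near-jammed polygonal cells; with
#' `relax_iter = 0` the cells are irregular and elongated, as in unjammed
#' tissue.
#'
#' @param n_cells number of Voronoi seed cells (>= 4).
#' @param image_size image extent in pixels, `c(height, width)`.
#' @param boundary_width nominal width of rendered junction lines (px).
#' @param boundary_intensity peak intensity of the boundary lines (a.u.).
#' @param enrichment dimensionless enrichment ratio rho: peak of a vertex
#'   puncta in the tricellular channel divided by `boundary_intensity`.
#'   `rho = 0` removes punctae entirely.
#' @param puncta_sigma Gaussian sigma of the rendered punctae (px).
#' @param noise_sd standard deviation of additive Gaussian noise (a.u.);
#'   images are clipped at 0 after noise.
#' @param nuclear_radius radius of rendered nuclei (px).
#' @param seed integer RNG seed; rendering is bit-reproducible for a fixed
#'   seed.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param relax_iter Lloyd (centroidal) relaxation iterations applied to the
#'   random Voronoi seeds.
#' @return an object of class `tj_spec`.
#' @export
tessellation_spec <- function(n_cells = 25, image_size = c(256, 256),
                              boundary_width = 3, boundary_intensity = 200,
                              enrichment = 2, puncta_sigma = 2,
                              noise_sd = 0, nuclear_radius = 5, seed = 1,
                              pixel_size = 0.3, relax_iter = 2) {
  if (n_cells < 4) stopf("n_cells must be >= 4 (got %d)", n_cells)
  if (length(image_size) != 2 || any(image_size < 16))
    stopf("image_size must be c(height, width), each >= 16")
  if (boundary_width < 1) stopf("boundary_width must be >= 1")
  if (enrichment < 0) stopf("enrichment (rho) must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  diam <- sqrt(prod(image_size) / n_cells)
  if (diam < 4 * boundary_width)
    stopf(paste0("image too small to host %d cells: expected cell diameter ",
                 "%.1f px < 4 x boundary_width = %.1f px; enlarge the image ",
                 "to at least %d x %d or reduce n_cells"),
          n_cells, diam, 4 * boundary_width,
          ceiling(sqrt(n_cells) * 4 * boundary_width),
          ceiling(sqrt(n_cells) * 4 * boundary_width))
  structure(list(n_cells = as.integer(n_cells),
                 image_size = as.integer(image_size),
                 boundary_width = boundary_width,
                 boundary_intensity = boundary_intensity,
                 enrichment = enrichment, puncta_sigma = puncta_sigma,
                 noise_sd = noise_sd, nuclear_radius = nuclear_radius,
                 seed = as.integer(seed), pixel_size = pixel_size,
                 relax_iter = as.integer(relax_iter)),
            class = "tj_spec")
}

# Per-pixel nearest-seed labels (discrete Voronoi).
.nearest_labels <- function(seeds, H, W) {
  best <- matrix(Inf, H, W)
  lab <- matrix(0L, H, W)
  for (k in seq_len(nrow(seeds))) {
    d2 <- outer((seq_len(H) - seeds[k, 1])^2, (seq_len(W) - seeds[k, 2])^2, "+")
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- k
  }
  lab
}

.lloyd <- function(seeds, H, W, iters) {
  lab <- .nearest_labels(seeds, H, W)
  if (iters > 0) {
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (i in seq_len(iters)) {
      n <- tabulate(lab, nbins = nrow(seeds))
      sr <- rowsum(as.vector(rows), as.vector(lab))[, 1]
      sc <- rowsum(as.vector(cols), as.vector(lab))[, 1]
      keep <- n > 0
      seeds[keep, 1] <- sr[keep] / n[keep]
      seeds[keep, 2] <- sc[keep] / n[keep]
      lab <- .nearest_labels(seeds, H, W)
    }
  }
  list(labels = lab, seeds = seeds)
}

# Interface core: pixels with a 4-neighbor carrying a different label.
.interface_core <- function(L) {
  core <- matrix(FALSE, nrow(L), ncol(L))
  H <- nrow(L); W <- ncol(L)
  dh <- L[, -W] != L[, -1]
  core[, -W] <- core[, -W] | dh
  core[, -1] <- core[, -1] | dh
  dv <- L[-H, ] != L[-1, ]
  core[-H, ] <- core[-H, ] | dv
  core[-1, ] <- core[-1, ] | dv
  core
}

# Table of interface pixels keyed by the unordered label pair they separate.
.interface_pairs <- function(L) {
  H <- nrow(L); W <- ncol(L)
  out <- list()
  dh <- which(L[, -W, drop = FALSE] != L[, -1, drop = FALSE])
  if (length(dh)) {
    rc <- rc_from_idx(dh, H)
    i1 <- idx_from_rc(rc, H)
    i2 <- idx_from_rc(cbind(rc[, 1], rc[, 2] + 1L), H)
    out[[1]] <- data.frame(idx = c(i1, i2), a = c(L[i1], L[i1]),
                           b = c(L[i2], L[i2]))
  }
  dv <- which(L[-H, , drop = FALSE] != L[-1, , drop = FALSE])
  if (length(dv)) {
    rc <- rc_from_idx(dv, H - 1L)
    i1 <- idx_from_rc(rc, H)
    i2 <- idx_from_rc(cbind(rc[, 1] + 1L, rc[, 2]), H)
    out[[2]] <- data.frame(idx = c(i1, i2), a = c(L[i1], L[i1]),
                           b = c(L[i2], L[i2]))
  }
  tab <- do.call(rbind, out)
  lo <- pmin(tab$a, tab$b); hi <- pmax(tab$a, tab$b)
  data.frame(idx = tab$idx, a = lo, b = hi)
}

# Ground-truth vertices from the 2x2 corner scan of the label raster.
# A corner where >= 3 distinct positive labels meet is a tricellular vertex.
.truth_vertices <- function(L) {
  H <- nrow(L); W <- ncol(L)
  a <- L[-H, -W]; b <- L[-H, -1]; cc <- L[-1, -W]; d <- L[-1, -1]
  nd <- 1L + (b != a) + ((cc != a) & (cc != b)) +
    ((d != a) & (d != b) & (d != cc))
  hit <- which(nd >= 3L)
  if (!length(hit))
    return(list(coords = matrix(numeric(0), 0, 2), cells = list()))
  rc <- rc_from_idx(hit, H - 1L)
  labs <- cbind(a[hit], b[hit], cc[hit], d[hit])
  keep <- logical(length(hit))
  cellsets <- vector("list", length(hit))
  for (i in seq_along(hit)) {
    u <- unique(labs[i, ])
    u <- u[u > 0]
    if (length(u) >= 3) { keep[i] <- TRUE; cellsets[[i]] <- sort(u) }
  }
  rc <- rc[keep, , drop = FALSE]
  cellsets <- cellsets[keep]
  if (!nrow(rc)) return(list(coords = matrix(numeric(0), 0, 2), cells = list()))
  pts <- cbind(rc[, 1] + 0.5, rc[, 2] + 0.5)
  # merge corner detections belonging to one physical vertex (adjacent corners)
  n <- nrow(pts)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n > 1) {
    d2 <- as.matrix(stats::dist(pts))
    pr <- which(d2 <= 1.6 & upper.tri(d2), arr.ind = TRUE)
    if (nrow(pr)) g <- igraph::add_edges(g, t(pr))
  }
  memb <- igraph::components(g)$membership
  k <- max(memb)
  coords <- matrix(0, k, 2)
  cells <- vector("list", k)
  for (m in seq_len(k)) {
    sel <- memb == m
    coords[m, ] <- colMeans(pts[sel, , drop = FALSE])
    cells[[m]] <- sort(unique(unlist(cellsets[sel])))
  }
  list(coords = coords, cells = cells)
}

.cell_table <- function(L, n_cells) {
  H <- nrow(L); W <- ncol(L)
  area <- tabulate(L, nbins = n_cells)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  lv <- as.vector(L)
  keep <- lv > 0
  sr <- rowsum(as.vector(rows)[keep], lv[keep])
  sc <- rowsum(as.vector(cols)[keep], lv[keep])
  ids <- as.integer(rownames(sr))
  cr <- rep(NA_real_, n_cells); ccol <- rep(NA_real_, n_cells)
  cr[ids] <- sr[, 1] / area[ids]
  ccol[ids] <- sc[, 1] / area[ids]
  border_labels <- unique(c(L[1, ], L[H, ], L[, 1], L[, W]))
  data.frame(id = seq_len(n_cells), area_px = area,
             centroid_row = cr, centroid_col = ccol,
             border = seq_len(n_cells) %in% border_labels)
}

.render_boundary <- function(core, width, intensity) {
  # distance from each pixel center to the nearest interface pixel; interface
  # lines run between pixel centers, so add half a pixel. Soft (anti-aliased)
  # profile clamped to [0, 1] then scaled.
  D <- EBImage::imageData(EBImage::distmap(1 - core * 1))
  dline <- D + 0.5
  val <- pmin(pmax(width / 2 + 0.5 - dline, 0), 1)
  val * intensity
}

.add_punctae <- function(img, coords, peaks, sigma) {
  H <- nrow(img); W <- ncol(img)
  r <- ceiling(4 * sigma)
  for (i in seq_len(nrow(coords))) {
    if (peaks[i] <= 0) next
    r0 <- coords[i, 1]; c0 <- coords[i, 2]
    rs <- max(1, floor(r0 - r)):min(H, ceiling(r0 + r))
    cs <- max(1, floor(c0 - r)):min(W, ceiling(c0 + r))
    d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
    img[rs, cs] <- img[rs, cs] + peaks[i] * exp(-d2 / (2 * sigma^2))
  }
  img
}

.render_nuclei <- function(cells, H, W, radius, intensity, L) {
  img <- matrix(0, H, W)
  for (i in seq_len(nrow(cells))) {
    if (is.na(cells$centroid_row[i])) next
    r0 <- cells$centroid_row[i]; c0 <- cells$centroid_col[i]
    ri <- round(r0); ci <- round(c0)
    ri <- min(max(ri, 1), H); ci <- min(max(ci, 1), W)
    if (L[ri, ci] != cells$id[i]) {
      px <- which(L == cells$id[i])
      if (!length(px)) next
      rc <- rc_from_idx(px, H)
      j <- which.min((rc[, 1] - r0)^2 + (rc[, 2] - c0)^2)
      r0 <- rc[j, 1]; c0 <- rc[j, 2]
    }
    rr <- ceiling(radius) + 1
    rs <- max(1, floor(r0 - rr)):min(H, ceiling(r0 + rr))
    cs <- max(1, floor(c0 - rr)):min(W, ceiling(c0 + rr))
    d <- sqrt(outer((rs - r0)^2, (cs - c0)^2, "+"))
    img[rs, cs] <- pmax(img[rs, cs],
                        intensity * pmin(pmax(radius + 0.5 - d, 0), 1))
  }
  img
}

.ordered_polygons <- function(cells, vcoords, vcells) {
  polys <- vector("list", nrow(cells))
  if (nrow(vcoords) == 0) return(polys)
  member <- lapply(seq_len(nrow(cells)), function(i) integer(0))
  for (v in seq_along(vcells))
    for (cid in vcells[[v]]) member[[cid]] <- c(member[[cid]], v)
  for (i in seq_len(nrow(cells))) {
    vs <- member[[i]]
    if (cells$border[i] || length(vs) < 3) next
    ang <- atan2(vcoords[vs, 1] - cells$centroid_row[i],
                 vcoords[vs, 2] - cells$centroid_col[i])
    polys[[i]] <- vs[order(ang)]
  }
  polys
}

.build_truth <- function(L, spec, rho_vertex = NULL, rows = NULL,
                         leader = NULL) {
  n <- spec$n_cells
  verts <- .truth_vertices(L)
  cells <- .cell_table(L, n)
  pairs <- .interface_pairs(L)
  adj <- unique(pairs[pairs$a > 0, c("a", "b")])
  core <- .interface_core(L)
  structure(list(labels = L, cells = cells,
                 vertex_coords = verts$coords, vertex_cells = verts$cells,
                 polygons = .ordered_polygons(cells, verts$coords,
                                              verts$cells),
                 adjacency = adj, interface_pairs = pairs, core = core,
                 rho_vertex = rho_vertex, rows = rows, leader = leader,
                 spec = spec),
            class = "tj_truth")
}

# Oracle scoring of the rendered (noiseless) tricellular channel with the
# same mask construction the pipeline scorer uses, so per-vertex expected
# T_L is exact rather than derived analytically from rho.
.truth_expected_tl <- function(truth, tric, r_tri = 4, w_bi = 2,
                               tl_form = "normalized") {
  vc <- truth$vertex_coords
  if (nrow(vc) == 0) return(numeric(0))
  pairs <- truth$interface_pairs
  key <- paste(pairs$a, pairs$b)
  by_pair <- split(pairs$idx, key)
  edge_px <- vector("list", nrow(vc))
  for (v in seq_len(nrow(vc))) {
    cs <- truth$vertex_cells[[v]]
    pr <- utils::combn(cs, 2)
    ks <- paste(pmin(pr[1, ], pr[2, ]), pmax(pr[1, ], pr[2, ]))
    edge_px[[v]] <- unique(unlist(by_pair[intersect(ks, names(by_pair))]))
  }
  fg <- truth$boundary_mask
  sc <- tl_score_engine(vc, edge_px, truth$core, fg, tric,
                        r_tri = r_tri, w_bi = w_bi, tl_form = tl_form)
  sc$T_L
}

#' Generate a synthetic monolayer with ground truth
#'
#' Renders the three channels of a synthetic confluent monolayer and returns
#' them together with the exact ground truth (vertex coordinates, cell
#' polygons, adjacency, per-vertex expected localization score). The expected
#' score is measured on the rendered noiseless tricellular channel with the
#' same masks the scorer uses, making it an exact oracle for the pipeline.
#'
#' @param spec a [tessellation_spec()].
#' @param r_tri,w_bi mask parameters forwarded to the expected-score oracle;
#'   keep in sync with the values used when scoring.
#' @return a list of class `tj_simulation` with elements `truth` (class
#'   `tj_truth`), `zo1`, `tric`, `nuclei` (numeric intensity matrices), and
#'   `noiseless` (the pre-noise channels).
#' @export
#' @examples
#' sim <- generate_tessellation(tessellation_spec(n_cells = 16,
#'   image_size = c(160, 160), seed = 7))
#' nrow(sim$truth$vertex_coords)
generate_tessellation <- function(spec, r_tri = 4, w_bi = 2) {
  stopifnot(inherits(spec, "tj_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  with_seed(spec$seed, {
    m <- 0.02 * c(H, W) + 1
    seeds <- cbind(stats::runif(spec$n_cells, m[1], H - m[1]),
                   stats::runif(spec$n_cells, m[2], W - m[2]))
    L <- .lloyd(seeds, H, W, spec$relax_iter)$labels
    truth <- .build_truth(L, spec)
    lineimg <- .render_boundary(truth$core, spec$boundary_width,
                                spec$boundary_intensity)
    truth$boundary_mask <- lineimg >= 0.5 * spec$boundary_intensity
    zo1 <- lineimg
    peaks <- rep(spec$enrichment * spec$boundary_intensity,
                 nrow(truth$vertex_coords))
    tric <- .add_punctae(lineimg, truth$vertex_coords, peaks,
                         spec$puncta_sigma)
    nuc <- .render_nuclei(truth$cells, H, W, spec$nuclear_radius,
                          0.9 * spec$boundary_intensity, L)
    truth$expected_tl <- .truth_expected_tl(truth, tric, r_tri, w_bi)
    truth$tl_params <- list(r_tri = r_tri, w_bi = w_bi,
                            tl_form = "normalized")
    noiseless <- list(zo1 = zo1, tric = tric, nuclei = nuc)
    if (spec$noise_sd > 0) {
      zo1 <- pmax(zo1 + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W), 0)
      tric <- pmax(tric + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W), 0)
      nuc <- pmax(nuc + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W), 0)
    }
    structure(list(truth = truth, zo1 = zo1, tric = tric, nuclei = nuc,
                   noiseless = noiseless),
              class = "tj_simulation")
  })
}

#' Generate a synthetic wound-front (migration finger) monolayer
#'
#' Removes the cells on one side of the tessellation to create a free wound
#' edge, flags the remaining cell closest to the wound as the leader, assigns
#' every cell a row index (leader = row 1, immediate neighbors = row 2, ...,
#' by breadth-first adjacency distance), and renders vertex punctae whose
#' enrichment depends on the row of the youngest (lowest-row) incident cell.
#'
#' @param spec a [tessellation_spec()]; `spec$enrichment` is ignored in favor
#'   of `rho_by_row`.
#' @param rho_by_row numeric vector of enrichment ratios per row; rows beyond
#'   `length(rho_by_row)` reuse the last value.
#' @param n_rows optional cap: rows larger than `n_rows` are clamped to
#'   `n_rows` before looking up `rho_by_row`.
#' @param wound_fraction fraction of the image width (right side) cleared of
#'   cells to form the wound.
#' @inheritParams generate_tessellation
#' @return a `tj_simulation`; `truth$rows` holds the per-cell row assignment
#'   and `truth$leader` the leader cell id.
#' @export
generate_wound_front <- function(spec, rho_by_row, n_rows = length(rho_by_row),
                                 wound_fraction = 0.3, r_tri = 4, w_bi = 2) {
  stopifnot(inherits(spec, "tj_spec"))
  if (length(rho_by_row) < 1) stopf("rho_by_row must have length >= 1")
  H <- spec$image_size[1]; W <- spec$image_size[2]
  with_seed(spec$seed, {
    m <- 0.02 * c(H, W) + 1
    seeds <- cbind(stats::runif(spec$n_cells, m[1], H - m[1]),
                   stats::runif(spec$n_cells, m[2], W - m[2]))
    L <- .lloyd(seeds, H, W, spec$relax_iter)$labels
    cells0 <- .cell_table(L, spec$n_cells)
    wound <- which(cells0$centroid_col >= (1 - wound_fraction) * W)
    if (length(wound) < 1)
      stopf("wound_fraction removed no cells; increase it")
    if (spec$n_cells - length(wound) < 4)
      stopf("wound_fraction leaves fewer than 4 cells; reduce it")
    L[L %in% wound] <- 0L
    truth <- .build_truth(L, spec)
    kept <- which(truth$cells$area_px > 0)
    leader <- kept[which.max(truth$cells$centroid_col[kept])]
    adj <- truth$adjacency
    g <- igraph::graph_from_edgelist(cbind(as.character(adj$a),
                                           as.character(adj$b)),
                                     directed = FALSE)
    dd <- igraph::distances(g, v = as.character(leader))
    rows <- rep(NA_real_, spec$n_cells)
    rows[as.integer(colnames(dd))] <- as.numeric(dd[1, ]) + 1
    rows[is.infinite(rows)] <- NA_real_
    truth$rows <- data.frame(cell_id = seq_len(spec$n_cells), row = rows)
    truth$leader <- leader
    # enrichment per vertex from the youngest (lowest-row) incident cell
    vrow <- vapply(truth$vertex_cells, function(cs)
      suppressWarnings(min(rows[cs], na.rm = TRUE)), numeric(1))
    vrow[is.infinite(vrow)] <- NA_real_
    ridx <- pmin(pmax(round(vrow), 1), min(n_rows, length(rho_by_row)))
    rho_v <- rho_by_row[ifelse(is.na(ridx), length(rho_by_row), ridx)]
    truth$rho_vertex <- rho_v
    truth$vertex_row <- vrow
    lineimg <- .render_boundary(truth$core, spec$boundary_width,
                                spec$boundary_intensity)
    truth$boundary_mask <- lineimg >= 0.5 * spec$boundary_intensity
    zo1 <- lineimg
    tric <- .add_punctae(lineimg, truth$vertex_coords,
                         rho_v * spec$boundary_intensity, spec$puncta_sigma)
    nuc <- .render_nuclei(truth$cells, H, W, spec$nuclear_radius,
                          0.9 * spec$boundary_intensity, L)
    truth$expected_tl <- .truth_expected_tl(truth, tric, r_tri, w_bi)
    truth$tl_params <- list(r_tri = r_tri, w_bi = w_bi,
                            tl_form = "normalized")
    noiseless <- list(zo1 = zo1, tric = tric, nuclei = nuc)
    if (spec$noise_sd > 0) {
      zo1 <- pmax(zo1 + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W), 0)
      tric <- pmax(tric + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W), 0)
      nuc <- pmax(nuc + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W), 0)
    }
    structure(list(truth = truth, zo1 = zo1, tric = tric, nuclei = nuc,
                   noiseless = noiseless),
              class = "tj_simulation")
  })
}

#' Build a constant or checkerboard focus profile
#'
#' Helper for [generate_zstack()]: a per-block map of the in-focus slice.
#'
#' @param n_blocks `c(rows, cols)` of the block grid.
#' @param slices either a single slice index (constant profile) or two
#'   indices alternated in a checkerboard.
#' @export
focus_profile <- function(n_blocks, slices = 1) {
  if (length(slices) == 1) return(matrix(as.integer(slices), n_blocks[1],
                                         n_blocks[2]))
  chk <- (outer(seq_len(n_blocks[1]), seq_len(n_blocks[2]), "+") %% 2) + 1L
  matrix(as.integer(slices[chk]), n_blocks[1], n_blocks[2])
}

#' Generate synthetic z-stacks with block-wise focus variation
#'
#' Turns the channels of a simulated monolayer into z-stacks in which each
#' `block_size` x `block_size` patch is sharp only in the slice given by
#' `focus_profile`; other slices hold Gaussian-defocused copies with blur
#' growing in the slice distance from focus. The junctional channel is
#' therefore maximal at the in-focus slice of each block, which is what the
#' guided projection exploits.
#'
#' @param spec a [tessellation_spec()], used to simulate the monolayer, or a
#'   ready `tj_simulation` to avoid regenerating it.
#' @param n_slices number of z slices (>= 2).
#' @param profile integer matrix over the block grid giving the in-focus
#'   slice per block; defaults to a smooth column gradient across slices.
#' @param block_size patch size in pixels.
#' @param defocus_sigma blur sigma per unit slice distance from focus; 0
#'   makes all slices identical (argmax ties resolve to the lowest slice).
#' @return list of class `tj_zstack_sim`: `stacks` (per channel, arrays
#'   indexed slice, row, col), `profile`, `block_size`, `truth`.
#' @export
generate_zstack <- function(spec, n_slices = 3, profile = NULL,
                            block_size = 20, defocus_sigma = 1.5) {
  if (n_slices < 2) stopf("n_slices must be >= 2")
  sim <- if (inherits(spec, "tj_simulation")) spec else
    generate_tessellation(spec)
  H <- nrow(sim$zo1); W <- ncol(sim$zo1)
  nbr <- ceiling(H / block_size); nbc <- ceiling(W / block_size)
  if (is.null(profile)) {
    profile <- matrix(rep(round(seq(1, n_slices, length.out = nbc)),
                          each = nbr), nbr, nbc)
  }
  if (!all(dim(profile) == c(nbr, nbc)))
    stopf("profile must be a %d x %d matrix", nbr, nbc)
  if (any(profile < 1 | profile > n_slices))
    stopf("profile values must lie in 1..n_slices")
  pix_profile <- profile[cbind(rep(ceiling(seq_len(H) / block_size), W),
                               rep(ceiling(seq_len(W) / block_size),
                                   each = H))]
  pix_profile <- matrix(pix_profile, H, W)
  mk_stack <- function(img) {
    blur <- list(img)
    for (d in seq_len(n_slices - 1)) {
      blur[[d + 1]] <- if (defocus_sigma > 0)
        EBImage::imageData(EBImage::gblur(img, sigma = defocus_sigma * d))
      else img
    }
    st <- array(0, dim = c(n_slices, H, W))
    for (s in seq_len(n_slices)) {
      dmap <- abs(s - pix_profile)
      sl <- matrix(0, H, W)
      for (d in 0:(n_slices - 1)) {
        sel <- dmap == d
        if (any(sel)) sl[sel] <- blur[[d + 1]][sel]
      }
      st[s, , ] <- sl
    }
    st
  }
  structure(list(stacks = list(zo1 = mk_stack(sim$zo1),
                               tric = mk_stack(sim$tric),
                               nuclei = mk_stack(sim$nuclei)),
                 profile = profile, block_size = block_size,
                 truth = sim$truth),
            class = "tj_zstack_sim")
}

#' Write a simulation to TIFF images plus a ground-truth JSON
#'
#' Each channel is written as a 32-bit float TIFF, rescaled to `[0, 1]` by a
#' common factor recorded in the JSON sidecar. Ground-truth coordinates are
#' exported 0-based as (row, col); polygons as 0-based vertex-index lists.
#'
#' @param sim a `tj_simulation`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "tj_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(sim$zo1, sim$tric, sim$nuclei, 1e-12)
  paths <- character(0)
  for (ch in c("zo1", "tric", "nuclei")) {
    p <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(sim[[ch]] / scale, p, bits.per.sample = 32,
                    compression = "none")
    paths <- c(paths, p)
  }
  tr <- sim$truth
  gt <- list(
    intensity_scale = scale,
    pixel_size = tr$spec$pixel_size,
    vertex_coords = unname(apply(tr$vertex_coords, 1,
                                 function(x) x - 1, simplify = FALSE)),
    vertex_cells = lapply(tr$vertex_cells, function(x) x - 1L),
    cell_polygons = lapply(tr$polygons, function(p)
      if (is.null(p)) NULL else p - 1L),
    cell_adjacency = unname(as.matrix(tr$adjacency)) - 1L,
    expected_tl = tr$expected_tl,
    leader = if (is.null(tr$leader)) NULL else tr$leader - 1L,
    rows = if (is.null(tr$rows)) NULL else tr$rows$row)
  jp <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, jp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, jp))
}
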