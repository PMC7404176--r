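# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Shift a matrix by (dr, dc), filling vacated entries.
shift_mat <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

OFFS8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
OFFS4 <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))

# Offsets of a filled disc of radius r (pixel centers), with distances.
disc_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  d <- sqrt(g$dr^2 + g$dc^2)
  keep <- d <= r
  cbind(dr = g$dr[keep], dc = g$dc[keep], dist = d[keep])
}

# Label connected components of a logical mask. 4-connectivity delegates to
# EBImage::bwlabel; 8-connectivity builds pixel adjacency and uses igraph.
label_components <- function(mask, connectivity = 8) {
  mask <- mask != 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (connectivity == 4) {
    return(matrix(as.integer(EBImage::imageData(EBImage::bwlabel(mask * 1))),
                  nrow(mask), ncol(mask)))
  }
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  id <- matrix(0L, H, W)
  id[idx] <- seq_along(idx)
  edges <- list()
  # four directed offsets cover all 8-neighbor pairs once
  for (k in seq_len(4)) {
    off <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))[[k]]
    sh <- shift_mat(id, -off[1], -off[2], fill = 0L)  # neighbor's id at pixel
    both <- mask & sh > 0
    if (any(both)) edges[[length(edges) + 1L]] <- cbind(id[both], sh[both])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership
  lab <- matrix(0L, H, W)
  lab[idx] <- as.integer(memb)
  lab
}

# Count of foreground 8-neighbors for every pixel of a logical mask.
neighbor_count8 <- function(mask) {
  m <- mask * 1L
  s <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(nrow(OFFS8)))
    s <- s + shift_mat(m, OFFS8[k, 1], OFFS8[k, 2], fill = 0L)
  s
}

# Convert between linear indices and (row, col) for an H x W matrix.
rc_from_idx <- function(idx, H) cbind(row = ((idx - 1L) %% H) + 1L,
                                      col = ((idx - 1L) %/% H) + 1L)
idx_from_rc <- function(rc, H) (rc[, 2] - 1L) * H + rc[, 1]

# Chain length of an ordered pixel path: 1 per axial step, sqrt(2) diagonal.
path_length <- function(path) {
  if (is.null(path) || nrow(path) < 2) return(0)
  dr <- abs(diff(path[, 1])); dc <- abs(diff(path[, 2]))
  sum(ifelse(dr + dc == 2, sqrt(2), 1))
}

# Greedy nearest-pair matching between two coordinate sets within `tol` px.
# Returns a two-column matrix of (index_a, index_b) matched pairs.
match_points <- function(a, b, tol = 3) {
  if (nrow(a) == 0 || nrow(b) == 0) return(cbind(integer(0), integer(0)))
  d <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  cand <- which(d <= tol^2, arr.ind = TRUE)
  if (nrow(cand) == 0) return(cbind(integer(0), integer(0)))
  cand <- cand[order(d[cand]), , drop = FALSE]
  usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ia <- cand[i, 1]; ib <- cand[i, 2]
    if (!usedA[ia] && !usedB[ib]) {
      keep[i] <- TRUE; usedA[ia] <- TRUE; usedB[ib] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

as_intensity_matrix <- function(x, what = "image") {
  if (inherits(x, "tj_projection")) x <- x$pixels
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix", what)
  x
}
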