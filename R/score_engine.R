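# Shared mask construction and scoring used by both the pipeline scorer
# (detected graph) and the synthetic ground-truth oracle (true geometry).
#
# Masks per vertex:
#  * tricellular mask: disc of radius r_tri at the vertex, intersected with a
#    dilation (half-width w_bi) of the thin junction network; pixels claimed
#    by several discs go to the nearest vertex.
#  * bicellular mask: the vertex's incident junction paths dilated by w_bi,
#    intersected with the binarized junction foreground, minus every
#    tricellular disc (of any vertex).
tl_score_engine <- function(coords, edge_px, network_mask, boundary_fg, tric,
                            r_tri = 4, w_bi = 2,
                            tl_form = c("normalized", "raw-clipped")) {
  tl_form <- match.arg(tl_form)
  H <- nrow(tric); W <- ncol(tric)
  nv <- nrow(coords)
  empty <- data.frame(vertex = integer(0), I_tri = numeric(0),
                      I_bi = numeric(0), T_L = numeric(0),
                      n_tri = integer(0), n_bi = integer(0),
                      unscorable = logical(0))
  if (nv == 0) return(empty)
  brush_sz <- 2 * w_bi + 1
  netdil <- EBImage::imageData(EBImage::dilate(
    network_mask * 1, EBImage::makeBrush(brush_sz, "disc"))) > 0

  # resolve overlapping tricellular discs: nearest vertex wins
  dof <- disc_offsets(r_tri)
  rr <- round(coords[, 1]); cc <- round(coords[, 2])
  claim_idx <- integer(0); claim_v <- integer(0); claim_d <- numeric(0)
  for (v in seq_len(nv)) {
    pr <- rr[v] + dof[, "dr"]; pc <- cc[v] + dof[, "dc"]
    ok <- pr >= 1 & pr <= H & pc >= 1 & pc <= W
    claim_idx <- c(claim_idx, (pc[ok] - 1L) * H + pr[ok])
    claim_v <- c(claim_v, rep(v, sum(ok)))
    claim_d <- c(claim_d, dof[ok, "dist"])
  }
  o <- order(claim_idx, claim_d)
  first <- !duplicated(claim_idx[o])
  owner_idx <- claim_idx[o][first]
  owner_v <- claim_v[o][first]
  disc_any <- logical(H * W)
  disc_any[claim_idx] <- TRUE
  tri_sets <- split(owner_idx, owner_v)

  bof <- disc_offsets(w_bi)
  net_vec <- as.vector(netdil)
  fg_vec <- as.vector(boundary_fg)
  I_tri_v <- I_bi_v <- tl_v <- rep(NA_real_, nv)
  n_tri_v <- n_bi_v <- integer(nv)
  unsc_v <- logical(nv)
  for (v in seq_len(nv)) {
    tri <- tri_sets[[as.character(v)]]
    tri <- tri[net_vec[tri]]
    ep <- edge_px[[v]]
    bi <- integer(0)
    if (length(ep)) {
      rc <- rc_from_idx(ep, H)
      pr <- rep(rc[, 1], each = nrow(bof)) + rep(bof[, "dr"], nrow(rc))
      pc <- rep(rc[, 2], each = nrow(bof)) + rep(bof[, "dc"], nrow(rc))
      ok <- pr >= 1 & pr <= H & pc >= 1 & pc <= W
      bi <- unique((pc[ok] - 1L) * H + pr[ok])
      bi <- bi[fg_vec[bi] & !disc_any[bi]]
    }
    n_tri <- length(tri); n_bi <- length(bi)
    I_tri <- if (n_tri) mean(tric[tri]) else NA_real_
    I_bi <- if (n_bi) mean(tric[bi]) else NA_real_
    unsc <- n_tri == 0 || n_bi == 0
    tl <- NA_real_
    if (!unsc) {
      if (tl_form == "normalized") {
        tl <- if (I_tri + I_bi <= 0) 0 else I_tri / (I_tri + I_bi)
      } else {
        tl <- if (I_bi <= 0) (if (I_tri > 0) 1 else 0) else
          min(I_tri / I_bi, 1)
      }
    }
    I_tri_v[v] <- I_tri; I_bi_v[v] <- I_bi; tl_v[v] <- tl
    n_tri_v[v] <- n_tri; n_bi_v[v] <- n_bi; unsc_v[v] <- unsc
  }
  data.frame(vertex = seq_len(nv), I_tri = I_tri_v, I_bi = I_bi_v,
             T_L = tl_v, n_tri = n_tri_v, n_bi = n_bi_v,
             unscorable = unsc_v)
}
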