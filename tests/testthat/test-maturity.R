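test_that("localization score takes its boundary values", {
  # equal mean intensities -> 0.5; empty bicellular signal -> 1; dark -> 0
  m <- fx_mono()
  flat <- matrix(5, m$graph$dim[1], m$graph$dim[2])
  vs <- score_vertices(m$graph, flat, m$boundary)
  sc <- vs[!vs$unscorable, ]
  expect_true(all(abs(sc$T_L - 0.5) < 1e-12))
  dark <- matrix(0, m$graph$dim[1], m$graph$dim[2])
  vs0 <- score_vertices(m$graph, dark, m$boundary)
  expect_true(all(vs0$T_L[!vs0$unscorable] == 0))
  # punctae only, nothing on the lines -> 1
  tric <- matrix(0, m$graph$dim[1], m$graph$dim[2])
  vt <- m$graph$vertices
  tric[cbind(round(vt$relocated_row), round(vt$relocated_col))] <- 50
  vs1 <- score_vertices(m$graph, tric, m$boundary)
  hit <- !vs1$unscorable & vs1$I_tri > 0
  expect_true(all(vs1$T_L[hit] == 1))
})

test_that("scores live in [0,1] and ignore global intensity scaling", {
  m <- fx_mono()
  vs <- m$scores
  expect_true(all(vs$T_L[!vs$unscorable] >= 0 & vs$T_L[!vs$unscorable] <= 1))
  vs10 <- score_vertices(m$graph, m$sim$tric * 10, m$boundary)
  expect_equal(vs10$T_L, vs$T_L, tolerance = 1e-12)
})

test_that("tricellular and bicellular masks are disjoint across all vertices", {
  m <- fx_mono()
  H <- m$graph$dim[1]
  # tri masks are discs around vertices and bi masks exclude every disc, so
  # a tric image lit only inside the discs must give I_bi exactly 0
  tric <- matrix(0, H, m$graph$dim[2])
  vt <- m$graph$vertices
  dof <- trijunct:::disc_offsets(4)
  for (v in seq_len(nrow(vt))) {
    pr <- round(vt$relocated_row[v]) + dof[, "dr"]
    pc <- round(vt$relocated_col[v]) + dof[, "dc"]
    ok <- pr >= 1 & pr <= H & pc >= 1 & pc <= m$graph$dim[2]
    tric[cbind(pr[ok], pc[ok])] <- 9
  }
  vs <- score_vertices(m$graph, tric, m$boundary)
  expect_true(all(vs$I_bi[!vs$unscorable] == 0))
})

test_that("recovered scores match the rendered-image oracle", {
  m <- fx_mono()
  vs <- m$scores
  keep <- !m$graph$vertices$border & !vs$unscorable
  mt <- trijunct:::match_points(cbind(vs$row, vs$col)[keep, , drop = FALSE],
                                m$sim$truth$vertex_coords, tol = 4)
  expect_gt(nrow(mt), 10)
  err <- abs(vs$T_L[keep][mt[, 1]] - m$sim$truth$expected_tl[mt[, 2]])
  expect_lt(median(err, na.rm = TRUE), 0.05)
})

test_that("raw-clipped score form is available and bounded", {
  m <- fx_mono()
  vs <- score_vertices(m$graph, m$sim$tric, m$boundary, tl_form = "raw-clipped")
  sc <- vs$T_L[!vs$unscorable]
  expect_true(all(sc >= 0 & sc <= 1))
  # enrichment 2 saturates the raw ratio at 1 for most vertices
  expect_gt(median(sc), 0.9)
})

test_that("cell aggregation is the plain mean over incident scored vertices", {
  g <- list(vertex_cells = list(c(1, 2), c(1, 2), 2))
  class(g) <- "tj_graph"
  vs <- data.frame(vertex_id = 1:3, T_L = c(0.2, 0.4, NA),
                   unscorable = c(FALSE, FALSE, TRUE))
  ct <- score_cells(g, vs)
  expect_equal(ct$T_L_cell[1], 0.3)
  expect_equal(ct$T_L_cell[2], 0.3)
  expect_equal(ct$n_vertices_scored, c(2L, 2L))
})

test_that("row assignment is breadth-first distance from the leader", {
  chain <- cbind(1:5, 2:6)
  rows <- assign_rows(chain, leader_cell_id = 1)
  expect_equal(rows$row, 1:6)
  # leader's direct neighbors are row 2
  star <- cbind(c(1, 1, 1, 2), c(2, 3, 4, 5))
  rs <- assign_rows(star, leader_cell_id = 1)
  expect_equal(rs$row[rs$cell_id == 1], 1)
  expect_true(all(rs$row[rs$cell_id %in% 2:4] == 2))
  expect_equal(rs$row[rs$cell_id == 5], 3)
  # unreachable cells are missing
  disc <- rbind(cbind(1, 2), cbind(3, 4))
  rd <- assign_rows(disc, 1)
  expect_true(all(is.na(rd$row[rd$cell_id %in% c(3, 4)])))
  # adjacency invariant on a detected monolayer
  m <- fx_mono()
  adj <- m$graph$cell_adjacency
  lead <- m$cells$table$id[!m$cells$table$border][1]
  rr <- assign_rows(adj, lead)
  lut <- stats::setNames(rr$row, rr$cell_id)
  dif <- abs(lut[as.character(adj[, 1])] - lut[as.character(adj[, 2])])
  expect_true(all(dif[!is.na(dif)] <= 1))
})

test_that("row profiles report SEM and flag single-cell rows as missing", {
  rows <- data.frame(cell_id = 1:5, row = c(1, 2, 2, 3, 15))
  tl <- data.frame(cell_id = 1:5, T_L_cell = c(0.1, 0.3, 0.5, 0.4, 0.45),
                   n_vertices_scored = 3)
  areas <- data.frame(id = 1:5, A_px = c(500, 300, 320, 280, 260))
  rp <- rowwise_profile(rows, tl, areas, interior_reference_row = 15)
  expect_true(is.na(rp$profile$sem_TL[rp$profile$row == 1]))
  expect_false(is.na(rp$profile$sem_TL[rp$profile$row == 2]))
  expect_equal(rp$profile$mean_TL[rp$profile$row == 2], 0.4)
  expect_equal(rp$reference$mean_TL, 0.45)
})

test_that("triplet grouping requires full label agreement, also at degree 4", {
  g <- list(vertex_cells = list(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4, 5),
                                c(1, 2, 6)))
  class(g) <- "tj_graph"
  labs <- data.frame(cell_id = 1:5,
                     label = c("G1", "G1", "G1", "S-G2", "G1"))
  tb <- triplet_by_label(g, labs)
  expect_equal(tb$group, c("G1", "mixed", "mixed", NA))
})

test_that("KS comparison agrees with a brute-force ECDF oracle", {
  expect_equal(compare_groups(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))$D, 1 / 3,
               tolerance = 1e-12)
  same <- c(0.15, 0.4, 0.62, 0.8)
  expect_equal(compare_groups(same, same)$D, 0)
  expect_equal(compare_groups(same, same)$p.value, 1)
  set.seed(7)
  for (i in 1:10) {
    a <- runif(sample(3:12, 1)); b <- runif(sample(3:12, 1))
    expect_equal(compare_groups(a, b)$D, ks_oracle(a, b), tolerance = 1e-12)
  }
  # disjoint supports -> D = 1
  expect_equal(compare_groups(runif(100, 0, 0.5), runif(100, 0.5, 1))$D, 1)
  expect_error(compare_groups(0.3, c(0.1, 0.2)), "at least 2")
})

test_that("control normalization rescales means and leaves KS invariant", {
  vals <- c(1, 2, 3, 2, 4, 6)
  grp <- rep(c("ctl", "trt"), each = 3)
  nn <- normalize_to_control(vals, grp, "ctl")
  expect_equal(mean(nn$normalized[nn$group == "ctl"]), 1)
  expect_equal(mean(nn$normalized[nn$group == "trt"]), 2)
  a <- runif(30); b <- runif(30, 0.2, 1.2)
  expect_equal(compare_groups(a, b)$D,
               compare_groups(a / mean(a), b / mean(a))$D)
  expect_error(normalize_to_control(vals, grp, "absent"), "empty")
})
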