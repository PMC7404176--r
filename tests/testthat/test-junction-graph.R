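test_that("binarization recovers rendered boundaries and fails loudly on blanks", {
  m <- fx_mono()
  expect_gt(mean(m$boundary[m$sim$truth$boundary_mask]), 0.99)
  expect_error(binarize_junctions(matrix(0, 50, 50)), "no signal|sensitivity")
  # 10% noise: network still one spanning component
  simn <- generate_tessellation(tessellation_spec(n_cells = 25,
                                                  image_size = c(256, 256),
                                                  seed = 3, enrichment = 2,
                                                  noise_sd = 20))
  bn <- binarize_junctions(simn$zo1)
  lab <- trijunct:::label_components(bn, 8)
  big <- which.max(tabulate(lab))
  expect_gt(mean(lab[bn] == big), 0.95)
})

test_that("thinning produces idempotent single-pixel skeletons", {
  # 5-px-wide bar -> a single 1-px line
  bar <- matrix(FALSE, 30, 40)
  bar[13:17, 5:35] <- TRUE
  sk <- skeletonize(bar)
  expect_true(all(colSums(sk[, 8:32]) == 1))
  expect_true(all(sk[15, 8:32]))
  expect_identical(skeletonize(sk), sk)
  # no 2x2 solid block anywhere
  s <- sk * 1
  solid <- s[-nrow(s), -ncol(s)] & s[-nrow(s), -1] & s[-1, -ncol(s)] & s[-1, -1]
  expect_equal(sum(solid), 0)
})

test_that("thinning preserves the Euler number of the boundary network", {
  m <- fx_mono()
  expect_equal(euler_number(m$skel), euler_number(m$boundary))
  # a ring keeps its hole
  d <- sqrt(outer((1:60 - 30)^2, (1:60 - 30)^2, "+"))
  ring <- d >= 15 & d <= 20
  skr <- skeletonize(ring)
  expect_equal(euler_number(skr), 0)  # one component, one hole
})

test_that("pixel counting finds Y junctions and none on plain lines", {
  Y <- matrix(FALSE, 40, 40)
  Y[20, 5:20] <- TRUE
  for (k in 0:14) { Y[20 - k, 20 + k] <- TRUE; Y[20 + k, 20 + k] <- TRUE }
  vd <- detect_vertices(skeletonize(Y))
  expect_equal(nrow(vd$table), 1)
  expect_lt(abs(vd$table$row[1] - 20) + abs(vd$table$col[1] - 20), 4)
  line <- matrix(FALSE, 20, 40); line[10, 3:37] <- TRUE
  expect_equal(nrow(detect_vertices(line)$table), 0)
})

test_that("vertex detection matches synthetic ground truth closely", {
  m <- fx_mono()
  det <- detected_interior_vertices(m$graph)
  mt <- trijunct:::match_points(det, m$sim$truth$vertex_coords, tol = 3)
  P <- nrow(mt) / nrow(det)
  R <- nrow(mt) / nrow(m$sim$truth$vertex_coords)
  expect_gt(2 * P * R / (P + R), 0.95)
})

test_that("graph building prunes spurs and dissolves degree-2 vertices", {
  # T with a 4-px spur on one arm
  sk <- matrix(FALSE, 40, 60)
  sk[20, 5:55] <- TRUE
  sk[21:35, 30] <- TRUE      # stem -> one real junction
  sk[19:16, 40] <- TRUE      # 4-px spur
  g <- build_graph(sk, detect_vertices(sk), min_branch_len = 10)
  deg3 <- sum(g$vertices$degree >= 3)
  expect_equal(deg3, 1)
  # the spur is gone: no remaining edge contains its pixels
  spur_present <- any(vapply(g$edges, function(e)
    any(e$path[, 2] == 40 & e$path[, 1] < 20), logical(1)))
  expect_false(spur_present)
  # all non-border vertices in the standard fixture have degree >= 3
  m <- fx_mono()
  vt <- m$graph$vertices
  expect_true(all(vt$degree[!vt$border & vt$degree > 0] >= 3))
})

test_that("interior subdivision satisfies the planar Euler relation", {
  m <- fx_mono()
  eu <- euler_summary(m$graph, m$cells)
  expect_true(all(eu$patches$euler == 1))
  expect_equal(eu$euler, eu$n_patches)
})

test_that("relocation snaps to punctae and never exceeds the search radius", {
  m <- fx_mono()
  vt <- m$graph$vertices
  expect_true(all(!vt$unrelocated[!vt$border]))
  disp <- sqrt((vt$relocated_row - vt$row)^2 + (vt$relocated_col - vt$col)^2)
  expect_true(all(disp <= 5 + 1e-9))
  rel <- cbind(vt$relocated_row, vt$relocated_col)[!vt$border, ]
  mt <- trijunct:::match_points(rel, m$sim$truth$vertex_coords, tol = 5)
  err <- sqrt(rowSums((rel[mt[, 1], ] -
                         m$sim$truth$vertex_coords[mt[, 2], ])^2))
  expect_lt(mean(err), 1.5)
})

test_that("without punctae every vertex stays put, flagged unrelocated", {
  sim0 <- generate_tessellation(tessellation_spec(n_cells = 16,
                                                  image_size = c(160, 160),
                                                  seed = 4, enrichment = 0))
  sk <- skeletonize(binarize_junctions(sim0$zo1))
  g <- build_graph(sk, detect_vertices(sk))
  g <- relocate_vertices(g, sim0$tric)
  expect_true(all(g$vertices$unrelocated))
  expect_equal(g$vertices$relocated_row, as.numeric(g$vertices$row))
})

test_that("edit scripts apply in order with an audit trail", {
  m <- fx_mono()
  g <- m$graph
  g0 <- apply_edits(g, list())
  expect_identical(g0$vertices, g$vertices)
  expect_length(attr(g0, "audit"), 0)
  # move then delete
  v <- which(g$vertices$degree == 3 & !g$vertices$border)[1]
  g1 <- apply_edits(g, list(
    list(op = "move_vertex", id = v, coords = c(100, 100)),
    list(op = "delete_vertex", id = v)))
  expect_length(attr(g1, "audit"), 2)
  expect_equal(g1$vertices$degree[v], 0)
  expect_lt(length(g1$edges), length(g$edges))
  # auxiliary point becomes a polygon vertex of its cell
  cells <- m$cells
  ci <- cells$table$id[!cells$table$border][1]
  ga <- apply_edits(g, list(list(
    op = "add_auxiliary_point",
    coords = c(cells$table$centroid_row[ci] + 1, cells$table$centroid_col[ci]),
    cell_id = ci)))
  ga <- link_cells(ga, cells)
  pa <- polygonize(cells, ga)
  p0 <- polygonize(cells, link_cells(g, cells))
  expect_equal(pa$table$n_vertices[ci], p0$table$n_vertices[ci] + 1)
  # bad reference names the command index
  expect_error(apply_edits(g, list(list(op = "delete_vertex", id = 99999))),
               "edit 1")
})

test_that("graph JSON serialization writes 0-based coordinates", {
  m <- fx_mono()
  path <- withr::local_tempfile(fileext = ".json")
  write_graph_json(m$graph, path, params = list(seed = 3))
  js <- jsonlite::read_json(path)
  expect_equal(length(js$vertices), nrow(m$graph$vertices))
  expect_equal(js$vertices[[1]]$coords[[1]], m$graph$vertices$row[1] - 1)
  expect_equal(js$provenance$seed, 3)
})
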