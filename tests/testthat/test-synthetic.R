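test_that("spec validation rejects impossible geometries", {
  expect_error(tessellation_spec(n_cells = 2), "n_cells")
  expect_error(tessellation_spec(n_cells = 400, image_size = c(64, 64),
                                 boundary_width = 4), "too small")
  expect_error(tessellation_spec(enrichment = -1), "rho")
})

test_that("rendering is bit-reproducible for a fixed seed", {
  spec <- tessellation_spec(n_cells = 16, image_size = c(128, 128), seed = 11,
                            enrichment = 1.5, noise_sd = 8)
  s1 <- generate_tessellation(spec)
  s2 <- generate_tessellation(spec)
  expect_identical(s1$zo1, s2$zo1)
  expect_identical(s1$tric, s2$tric)
  expect_identical(s1$nuclei, s2$nuclei)
  expect_identical(s1$truth$vertex_coords, s2$truth$vertex_coords)
})

test_that("zero enrichment removes punctae: tric equals zo1", {
  sim <- generate_tessellation(tessellation_spec(n_cells = 16,
                                                 image_size = c(128, 128),
                                                 seed = 2, enrichment = 0))
  expect_identical(sim$zo1, sim$tric)
})

test_that("ground-truth vertices join exactly three cells and tile the interior", {
  m <- fx_mono()
  tr <- m$sim$truth
  expect_true(all(lengths(tr$vertex_cells) >= 3))
  expect_gt(mean(lengths(tr$vertex_cells) == 3), 0.9)
  interior <- which(!tr$cells$border)
  polys <- tr$polygons[interior]
  expect_true(all(!vapply(polys, is.null, logical(1))))
  expect_true(all(vapply(polys, length, integer(1)) >= 3))
  # polygon areas of interior cells track the pixel-region areas
  for (i in seq_along(interior)) {
    pts <- tr$vertex_coords[polys[[i]], , drop = FALSE]
    expect_lt(abs(polygon_area(pts) - tr$cells$area_px[interior[i]]) /
                tr$cells$area_px[interior[i]], 0.15)
  }
})

test_that("boundary-line versus puncta-peak intensity follows the enrichment", {
  for (rho in c(1, 4)) {
    sim <- generate_tessellation(tessellation_spec(n_cells = 16,
                                                   image_size = c(160, 160),
                                                   seed = 6, enrichment = rho,
                                                   puncta_sigma = 2))
    tr <- sim$truth
    centers <- round(tr$vertex_coords)
    peak <- mean(sim$tric[centers])
    # full-intensity interface pixels away from any puncta
    d2v <- matrix(Inf, nrow(sim$tric), ncol(sim$tric))
    for (v in seq_len(nrow(centers))) {
      d2 <- outer((seq_len(nrow(sim$tric)) - centers[v, 1])^2,
                  (seq_len(ncol(sim$tric)) - centers[v, 2])^2, "+")
      d2v <- pmin(d2v, d2)
    }
    line <- tr$core & d2v > 12^2
    ratio <- mean(sim$tric[line]) / peak
    # punctae are additive on the boundary line: peak = (1 + rho) x line
    expect_lt(abs(ratio - 1 / (1 + rho)), 0.1 * 1 / (1 + rho))
  }
})

test_that("expected localization oracle increases with enrichment", {
  meds <- vapply(c(0.5, 2, 8), function(rho) {
    sim <- generate_tessellation(tessellation_spec(n_cells = 16,
                                                   image_size = c(160, 160),
                                                   seed = 8, enrichment = rho))
    median(sim$truth$expected_tl, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  expect_true(all(meds >= 0 & meds <= 1))
})

test_that("wound front assigns rows by adjacency distance from one leader", {
  spec <- tessellation_spec(n_cells = 40, image_size = c(320, 320), seed = 13,
                            enrichment = 2)
  sim <- generate_wound_front(spec, rho_by_row = c(0.5, 2, 2, 2))
  tr <- sim$truth
  expect_length(tr$leader, 1)
  expect_equal(tr$rows$row[tr$leader], 1)
  # adjacent cells differ by at most one row
  adj <- tr$adjacency
  r <- tr$rows$row
  dif <- abs(r[adj$a] - r[adj$b])
  expect_true(all(dif[!is.na(dif)] <= 1))
  # vertices on young rows carry lower expected scores than interior ones
  young <- tr$vertex_row <= 1
  old <- tr$vertex_row >= 3
  expect_lt(mean(tr$expected_tl[young], na.rm = TRUE),
            mean(tr$expected_tl[old], na.rm = TRUE))
})

test_that("z-stacks encode the focus profile and respect ties", {
  sim <- generate_tessellation(tessellation_spec(n_cells = 16,
                                                 image_size = c(120, 120),
                                                 seed = 2))
  prof <- focus_profile(c(6, 6), c(1, 3))
  zs <- generate_zstack(sim, n_slices = 3, profile = prof)
  expect_equal(dim(zs$stacks$zo1), c(3, 120, 120))
  # the in-focus slice holds the sharp data
  sig <- focus_signal_blocks(sim$noiseless$zo1, 20)
  for (i in 1:6) for (j in 1:6) {
    if (!sig[i, j]) next
    rs <- (i * 20 - 19):(i * 20); cs <- (j * 20 - 19):(j * 20)
    expect_equal(zs$stacks$zo1[prof[i, j], rs, cs], sim$zo1[rs, cs])
  }
  # no blur difference: all slices equal
  zs0 <- generate_zstack(sim, n_slices = 2, profile = focus_profile(c(6, 6), 2),
                         defocus_sigma = 0)
  expect_equal(zs0$stacks$zo1[1, , ], zs0$stacks$zo1[2, , ])
})

test_that("simulation export round-trips through TIFF and JSON", {
  sim <- generate_tessellation(tessellation_spec(n_cells = 9,
                                                 image_size = c(96, 96),
                                                 seed = 4, enrichment = 2))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  z <- read_stack(file.path(dir, "zo1.tif"))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_lt(max(abs(z * gt$intensity_scale - sim$zo1)), 1e-4)
  expect_length(gt$vertex_coords, nrow(sim$truth$vertex_coords))
  # exported coordinates are 0-based
  expect_equal(gt$vertex_coords[[1]][[1]], sim$truth$vertex_coords[1, 1] - 1)
})
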