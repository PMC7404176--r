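# Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# Standard noiseless 25-cell monolayer plus its full detection chain.
fx_mono <- function() fx("mono", function() {
  spec <- tessellation_spec(n_cells = 25, image_size = c(256, 256), seed = 3,
                            enrichment = 2)
  sim <- generate_tessellation(spec)
  boundary <- binarize_junctions(sim$zo1)
  skel <- skeletonize(boundary)
  graph <- build_graph(skel, detect_vertices(skel))
  graph <- relocate_vertices(graph, sim$tric)
  cells <- segment_cells(graph$skeleton)
  graph <- link_cells(graph, cells)
  cells <- polygonize(cells, graph)
  scores <- score_vertices(graph, sim$tric, boundary)
  list(spec = spec, sim = sim, boundary = boundary, skel = skel,
       graph = graph, cells = cells, scores = scores)
})

# Small noisy monolayer for the noise/contrast path.
fx_noisy <- function() fx("noisy", function() {
  spec <- tessellation_spec(n_cells = 16, image_size = c(160, 160), seed = 5,
                            enrichment = 3, noise_sd = 10)
  generate_tessellation(spec)
})

# Hand-drawn skeleton: 3 x 3 grid of 40-px square cells inside a frame.
fx_lattice <- function() fx("lattice", function() {
  n <- 140
  sk <- matrix(FALSE, n, n)
  for (p in c(10, 50, 90, 130)) { sk[p, 10:130] <- TRUE; sk[10:130, p] <- TRUE }
  sk[1, ] <- TRUE; sk[n, ] <- TRUE; sk[, 1] <- TRUE; sk[, n] <- TRUE
  sk
})

# Brute-force two-sample KS statistic: sup over the pooled sample of the
# ECDF difference (independent oracle for compare_groups).
ks_oracle <- function(a, b) {
  x <- sort(unique(c(a, b)))
  Fa <- vapply(x, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(x, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Euler number (components minus holes) of a binary mask.
euler_number <- function(mask) {
  fg <- max(trijunct:::label_components(mask, connectivity = 8))
  padded <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  bg <- max(trijunct:::label_components(!padded, connectivity = 4))
  fg - (bg - 1)
}

detected_interior_vertices <- function(graph) {
  keep <- !graph$vertices$border & graph$vertices$degree >= 3
  as.matrix(graph$vertices[keep, c("row", "col")])
}
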