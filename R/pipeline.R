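#' Read a single- or multi-page TIFF as image or stack
#'
#' Multi-page files come back as a 3D array (slice, row, col), single pages
#' as a matrix. Intensity scaling follows the `tiff` package conventions;
#' every downstream score is invariant to a global positive scale.
#'
#' @param path TIFF file.
#' @return numeric matrix or 3D array.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # first channel of RGB pages
    p
  })
  if (length(pages) == 1) return(pages[[1]])
  st <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (s in seq_along(pages)) st[s, , ] <- pages[[s]]
  st
}

#' Assemble a pipeline configuration
#'
#' All tunable parameters of the pipeline in one serializable object; a run
#' is reproducible from its configuration (plus input files). Either give
#' file paths for the channels (`zo1`, `tric`, `nuclei`) or a
#' [tessellation_spec()] in `simulation`.
#'
#' @param zo1,tric,nuclei TIFF paths (each single- or multi-page), or `NULL`.
#' @param simulation optional `tj_spec`; overrides the file inputs.
#' @param out_dir output directory.
#' @param block_size guided-projection block size (px).
#' @param sensitivity,min_object_area,close_radius binarization parameters.
#' @param min_branch_len spur-pruning threshold (px).
#' @param search_radius vertex relocation radius (px).
#' @param r_tri,w_bi scoring mask parameters (px).
#' @param tl_form `"normalized"` or `"raw-clipped"`.
#' @param pixel_size micrometres per pixel.
#' @param edits optional edit script (list or JSON path).
#' @param seed RNG seed recorded with the run.
#' @return list of class `tj_config`.
#' @export
run_config <- function(zo1 = NULL, tric = NULL, nuclei = NULL,
                       simulation = NULL, out_dir = NULL,
                       block_size = 20, sensitivity = 0.1,
                       min_object_area = 64, close_radius = 2,
                       min_branch_len = 10, search_radius = 5,
                       r_tri = 4, w_bi = 2, tl_form = "normalized",
                       pixel_size = 0.3, edits = NULL, seed = 1) {
  structure(list(zo1 = zo1, tric = tric, nuclei = nuclei,
                 simulation = simulation, out_dir = out_dir,
                 block_size = block_size, sensitivity = sensitivity,
                 min_object_area = min_object_area,
                 close_radius = close_radius,
                 min_branch_len = min_branch_len,
                 search_radius = search_radius, r_tri = r_tri, w_bi = w_bi,
                 tl_form = tl_form, pixel_size = pixel_size, edits = edits,
                 seed = as.integer(seed)),
            class = "tj_config")
}

.load_channel <- function(config, name) {
  if (!is.null(config$simulation)) return(NULL)  # handled by caller
  p <- config[[name]]
  if (is.null(p)) return(NULL)
  if (!file.exists(p)) stopf("input file for channel '%s' not found: %s",
                             name, p)
  read_stack(p)
}

#' Run the full pipeline
#'
#' project -> binarize -> skeletonize -> vertices -> graph -> (edits) ->
#' relocate -> segment -> polygonize -> geometry -> score. Any stage
#' failure aborts with the stage name. Without a tricellular channel the
#' pipeline runs in geometry-only mode (no localization score) with an
#' explicit notice. When `config$out_dir` is set, CSV/JSON outputs, the
#' serialized configuration and a per-stage log are written there; reruns
#' with identical config and inputs are byte-identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `graph`, `cells`, `geometry`, `summary`,
#'   `vertex_scores`, `cell_scores`, `noise_model`, `log`, and `truth` when
#'   simulating.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tj_config"))
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", generate_tessellation(config$simulation,
                                                   r_tri = config$r_tri,
                                                   w_bi = config$w_bi))
    zo1 <- sim$zo1; tric <- sim$tric; nuclei <- sim$nuclei
    truth <- sim$truth
  } else {
    zo1 <- stage("load", .load_channel(config, "zo1"))
    tric <- stage("load", .load_channel(config, "tric"))
    nuclei <- stage("load", .load_channel(config, "nuclei"))
    if (is.null(zo1)) stopf("pipeline stage 'load' failed: a junctional (zo1) channel is required")
  }
  # projection: guided by the junctional stack when stacks are supplied
  if (length(dim(zo1)) == 3) {
    guide <- zo1
    zo1 <- stage("project", guided_block_projection(guide, guide,
                                                    config$block_size))
    prov <- zo1$provenance; zo1 <- zo1$pixels
    if (!is.null(tric) && length(dim(tric)) == 3)
      tric <- stage("project", guided_block_projection(guide, tric,
                                                       config$block_size))$pixels
    if (!is.null(nuclei) && length(dim(nuclei)) == 3)
      nuclei <- stage("project", guided_block_projection(guide, nuclei,
                                                         config$block_size))$pixels
    log$projection_blocks <- dim(prov)
  }
  noise_model <- NULL
  if (!is.null(tric)) {
    if (!is.null(nuclei)) {
      nmask <- stage("noise", nuclear_mask(nuclei))
      noise_model <- stage("noise", estimate_noise(tric, nmask))
      tric <- stage("adjust", adjust_contrast(tric, noise_model))
    } else {
      message("no nuclear channel: skipping noise estimation, using raw tricellular intensities")
    }
  } else {
    message("no tricellular channel: geometry-only mode, localization scores unavailable")
  }
  boundary <- stage("binarize",
                    binarize_junctions(zo1, sensitivity = config$sensitivity,
                                       min_object_area = config$min_object_area,
                                       close_radius = config$close_radius))
  skel <- stage("skeletonize", skeletonize(boundary))
  verts <- stage("vertices", detect_vertices(skel))
  graph <- stage("graph", build_graph(skel, verts, config$min_branch_len))
  if (!is.null(config$edits))
    graph <- stage("edits", apply_edits(graph, config$edits))
  if (!is.null(tric))
    graph <- stage("relocate",
                   relocate_vertices(graph, tric, config$search_radius))
  cells <- stage("segment", segment_cells(graph$skeleton))
  graph <- stage("link", link_cells(graph, cells))
  cells <- stage("polygonize", polygonize(cells, graph))
  geometry <- stage("geometry", cell_geometry(cells, config$pixel_size))
  summary <- stage("geometry", summarize_monolayer(cells, config$pixel_size))
  vertex_scores <- NULL; cell_scores <- NULL
  if (!is.null(tric)) {
    vertex_scores <- stage("score",
                           score_vertices(graph, tric, boundary,
                                          r_tri = config$r_tri,
                                          w_bi = config$w_bi,
                                          tl_form = config$tl_form))
    cell_scores <- stage("score", score_cells(graph, vertex_scores))
  }
  log$n_cells <- nrow(cells$table)
  log$n_interior_cells <- sum(!cells$table$border)
  log$n_vertices <- nrow(graph$vertices)
  log$n_edges <- length(graph$edges)
  log$n_scored <- if (is.null(vertex_scores)) 0L else
    sum(!vertex_scores$unscorable)
  log$n_unscorable <- if (is.null(vertex_scores)) NA_integer_ else
    sum(vertex_scores$unscorable)
  log$edits_applied <- length(attr(graph, "audit"))
  out <- list(graph = graph, cells = cells, geometry = geometry,
              summary = summary, vertex_scores = vertex_scores,
              cell_scores = cell_scores, noise_model = noise_model,
              boundary = boundary, tric_adjusted = tric,
              truth = truth, log = log, config = config)
  if (!is.null(config$out_dir)) .write_bundle(out, config$out_dir)
  invisible(out)
}

.write_bundle <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- out$config
  cfg$simulation <- if (is.null(cfg$simulation)) NULL else
    unclass(cfg$simulation)
  jsonlite::write_json(list(config = unclass(cfg),
                            package_version =
                              as.character(utils::packageVersion("trijunct"))),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(out$geometry, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  if (!is.null(out$vertex_scores))
    utils::write.csv(out$vertex_scores, file.path(dir, "vertices.csv"),
                     row.names = FALSE)
  if (!is.null(out$cell_scores))
    utils::write.csv(out$cell_scores, file.path(dir, "cell_scores.csv"),
                     row.names = FALSE)
  utils::write.csv(out$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  write_graph_json(out$graph, file.path(dir, "graph.json"),
                   params = list(seed = out$config$seed))
  jsonlite::write_json(out$log, file.path(dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Render a spatial map of per-cell values
#'
#' Fills each cell polygon with a color encoding its value (shape index,
#' localization score, ...) over the image extent, with a small color bar;
#' cells without a value are hatched.
#'
#' @param cells a `tj_cells` after [polygonize()].
#' @param graph the linked `tj_graph`.
#' @param values named or cell-id-aligned numeric vector, or a data frame
#'   with `cell_id` and a value column.
#' @param file output PNG path.
#' @param range color scale range; defaults to the finite value range.
#' @param palette color ramp endpoints.
#' @param title drawn above the color bar.
#' @return invisibly, `file`.
#' @export
render_map <- function(cells, graph, values, file, range = NULL,
                       palette = c("#2c7bb6", "#ffffbf", "#d7191c"),
                       title = "") {
  if (is.data.frame(values)) {
    vcol <- setdiff(names(values), "cell_id")[1]
    v <- rep(NA_real_, nrow(cells$table))
    v[values$cell_id] <- values[[vcol]]
    values <- v
  }
  H <- dim(cells$labels)[1]; W <- dim(cells$labels)[2]
  if (is.null(range)) {
    fin <- values[is.finite(values)]
    range <- if (length(fin)) base::range(fin) else c(0, 1)
    if (diff(range) == 0) range <- range + c(-0.5, 0.5)
  }
  ramp <- grDevices::colorRamp(palette)
  col_of <- function(x) {
    t <- pmin(pmax((x - range[1]) / diff(range), 0), 1)
    grDevices::rgb(ramp(t), maxColorValue = 255)
  }
  grDevices::png(file, width = W, height = H)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot(NA, xlim = c(0.5, W + 0.5), ylim = c(H + 0.5, 0.5),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  for (i in seq_len(nrow(cells$table))) {
    ids <- cells$polygons[[i]]
    if (is.null(ids) || length(ids) < 3) next
    pr <- ifelse(ids > 0, graph$vertices$relocated_row[pmax(ids, 1)],
                 vapply(-ids, function(a) graph$aux_points[[max(a, 1)]]$row,
                        numeric(1)))
    pc <- ifelse(ids > 0, graph$vertices$relocated_col[pmax(ids, 1)],
                 vapply(-ids, function(a) graph$aux_points[[max(a, 1)]]$col,
                        numeric(1)))
    if (is.na(values[i]) || !is.finite(values[i])) {
      graphics::polygon(pc, pr, border = "grey40", density = 12, angle = 45)
    } else {
      graphics::polygon(pc, pr, border = "grey20", col = col_of(values[i]))
    }
  }
  # color bar, drawn inside the image extent (bottom-left corner)
  nseg <- 50
  x0 <- 0.03 * W; x1 <- 0.28 * W; y0 <- 0.96 * H; y1 <- 0.935 * H
  xs <- seq(x0, x1, length.out = nseg + 1)
  for (s in seq_len(nseg))
    graphics::rect(xs[s], y0, xs[s + 1], y1, border = NA,
                   col = col_of(range[1] + (s - 0.5) / nseg * diff(range)))
  graphics::text(c(x0, x1), y0 + 0.015 * H,
                 labels = formatC(range, format = "g", digits = 3),
                 adj = c(0.5, 1), cex = max(0.6, W / 640))
  if (nzchar(title))
    graphics::text((x0 + x1) / 2, y1 - 0.01 * H, labels = title,
                   adj = c(0.5, 1), cex = max(0.6, W / 640))
  invisible(file)
}
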