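default_config <- function() {
  list(
    input = NULL,            # TIFF path, or a phantom spec YAML via input_phantom
    input_phantom = NULL,
    spacing = c(0.98, 0.98, 5),
    downsampling = 1L,
    segmenter = "chan-vese", # or "external"
    mask_path = NULL,
    iterations = 100L,
    smoothing = 1L,
    init = "otsu",
    align = TRUE,
    mode = "3d",             # or "2d"
    n_r = 3L,
    spline_smoothing = 2L,
    min_branch_length = 0,
    eccentricity = "axis-ratio",
    flow = TRUE,
    pressure_in = 100,
    pressure_out = 0,
    viscosity = 1.0,         # mPa.s
    flow_axis = "x",
    seed = 1L)
}

load_config <- function(config) {
  base <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates the eight stages — input, preprocessing (isotropization
#' and optional downsampling), segmentation, vertical alignment,
#' skeletonization, branch processing, descriptive metrics, and flow/
#' velocity estimation — persisting every stage artifact plus a
#' machine-readable provenance log into `out_dir`. Reruns with the same
#' config produce identical outputs (all stochastic stages are seeded).
#'
#' @param config a named list or path to a YAML file; unset entries take
#'   the package defaults (printed into the provenance log). Recognized
#'   entries include `input` (TIFF path), `input_phantom` (phantom spec
#'   YAML; rendered instead of reading a TIFF), `spacing`,
#'   `downsampling`, `segmenter` (`"chan-vese"` or `"external"` +
#'   `mask_path`), `align`, `mode` (`"3d"`/`"2d"`), `n_r`,
#'   `min_branch_length`, `flow`, `pressure_in`/`pressure_out` (Pa),
#'   `viscosity` (mPa.s), `flow_axis`, `seed`.
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the mask, graph, morphometry table and
#'   flow solution (where applicable).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  img <- stage("input", {
    if (!is.null(cfg$input_phantom)) {
      spec <- if (inherits(cfg$input_phantom, "phantom_spec"))
        cfg$input_phantom else read_phantom_spec(cfg$input_phantom)
      ph <- render_phantom(spec)
      ph$image
    } else {
      read_stack(cfg$input, cfg$spacing)
    }
  })
  img <- stage("preprocess", {
    v <- isotropize(img)
    if (cfg$downsampling > 1L) v <- downsample(v, cfg$downsampling)
    v
  })

  if (identical(cfg$mode, "2d")) {
    tab <- stage("morphometry_2d",
                 analyze_projection(img,
                                    min_branch_length = cfg$min_branch_length,
                                    smoothing = cfg$spline_smoothing))
    utils::write.csv(as.data.frame(tab),
                     file.path(out_dir, "branches_2d.csv"),
                     row.names = FALSE)
    jsonlite::write_json(attr(tab, "summary"),
                         file.path(out_dir, "summary_2d.json"),
                         auto_unbox = TRUE, digits = NA)
    write_provenance(cfg, timings, out_dir, t_start)
    return(invisible(list(table = tab)))
  }

  mask <- stage("segmentation", {
    if (identical(cfg$segmenter, "external")) {
      m <- load_mask(cfg$mask_path, img$spacing)
    } else {
      init <- cfg$init
      if (is.character(init) && startsWith(init, "threshold:"))
        init <- as.numeric(sub("threshold:", "", init))
      m <- segment_active_contour(img, iterations = cfg$iterations,
                                  smoothing = cfg$smoothing, init = init)
    }
    keep_largest_component(m)
  })
  write_stack(mask, file.path(out_dir, "mask.tif"), bits = 8L)

  if (isTRUE(cfg$align))
    mask <- stage("alignment", align_vertical(mask))

  skel <- stage("skeletonization", skeletonize(mask))
  write_stack(skel, file.path(out_dir, "skeleton.tif"), bits = 8L)

  graph <- stage("branch_processing", {
    g <- build_graph(skel)
    if (cfg$min_branch_length > 0)
      g <- prune_short_branches(g, cfg$min_branch_length)
    extend_tips(g, mask)
  })

  tab <- stage("morphometry",
               morphometry(graph, mask, n_r = cfg$n_r,
                           smoothing = cfg$spline_smoothing,
                           eccentricity = cfg$eccentricity))
  utils::write.csv(as.data.frame(tab), file.path(out_dir, "branches.csv"),
                   row.names = FALSE)
  jsonlite::write_json(attr(tab, "summary"),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  mgraph <- attr(tab, "graph")
  export_graph(mgraph, file.path(out_dir, "graph.json"), "json")
  export_graph(mgraph, file.path(out_dir, "edges.csv"), "csv")

  sol <- NULL
  if (isTRUE(cfg$flow)) {
    sol <- stage("flow", {
      prob <- flow_problem(mgraph, p_in = cfg$pressure_in,
                           p_out = cfg$pressure_out,
                           mu = cfg$viscosity * 1e-3,
                           axis = cfg$flow_axis)
      solve_flow(prob)
    })
    utils::write.csv(sol$branches, file.path(out_dir, "flow_branches.csv"),
                     row.names = FALSE)
    utils::write.csv(sol$nodes, file.path(out_dir, "flow_nodes.csv"),
                     row.names = FALSE)
    export_3d1d_inputs(mgraph, file.path(out_dir, "network"), sol)
  }
  write_provenance(cfg, timings, out_dir, t_start)
  invisible(list(mask = mask, skeleton = skel, graph = mgraph,
                 table = tab, flow = sol))
}

write_provenance <- function(cfg, timings, out_dir, t_start) {
  prov <- list(
    package = "microvessel",
    version = as.character(utils::packageVersion("microvessel")),
    r_version = R.version.string,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    parameters = cfg[!vapply(cfg, is.null, logical(1))],
    timings_s = timings)
  prov$parameters$input_phantom <- NULL
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Compare 2D-projection and full 3D analyses of one volume
#'
#' Runs the complete 3D morphometry and the z-projection (2D) analysis
#' of the same input and reports the paired radius/length summaries with
#' their deltas. Projection flattens the vertical semi-axis, so flat
#' elliptical vessels read wider in 2D while the projected total length
#' can only shrink.
#'
#' @param mask a [binary_mask()] (segment first if starting from
#'   intensities).
#' @param n_r radius stations for the 3D analysis.
#' @param min_branch_length prune threshold, micrometres.
#' @return A list with `table_3d`, `table_2d` and `comparison`
#'   (data.frame of paired summaries).
#' @export
compare_2d_3d <- function(mask, n_r = 3L, min_branch_length = 0) {
  stopifnot(inherits(mask, "binary_mask"))
  skel <- skeletonize(mask)
  g <- build_graph(skel)
  if (min_branch_length > 0) g <- prune_short_branches(g, min_branch_length)
  g <- extend_tips(g, mask)
  t3 <- morphometry(g, mask, n_r = n_r)
  t2 <- analyze_projection(mask, min_branch_length = min_branch_length)
  s3 <- attr(t3, "summary"); s2 <- attr(t2, "summary")
  comparison <- data.frame(
    metric = c("mean_radius_um", "total_length_mm"),
    analysis_2d = c(s2$radius_mean, s2$total_length_mm),
    analysis_3d = c(s3$radius_mean, s3$total_length_mm))
  comparison$delta <- comparison$analysis_2d - comparison$analysis_3d
  list(table_3d = t3, table_2d = t2, comparison = comparison)
}

#' Plot a vessel graph
#'
#' Draws the x-y projection of the centerlines, line width scaled by
#' branch diameter when metrics are available.
#'
#' @param x a `vessel_graph`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vessel_graph <- function(x, ...) {
  allpts <- do.call(rbind, lapply(x$branches, `[[`, "points"))
  graphics::plot(allpts[, 1], allpts[, 2], type = "n", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  dmax <- max(vapply(x$branches, function(b)
    b$metrics$diameter %||% 1, numeric(1)), na.rm = TRUE)
  for (b in x$branches) {
    lw <- 0.5 + 2.5 * (b$metrics$diameter %||% dmax) / dmax
    graphics::lines(b$points[, 1], b$points[, 2], lwd = lw,
                    col = "firebrick")
  }
  jn <- x$nodes[x$nodes$kind == "junction", ]
  if (nrow(jn)) graphics::points(jn$x, jn$y, pch = 16, cex = 0.6)
  invisible(x)
}
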