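#' Reduce a lumen mask to a one-voxel-wide centerline
#'
#' Topology-preserving parallel directional thinning: each pass visits
#' the six face directions in turn and deletes border voxels that are
#' *simple* — whose removal provably changes neither connectivity nor
#' tunnels/cavities in the (26, 6) digital topology — with a sequential
#' re-check so topology is preserved exactly. Line ends (voxels with a
#' single foreground neighbor) are never deleted. Symmetric erosion from
#' opposite faces keeps the surviving curve centered in the vessel and
#' collapses the medial sheets of flattened lumina to curves.
#'
#' @param mask a nonempty [binary_mask()]; a single connected component
#'   is recommended (see [keep_largest_component()]).
#' @return A [binary_mask()] containing the skeleton (subset of input).
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("empty mask")
  sk <- .thin_parallel(as.vector(mask$data), dim(mask$data))
  binary_mask(array(sk, dim(mask$data)), mask$spacing, mask$origin)
}

# 26-neighbor count of each foreground voxel (array of counts, 0 outside)
neighbor_count26 <- function(a) {
  acc <- array(0L, dim(a))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    acc <- acc + shift3(a * 1L, dx, dy, dz, fill = 0L)
  }
  acc * (a * 1L)
}

new_vessel_graph <- function(nodes, branches, spacing = NULL) {
  structure(list(nodes = nodes, branches = branches, spacing = spacing),
            class = "vessel_graph")
}

#' Construct a vessel graph directly from tables
#'
#' Builds a [vessel_graph] without imaging input — useful for flow
#' studies on idealized networks. Branch centerlines default to straight
#' segments between their node positions.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (micrometres)
#'   and optionally `kind` (`"junction"`/`"endpoint"`).
#' @param branches data.frame with columns `node_a`, `node_b` and
#'   optionally `length` (micrometres) and `diameter` (micrometres).
#' @export
vessel_graph <- function(nodes, branches) {
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)),
            all(c("node_a", "node_b") %in% names(branches)))
  if (is.null(nodes$kind)) {
    deg <- tabulate(match(c(branches$node_a, branches$node_b), nodes$id),
                    nrow(nodes))
    nodes$kind <- ifelse(deg >= 3, "junction",
                         ifelse(deg == 1, "endpoint", "junction"))
  }
  brl <- lapply(seq_len(nrow(branches)), function(i) {
    a <- nodes[match(branches$node_a[i], nodes$id), ]
    b <- nodes[match(branches$node_b[i], nodes$id), ]
    pts <- rbind(c(a$x, a$y, a$z), c(b$x, b$y, b$z))
    len <- if (!is.null(branches$length)) branches$length[i] else
      sqrt(sum((pts[2, ] - pts[1, ])^2))
    metrics <- list(length = len)
    if (!is.null(branches$diameter)) {
      metrics$diameter <- branches$diameter[i]
      metrics$radius_mean <- branches$diameter[i] / 2
    }
    list(node_a = branches$node_a[i], node_b = branches$node_b[i],
         points = pts, metrics = metrics)
  })
  new_vessel_graph(nodes, brl)
}

#' @exportS3Method base::print
print.vessel_graph <- function(x, ...) {
  nk <- table(factor(x$nodes$kind, levels = c("junction", "endpoint")))
  cat(sprintf("<vessel_graph> %d branches, %d junctions, %d endpoints\n",
              length(x$branches), nk[["junction"]], nk[["endpoint"]]))
  lens <- vapply(x$branches, function(b) b$metrics$length %||% NA_real_,
                 numeric(1))
  if (all(is.finite(lens)))
    cat(sprintf("  total length %.1f um\n", sum(lens)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the branch/junction graph from a skeleton
#'
#' Skeleton voxels with three or more 26-neighbors are junction voxels;
#' 26-adjacent junction voxels are clustered into a single node placed at
#' their centroid (raw thinning output yields junction clumps, not single
#' voxels). Voxels with exactly one neighbor are endpoints. The remaining
#' voxels form maximal paths, each becoming a branch with its ordered
#' centerline coordinates in micrometres. Self-loops and multi-edges are
#' retained (anastomoses occur in real networks).
#'
#' @param skel skeleton [binary_mask()] from [skeletonize()].
#' @param spacing optional spacing override (micrometres).
#' @return A `vessel_graph`: `nodes` (data.frame id/x/y/z/kind) and
#'   `branches` (list of node_a/node_b/points/metrics).
#' @export
build_graph <- function(skel, spacing = NULL) {
  stopifnot(inherits(skel, "binary_mask"))
  if (!any(skel$data)) stop("empty skeleton")
  sp <- spacing %||% skel$spacing
  d <- dim(skel$data)
  cnt <- neighbor_count26(skel$data)
  junc <- skel$data & cnt >= 3L
  path <- skel$data & !junc

  # cluster junction voxels into nodes
  nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), kind = character(0))
  jlab <- array(0L, d)
  n_jc <- 0L
  if (any(junc)) {
    jl <- .cc_label(as.vector(junc), d, 26L)
    n_jc <- attr(jl, "n_components")
    jlab <- array(jl, d)
    jidx <- which(junc, arr.ind = TRUE)
    jpos <- voxel_coords(jidx, sp)
    lab_of <- jlab[jidx]
    cx <- rowsum(jpos[, 1], lab_of) / tabulate(lab_of, n_jc)
    cy <- rowsum(jpos[, 2], lab_of) / tabulate(lab_of, n_jc)
    cz <- rowsum(jpos[, 3], lab_of) / tabulate(lab_of, n_jc)
    nodes <- data.frame(id = seq_len(n_jc), x = cx[, 1], y = cy[, 1],
                        z = cz[, 1], kind = "junction")
  }

  lin <- function(i) i[, 1] + d[1] * (i[, 2] - 1) + d[1] * d[2] * (i[, 3] - 1)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  off_lin <- offs[, 1] + d[1] * offs[, 2] + d[1] * d[2] * offs[, 3]

  branches <- list()
  next_node <- n_jc

  add_node <- function(pos, kind) {
    next_node <<- next_node + 1L
    nodes <<- rbind(nodes, data.frame(id = next_node, x = pos[1],
                                      y = pos[2], z = pos[3], kind = kind))
    next_node
  }

  if (any(path)) {
    pl <- .cc_label(as.vector(path), d, 26L)
    n_pc <- attr(pl, "n_components")
    plab <- array(pl, d)
    pidx <- which(path, arr.ind = TRUE)
    plin <- lin(pidx)
    comp <- plab[pidx]
    # adjacency within the path set, via linear-index lookup
    vox_id <- array(0L, d)          # path voxel -> row in pidx
    vox_id[pidx] <- seq_len(nrow(pidx))
    for (cpt in seq_len(n_pc)) {
      rows <- which(comp == cpt)
      sub <- pidx[rows, , drop = FALSE]
      sublin <- plin[rows]
      m <- length(rows)
      # neighbors of each voxel restricted to this component
      nb_list <- vector("list", m)
      deg <- integer(m)
      local_id <- integer(nrow(pidx))
      local_id[rows] <- seq_len(m)
      for (t in seq_len(m)) {
        cand <- sublin[t] + off_lin
        ci <- sub[t, 1] + offs[, 1]; cj <- sub[t, 2] + offs[, 2]
        ck <- sub[t, 3] + offs[, 3]
        ok <- ci >= 1 & ci <= d[1] & cj >= 1 & cj <= d[2] &
              ck >= 1 & ck <= d[3]
        cand <- cand[ok]
        hits <- vox_id[cand]
        hits <- hits[hits > 0]
        hits <- hits[comp[hits] == cpt]
        nb_list[[t]] <- local_id[hits]
        deg[t] <- length(hits)
      }
      ends <- which(deg <= 1)
      # order the path by walking from one end (or anywhere on a cycle)
      start <- if (length(ends) > 0) ends[1] else 1L
      order_ids <- integer(m)
      used <- logical(m)
      cur <- start; used[cur] <- TRUE; order_ids[1] <- cur
      for (t in seq_len(m - 1)) {
        nxt <- nb_list[[cur]][!used[nb_list[[cur]]]]
        if (length(nxt) == 0) break
        # prefer face neighbors for a tight walk when several are free
        cur <- nxt[1]
        used[cur] <- TRUE
        order_ids[t + 1] <- cur
      }
      order_ids <- order_ids[order_ids > 0]
      ordered <- sub[order_ids, , drop = FALSE]
      pts <- voxel_coords(ordered, sp)

      # junction clusters adjacent to each end of the ordered path
      adj_junction <- function(vrow) {
        ci <- vrow[1] + offs[, 1]; cj <- vrow[2] + offs[, 2]
        ck <- vrow[3] + offs[, 3]
        ok <- ci >= 1 & ci <= d[1] & cj >= 1 & cj <= d[2] &
              ck >= 1 & ck <= d[3]
        labs <- jlab[cbind(ci[ok], cj[ok], ck[ok])]
        unique(labs[labs > 0])
      }
      first <- ordered[1, ]; last <- ordered[nrow(ordered), ]
      ja <- adj_junction(first); jb <- adj_junction(last)

      if (length(ends) == 0) {
        # pure cycle: close it; attach to adjacent junction if any
        pts <- rbind(pts, pts[1, ])
        nid <- if (length(ja) > 0) ja[1] else add_node(pts[1, ], "junction")
        branches[[length(branches) + 1L]] <-
          list(node_a = nid, node_b = nid, points = pts, metrics = list())
        next
      }
      node_a <- if (length(ja) > 0) ja[1] else add_node(pts[1, ], "endpoint")
      # a one-voxel path bridging two junction clusters sees both at the
      # same end: connect to two distinct clusters when available
      if (nrow(ordered) == 1 && length(ja) >= 2) jb <- ja[-1]
      node_b <- if (length(jb) > 0) jb[1]
        else add_node(pts[nrow(pts), ], "endpoint")
      # prepend/append the node centroids so points start/end at nodes
      if (length(ja) > 0)
        pts <- rbind(unlist(nodes[match(node_a, nodes$id), c("x", "y", "z")]),
                     pts)
      if (length(jb) > 0)
        pts <- rbind(pts,
                     unlist(nodes[match(node_b, nodes$id), c("x", "y", "z")]))
      branches[[length(branches) + 1L]] <-
        list(node_a = node_a, node_b = node_b, points = pts, metrics = list())
    }
  }

  # junction clusters directly adjacent to each other merged already by
  # 26-labelling; a junction node with no incident path (blob) is kept as
  # an isolated node.
  rownames(nodes) <- NULL
  new_vessel_graph(nodes, branches, sp)
}

#' Smooth a branch centerline with a spline
#'
#' The voxel-grid centerline is a staircase whose raw polyline length
#' overestimates the true arc length. Interior points are pre-smoothed
#' with a centered moving average of half-window `smoothing` (endpoints
#' pinned), then each coordinate is interpolated with a natural cubic
#' spline against the cumulative chord-length parameter and resampled
#' densely. With `smoothing = 0` the spline interpolates every input
#' point. The default half-window is calibrated so a straight staircase
#' digitized at 45 degrees recovers its length to within 1%.
#'
#' @param branch a branch (list with `points` matrix) from [build_graph()].
#' @param smoothing non-negative integer half-window (default 2).
#' @param step resampling step along the curve (micrometres); defaults to
#'   half the typical input point spacing.
#' @return The branch with `points` replaced by the resampled smooth
#'   curve (original points kept as `raw_points`).
#' @export
smooth_branch <- function(branch, smoothing = 2L, step = NULL) {
  pts <- branch$points
  if (nrow(pts) < 2) return(branch)
  if (nrow(pts) == 2) {
    branch$raw_points <- pts
    return(branch)
  }
  sm <- pts
  if (smoothing > 0 && nrow(pts) > 3) {
    w <- as.integer(smoothing)
    n <- nrow(pts)
    for (col in 1:3) {
      v <- pts[, col]
      out <- v
      for (i in 2:(n - 1)) {
        lo <- max(1, i - w); hi <- min(n, i + w)
        out[i] <- mean(v[lo:hi])
      }
      sm[, col] <- out
    }
    sm[1, ] <- pts[1, ]; sm[nrow(sm), ] <- pts[nrow(pts), ]
  }
  seg <- sqrt(rowSums(diff(sm)^2))
  keep <- c(TRUE, seg > 1e-9)
  sm <- sm[keep, , drop = FALSE]
  if (nrow(sm) < 2) {
    branch$raw_points <- pts
    return(branch)
  }
  t0 <- c(0, cumsum(sqrt(rowSums(diff(sm)^2))))
  if (is.null(step)) step <- max(mean(diff(t0)) / 2, max(t0) / 2000)
  tt <- seq(0, max(t0), length.out = max(2, ceiling(max(t0) / step) + 1))
  fx <- stats::splinefun(t0, sm[, 1], method = "natural")
  fy <- stats::splinefun(t0, sm[, 2], method = "natural")
  fz <- stats::splinefun(t0, sm[, 3], method = "natural")
  res <- cbind(fx(tt), fy(tt), fz(tt))
  branch$raw_points <- pts
  branch$points <- res
  branch
}

branch_degree <- function(graph) {
  ids <- graph$nodes$id
  deg <- integer(length(ids))
  for (b in graph$branches) {
    deg[match(b$node_a, ids)] <- deg[match(b$node_a, ids)] + 1L
    deg[match(b$node_b, ids)] <- deg[match(b$node_b, ids)] + 1L
  }
  deg
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Prune short terminal branches
#'
#' Removes terminal (endpoint-attached) branches and short self-loops
#' (thinning artifacts) shorter than `min_length`; junctions left with
#' exactly two incident branches are then dissolved and their branches
#' concatenated. Interior (junction-to-junction) branches are never
#' removed.
#'
#' @param graph a `vessel_graph`.
#' @param min_length micrometres; 0 is the identity.
#' @export
prune_short_branches <- function(graph, min_length) {
  stopifnot(min_length >= 0)
  if (min_length == 0 || length(graph$branches) == 0) return(graph)
  deg <- branch_degree(graph)
  ids <- graph$nodes$id
  is_end <- graph$nodes$kind == "endpoint" | deg == 1
  keep <- vapply(graph$branches, function(b) {
    terminal <- is_end[match(b$node_a, ids)] || is_end[match(b$node_b, ids)]
    loop <- b$node_a == b$node_b
    L <- b$metrics$length %||% polyline_length(b$points)
    !((terminal || loop) && L < min_length)
  }, logical(1))
  graph$branches <- graph$branches[keep]
  # drop orphan nodes, then dissolve degree-2 junctions
  used <- unique(unlist(lapply(graph$branches, function(b)
    c(b$node_a, b$node_b))))
  graph$nodes <- graph$nodes[graph$nodes$id %in% used, , drop = FALSE]
  merge_degree2(graph)
}

merge_degree2 <- function(graph) {
  repeat {
    deg <- branch_degree(graph)
    cand <- which(deg == 2 & graph$nodes$kind == "junction")
    if (length(cand) == 0) break
    nid <- graph$nodes$id[cand[1]]
    inc <- which(vapply(graph$branches, function(b)
      b$node_a == nid || b$node_b == nid, logical(1)))
    if (length(inc) != 2) {           # self-loop at this node: leave it
      graph$nodes$kind[cand[1]] <- "endpoint"
      next
    }
    b1 <- graph$branches[[inc[1]]]; b2 <- graph$branches[[inc[2]]]
    p1 <- b1$points; if (b1$node_b != nid) { p1 <- p1[nrow(p1):1, ]; }
    a_end <- if (b1$node_b == nid) b1$node_a else b1$node_b
    p2 <- b2$points; if (b2$node_a != nid) { p2 <- p2[nrow(p2):1, ]; }
    b_end <- if (b2$node_a == nid) b2$node_b else b2$node_a
    merged <- list(node_a = a_end, node_b = b_end,
                   points = rbind(p1, p2[-1, , drop = FALSE]),
                   metrics = list())
    graph$branches[[inc[1]]] <- merged
    graph$branches <- graph$branches[-inc[2]]
    graph$nodes <- graph$nodes[graph$nodes$id != nid, , drop = FALSE]
  }
  graph
}

#' Rectify and extend terminal branch tips
#'
#' Thinning retracts free tube ends by roughly one vessel radius, and on
#' flattened lumina the last few skeleton voxels can bend sharply toward
#' a cap corner ("claw" artifact). For every terminal (degree-1) branch
#' end this correction (1) trims the tip back to where the local tangent
#' last agreed (within 40 degrees) with the pre-tip direction, and
#' (2) marches straight outward along that direction, in steps of half a
#' voxel, while still inside the lumen mask — restoring the retracted
#' tip length with a clean tip. Smoothly curved ends are not trimmed, so
#' arc length and tortuosity of curved branches are preserved.
#'
#' @param graph a `vessel_graph`.
#' @param mask the lumen [binary_mask()] the skeleton came from.
#' @param max_angle_deg tangent deviation that marks a claw (default 40).
#' @export
extend_tips <- function(graph, mask, max_angle_deg = 40) {
  sp <- min(mask$spacing)
  d <- dim(mask$data)
  ids <- graph$nodes$id
  deg <- branch_degree(graph)
  edt <- attr(mask, "edt")
  if (is.null(edt)) edt <- distance_transform(mask)
  inside <- function(p) {
    i <- round(p / mask$spacing) + 1
    all(i >= 1) && all(i <= d) && mask$data[i[1], i[2], i[3]]
  }
  edt_at <- function(p) {
    i <- pmin(pmax(round(p / mask$spacing) + 1, 1), d)
    edt[i[1], i[2], i[3]]
  }
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-9) NULL else v / n
  }
  step <- sp / 2
  cos_max <- cos(max_angle_deg * pi / 180)
  for (bi in seq_along(graph$branches)) {
    b <- graph$branches[[bi]]
    for (side in c("a", "b")) {
      nid <- if (side == "a") b$node_a else b$node_b
      krow <- match(nid, ids)
      if (is.na(krow) || graph$nodes$kind[krow] != "endpoint" ||
          deg[krow] != 1) next
      pts <- b$points
      if (side == "a") pts <- pts[nrow(pts):1, , drop = FALSE]
      if (nrow(pts) < 2) next
      L <- polyline_length(pts)
      r_loc <- max(edt_at(polyline_at(pts, L / 2)$p[1, ]), sp)
      w_ref <- min(L / 3, max(6 * sp, 2 * r_loc))
      dir_ref <- unit(polyline_at(pts, L - w_ref)$p[1, ] -
                        polyline_at(pts, max(0, L - 2 * w_ref))$p[1, ])
      if (is.null(dir_ref))
        dir_ref <- unit(pts[nrow(pts), ] - pts[1, ])
      if (is.null(dir_ref)) next
      # trim back to the last point whose local tangent agrees with the
      # pre-tip direction
      L_t <- L
      ss <- seq(max(0, L - w_ref), L, by = step)
      if (length(ss) >= 2) {
        loc_a <- polyline_at(pts, ss)$p
        loc_b <- polyline_at(pts, pmax(0, ss - 2 * sp))$p
        dirs <- loc_a - loc_b
        nn <- sqrt(rowSums(dirs^2))
        cosang <- (dirs %*% dir_ref) / pmax(nn, 1e-12)
        bad <- which(cosang < cos_max & nn > 1e-9)
        if (length(bad) > 0) L_t <- max(0, ss[bad[1]] - sp)
      }
      tip <- polyline_at(pts, L_t)$p[1, ]
      w <- min(max(L_t / 2, 1e-9), max(4 * sp, 10))
      dir <- unit(tip - polyline_at(pts, max(0, L_t - w))$p[1, ])
      if (is.null(dir)) dir <- dir_ref
      arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
      pts <- rbind(pts[arc < L_t - 1e-9, , drop = FALSE],
                   matrix(tip, 1, 3))
      max_len <- (L - L_t) + 2 * r_loc + 4 * sp
      p <- tip
      added <- NULL
      for (s in seq_len(ceiling(max_len / step))) {
        q <- p + dir * step
        if (!inside(q)) break
        added <- rbind(added, q)
        p <- q
      }
      if (!is.null(added)) pts <- rbind(pts, added)
      if (side == "a") pts <- pts[nrow(pts):1, , drop = FALSE]
      b$points <- pts
      graph$nodes[krow, c("x", "y", "z")] <- as.list(p)
    }
    graph$branches[[bi]] <- b
  }
  graph
}

#' Export a vessel graph to JSON or CSV
#'
#' `format = "json"` writes nodes and branches (with coordinates and any
#' computed metrics) as one JSON document; `format = "csv"` writes an
#' edge list (node_a, node_b, length, diameter).
#'
#' @param graph a `vessel_graph`.
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @export
export_graph <- function(graph, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      nodes = graph$nodes,
      branches = lapply(graph$branches, function(b) {
        list(node_a = b$node_a, node_b = b$node_b,
             points = unname(apply(b$points, 1, as.numeric, simplify = FALSE)),
             metrics = b$metrics)
      }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(
      node_a = vapply(graph$branches, `[[`, integer(1) * 1, "node_a"),
      node_b = vapply(graph$branches, `[[`, integer(1) * 1, "node_b"),
      length = vapply(graph$branches, function(b)
        b$metrics$length %||% polyline_length(b$points), numeric(1)),
      diameter = vapply(graph$branches, function(b)
        b$metrics$diameter %||% NA_real_, numeric(1)))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
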