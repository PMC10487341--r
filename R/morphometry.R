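#' Branch arc length
#'
#' Sum of Euclidean distances between consecutive centerline points
#' (apply [smooth_branch()] first to avoid voxel-staircase inflation).
#'
#' @param branch a branch with a `points` matrix (micrometres).
#' @return Length in micrometres.
#' @export
branch_length <- function(branch) {
  polyline_length(branch$points)
}

#' Branch tortuosity
#'
#' Arc length divided by the start-to-end chord; 1 for a perfectly
#' straight vessel, larger for winding ones. A closed loop (zero chord)
#' has no defined tortuosity and yields `NaN` with a warning.
#'
#' @inheritParams branch_length
#' @export
branch_tortuosity <- function(branch) {
  pts <- branch$points
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  if (chord < 1e-9) {
    warning("closed-loop branch: tortuosity undefined")
    return(NaN)
  }
  branch_length(branch) / chord
}

# Orthonormal frame (u, v) spanning the plane perpendicular to tangent t.
# u is chosen horizontal when possible (vessels lie mostly in-plane).
normal_frame <- function(t) {
  t <- t / sqrt(sum(t^2))
  h <- c(-t[2], t[1], 0)
  if (sqrt(sum(h^2)) < 1e-6) h <- c(1, 0, 0)
  u <- h - sum(h * t) * t
  u <- u / sqrt(sum(u^2))
  v <- c(t[2] * u[3] - t[3] * u[2],
         t[3] * u[1] - t[1] * u[3],
         t[1] * u[2] - t[2] * u[1])
  list(u = u, v = v)
}

# Sample the mask on a 2D grid in the plane through 'center' spanned by
# (u, v); returns the in-plane connected region containing the center.
cross_section <- function(mask, center, tangent, half_width, step) {
  sp <- mask$spacing
  d <- dim(mask$data)
  fr <- normal_frame(tangent)
  g <- seq(-half_width, half_width, by = step)
  n <- length(g)
  pu <- matrix(rep(g, n), n, n)
  pv <- matrix(rep(g, each = n), n, n)
  px <- center[1] + pu * fr$u[1] + pv * fr$v[1]
  py <- center[2] + pu * fr$u[2] + pv * fr$v[2]
  pz <- center[3] + pu * fr$u[3] + pv * fr$v[3]
  ix <- round(px / sp[1]) + 1
  iy <- round(py / sp[2]) + 1
  iz <- round(pz / sp[3]) + 1
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  val <- matrix(FALSE, n, n)
  val[ok] <- mask$data[cbind(ix[ok], iy[ok], iz[ok])]
  ctr <- (n + 1) %/% 2
  if (!val[ctr, ctr]) return(NULL)
  lab <- array(.cc_label(as.vector(array(val, c(n, n, 1))), c(n, n, 1L), 6L),
               c(n, n))
  comp <- lab == lab[ctr, ctr]
  # if the region touches the grid border the window was too small
  touches <- any(comp[1, ]) || any(comp[n, ]) || any(comp[, 1]) ||
    any(comp[, n])
  list(comp = comp, u = pu, v = pv, step = step, touches_border = touches)
}

section_boundary <- function(comp) {
  n <- nrow(comp)
  pad <- matrix(FALSE, n, n)
  inner <- comp &
    rbind(pad[1, ], comp[-n, ]) & rbind(comp[-1, ], pad[1, ]) &
    cbind(pad[, 1], comp[, -n]) & cbind(comp[, -1], pad[, 1])
  comp & !inner
}

# Direct least-squares ellipse fit (Halir & Flusser's numerically stable
# formulation); returns semi-axes a >= b or NULL on failure.
fit_ellipse <- function(x, y) {
  if (length(x) < 5) return(NULL)
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, rep(1, length(xs)))
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) return(NULL)
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  idx <- which(cond > 1e-12)
  if (length(idx) == 0) return(NULL)
  a1 <- V[, idx[1]]
  coefs <- c(a1, T1 %*% a1)   # A B C D E F for Ax2+Bxy+Cy2+Dx+Ey+F
  A <- coefs[1]; B <- coefs[2] / 2; C <- coefs[3]
  D <- coefs[4] / 2; E <- coefs[5] / 2; F <- coefs[6]
  den <- B^2 - A * C
  if (abs(den) < 1e-14) return(NULL)
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - 2 * B * D * E - A * C * F)
  s <- sqrt((A - C)^2 + 4 * B^2)
  a2 <- num / (den * (s - (A + C)))
  b2 <- num / (den * (-s - (A + C)))
  if (!is.finite(a2) || !is.finite(b2) || a2 <= 0 || b2 <= 0) return(NULL)
  ax <- sqrt(c(a2, b2))
  list(a = max(ax), b = min(ax))
}

# Fallback: semi-axes from second moments of the filled region
# (a filled ellipse has variance a^2/4 along its major axis).
moment_axes <- function(pu, pv) {
  cm <- stats::cov(cbind(pu, pv))
  ev <- eigen(cm, symmetric = TRUE)$values
  ev[ev < 0] <- 0
  list(a = 2 * sqrt(ev[1]), b = 2 * sqrt(ev[2]))
}

# Equidistant arc-length sample positions; 'delta' pulls the end
# samples inward (callers pass ~1.5 local radii so junction blobs and
# oblique cap cuts do not corrupt end stations).
sample_positions <- function(L, n_r, delta) {
  delta <- min(delta, L / 4)
  if (n_r == 1) return(L / 2)
  seq(delta, L - delta, length.out = n_r)
}

# linear interpolation of a polyline at arc-length positions; returns
# positions and unit tangents
polyline_at <- function(pts, s) {
  seg <- sqrt(rowSums(diff(pts)^2))
  t0 <- c(0, cumsum(seg))
  L <- t0[length(t0)]
  s <- pmin(pmax(s, 0), L)
  idx <- findInterval(s, t0, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1), nrow(pts) - 1)
  w <- (s - t0[idx]) / pmax(seg[idx], 1e-12)
  p <- pts[idx, , drop = FALSE] * (1 - w) +
    pts[idx + 1, , drop = FALSE] * w
  tangent <- pts[idx + 1, , drop = FALSE] - pts[idx, , drop = FALSE]
  # smooth tangent over a wider window for robustness
  for (r in seq_along(s)) {
    lo <- max(1, idx[r] - 3); hi <- min(nrow(pts), idx[r] + 4)
    tv <- pts[hi, ] - pts[lo, ]
    if (sqrt(sum(tv^2)) > 1e-9) tangent[r, ] <- tv
  }
  list(p = p, tangent = tangent)
}

#' Branch radius from perpendicular cross-sections
#'
#' At `n_r` equidistant arc-length stations the lumen mask is sliced by
#' the plane perpendicular to the local centerline tangent; the in-plane
#' connected region containing the centerline point is kept (so
#' neighboring vessels crossing the plane are not counted) and the
#' radius is half the equivalent diameter `2*sqrt(Area/pi)` of that
#' cross-section.
#'
#' @param branch branch with centerline `points` inside `mask`.
#' @param mask the lumen [binary_mask()].
#' @param n_r number of radius stations per branch (>= 1).
#' @return List with `radii` (micrometres, one per non-empty station,
#'   skipped stations are dropped with a warning), `mean`, and the
#'   stations' arc-length positions.
#' @export
branch_radius <- function(branch, mask, n_r = 3L) {
  stopifnot(n_r >= 1)
  sections <- branch_sections(branch, mask, n_r)
  radii <- vapply(sections, function(s)
    if (is.null(s)) NA_real_ else sqrt(sum(s$comp) * s$step^2 / pi),
    numeric(1))
  if (all(is.na(radii)))
    stop("all cross-sections empty: mask and centerline disagree")
  if (anyNA(radii))
    warning(sum(is.na(radii)), " empty cross-section sample(s) skipped")
  ok <- !is.na(radii)
  list(radii = radii[ok], mean = mean(radii[ok]),
       positions = attr(sections, "positions")[ok])
}

branch_sections <- function(branch, mask, n_r) {
  pts <- branch$points
  L <- polyline_length(pts)
  sp <- min(mask$spacing)
  edt <- attr(mask, "edt")
  if (is.null(edt)) edt <- distance_transform(mask)
  mid <- pmin(pmax(round(polyline_at(pts, L / 2)$p[1, ] / mask$spacing) + 1,
                   1), dim(mask$data))
  r_mid <- max(edt[mid[1], mid[2], mid[3]], sp)
  # end stations sit clear of junction blobs and oblique cap cuts: inset
  # by 1.5 local radii (capped at a quarter of the branch length)
  s <- sample_positions(L, n_r, max(sp / 2, 1.5 * r_mid))
  at <- polyline_at(pts, s)
  # station tangents from a wide arc-length chord: the voxel centerline
  # can wander inside the medial sheet of flattened lumina, and an
  # oblique section plane inflates the measured area
  w <- min(L / 3, max(5 * sp, 0.1 * L))
  ahead <- polyline_at(pts, pmin(s + w, L))
  behind <- polyline_at(pts, pmax(s - w, 0))
  chord <- ahead$p - behind$p
  ok <- sqrt(rowSums(chord^2)) > 1e-9
  at$tangent[ok, ] <- chord[ok, , drop = FALSE]
  out <- vector("list", length(s))
  for (k in seq_along(s)) {
    ctr <- at$p[k, ]
    # local radius guess from the distance transform
    i <- pmin(pmax(round(ctr / mask$spacing) + 1, 1), dim(mask$data))
    guess <- max(edt[i[1], i[2], i[3]], sp)
    hw <- max(4 * guess, 6 * sp)
    for (try in 1:3) {
      cs <- cross_section(mask, ctr, at$tangent[k, ], hw, sp / 2)
      if (is.null(cs) || !cs$touches_border) break
      hw <- hw * 2
    }
    out[[k]] <- cs
  }
  attr(out, "positions") <- s
  out
}

#' Branch cross-section eccentricity
#'
#' An ellipse is fitted (direct least squares) to the boundary pixels of
#' each of the `n_r` cross-sections used for the radius; per-section
#' shape values are averaged. Two conventions are available:
#' `"axis-ratio"` (default) reports the mean minor/major semi-axis ratio
#' b/a, so a circular vessel scores 1 and flattened ones score lower;
#' `"classical"` reports the standard ellipse eccentricity
#' `sqrt(1 - (b/a)^2)` (0 for a circle). Sections with fewer than 5
#' boundary pixels are skipped.
#'
#' @inheritParams branch_radius
#' @param convention `"axis-ratio"` or `"classical"`.
#' @export
branch_eccentricity <- function(branch, mask, n_r = 3L,
                                convention = c("axis-ratio", "classical")) {
  convention <- match.arg(convention)
  sections <- branch_sections(branch, mask, n_r)
  vals <- vapply(sections, function(s) {
    if (is.null(s)) return(NA_real_)
    bd <- section_boundary(s$comp)
    if (sum(bd) < 5) return(NA_real_)
    fit <- fit_ellipse(s$u[bd], s$v[bd])
    if (is.null(fit)) fit <- moment_axes(s$u[s$comp], s$v[s$comp])
    if (fit$a <= 0) return(NA_real_)
    ratio <- min(1, fit$b / fit$a)
    if (convention == "axis-ratio") ratio else sqrt(1 - ratio^2)
  }, numeric(1))
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Branch lateral (exchange) surface area
#'
#' Frustum-sum approximation from the `n_r` radius stations: each
#' inter-station segment contributes `pi * (r_k + r_{k+1}) * ds`, and the
#' stretches outside the first/last station contribute as cylinders of
#' the end radii, so a constant-radius branch gives exactly `2*pi*r*L`
#' (with `n_r = 1`, `2*pi*rbar*L`).
#'
#' @param branch branch with `points`.
#' @param radii radii at the stations (micrometres), e.g. from
#'   [branch_radius()].
#' @param positions arc-length positions of the stations.
#' @return Area in square micrometres.
#' @export
branch_lateral_area <- function(branch, radii, positions = NULL) {
  L <- polyline_length(branch$points)
  if (L <= 0 || length(radii) == 0) return(0)
  n <- length(radii)
  if (is.null(positions)) positions <- sample_positions(L, n, 0)
  if (n == 1) return(2 * pi * radii * L)
  core <- sum(pi * (radii[-n] + radii[-1]) * diff(positions))
  core + 2 * pi * radii[1] * positions[1] +
    2 * pi * radii[n] * (L - positions[n])
}

#' Surface-over-volume ratio of the network
#'
#' Ratio of the total vascular lateral surface (the area available for
#' exchange) to the extravascular volume of the analysis region:
#' `S/V = sum(A_i) / (V_box - V_lumen)`, reported in mm^2/mm^3.
#'
#' @param table a morphometry table (from [morphometry()]) or a numeric
#'   vector of branch lateral areas in square micrometres.
#' @param mask the lumen [binary_mask()] (for the lumen volume).
#' @param box analysis box dimensions (Lx, Ly, Lz) in micrometres;
#'   defaults to the full mask extent. Must enclose the mask.
#' @export
surface_over_volume <- function(table, mask, box = NULL) {
  areas <- if (is.data.frame(table)) table$lateral_area else table
  sp <- mask$spacing
  d <- dim(mask$data)
  extent <- d * sp
  if (is.null(box)) box <- extent
  if (any(box < extent - 1e-6))
    stop("analysis box smaller than the mask extent")
  lumen <- sum(mask$data) * prod(sp)
  sv_um <- sum(areas) / (prod(box) - lumen)   # 1/um
  sv_um * 1000                                # mm^2/mm^3
}

set_branch_metrics <- function(graph, mask, n_r = 3L, smoothing = 2L,
                               eccentricity = "axis-ratio") {
  attr(mask, "edt") <- distance_transform(mask)
  for (i in seq_along(graph$branches)) {
    b <- smooth_branch(graph$branches[[i]], smoothing = smoothing)
    L <- branch_length(b)
    tort <- suppressWarnings(branch_tortuosity(b))
    rr <- tryCatch(branch_radius(b, mask, n_r), error = function(e) NULL)
    ecc <- tryCatch(
      suppressWarnings(branch_eccentricity(b, mask, n_r,
                                           convention = eccentricity)),
      error = function(e) NA_real_)
    if (is.null(rr)) {
      metrics <- list(length = L, tortuosity = tort, radius_mean = NA_real_,
                      radii = numeric(0), eccentricity = NA_real_,
                      lateral_area = NA_real_, diameter = NA_real_)
    } else {
      metrics <- list(
        length = L, tortuosity = tort, radius_mean = rr$mean,
        radii = rr$radii, eccentricity = ecc,
        lateral_area = branch_lateral_area(b, rr$radii, rr$positions),
        diameter = 2 * rr$mean)
    }
    b$metrics <- metrics
    graph$branches[[i]] <- b
  }
  graph
}

#' Per-branch morphometry table and network summary
#'
#' Smooths every branch, then computes length, tortuosity, the `n_r`
#' cross-section radii, eccentricity, lateral area and diameter per
#' branch, plus network totals (total length in mm, radius distribution
#' summaries with plain and length-weighted means, vessel count, and
#' S/V in mm^2/mm^3).
#'
#' @param graph a `vessel_graph` (typically from [build_graph()]).
#' @param mask the lumen [binary_mask()].
#' @param n_r radius stations per branch (default 3).
#' @param smoothing centerline smoothing half-window (see
#'   [smooth_branch()]).
#' @param eccentricity eccentricity convention, see
#'   [branch_eccentricity()].
#' @param box analysis box (micrometres) for S/V; default full volume.
#' @return A data.frame of class `morphometry_table` with one row per
#'   branch and a `summary` attribute (list). The metric-annotated graph
#'   is attached as attribute `graph` for downstream flow analysis.
#' @export
morphometry <- function(graph, mask, n_r = 3L, smoothing = 2L,
                        eccentricity = c("axis-ratio", "classical"),
                        box = NULL) {
  eccentricity <- match.arg(eccentricity)
  graph <- set_branch_metrics(graph, mask, n_r = n_r, smoothing = smoothing,
                              eccentricity = eccentricity)
  rows <- lapply(seq_along(graph$branches), function(i) {
    m <- graph$branches[[i]]$metrics
    data.frame(branch = i, node_a = graph$branches[[i]]$node_a,
               node_b = graph$branches[[i]]$node_b,
               length = m$length, tortuosity = m$tortuosity,
               radius_mean = m$radius_mean, eccentricity = m$eccentricity,
               lateral_area = m$lateral_area, diameter = m$diameter)
  })
  tab <- do.call(rbind, rows)
  w <- tab$length
  summary <- list(
    n_vessels = nrow(tab),
    total_length_mm = sum(tab$length) / 1000,
    radius_mean = mean(tab$radius_mean, na.rm = TRUE),
    radius_sd = stats::sd(tab$radius_mean, na.rm = TRUE),
    radius_mean_length_weighted =
      sum(w * tab$radius_mean, na.rm = TRUE) /
        sum(w[!is.na(tab$radius_mean)]),
    tortuosity_mean = mean(tab$tortuosity, na.rm = TRUE),
    eccentricity_mean = mean(tab$eccentricity, na.rm = TRUE),
    sv_mm2_mm3 = surface_over_volume(tab$lateral_area[!is.na(tab$lateral_area)],
                                     mask, box))
  structure(tab, summary = summary, graph = graph,
            class = c("morphometry_table", "data.frame"))
}

#' @exportS3Method base::summary
summary.morphometry_table <- function(object, ...) {
  s <- attr(object, "summary")
  cat(sprintf("Network morphometry: %d vessels\n", s$n_vessels))
  cat(sprintf("  total length     %.2f mm\n", s$total_length_mm))
  cat(sprintf("  mean radius      %.1f um (length-weighted %.1f um)\n",
              s$radius_mean, s$radius_mean_length_weighted))
  cat(sprintf("  mean tortuosity  %.3f\n", s$tortuosity_mean))
  cat(sprintf("  mean eccentricity %.3f\n", s$eccentricity_mean))
  cat(sprintf("  S/V              %.2f mm2/mm3\n", s$sv_mm2_mm3))
  invisible(s)
}

#' 2D morphometry of the z-projection
#'
#' Projects the volume along z (any-voxel projection for masks,
#' maximum-intensity + segmentation for grayscale volumes), skeletonizes
#' the 2D shape, and measures lengths and tortuosity as in 3D with the z
#' coordinate dropped. Radii come from the 2D Euclidean distance
#' transform at the centerline (half the local vessel width), the
#' estimate available to planar analyses.
#'
#' @param x a [binary_mask()] or [volume_image()].
#' @param min_branch_length prune threshold (micrometres).
#' @param smoothing centerline smoothing half-window.
#' @return A `morphometry_table` (no eccentricity or S/V: both need 3D).
#' @export
analyze_projection <- function(x, min_branch_length = 0, smoothing = 2L) {
  stopifnot(inherits(x, "volume_image"))
  if (inherits(x, "binary_mask")) {
    proj <- apply(x$data, c(1, 2), any)
  } else {
    mip <- apply(x$data, c(1, 2), max)
    v2 <- volume_image(array(mip, c(dim(mip), 1)), c(x$spacing[1:2], x$spacing[1]))
    proj <- segment_active_contour(v2)$data[, , 1]
  }
  m2 <- binary_mask(array(proj, c(dim(proj), 1)),
                    c(x$spacing[1], x$spacing[2], x$spacing[1]))
  sk <- skeletonize(m2)
  g <- build_graph(sk)
  if (min_branch_length > 0) g <- prune_short_branches(g, min_branch_length)
  edt2 <- distance_transform(m2)
  rows <- lapply(seq_along(g$branches), function(i) {
    b <- smooth_branch(g$branches[[i]], smoothing = smoothing)
    L <- branch_length(b)
    tort <- suppressWarnings(branch_tortuosity(b))
    midp <- polyline_at(b$points, L / 2)$p[1, ]
    mi <- pmin(pmax(round(midp / m2$spacing) + 1, 1), dim(m2$data))
    r_mid <- max(edt2[mi[1], mi[2], mi[3]], m2$spacing[1])
    s <- sample_positions(L, 3L, max(m2$spacing[1] / 2, 1.5 * r_mid))
    at <- polyline_at(b$points, s)
    idx <- pmin(pmax(round(sweep(at$p, 2, m2$spacing, "/")) + 1, 1),
                matrix(dim(m2$data), length(s), 3, byrow = TRUE))
    radii <- edt2[idx]
    data.frame(branch = i, node_a = b$node_a, node_b = b$node_b,
               length = L, tortuosity = tort,
               radius_mean = mean(radii), eccentricity = NA_real_,
               lateral_area = NA_real_, diameter = 2 * mean(radii))
  })
  tab <- do.call(rbind, rows)
  summary <- list(n_vessels = nrow(tab),
                  total_length_mm = sum(tab$length) / 1000,
                  radius_mean = mean(tab$radius_mean, na.rm = TRUE),
                  radius_sd = stats::sd(tab$radius_mean, na.rm = TRUE),
                  tortuosity_mean = mean(tab$tortuosity, na.rm = TRUE))
  structure(tab, summary = summary, graph = g,
            class = c("morphometry_table", "data.frame"))
}
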