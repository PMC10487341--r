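#' Declare a synthetic tube-network phantom
#'
#' A phantom is a declarative ground-truth description of a tube network:
#' each branch has a centerline polyline (micrometres), elliptical
#' cross-section semi-axes `a >= b` (major axis horizontal by default,
#' as in vasculogenic chips), a foreground/background intensity pair,
#' an optional tilt, and an optional noise model. Rendering keeps the
#' lumen in/out test exact, so analytic truth values (length,
#' tortuosity, lateral area) are exact by construction.
#'
#' @param box volume extent (Lx, Ly, Lz) in micrometres.
#' @param spacing cubic voxel size, micrometres.
#' @param branches list of branch specs: each a list with `points`
#'   (n x 3 matrix of centerline points, micrometres), `a`, `b`
#'   (semi-axes, micrometres; `b` defaults to `a` = circular).
#' @param fg,bg foreground/background intensities.
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param tilt_deg rigid tilt about the y axis applied to all
#'   centerlines (degrees).
#' @param seed RNG seed used by the renderer's noise stage.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(box, spacing = 1, branches, fg = 200, bg = 10,
                         noise = c("none", "gaussian", "poisson"),
                         noise_sd = 0, tilt_deg = 0, seed = 1L) {
  noise <- match.arg(noise)
  branches <- lapply(branches, function(br) {
    if (is.null(br$b)) br$b <- br$a
    stopifnot(br$a >= br$b, br$b > 0)
    br$points <- as.matrix(br$points)
    br
  })
  structure(list(box = box, spacing = spacing, branches = branches,
                 fg = fg, bg = bg, noise = noise, noise_sd = noise_sd,
                 tilt_deg = tilt_deg, seed = as.integer(seed)),
            class = "phantom_spec")
}

# dense resampling of a polyline at step ds
densify <- function(pts, ds) {
  seg <- sqrt(rowSums(diff(pts)^2))
  t0 <- c(0, cumsum(seg))
  L <- t0[length(t0)]
  s <- seq(0, L, by = ds)
  if (s[length(s)] < L) s <- c(s, L)
  polyline_at(pts, s)
}

# Ramanujan's ellipse perimeter approximation (relative error < 1e-4 for
# the axis ratios used here)
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Render a phantom volume with its ground truth
#'
#' A voxel belongs to the lumen iff it lies inside the elliptical tube
#' of some branch (distance test in the local plane normal to the
#' centerline). Intensities are foreground inside and background
#' outside, with optional seeded noise added afterwards; the binary
#' truth mask itself is never noisy, keeping the analytic truth exact.
#' Overlapping branches are allowed (junctions are intentional
#' overlaps).
#'
#' @param spec a [phantom_spec()].
#' @return List with `image` ([volume_image()]), `mask` (truth
#'   [binary_mask()]), `graph` (truth `vessel_graph`) and `truth`
#'   (per-branch data.frame: length, tortuosity, a, b, equivalent
#'   radius `sqrt(ab)`, lateral area).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  d <- pmax(2L, as.integer(round(spec$box / sp)))
  vol <- array(FALSE, d)
  tilt <- spec$tilt_deg * pi / 180
  Rt <- matrix(c(cos(tilt), 0, sin(tilt), 0, 1, 0,
                 -sin(tilt), 0, cos(tilt)), 3, 3)
  ctr <- spec$box / 2
  truth_rows <- list()
  nodes <- NULL
  gbranches <- list()
  next_id <- 0L
  for (bi in seq_along(spec$branches)) {
    br <- spec$branches[[bi]]
    pts <- br$points
    if (spec$tilt_deg != 0)
      pts <- sweep(sweep(pts, 2, ctr, "-") %*% t(Rt), 2, ctr, "+")
    ds <- sp / 2
    den <- densify(pts, ds)
    P <- den$p
    Tg <- den$tangent / sqrt(rowSums(den$tangent^2))
    amax <- br$a + sp
    for (k in seq_len(nrow(P))) {
      c0 <- P[k, ]
      lo <- pmax(1L, as.integer(ceiling((c0 - amax) / sp + 1)))
      hi <- pmin(d, as.integer(floor((c0 + amax) / sp + 1)))
      if (any(lo > hi)) next
      xs <- (seq(lo[1], hi[1]) - 1) * sp - c0[1]
      ys <- (seq(lo[2], hi[2]) - 1) * sp - c0[2]
      zs <- (seq(lo[3], hi[3]) - 1) * sp - c0[3]
      nx <- length(xs); ny <- length(ys); nz <- length(zs)
      dx <- array(xs, c(nx, ny, nz))
      dy <- array(rep(ys, each = nx), c(nx, ny, nz))
      dz <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
      t_ <- Tg[k, ]
      fr <- normal_frame(t_)
      ax <- dx * t_[1] + dy * t_[2] + dz * t_[3]
      pu <- dx * fr$u[1] + dy * fr$u[2] + dz * fr$u[3]
      pv <- dx * fr$v[1] + dy * fr$v[2] + dz * fr$v[3]
      inside <- abs(ax) <= ds * 0.75 &
        (pu / br$a)^2 + (pv / br$b)^2 <= 1
      if (any(inside)) {
        sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
        vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub | inside
      }
    }
    # exact truth
    L <- polyline_length(P)
    chord <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
    truth_rows[[bi]] <- data.frame(
      branch = bi, length = L,
      tortuosity = if (chord > 1e-9) L / chord else NaN,
      a = br$a, b = br$b, r_eq = sqrt(br$a * br$b),
      lateral_area = ellipse_perimeter(br$a, br$b) * L)
    na <- next_id + 1L; nb <- next_id + 2L; next_id <- nb
    nodes <- rbind(nodes,
                   data.frame(id = c(na, nb),
                              x = c(P[1, 1], P[nrow(P), 1]),
                              y = c(P[1, 2], P[nrow(P), 2]),
                              z = c(P[1, 3], P[nrow(P), 3]),
                              kind = "endpoint"))
    gbranches[[bi]] <- list(node_a = na, node_b = nb, points = P,
                            metrics = list(length = L,
                                           diameter = 2 * sqrt(br$a * br$b)))
  }
  img <- array(spec$bg, d)
  img[vol] <- spec$fg
  if (spec$noise != "none") {
    set.seed(spec$seed)
    if (spec$noise == "gaussian") {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), d)
    } else {
      img <- array(stats::rpois(length(img), lambda = pmax(img, 0)), d)
    }
  }
  list(image = volume_image(img, rep(sp, 3)),
       mask = binary_mask(vol, rep(sp, 3)),
       graph = new_vessel_graph(nodes, gbranches, rep(sp, 3)),
       truth = do.call(rbind, truth_rows))
}

# straight tube helper
straight_branch <- function(p0, p1, a, b = a) {
  list(points = rbind(p0, p1), a = a, b = b)
}

# planar arc (in the xy plane at height z0) helper
arc_branch <- function(center, radius, theta0, theta1, z0, a, b = a,
                       n = 200) {
  th <- seq(theta0, theta1, length.out = n)
  list(points = cbind(center[1] + radius * cos(th),
                      center[2] + radius * sin(th),
                      z0), a = a, b = b)
}

#' Generate a ground-truthed reference network
#'
#' Builds a phantom whose analytic surface-over-volume ratio hits a
#' target density, emulating the scale of vasculogenic chips (branch
#' lengths of order 100 um, radii of order 10-20 um). Two styles:
#' `"grid"` lays an n x n lattice of horizontal tubes (an n x n grid has
#' 2n(n-1) branches and n^2 lattice points); `"random-vasculogenic"`
#' jitters the lattice points and drops a random subset of edges for an
#' irregular topology. The tube radius is solved (monotone closed form)
#' so the analytic S/V matches `target_sv`; an infeasible target fails
#' with the attainable range.
#'
#' @param style `"grid"` or `"random-vasculogenic"`.
#' @param target_sv target surface-over-volume, mm^2/mm^3.
#' @param seed RNG seed (placement jitter and noise).
#' @param n lattice points per side.
#' @param pitch lattice pitch, micrometres.
#' @param spacing voxel size, micrometres.
#' @param axis_ratio cross-section b/a (1 = circular).
#' @param slab_height box height, micrometres.
#' @return A [phantom_spec()] with attribute `analytic_sv` (the exact
#'   S/V implied by the spec, mm^2/mm^3).
#' @export
make_reference_network <- function(style = c("grid", "random-vasculogenic"),
                                   target_sv = 4.5, seed = 1L, n = 3L,
                                   pitch = 150, spacing = 2,
                                   axis_ratio = 1, slab_height = 100) {
  style <- match.arg(style)
  set.seed(seed)
  margin <- pitch / 2
  side <- pitch * (n - 1) + 2 * margin
  box <- c(side, side, slab_height)
  z0 <- slab_height / 2
  gx <- margin + (seq_len(n) - 1) * pitch
  pt <- as.matrix(expand.grid(x = gx, y = gx))
  if (style == "random-vasculogenic")
    pt <- pt + matrix(stats::runif(length(pt), -pitch / 5, pitch / 5),
                      ncol = 2)
  edges <- NULL
  id_at <- function(i, j) (j - 1) * n + i
  for (j in seq_len(n)) for (i in seq_len(n - 1))
    edges <- rbind(edges, c(id_at(i, j), id_at(i + 1, j)))
  for (j in seq_len(n - 1)) for (i in seq_len(n))
    edges <- rbind(edges, c(id_at(i, j), id_at(i, j + 1)))
  if (style == "random-vasculogenic") {
    keep <- stats::runif(nrow(edges)) < 0.85
    if (sum(keep) < nrow(edges) * 0.6) keep[] <- TRUE
    edges <- edges[keep, , drop = FALSE]
  }
  seg_len <- sqrt(rowSums((pt[edges[, 1], ] - pt[edges[, 2], ])^2))
  total_len <- sum(seg_len)
  vbox <- prod(box)
  # analytic S/V (in 1/um, converted to mm2/mm3 by *1000):
  #   sv(r) = P(r) * Ltot / (Vbox - A(r) * Ltot)
  # with elliptical section a = r/sqrt(q), b = r*sqrt(q), q = axis_ratio
  sv_of <- function(r) {
    a <- r / sqrt(axis_ratio); b <- r * sqrt(axis_ratio)
    1000 * ellipse_perimeter(a, b) * total_len /
      (vbox - pi * a * b * total_len)
  }
  r_lo <- 2 * spacing
  r_hi <- min(pitch / 3, slab_height / 2 - 2 * spacing)
  if (target_sv < sv_of(r_lo) || target_sv > sv_of(r_hi))
    stop(sprintf("target S/V %.2f outside attainable range [%.2f, %.2f]",
                 target_sv, sv_of(r_lo), sv_of(r_hi)))
  r <- stats::uniroot(function(r) sv_of(r) - target_sv,
                      c(r_lo, r_hi), tol = 1e-8)$root
  a <- r / sqrt(axis_ratio); b <- r * sqrt(axis_ratio)
  branches <- lapply(seq_len(nrow(edges)), function(e) {
    straight_branch(c(pt[edges[e, 1], ], z0), c(pt[edges[e, 2], ], z0),
                    a = a, b = b)
  })
  spec <- phantom_spec(box = box, spacing = spacing, branches = branches,
                       seed = seed)
  attr(spec, "analytic_sv") <- sv_of(r)
  attr(spec, "radius") <- r
  spec
}

#' Write a phantom spec as YAML
#' @param spec a [phantom_spec()].
#' @param path output path.
#' @export
write_phantom_spec <- function(spec, path) {
  obj <- unclass(spec)
  obj$branches <- lapply(obj$branches, function(b) {
    b$points <- apply(unname(b$points), 1, as.numeric, simplify = FALSE)
    b
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a phantom spec from YAML
#' @param path YAML file written by [write_phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$branches <- lapply(obj$branches, function(b) {
    b$points <- do.call(rbind, b$points)
    b
  })
  phantom_spec(box = unlist(obj$box), spacing = obj$spacing,
               branches = obj$branches, fg = obj$fg, bg = obj$bg,
               noise = obj$noise, noise_sd = obj$noise_sd,
               tilt_deg = obj$tilt_deg, seed = obj$seed)
}
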