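#' Hydraulic resistance of a cylindrical vessel
#'
#' Laminar (Poiseuille) resistance `R = 128 mu L / (pi D^4)` with inputs
#' in the units the imaging side produces (micrometres) and output in SI.
#'
#' @param L branch length, micrometres.
#' @param D branch diameter, micrometres.
#' @param mu dynamic viscosity, Pa.s.
#' @return Resistance in Pa.s/m^3.
#' @export
hydraulic_resistance <- function(L, D, mu) {
  if (any(L <= 0) || any(D <= 0) || any(mu <= 0))
    stop("L, D and mu must all be positive")
  128 * mu * (L * 1e-6) / (pi * (D * 1e-6)^4)
}

#' Define a network flow problem
#'
#' Boundary conditions impose constant pressure on the two sides of the
#' chip: nodes whose position lies within `margin` of the two opposite
#' faces of the analysis box along `axis` receive `p_in` (low face) and
#' `p_out` (high face). Alternatively pass an explicit `bc` data.frame
#' (`node`, `pressure`). Junctions exactly on the margin boundary are
#' included as boundary nodes.
#'
#' @param graph a `vessel_graph` whose branches carry `length` and
#'   `diameter` metrics (micrometres), e.g. from [morphometry()] or
#'   [vessel_graph()].
#' @param p_in,p_out boundary pressures (Pa) on the low/high face.
#' @param mu dynamic viscosity in Pa.s (default 1.0e-3, aqueous medium).
#' @param axis `"x"`, `"y"` or `"z"`: perfusion direction.
#' @param margin distance from the face within which a node is a
#'   boundary node (micrometres); default 5% of the network extent.
#' @param bc optional explicit data.frame(node, pressure) overriding the
#'   side rule.
#' @return An object of class `flow_problem`.
#' @export
flow_problem <- function(graph, p_in = 100, p_out = 0, mu = 1e-3,
                         axis = c("x", "y", "z"), margin = NULL, bc = NULL) {
  axis <- match.arg(axis)
  L <- vapply(graph$branches, function(b)
    b$metrics$length %||% polyline_length(b$points), numeric(1))
  D <- vapply(graph$branches, function(b)
    b$metrics$diameter %||% NA_real_, numeric(1))
  if (anyNA(D))
    stop("branches lack diameters: run morphometry() first or supply them")
  if (any(L <= 0) || any(D <= 0)) stop("all branch L and D must be positive")
  if (is.null(bc)) {
    pos <- graph$nodes[[axis]]
    rng <- range(pos)
    if (is.null(margin)) margin <- 0.05 * diff(rng)
    lo <- which(pos <= rng[1] + margin)
    hi <- which(pos >= rng[2] - margin)
    if (length(lo) == 0 || length(hi) == 0)
      stop("no boundary nodes found on the ", axis, " faces")
    bc <- data.frame(node = c(graph$nodes$id[lo], graph$nodes$id[hi]),
                     pressure = c(rep(p_in, length(lo)),
                                  rep(p_out, length(hi))))
    bc <- bc[!duplicated(bc$node), ]
  }
  if (length(unique(bc$pressure)) < 2)
    stop("need at least two distinct boundary pressures")
  structure(list(graph = graph, mu = mu, bc = bc,
                 L = L, D = D), class = "flow_problem")
}

#' Solve the Poiseuille / mass-conservation network system
#'
#' Every branch obeys `p_a - p_b = R_i Q_i` and every interior node
#' conserves mass. The implementation eliminates the branch equations
#' and solves the sparse nodal conductance system for the unknown
#' pressures; boundary pressures are honored exactly. Sub-networks with
#' no path to any boundary node carry zero flow (a warning is issued);
#' a network whose boundary nodes are not mutually connected fails.
#'
#' @param problem a [flow_problem()].
#' @return A `flow_solution`: `branches` data.frame (Q m^3/s signed from
#'   node_a to node_b, velocity um/s, wss Pa, resistance Pa.s/m^3) and
#'   `nodes` data.frame (pressure Pa).
#' @export
solve_flow <- function(problem) {
  stopifnot(inherits(problem, "flow_problem"))
  g <- problem$graph
  ids <- g$nodes$id
  n <- length(ids)
  m <- length(g$branches)
  a <- match(vapply(g$branches, `[[`, numeric(1), "node_a"), ids)
  b <- match(vapply(g$branches, `[[`, numeric(1), "node_b"), ids)
  R <- hydraulic_resistance(problem$L, problem$D, problem$mu)
  cond <- 1 / R
  bnd <- match(problem$bc$node, ids)
  if (anyNA(bnd)) stop("boundary condition references unknown node id")
  pfix <- rep(NA_real_, n)
  pfix[bnd] <- problem$bc$pressure

  # connected components of the graph (ignoring self-loops)
  comp <- rep(0L, n)
  cc <- 0L
  adj <- vector("list", n)
  for (i in seq_len(m)) {
    if (a[i] != b[i]) {
      adj[[a[i]]] <- c(adj[[a[i]]], b[i])
      adj[[b[i]]] <- c(adj[[b[i]]], a[i])
    }
  }
  for (s in seq_len(n)) {
    if (comp[s]) next
    cc <- cc + 1L
    stack <- s
    comp[s] <- cc
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in adj[[v]]) if (!comp[w]) { comp[w] <- cc; stack <- c(stack, w) }
    }
  }
  bcomp <- unique(comp[bnd])
  if (length(unique(comp[bnd[!duplicated(problem$bc$pressure)]])) >= 1 &&
      length(bcomp) > 1) {
    # boundary nodes in several components: each component must contain
    # at least two distinct pressures to carry flow
    for (ccid in bcomp) {
      pr <- unique(pfix[bnd][comp[bnd] == ccid])
      if (length(pr) < 2 && sum(comp == ccid) > 1)
        warning("component ", ccid,
                " touches a single boundary pressure; it carries no flow")
    }
  }
  if (!any(comp %in% bcomp))
    stop("no pressure path: boundary sets are disconnected from the network")
  orphan <- setdiff(unique(comp), bcomp)
  if (length(orphan) > 0)
    warning(length(orphan), " isolated subnetwork(s) get zero flow")

  p <- rep(NA_real_, n)
  p[bnd] <- problem$bc$pressure
  free <- which(is.na(pfix) & comp %in% bcomp)
  if (length(free) > 0) {
    idx_free <- match(seq_len(n), free)
    rhs <- numeric(length(free))
    diag_acc <- numeric(length(free))
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (e in seq_len(m)) {
      if (a[e] == b[e]) next
      for (side in 1:2) {
        u <- if (side == 1) a[e] else b[e]
        v <- if (side == 1) b[e] else a[e]
        fu <- idx_free[u]
        if (is.na(fu)) next
        diag_acc[fu] <- diag_acc[fu] + cond[e]
        fv <- idx_free[v]
        if (is.na(fv)) rhs[fu] <- rhs[fu] + cond[e] * pfix[v]
        else { ii <- c(ii, fu); jj <- c(jj, fv); xx <- c(xx, -cond[e]) }
      }
    }
    A <- Matrix::sparseMatrix(i = c(ii, seq_along(free)),
                              j = c(jj, seq_along(free)),
                              x = c(xx, diag_acc),
                              dims = c(length(free), length(free)))
    sol <- Matrix::solve(A, rhs)
    p[free] <- as.numeric(sol)
  }
  # nodes in orphan components: pressure undefined -> set to NA, flow 0
  Q <- ifelse(a == b | is.na(p[a]) | is.na(p[b]), 0,
              cond * (p[a] - p[b]))
  r_m <- problem$D / 2 * 1e-6
  v_ms <- Q / (pi * r_m^2)
  v_um_s <- abs(v_ms) * 1e6
  tau <- 4 * problem$mu * abs(v_ms) / r_m
  structure(list(
    branches = data.frame(
      branch = seq_len(m),
      node_a = ids[a], node_b = ids[b],
      Q = Q, velocity = v_um_s, wss = tau, resistance = R,
      length = problem$L, diameter = problem$D),
    nodes = data.frame(id = ids, pressure = p,
                       boundary = seq_len(n) %in% bnd),
    mu = problem$mu), class = "flow_solution")
}

#' @exportS3Method base::print
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %d branches, %d nodes (%d boundary)\n",
              nrow(x$branches), nrow(x$nodes), sum(x$nodes$boundary)))
  cat(sprintf("  median velocity %.1f um/s, median WSS %.1f mPa\n",
              stats::median(x$branches$velocity),
              1000 * stats::median(x$branches$wss)))
  invisible(x)
}

#' Wall shear stress per branch
#'
#' Under the Poiseuille assumptions the wall shear stress is
#' `tau = 4 mu |v| / r`. [solve_flow()] already computes this; the
#' function re-derives it from a solution for clarity and testing.
#'
#' @param solution a `flow_solution`.
#' @return Numeric vector of per-branch WSS in Pa.
#' @export
wall_shear_stress <- function(solution) {
  stopifnot(inherits(solution, "flow_solution"))
  r_m <- solution$branches$diameter / 2 * 1e-6
  v_ms <- solution$branches$velocity * 1e-6
  4 * solution$mu * v_ms / r_m
}

#' Analytic propagation of radius uncertainty
#'
#' For a single Poiseuille vessel at fixed pressure drop, a radius
#' uncertainty `dr` propagates to the velocity as
#' `dv = (dp/(8 mu l)) * 2 r dr = 2 v dr / r` and to the wall shear
#' stress as `dWSS = (dp/(2 l)) * dr = tau dr / r`.
#'
#' @param v nominal velocity (any unit; `dv` comes back in the same).
#' @param tau nominal wall shear stress (any unit).
#' @param r nominal radius, micrometres.
#' @param dr radius uncertainty, micrometres.
#' @return List with `dv` and `dwss`.
#' @export
uncertainty_analytic <- function(v, tau, r, dr) {
  if (r <= 0 || dr < 0) stop("r must be positive and dr non-negative")
  list(dv = 2 * v * dr / r, dwss = tau * dr / r)
}

#' Pressure drop giving a target Poiseuille velocity
#'
#' `dp = 8 mu l v / r^2` for a single cylindrical vessel.
#'
#' @param v target mean velocity, micrometres/second.
#' @param r radius, micrometres.
#' @param l length, micrometres.
#' @param mu viscosity, Pa.s.
#' @return Pressure drop in Pa.
#' @export
poiseuille_dp <- function(v, r, l, mu = 1e-3) {
  8 * mu * (l * 1e-6) * (v * 1e-6) / (r * 1e-6)^2
}

#' Single-vessel flow problem
#'
#' Convenience constructor: one straight branch of length `l` and radius
#' `r` between two boundary nodes held at pressures `dp` and 0.
#'
#' @param l length, micrometres.
#' @param r radius, micrometres.
#' @param dp pressure drop, Pa.
#' @param mu viscosity, Pa.s.
#' @export
single_vessel_problem <- function(l, r, dp, mu = 1e-3) {
  g <- vessel_graph(
    nodes = data.frame(id = 1:2, x = c(0, l), y = 0, z = 0),
    branches = data.frame(node_a = 1, node_b = 2, length = l,
                          diameter = 2 * r))
  flow_problem(g, bc = data.frame(node = 1:2, pressure = c(dp, 0)), mu = mu)
}

#' Monte-Carlo propagation of radius uncertainty
#'
#' Perturbs every branch radius with independent draws from
#' `Normal(r_nominal, dr_sd)` (truncated positive; non-positive draws
#' are redrawn and counted), re-evaluates the flow at fixed boundary
#' pressures for each scenario, and accumulates the velocity and WSS
#' distributions. A single-vessel problem is evaluated in closed form
#' (vectorized over draws); networks are re-solved per draw and the
#' per-draw network medians are recorded.
#'
#' Normality is assessed with a Shapiro-Wilk test on a fixed-size
#' subsample (first `min(n_draws, 5000)` draws): with millions of draws
#' any omnibus test flags microscopic departures, so a bounded subsample
#' keeps the check informative.
#'
#' @param problem a [flow_problem()].
#' @param dr_sd radius standard deviation, micrometres.
#' @param n_draws number of Monte-Carlo scenarios.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `mc_uncertainty` with elements `draws`
#'   (data.frame: radius, velocity, wss for a single vessel; medians per
#'   draw for networks), `summary` (mean/sd/median of velocity um/s and
#'   WSS Pa), `normality` (Shapiro-Wilk p-values for wss, velocity and
#'   sqrt-velocity) and `n_redrawn`.
#' @export
uncertainty_monte_carlo <- function(problem, dr_sd, n_draws = 1e4,
                                    seed = NULL) {
  stopifnot(inherits(problem, "flow_problem"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- length(problem$graph$branches)
  r_nom <- problem$D / 2
  draw_radii <- function(k, r0) {
    r <- stats::rnorm(k, r0, dr_sd)
    bad <- which(r <= 0)
    redrawn <- 0L
    while (length(bad) > 0) {
      r[bad] <- stats::rnorm(length(bad), r0, dr_sd)
      redrawn <- redrawn + length(bad)
      bad <- bad[r[bad] <= 0]
    }
    list(r = r, redrawn = redrawn)
  }
  if (m == 1) {
    dp <- abs(diff(range(problem$bc$pressure)))
    l <- problem$L[1]
    dr <- draw_radii(n_draws, r_nom[1])
    r <- dr$r
    # closed-form Poiseuille at fixed dp: v = dp r^2 / (8 mu l), tau = dp r / (2 l)
    v <- dp * (r * 1e-6)^2 / (8 * problem$mu * (l * 1e-6)) * 1e6  # um/s
    tau <- dp * (r * 1e-6) / (2 * (l * 1e-6))                     # Pa
    draws <- data.frame(radius = r, velocity = v, wss = tau)
    n_redrawn <- dr$redrawn
  } else {
    rec <- matrix(NA_real_, n_draws, 3,
                  dimnames = list(NULL, c("radius", "velocity", "wss")))
    n_redrawn <- 0L
    for (t in seq_len(n_draws)) {
      dr <- draw_radii(m, r_nom)
      n_redrawn <- n_redrawn + dr$redrawn
      prob_t <- problem
      prob_t$D <- 2 * dr$r
      sol <- solve_flow(prob_t)
      rec[t, ] <- c(stats::median(dr$r),
                    stats::median(sol$branches$velocity),
                    stats::median(sol$branches$wss))
    }
    draws <- as.data.frame(rec)
  }
  sub <- seq_len(min(nrow(draws), 5000L))
  shapiro_p <- function(x) {
    x <- x[sub]
    if (length(unique(x)) < 3) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  structure(list(
    draws = draws,
    summary = data.frame(
      quantity = c("velocity_um_s", "wss_pa"),
      mean = c(mean(draws$velocity), mean(draws$wss)),
      sd = c(stats::sd(draws$velocity), stats::sd(draws$wss)),
      median = c(stats::median(draws$velocity), stats::median(draws$wss))),
    normality = c(wss = shapiro_p(draws$wss),
                  velocity = shapiro_p(draws$velocity),
                  sqrt_velocity = shapiro_p(sqrt(draws$velocity))),
    n_redrawn = n_redrawn), class = "mc_uncertainty")
}

#' @exportS3Method base::print
print.mc_uncertainty <- function(x, ...) {
  cat("<mc_uncertainty>", nrow(x$draws), "draws\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("  normality p (Shapiro, <=5000 draws): wss %.3g, v %.3g, sqrt(v) %.3g\n",
              x$normality["wss"], x$normality["velocity"],
              x$normality["sqrt_velocity"]))
  invisible(x)
}

#' Export node/segment tables for an external 3D-1D flow solver
#'
#' Writes two plain-text tab-separated tables: `<prefix>_nodes.tsv`
#' (id, x, y, z in micrometres, boundary pressure in Pa or NA) and
#' `<prefix>_segments.tsv` (node_a, node_b, radius, length in
#' micrometres). These carry all the geometry a 1D network flow or
#' filtration solver needs. [read_3d1d_inputs()] restores the graph.
#'
#' @param graph a `vessel_graph` with branch metrics.
#' @param prefix output path prefix.
#' @param solution optional `flow_solution` whose boundary pressures are
#'   exported; alternatively a `bc` data.frame(node, pressure).
#' @export
export_3d1d_inputs <- function(graph, prefix, solution = NULL) {
  press <- rep(NA_real_, nrow(graph$nodes))
  if (inherits(solution, "flow_solution")) {
    i <- match(graph$nodes$id, solution$nodes$id)
    press <- ifelse(solution$nodes$boundary[i], solution$nodes$pressure[i],
                    NA_real_)
  } else if (is.data.frame(solution)) {
    i <- match(graph$nodes$id, solution$node)
    press[!is.na(i)] <- solution$pressure[i[!is.na(i)]]
  }
  nodes <- data.frame(id = graph$nodes$id, x = graph$nodes$x,
                      y = graph$nodes$y, z = graph$nodes$z,
                      pressure = press)
  segs <- data.frame(
    node_a = vapply(graph$branches, `[[`, numeric(1), "node_a"),
    node_b = vapply(graph$branches, `[[`, numeric(1), "node_b"),
    radius = vapply(graph$branches, function(b)
      (b$metrics$diameter %||% NA_real_) / 2, numeric(1)),
    length = vapply(graph$branches, function(b)
      b$metrics$length %||% polyline_length(b$points), numeric(1)))
  utils::write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(segs, paste0(prefix, "_segments.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read back a node/segment table pair
#'
#' @param prefix path prefix used by [export_3d1d_inputs()].
#' @return A `vessel_graph` with branch length/diameter metrics.
#' @export
read_3d1d_inputs <- function(prefix) {
  nodes <- utils::read.table(paste0(prefix, "_nodes.tsv"), sep = "\t",
                             header = TRUE)
  segs <- utils::read.table(paste0(prefix, "_segments.tsv"), sep = "\t",
                            header = TRUE)
  vessel_graph(nodes[, c("id", "x", "y", "z")],
               data.frame(node_a = segs$node_a, node_b = segs$node_b,
                          length = segs$length, diameter = 2 * segs$radius))
}
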