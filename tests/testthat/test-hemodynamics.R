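test_that("hydraulic resistance follows 128 mu L / (pi D^4)", {
  expect_equal(hydraulic_resistance(100, 30, 1e-3),
               128 * 1e-3 * 1e-4 / (pi * (30e-6)^4))
  expect_equal(hydraulic_resistance(100, 30, 1e-3) / 1e12, 5.03,
               tolerance = 0.01)
  expect_equal(hydraulic_resistance(100, 60, 1e-3),
               hydraulic_resistance(100, 30, 1e-3) / 16)
  expect_equal(hydraulic_resistance(200, 30, 1e-3),
               2 * hydraulic_resistance(100, 30, 1e-3))
  expect_error(hydraulic_resistance(-1, 30, 1e-3), "positive")
})

test_that("a single vessel reproduces the Poiseuille closed form", {
  sol <- solve_flow(single_vessel_problem(l = 100, r = 15, dp = 100))
  Q_true <- pi * 100 * (30e-6)^4 / (128 * 1e-3 * 100e-6)
  expect_equal(sol$branches$Q, Q_true, tolerance = 1e-12)
  expect_equal(sol$branches$velocity, Q_true / (pi * (15e-6)^2) * 1e6,
               tolerance = 1e-12)
  expect_equal(sol$branches$velocity, 2.81e4, tolerance = 0.01)
})

test_that("a symmetric bifurcation splits flow equally", {
  g <- vessel_graph(
    nodes = data.frame(id = 1:4, x = c(0, 100, 200, 200),
                       y = c(0, 0, 50, -50), z = 0),
    branches = data.frame(node_a = c(1, 2, 2), node_b = c(2, 3, 4),
                          length = c(100, 120, 120),
                          diameter = c(30, 20, 20)))
  prob <- flow_problem(g, bc = data.frame(node = c(1, 3, 4),
                                          pressure = c(100, 0, 0)))
  sol <- solve_flow(prob)
  expect_equal(sol$branches$Q[2], sol$branches$Q[3], tolerance = 1e-12)
  expect_equal(sol$branches$Q[1], sol$branches$Q[2] + sol$branches$Q[3],
               tolerance = 1e-12)
})

test_that("sparse solver matches the dense (n_branch + n_nodes) oracle", {
  for (seed in 1:5) {
    edges <- random_network(seed)
    n_nodes <- max(edges$node_a, edges$node_b)
    nodes <- data.frame(id = seq_len(n_nodes), x = 0, y = 0, z = 0)
    bc <- data.frame(node = c(1, n_nodes), pressure = c(200, 0))
    g <- vessel_graph(nodes, edges)
    sol <- solve_flow(flow_problem(g, bc = bc))
    oracle <- dense_flow_oracle(nodes, edges, 1e-3, bc)
    expect_lt(max(abs(sol$branches$Q - oracle$Q)) / max(abs(oracle$Q)),
              1e-10)
    expect_lt(max(abs(sol$nodes$pressure - oracle$p)) / max(abs(oracle$p)),
              1e-10)
    # interior mass balance
    res <- vapply(nodes$id[-c(1, n_nodes)], function(id) {
      sum(sol$branches$Q[sol$branches$node_a == id]) -
        sum(sol$branches$Q[sol$branches$node_b == id])
    }, numeric(1))
    expect_lt(max(abs(res)), 1e-9 * max(abs(sol$branches$Q)))
    # global conservation: inflow at node 1 equals outflow at node n
    inflow <- sum(sol$branches$Q[sol$branches$node_a == 1]) -
      sum(sol$branches$Q[sol$branches$node_b == 1])
    outflow <- sum(sol$branches$Q[sol$branches$node_b == n_nodes]) -
      sum(sol$branches$Q[sol$branches$node_a == n_nodes])
    expect_equal(inflow, outflow, tolerance = 1e-9)
  }
})

test_that("scaling the pressure drop scales Q, v and WSS exactly", {
  edges <- random_network(11)
  n_nodes <- max(edges$node_a, edges$node_b)
  nodes <- data.frame(id = seq_len(n_nodes), x = 0, y = 0, z = 0)
  g <- vessel_graph(nodes, edges)
  sols <- lapply(c(100, 200, 400), function(dp)
    solve_flow(flow_problem(g, bc = data.frame(node = c(1, n_nodes),
                                               pressure = c(dp, 0)))))
  for (k in 2:3) {
    f <- c(1, 2, 4)[k]
    expect_equal(sols[[k]]$branches$Q, f * sols[[1]]$branches$Q,
                 tolerance = 1e-13)
    expect_equal(sols[[k]]$branches$velocity,
                 f * sols[[1]]$branches$velocity, tolerance = 1e-13)
    expect_equal(sols[[k]]$branches$wss, f * sols[[1]]$branches$wss,
                 tolerance = 1e-13)
  }
})

test_that("wall shear stress is 4 mu v / r, zero on zero-flow branches", {
  dp <- poiseuille_dp(500, 15, 100)
  sol <- solve_flow(single_vessel_problem(l = 100, r = 15, dp = dp))
  expect_equal(sol$branches$velocity, 500, tolerance = 1e-9)
  expect_equal(sol$branches$wss, 4 * 1e-3 * 500e-6 / 15e-6, tolerance = 1e-9)
  expect_equal(sol$branches$wss, 0.1333, tolerance = 1e-3)
  expect_equal(wall_shear_stress(sol), sol$branches$wss)

  # dead-end branch gets zero flow and zero WSS
  g <- vessel_graph(
    nodes = data.frame(id = 1:4, x = c(0, 100, 200, 100),
                       y = c(0, 0, 0, 80), z = 0),
    branches = data.frame(node_a = c(1, 2, 2), node_b = c(2, 3, 4),
                          length = c(100, 100, 80), diameter = 20))
  sol2 <- solve_flow(flow_problem(g, bc = data.frame(node = c(1, 3),
                                                     pressure = c(100, 0))))
  expect_equal(sol2$branches$Q[3], 0)
  expect_equal(sol2$branches$wss[3], 0)
})

test_that("disconnected boundary sets fail; isolated subnetworks warn", {
  g <- vessel_graph(
    nodes = data.frame(id = 1:4, x = c(0, 100, 300, 400), y = 0, z = 0),
    branches = data.frame(node_a = c(1, 3), node_b = c(2, 4),
                          length = 100, diameter = 20))
  expect_warning(
    sol <- solve_flow(flow_problem(g, bc = data.frame(node = c(1, 2),
                                                      pressure = c(100, 0)))),
    "zero flow")
  expect_equal(sol$branches$Q[2], 0)
  expect_error(flow_problem(g, bc = data.frame(node = 1, pressure = 100)),
               "two distinct")
})

test_that("analytic uncertainty propagation matches its closed forms", {
  ua <- uncertainty_analytic(v = 500, tau = 4 * 1e-3 * 500e-6 / 15e-6,
                             r = 15, dr = 1.6)
  expect_equal(ua$dv, 2 * 500 * 1.6 / 15)
  expect_equal(round(ua$dv), 107)
  expect_equal(ua$dwss * 1000, 14.2, tolerance = 0.02)
  z <- uncertainty_analytic(v = 500, tau = 0.133, r = 15, dr = 0)
  expect_equal(z$dv, 0)
  expect_equal(z$dwss, 0)
})

test_that("Monte-Carlo single-vessel WSS converges to the linear closed form", {
  dp <- poiseuille_dp(500, 15, 100)
  prob <- single_vessel_problem(l = 100, r = 15, dp = dp)
  mc <- uncertainty_monte_carlo(prob, dr_sd = 1.6, n_draws = 2e5, seed = 9)
  # WSS = dp r / (2 l) is linear in r: mean and SD follow directly
  expect_equal(mc$summary$mean[2], dp * 15e-6 / (2 * 100e-6),
               tolerance = 0.005)
  expect_equal(mc$summary$sd[2], dp * 1.6e-6 / (2 * 100e-6),
               tolerance = 0.01)
  # distribution shapes: WSS gaussian, velocity not, sqrt(velocity) yes
  expect_gt(mc$normality["wss"], 0.01)
  expect_lt(mc$normality["velocity"], 1e-4)
  expect_gt(mc$normality["sqrt_velocity"], 0.01)
  # reproducible by seed
  mc2 <- uncertainty_monte_carlo(prob, dr_sd = 1.6, n_draws = 1000, seed = 5)
  mc3 <- uncertainty_monte_carlo(prob, dr_sd = 1.6, n_draws = 1000, seed = 5)
  expect_identical(mc2$draws, mc3$draws)
})

test_that("eight-vessel network medians vary comparably to the single vessel", {
  # two parallel chains of four vessels with the stated radius set
  radii <- c(13, 14, 14, 15, 15, 16, 16, 17)
  nodes <- data.frame(id = 1:8,
                      x = c(0, 100, 200, 300, 400, 100, 200, 300),
                      y = c(0, 40, 40, 40, 0, -40, -40, -40), z = 0)
  edges <- data.frame(node_a = c(1, 2, 3, 4, 1, 6, 7, 8),
                      node_b = c(2, 3, 4, 5, 6, 7, 8, 5),
                      length = 100, diameter = 2 * radii)
  g <- vessel_graph(nodes, edges)
  dp <- poiseuille_dp(500, 15, 100) * 4   # four vessels in series
  prob <- flow_problem(g, bc = data.frame(node = c(1, 5),
                                          pressure = c(dp, 0)))
  mc <- uncertainty_monte_carlo(prob, dr_sd = 1.6, n_draws = 400, seed = 21)
  # relative spread of the median WSS stays comparable to the
  # single-vessel case (sd/mean = 1.6/15 ~ 0.107)
  rel <- mc$summary$sd[2] / mc$summary$mean[2]
  expect_gt(rel, 0.02)
  expect_lt(rel, 0.3)
})

test_that("3D-1D exchange tables round-trip the network", {
  g <- vessel_graph(
    nodes = data.frame(id = 1:4, x = c(0, 100, 200, 200),
                       y = c(0, 0, 60, -60), z = 0),
    branches = data.frame(node_a = c(1, 2, 2), node_b = c(2, 3, 4),
                          length = c(100, 120, 120), diameter = 24))
  prefix <- file.path(withr::local_tempdir(), "net")
  export_3d1d_inputs(g, prefix)
  expect_true(file.exists(paste0(prefix, "_nodes.tsv")))
  segs <- read.table(paste0(prefix, "_segments.tsv"), header = TRUE)
  expect_equal(nrow(segs), 3)
  nodes <- read.table(paste0(prefix, "_nodes.tsv"), header = TRUE)
  expect_equal(nrow(nodes), 4)
  g2 <- read_3d1d_inputs(prefix)
  expect_equal(length(g2$branches), 3)
  expect_equal(vapply(g2$branches, function(b) b$metrics$diameter,
                      numeric(1)), rep(24, 3))
  expect_equal(g2$nodes$x, g$nodes$x)

  # single tube: two nodes, one segment
  g1 <- vessel_graph(nodes = data.frame(id = 1:2, x = c(0, 100), y = 0, z = 0),
                     branches = data.frame(node_a = 1, node_b = 2,
                                           length = 100, diameter = 30))
  p1 <- file.path(withr::local_tempdir(), "tube")
  export_3d1d_inputs(g1, p1)
  expect_equal(nrow(read.table(paste0(p1, "_nodes.tsv"), header = TRUE)), 2)
  expect_equal(nrow(read.table(paste0(p1, "_segments.tsv"), header = TRUE)), 1)
})
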