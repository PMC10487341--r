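# quadrature oracle for the arc length of a parametric curve
arc_length_quadrature <- function(f, t0, t1, n = 20000) {
  t <- seq(t0, t1, length.out = n)
  p <- f(t)
  sum(sqrt(rowSums(diff(p)^2)))
}

test_that("branch_length sums Euclidean steps along the centerline", {
  expect_equal(branch_length(list(points = rbind(c(0, 0, 0), c(10, 0, 0)))),
               10)
  th <- seq(0, pi / 2, length.out = 500)
  qc <- list(points = cbind(20 * cos(th), 20 * sin(th), 0))
  expect_equal(branch_length(qc), 10 * pi, tolerance = 0.6 / (10 * pi))
})

test_that("tortuosity is arc over chord, 1 for straight vessels", {
  straight <- list(points = cbind(seq(0, 50, 1), 3, 7))
  expect_equal(branch_tortuosity(straight), 1)
  th <- seq(0, pi, length.out = 500)
  semi <- list(points = cbind(30 * cos(th), 30 * sin(th), 0))
  expect_equal(branch_tortuosity(semi), pi / 2, tolerance = 1e-4)
  loop <- list(points = cbind(cos(seq(0, 2 * pi, length.out = 100)),
                              sin(seq(0, 2 * pi, length.out = 100)), 0))
  expect_warning(tl <- branch_tortuosity(loop), "undefined")
  expect_true(is.nan(tl))
})

test_that("pipeline tortuosity matches a quadrature oracle on a sine vessel", {
  f <- function(t) cbind(15 + 110 * t, 30 + 8 * sin(2 * pi * t), 25)
  oracle_arc <- arc_length_quadrature(f, 0, 1)
  oracle_tort <- oracle_arc / sqrt(110^2)
  spec <- phantom_spec(box = c(140, 60, 50), spacing = 1,
                       branches = list(list(points = f(seq(0, 1, 0.005)),
                                            a = 5)))
  ph <- render_phantom(spec)
  b <- measure_single_branch(ph, prune = 10)
  expect_equal(branch_tortuosity(b), oracle_tort, tolerance = 0.01)
})

test_that("cross-section radii recover circular and elliptical truth", {
  # circular radii across the physiological-to-large range
  for (r in c(4, 8, 15, 30)) {
    ph <- render_phantom(tube_phantom(r))
    b <- measure_single_branch(ph)
    rr <- branch_radius(b, ph$mask, 3)
    tol <- max(1 * ph$mask$spacing[1], 0.05 * r)
    expect_lt(max(abs(rr$radii - r)), tol, label = paste("radius", r))
  }
  # elliptical lumen: equivalent radius sqrt(a b)
  eph <- render_phantom(tube_phantom(12, b = 6))
  be <- measure_single_branch(eph)
  re <- branch_radius(be, eph$mask, 3)
  expect_equal(re$mean, sqrt(12 * 6), tolerance = 0.05)
})

test_that("n_r = 1 and n_r = 3 disagree on tapered vessels", {
  taper <- phantom_spec(box = c(160, 70, 70), spacing = 1, branches = list(
    list(points = rbind(c(10, 35, 35), c(60, 35, 35)), a = 14),
    list(points = rbind(c(60, 35, 35), c(110, 35, 35)), a = 10),
    list(points = rbind(c(110, 35, 35), c(150, 35, 35)), a = 5)))
  ph <- render_phantom(taper)
  b <- measure_single_branch(ph, prune = 8)
  r1 <- branch_radius(b, ph$mask, 1)$mean
  r3 <- branch_radius(b, ph$mask, 3)$mean
  expect_gt(abs(r1 - r3), 0.25)
})

test_that("eccentricity conventions behave as documented", {
  cph <- render_phantom(tube_phantom(10))
  bc <- measure_single_branch(cph)
  expect_equal(branch_eccentricity(bc, cph$mask, 3), 1, tolerance = 0.05)
  expect_equal(branch_eccentricity(bc, cph$mask, 3, convention = "classical"),
               0, tolerance = 0.3)

  eph <- render_phantom(tube_phantom(12, b = 6))
  be <- measure_single_branch(eph)
  expect_equal(branch_eccentricity(be, eph$mask, 3), 0.5, tolerance = 0.05)
  expect_equal(branch_eccentricity(be, eph$mask, 3, convention = "classical"),
               sqrt(1 - 0.25), tolerance = 0.05)
})

test_that("lateral area follows the frustum closed forms", {
  # constant radius: 2 pi r L exactly, given exact inputs
  cyl <- list(points = rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(branch_lateral_area(cyl, radii = 10, positions = 50),
               2 * pi * 10 * 100)
  expect_equal(branch_lateral_area(cyl, radii = c(10, 10, 10),
                                   positions = c(10, 50, 90)),
               2 * pi * 10 * 100)
  # linear taper 10 -> 20 over 100: pi (r1 + r2) L
  expect_equal(branch_lateral_area(cyl, radii = c(10, 20),
                                   positions = c(0, 100)),
               pi * 30 * 100)
  # zero-length branch
  pt <- list(points = rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(branch_lateral_area(pt, radii = 5), 0)
  # measured cylinder within 5 percent
  ph <- render_phantom(tube_phantom(10))
  b <- measure_single_branch(ph)
  rr <- branch_radius(b, ph$mask, 3)
  area <- branch_lateral_area(b, rr$radii, rr$positions)
  expect_equal(area, ph$truth$lateral_area, tolerance = 0.05)
})

test_that("surface over volume matches the cylinder-in-box closed form", {
  cy <- phantom_spec(box = c(500, 500, 100), spacing = 2, branches = list(
    list(points = rbind(c(20, 250, 50), c(480, 250, 50)), a = 10)))
  ph <- render_phantom(cy)
  g <- build_graph(skeletonize(ph$mask))
  g <- extend_tips(prune_short_branches(g, 6), ph$mask)
  tab <- morphometry(g, ph$mask)
  sv_true <- 1000 * 2 * pi * 10 * 460 / (500 * 500 * 100 - pi * 100 * 460)
  expect_equal(attr(tab, "summary")$sv_mm2_mm3, sv_true, tolerance = 0.05)

  # doubling the box at fixed network scales S/V by the exact volume ratio
  areas <- tab$lateral_area
  sv1 <- surface_over_volume(areas, ph$mask)
  box1 <- dim(ph$mask$data) * ph$mask$spacing
  sv2 <- surface_over_volume(areas, ph$mask, box = box1 * c(1, 1, 2))
  lumen <- sum(ph$mask$data) * prod(ph$mask$spacing)
  expect_equal(sv2 / sv1,
               (prod(box1) - lumen) / (prod(box1 * c(1, 1, 2)) - lumen))
  expect_error(surface_over_volume(areas, ph$mask, box = box1 / 2), "smaller")
})

test_that("2D projection widens flat ellipses and shortens undulating vessels", {
  eph <- render_phantom(tube_phantom(12, b = 6))
  cmp <- compare_2d_3d(eph$mask, min_branch_length = 6)
  r2d <- cmp$comparison$analysis_2d[1]
  r3d <- cmp$comparison$analysis_3d[1]
  expect_gt(r2d, r3d)

  # circular tube: 2D and 3D agree within 10 percent
  cph <- render_phantom(tube_phantom(10))
  c2 <- compare_2d_3d(cph$mask, min_branch_length = 6)
  expect_equal(c2$comparison$analysis_2d[1], c2$comparison$analysis_3d[1],
               tolerance = 0.1)

  # undulating vessel: projection can only shorten
  t <- seq(0, 1, length.out = 100)
  und <- phantom_spec(box = c(120, 50, 60), spacing = 1, branches = list(
    list(points = cbind(10 + 100 * t, 25, 30 + 12 * sin(4 * pi * t)), a = 5)))
  uph <- render_phantom(und)
  cu <- compare_2d_3d(uph$mask, min_branch_length = 6)
  expect_lte(cu$comparison$analysis_2d[2], cu$comparison$analysis_3d[2])
})

test_that("tortuosity is invariant under rigid rotation of the phantom", {
  f <- function(t) cbind(15 + 100 * t, 30 + 8 * sin(2 * pi * t), 25)
  flat <- phantom_spec(box = c(130, 60, 50), spacing = 1,
                       branches = list(list(points = f(seq(0, 1, 0.005)),
                                            a = 5)))
  tilted <- flat
  tilted$tilt_deg <- 10
  b1 <- measure_single_branch(render_phantom(flat), prune = 10)
  b2 <- measure_single_branch(render_phantom(tilted), prune = 10)
  expect_equal(branch_tortuosity(b1), branch_tortuosity(b2),
               tolerance = 0.01)
})
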