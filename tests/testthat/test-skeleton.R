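test_that("a straight cylinder thins to its axis", {
  ph <- render_phantom(tube_phantom(6, length = 100))
  sk <- skeletonize(ph$mask)
  idx <- which(sk$data, arr.ind = TRUE)
  pos <- sweep(idx - 1, 2, sk$spacing, "*")
  ctr <- dim(sk$data)[2:3] * sk$spacing[2:3] / 2   # tube axis position
  off_axis <- sqrt((pos[, 2] - ctr[1])^2 + (pos[, 3] - ctr[2])^2)
  expect_lte(max(off_axis), sqrt(2) + 1e-9)   # within one voxel of the axis
  expect_true(all(sk$data[ph$mask$data == FALSE] == FALSE))  # subset of mask
})

test_that("a one-voxel-wide line is already thin", {
  arr <- array(FALSE, c(40, 10, 10))
  arr[5:35, 5, 5] <- TRUE
  m <- binary_mask(arr, c(1, 1, 1))
  expect_identical(skeletonize(m)$data, arr)
})

test_that("skeletonization preserves connected-component count", {
  two <- phantom_spec(box = c(100, 90, 40), spacing = 1, branches = list(
    list(points = rbind(c(10, 25, 20), c(90, 25, 20)), a = 6),
    list(points = rbind(c(10, 65, 20), c(90, 65, 20)), a = 6)))
  ph <- render_phantom(two)
  expect_equal(microvessel:::count_components(ph$mask), 2L)
  expect_equal(microvessel:::count_components(skeletonize(ph$mask)), 2L)

  yph <- render_phantom(y_phantom())
  expect_equal(microvessel:::count_components(yph$mask), 1L)
  expect_equal(microvessel:::count_components(skeletonize(yph$mask)), 1L)
})

test_that("build_graph identifies branches, junctions and endpoints", {
  tube <- render_phantom(tube_phantom(6, length = 80))
  gt <- build_graph(skeletonize(tube$mask))
  expect_length(gt$branches, 1L)
  expect_equal(sum(gt$nodes$kind == "junction"), 0L)
  expect_equal(sum(gt$nodes$kind == "endpoint"), 2L)

  yg <- build_graph(skeletonize(render_phantom(y_phantom())$mask))
  expect_length(yg$branches, 3L)
  expect_equal(sum(yg$nodes$kind == "junction"), 1L)
  expect_equal(sum(yg$nodes$kind == "endpoint"), 3L)

  hg <- build_graph(skeletonize(render_phantom(h_phantom())$mask))
  expect_length(hg$branches, 5L)
  expect_equal(sum(hg$nodes$kind == "junction"), 2L)
  expect_equal(sum(hg$nodes$kind == "endpoint"), 4L)

  # branches reference existing nodes and start/end at node positions
  for (b in hg$branches) {
    expect_true(all(c(b$node_a, b$node_b) %in% hg$nodes$id))
    na <- hg$nodes[match(b$node_a, hg$nodes$id), ]
    expect_equal(unname(b$points[1, ]), c(na$x, na$y, na$z))
  }
})

test_that("smooth_branch interpolates exactly at smoothing 0 and is exact on lines", {
  pts <- cbind(seq(0, 30, by = 1), 5, 2)
  br <- list(points = pts)
  sm <- smooth_branch(br, smoothing = 0)
  expect_equal(branch_length(sm), 30, tolerance = 1e-8)
  # smoothing 0: curve passes through every input point
  wig <- cbind(c(0, 1, 2, 3, 4), c(0, 1, 0, -1, 0), 0)
  sw <- smooth_branch(list(points = wig), smoothing = 0)
  for (k in seq_len(nrow(wig))) {
    dmin <- min(sqrt(rowSums(sweep(sw$points, 2, wig[k, ])^2)))
    expect_lt(dmin, 1e-6)
  }
})

test_that("spline smoothing recovers arc length of digitized curves", {
  # 45-degree staircase: raw polyline overestimates length by sqrt(2)-ish
  stair <- cbind(rep(0:50, each = 2)[-1], rep(0:50, each = 2)[-102], 0)
  sm <- smooth_branch(list(points = stair))   # default smoothing
  expect_equal(branch_length(sm), 50 * sqrt(2), tolerance = 0.025)

  # digitized quarter circle, radius 20
  th <- seq(0, pi / 2, length.out = 200)
  qc <- unique(round(cbind(20 * cos(th), 20 * sin(th), 0)))
  sq <- smooth_branch(list(points = qc))
  expect_equal(branch_length(sq), 10 * pi, tolerance = 0.02 * 10 * pi)
})

test_that("prune_short_branches removes stubs and merges pass-through junctions", {
  yg <- build_graph(skeletonize(render_phantom(y_phantom())$mask))
  expect_identical(prune_short_branches(yg, 0), yg)

  # Y with one short stub: stub goes, junction dissolves, one branch left
  ystub <- phantom_spec(box = c(120, 60, 40), spacing = 1, branches = list(
    list(points = rbind(c(10, 30, 20), c(60, 30, 20)), a = 4),
    list(points = rbind(c(60, 30, 20), c(110, 30, 20)), a = 4),
    list(points = rbind(c(60, 30, 20), c(68, 38, 20)), a = 4)))
  g <- build_graph(skeletonize(render_phantom(ystub)$mask))
  pruned <- prune_short_branches(g, 20)
  expect_length(pruned$branches, 1L)
  expect_gt(microvessel:::polyline_length(pruned$branches[[1]]$points), 80)

  # interior (junction-to-junction) branches survive any threshold
  hg <- build_graph(skeletonize(render_phantom(h_phantom())$mask))
  hp <- prune_short_branches(hg, 60)   # taller than the crossbar
  lens <- vapply(hp$branches, function(b)
    microvessel:::polyline_length(b$points), numeric(1))
  expect_true(any(lens > 60))  # crossbar region still connects the rails
  expect_equal(microvessel:::count_components(
    skeletonize(render_phantom(h_phantom())$mask)), 1L)
})

test_that("graph re-extraction from the same skeleton is stable", {
  sk <- skeletonize(render_phantom(h_phantom())$mask)
  g1 <- build_graph(sk)
  g2 <- build_graph(sk)
  l1 <- sum(vapply(g1$branches, function(b)
    microvessel:::polyline_length(b$points), numeric(1)))
  l2 <- sum(vapply(g2$branches, function(b)
    microvessel:::polyline_length(b$points), numeric(1)))
  expect_equal(l1, l2, tolerance = 0.005)
})

test_that("graph export writes JSON and CSV edge lists", {
  g <- build_graph(skeletonize(render_phantom(y_phantom())$mask))
  pj <- withr::local_tempfile(fileext = ".json")
  pc <- withr::local_tempfile(fileext = ".csv")
  export_graph(g, pj, "json")
  export_graph(g, pc, "csv")
  doc <- jsonlite::read_json(pj)
  expect_length(doc$branches, 3L)
  df <- read.csv(pc)
  expect_equal(nrow(df), 3L)
  expect_true(all(c("node_a", "node_b", "length") %in% names(df)))
})
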