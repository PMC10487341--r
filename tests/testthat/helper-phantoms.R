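# Shared phantom builders. All fixtures are generated in code at test
# time; geometry is exact so analytic truth values are available.

tube_phantom <- function(r, length = 100, b = r, spacing = 1,
                         fg = 200, bg = 10, noise = "none", noise_sd = 0,
                         seed = 1L) {
  box <- c(length + 20, 4 * r + 20, 4 * b + 20)
  phantom_spec(
    box = box, spacing = spacing,
    branches = list(list(points = rbind(c(10, box[2] / 2, box[3] / 2),
                                        c(box[1] - 10, box[2] / 2, box[3] / 2)),
                         a = r, b = b)),
    fg = fg, bg = bg, noise = noise, noise_sd = noise_sd, seed = seed)
}

y_phantom <- function(a = 5) {
  phantom_spec(box = c(120, 120, 40), spacing = 1, branches = list(
    list(points = rbind(c(10, 60, 20), c(60, 60, 20)), a = a),
    list(points = rbind(c(60, 60, 20), c(110, 100, 20)), a = a),
    list(points = rbind(c(60, 60, 20), c(110, 20, 20)), a = a)))
}

h_phantom <- function(a = 5) {
  phantom_spec(box = c(120, 120, 40), spacing = 1, branches = list(
    list(points = rbind(c(10, 20, 20), c(110, 20, 20)), a = a),
    list(points = rbind(c(10, 100, 20), c(110, 100, 20)), a = a),
    list(points = rbind(c(60, 20, 20), c(60, 100, 20)), a = a)))
}

arc_phantom <- function(radius = 40, a = 5, theta = c(0, pi)) {
  th <- seq(theta[1], theta[2], length.out = 200)
  ctr <- c(radius + 30, 20)
  box <- c(2 * radius + 60, radius + 50, 40)
  phantom_spec(box = box, spacing = 1, branches = list(
    list(points = cbind(ctr[1] + radius * cos(th),
                        ctr[2] + radius * sin(th), 20), a = a)))
}

# measured single branch from a rendered phantom, via the full
# skeleton -> graph -> tip rectification -> spline route
measure_single_branch <- function(ph, prune = 0, smoothing = 2L) {
  g <- build_graph(skeletonize(ph$mask))
  if (prune > 0) g <- prune_short_branches(g, prune)
  g <- extend_tips(g, ph$mask)
  expect_length(g$branches, 1L)
  smooth_branch(g$branches[[1]], smoothing = smoothing)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
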