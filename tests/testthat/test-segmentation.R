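test_that("active contour recovers phantom lumina (noiseless and noisy)", {
  ph <- render_phantom(tube_phantom(10, fg = 200, bg = 10))
  m <- segment_active_contour(ph$image)
  expect_gt(dice_coef(m$data, ph$mask$data), 0.95)

  phn <- render_phantom(tube_phantom(10, fg = 200, bg = 10,
                                     noise = "gaussian", noise_sd = 20,
                                     seed = 7))
  mn <- segment_active_contour(phn$image)
  expect_gt(dice_coef(mn$data, phn$mask$data), 0.90)
})

test_that("segmentation is invariant to affine intensity rescaling", {
  phn <- render_phantom(tube_phantom(8, fg = 200, bg = 10,
                                     noise = "gaussian", noise_sd = 15,
                                     seed = 4))
  m1 <- segment_active_contour(phn$image)
  img2 <- phn$image
  img2$data <- 3.2 * img2$data + 17
  m2 <- segment_active_contour(img2)
  expect_identical(m1$data, m2$data)
})

test_that("segmented volume tracks true lumen volume across tube radii", {
  for (r in c(5, 12, 30)) {
    ph <- render_phantom(tube_phantom(r, length = 60, fg = 200, bg = 10))
    m <- segment_active_contour(ph$image)
    expect_lt(abs(sum(m$data) - sum(ph$mask$data)) / sum(ph$mask$data),
              0.05, label = paste("radius", r))
  }
})

test_that("mask-initialized run on a binary volume is a fixed point", {
  blk <- array(FALSE, c(30, 30, 30))
  blk[8:22, 8:22, 8:22] <- TRUE
  img <- volume_image(blk * 255, c(1, 1, 1))
  out <- segment_active_contour(img, init = blk)
  expect_identical(out$data, blk)
})

test_that("uniform volumes are rejected", {
  expect_error(segment_active_contour(volume_image(array(5, c(8, 8, 8)),
                                                   c(1, 1, 1))),
               "no separable phases")
})

test_that("keep_largest_component removes speckle deterministically", {
  ph <- render_phantom(tube_phantom(6, length = 60))
  withspeck <- ph$mask
  d <- dim(withspeck$data)
  speck <- rbind(c(2, 2, 2), c(2, d[2] - 1, 2), c(d[1] - 1, 2, 2),
                 c(d[1] - 1, d[2] - 1, d[3] - 1), c(2, 2, d[3] - 1))
  withspeck$data[speck] <- TRUE
  cleaned <- keep_largest_component(withspeck)
  expect_identical(cleaned$data, ph$mask$data)
  # single component: identity
  expect_identical(keep_largest_component(ph$mask)$data, ph$mask$data)
  # equal-size tie: the scan-order-first component wins
  twin <- array(FALSE, c(20, 10, 10))
  twin[2:5, 3:6, 3:6] <- TRUE
  twin[14:17, 3:6, 3:6] <- TRUE
  kept <- keep_largest_component(binary_mask(twin, c(1, 1, 1)))
  expect_true(all(which(kept$data, arr.ind = TRUE)[, 1] <= 5))
  expect_error(keep_largest_component(
    binary_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))), "empty")
})

test_that("load_mask maps nonzero to foreground and rejects >2 levels", {
  ph <- render_phantom(tube_phantom(5, length = 40))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(ph$mask, path, bits = 8L)
  m <- load_mask(path, ph$mask$spacing)
  expect_identical(m$data, ph$mask$data)

  tri <- volume_image(array(rep(c(0, 128, 255), length.out = 4 * 4 * 2),
                            c(4, 4, 2)), c(1, 1, 1))
  path2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(tri, path2, bits = 8L)
  expect_error(load_mask(path2, c(1, 1, 1)), "distinct values")

  # all-zero volume is accepted as an (empty) mask
  zero <- volume_image(array(0, c(4, 4, 2)), c(1, 1, 1))
  path3 <- withr::local_tempfile(fileext = ".tif")
  write_stack(zero, path3, bits = 8L)
  expect_false(any(load_mask(path3, c(1, 1, 1))$data))
})
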