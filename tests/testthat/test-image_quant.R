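test_that("projection slice counts follow depth / z-step", {
  stack <- array(runif(8 * 8 * 40), c(8, 8, 40))
  expect_equal(dim(project_stack(stack, "sum", 30, 2)), c(8, 8))
  # 30 um at 2 um steps -> 15 slices; verify via sum identity
  expect_equal(project_stack(stack, "sum", 30, 2),
               apply(stack[, , 1:15], c(1, 2), sum))
  expect_equal(project_stack(stack, "max", 60, 2),
               apply(stack[, , 1:30], c(1, 2), max))
  expect_error(project_stack(stack, "max", 100, 2),
               class = "tm_parameter_error")
  # a single bright voxel survives a max projection at its (x, y)
  stack0 <- array(0, c(5, 5, 10))
  stack0[3, 4, 7] <- 1
  expect_equal(project_stack(stack0, "max", 20, 2)[3, 4], 1)
})

test_that("start-slice rule finds the first slice with signal", {
  stack <- array(0.01, c(10, 10, 12))
  stack[, , 5:12] <- stack[, , 5:12] + 0.5
  expect_identical(find_start_slice(stack), 5L)
})

test_that("particle analysis counts discs and areas exactly", {
  img <- matrix(0, 60, 60)
  centers <- cbind(c(10, 10, 30, 50, 50), c(10, 50, 30, 10, 50))
  for (i in 1:5) {
    off <- expand.grid(dy = -3:3, dx = -3:3)
    off <- off[off$dy^2 + off$dx^2 <= 2.55^2, ]  # 21-px disc
    img[cbind(centers[i, 1] + off$dy, centers[i, 2] + off$dx)] <- 1
  }
  seg <- segment_particles(img, threshold = 0.5)
  expect_identical(nrow(seg$particles), 5L)
  expect_equal(seg$total_area, 105)
  expect_true(all(seg$particles$area == 21))
  # blank image: no particles, zero area
  seg0 <- segment_particles(matrix(0, 20, 20), threshold = 0.5)
  expect_identical(nrow(seg0$particles), 0L)
  expect_equal(seg0$total_area, 0)
})

test_that("circularity filtering excludes elongated bars", {
  img <- matrix(0, 40, 60)
  img[19:21, 11:40] <- 1  # 3 x 30 bar
  circ_oracle <- 4 * pi * 90 / oracle_perimeter(img > 0.5)^2
  expect_lt(circ_oracle, 0.5)
  seg <- segment_particles(img, threshold = 0.5,
                           filter = particle_filter(circ_low = 0.5))
  expect_equal(seg$total_area, 0)
  # permissive filter keeps it
  seg2 <- segment_particles(img, threshold = 0.5,
                            filter = particle_filter(circ_low = 0))
  expect_equal(seg2$total_area, 90)
  expect_equal(seg2$particles$circularity, circ_oracle, tolerance = 1e-12)
})

test_that("8-connectivity joins diagonal pixels into one particle", {
  img <- matrix(0, 10, 10)
  img[3, 3] <- 1; img[4, 4] <- 1; img[5, 5] <- 1
  seg <- segment_particles(img, threshold = 0.5,
                           filter = particle_filter(circ_low = 0))
  expect_identical(nrow(seg$particles), 1L)
  expect_equal(seg$particles$area, 3)
})

test_that("total area is additive and label-order invariant", {
  g <- gen_puncta_image(n_roi = 15, n_bg = 7, seed = 12)
  seg <- segment_particles(g$image, threshold = 0.5)
  expect_equal(seg$total_area, sum(seg$particles$area))
  expect_equal(seg$total_area, sum(g$truth$signal_area))
})

test_that("normalized expression dispatches on variant and is scale invariant", {
  r <- normalized_expression(0.2, bg_signal_areas = c(0.05, 0.15),
                             variant = "sema3a-ratio")
  expect_equal(r$normalized_expression, 2)
  expect_equal(normalized_expression(0.1, bg_signal_areas = 0.1,
                                     variant = "cs-ratio")$normalized_expression, 1)
  f <- normalized_expression(50, region_area = 1000,
                             variant = "slit1-fraction")
  expect_equal(f$normalized_expression, 0.05)
  # scale invariance
  r2 <- normalized_expression(2000, bg_signal_areas = c(500, 1500),
                              variant = "sema3a-ratio")
  expect_equal(r2$normalized_expression, r$normalized_expression)
  expect_error(normalized_expression(0.2, bg_signal_areas = 0,
                                     variant = "sema3a-ratio"),
               class = "tm_empty_background")
  expect_error(normalized_expression(0.2, region_area = 0,
                                     variant = "lpa-fraction"),
               class = "tm_empty_region")
})

test_that("measured normalized expression recovers generator ground truth", {
  g <- gen_puncta_image(n_roi = 24, n_bg = 12, seed = 21)
  roi_frac <- segment_particles(g$image * g$roi_mask,
                                threshold = 0.5)$total_area / sum(g$roi_mask)
  bg_frac <- segment_particles(g$image * g$bg_masks[[1]],
                               threshold = 0.5)$total_area /
    sum(g$bg_masks[[1]])
  meas <- normalized_expression(roi_frac, bg_signal_areas = bg_frac,
                                variant = "sema3a-ratio")$normalized_expression
  truth <- g$truth$area_fraction[1] / g$truth$area_fraction[2]
  expect_lt(abs(meas - truth) / truth, 0.05)
})

test_that("nuclear area fraction matches the constructed fixture", {
  gn <- gen_nuclei_image(n_nuclei = 10, seed = 4)
  # without blur the segmentation recovers the exact disc area
  res0 <- nuclear_area_fraction(gn$image, gn$roi, blur_sigma = 0,
                                threshold = 0.5)
  expect_equal(res0$area_fraction, gn$truth$area_fraction)
  # the documented pipeline (blur sigma 2) stays close for nuclei >> sigma
  gn2 <- gen_nuclei_image(n_nuclei = 6, nucleus_radius = 8, seed = 5)
  res2 <- nuclear_area_fraction(gn2$image, gn2$roi, blur_sigma = 2,
                                threshold = (0.9 + 0.05) / 2)
  expect_lt(abs(res2$area_fraction - gn2$truth$area_fraction) /
              gn2$truth$area_fraction, 0.15)
  # blank ROI -> 0; ROI outside image errors
  blank <- matrix(0, 100, 100)
  expect_equal(nuclear_area_fraction(blank, c(10, 10, 50, 50),
                                     threshold = 0.5)$area_fraction, 0)
  expect_error(nuclear_area_fraction(blank, c(90, 90, 50, 50),
                                     threshold = 0.5),
               class = "tm_parameter_error")
})

test_that("elongation equals the axis ratio of generated ellipses", {
  # disc
  expect_equal(elongation(gen_ellipse_mask(40, 40, 0, 101)), 1,
               tolerance = 0.02)
  # axis ratios across rotations
  for (ratio in c(1.5, 2, 3)) {
    b <- 30
    for (ang in seq(0, pi, length.out = 7)) {
      e <- elongation(gen_ellipse_mask(ratio * b, b, ang, 201))
      expect_equal(e, ratio, tolerance = 0.02 * ratio)
    }
  }
})

test_that("elongation is translation invariant and guards degeneracy", {
  m <- gen_ellipse_mask(30, 15, 0.4, 101)
  shifted <- matrix(FALSE, 141, 141)
  shifted[30 + seq_len(101) - 1, 10 + seq_len(101) - 1] <- m
  expect_equal(elongation(shifted), elongation(m))
  # single row: no planar extent
  row_mask <- matrix(FALSE, 20, 120)
  row_mask[10, 11:110] <- TRUE
  expect_error(elongation(row_mask), class = "tm_degenerate_mask")
  expect_error(elongation(matrix(FALSE, 5, 5)), class = "tm_parameter_error")
})
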