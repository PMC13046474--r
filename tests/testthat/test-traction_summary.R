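test_that("uniform fields lose nothing to the neighbour filter", {
  fld <- gen_displacement_frames(nx = 5, ny = 5, nz = 3, amplitude = 2e-6,
                                 decay_length = 1, seed = 1)
  fr <- fld$frames[fld$frames$frame == 0, ]
  res <- filter_neighbor_outliers(fr)
  expect_identical(nrow(res$removed), 0L)
})

test_that("the 40 % neighbour rule removes a 1.5x planted outlier, strictly", {
  fld <- gen_displacement_frames(outlier_idx = 77, outlier_multiplier = 1.5,
                                 seed = 2)
  fr <- fld$frames[fld$frames$frame == 0, ]
  res <- filter_neighbor_outliers(fr, factor = 0.4)
  expect_identical(res$removed_idx, 77L)  # 1.5 > 1.4
  # a vector at exactly 1.4x its neighbours is retained
  u <- matrix(0, 5, 3); u[, 1] <- c(1, 1, 1.4, 1, 1) * 1e-6
  fr2 <- make_frame(u)
  expect_identical(nrow(filter_neighbor_outliers(fr2, 0.4)$removed), 0L)
  # but 1.41x is removed
  u[3, 1] <- 1.41e-6
  expect_identical(filter_neighbor_outliers(make_frame(u), 0.4)$removed_idx,
                   3L)
  expect_error(filter_neighbor_outliers(fr, factor = -1),
               class = "tm_parameter_error")
})

test_that("z-score filter removes only gross magnitude outliers", {
  set.seed(3)
  x <- rnorm(1000, 10, 1)
  x[500] <- mean(x) + 8 * sd(x)
  res <- zscore_filter(x, z_max = 4)
  expect_identical(res$removed_idx, 500L)
  # all |z| <= 4: unchanged
  expect_identical(length(zscore_filter(rnorm(100, 5, 0.1))$removed_idx), 0L)
  # constant magnitudes: sigma = 0 rule, nothing removed
  expect_identical(length(zscore_filter(rep(2, 10))$removed_idx), 0L)
})

test_that("both filters together recover exactly the planted outlier set", {
  planted <- c(11L, 97L, 160L)
  fld <- gen_displacement_frames(outlier_idx = planted,
                                 outlier_multiplier = 2, seed = 6)
  fr <- fld$frames[fld$frames$frame == 0, ]
  r1 <- filter_neighbor_outliers(fr, 0.4)
  expect_identical(r1$removed_idx, planted)
  r2 <- zscore_filter(r1$frame, z_max = 4)
  expect_identical(nrow(r2$removed), 0L)
})

test_that("frame extrema and strain energy match per-node arithmetic", {
  u <- matrix(c(3e-6, 4e-6, 0), 1, 3)
  f <- matrix(c(1e-9, 0, 0), 1, 3)
  fr <- make_frame(u, f = f)
  ex <- frame_extrema(fr)
  expect_equal(ex$max_displacement_m, 5e-6)
  expect_equal(ex$max_force_n, 1e-9)
  # parallel unit case: U = 0.5 * 1 nN * 1 um = 0.5 fJ
  fr2 <- make_frame(matrix(c(1e-6, 0, 0), 1, 3),
                    f = matrix(c(1e-9, 0, 0), 1, 3))
  expect_equal(strain_energy(fr2), 0.5e-15)
  # orthogonal vectors contribute nothing
  fr3 <- make_frame(matrix(c(1e-6, 0, 0), 1, 3),
                    f = matrix(c(0, 1e-9, 0), 1, 3))
  expect_equal(strain_energy(fr3), 0)
  expect_error(strain_energy(make_frame(u)), class = "tm_parameter_error")
  expect_error(frame_extrema(fr[0, ]), class = "tm_parameter_error")
})

test_that("strain energy equals a brute-force per-node oracle", {
  fld <- gen_displacement_frames(seed = 8)
  fr <- fld$frames[fld$frames$frame == 1, ]
  u_brute <- 0
  for (i in seq_len(nrow(fr))) {
    u_brute <- u_brute + 0.5 * (fr$fx_n[i] * fr$ux_m[i] +
                                  fr$fy_n[i] * fr$uy_m[i] +
                                  fr$fz_n[i] * fr$uz_m[i])
  }
  expect_equal(strain_energy(fr), u_brute, tolerance = 1e-12)
  # quadratic scaling under u, f -> lambda u, lambda f
  fr2 <- fr
  for (cn in c("ux_m", "uy_m", "uz_m", "fx_n", "fy_n", "fz_n")) {
    fr2[[cn]] <- 3 * fr2[[cn]]
  }
  expect_equal(strain_energy(fr2), 9 * strain_energy(fr), tolerance = 1e-12)
})

test_that("summaries are invariant under rigid rotation", {
  fld <- gen_displacement_frames(seed = 9)
  fr <- fld$frames[fld$frames$frame == 0, ]
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- function(df, cols) {
    m <- as.matrix(df[, cols]) %*% t(R)
    df[, cols] <- m
    df
  }
  fr_rot <- rot(rot(rot(fr, c("x_m", "y_m", "z_m")),
                    c("ux_m", "uy_m", "uz_m")), c("fx_n", "fy_n", "fz_n"))
  expect_equal(frame_extrema(fr_rot), frame_extrema(fr), tolerance = 1e-12)
  expect_equal(strain_energy(fr_rot), strain_energy(fr), tolerance = 1e-12)
})

test_that("explant summaries take across-frame medians", {
  frames <- lapply(1:3, function(i) {
    make_frame(matrix(c(i * 1e-6, 0, 0), 1, 3),
               f = matrix(c(c(10, 13, 20)[i] * 1e-9, 0, 0), 1, 3))
  })
  # single-node frames cannot pass the neighbour filter; skip filters
  s <- explant_summary(frames, neighbor_factor = NULL, z_max = NULL)
  expect_equal(s$median$max_force_n, 13e-9)
  expect_equal(s$median$max_displacement_m, 2e-6)
  # single frame: the median is that frame's value
  s1 <- explant_summary(frames[1], neighbor_factor = NULL, z_max = NULL)
  expect_equal(s1$median$max_force_n, 10e-9)
})

test_that("full summary pipeline is stable on generated multi-frame fields", {
  fld <- gen_displacement_frames(outlier_idx = c(40, 120),
                                 outlier_multiplier = 3, seed = 10)
  s <- explant_summary(fld$frames)
  expect_identical(nrow(s$per_frame), 3L)
  expect_true(all(s$per_frame$strain_energy_j >= 0))
  # outliers were filtered in every frame: the reported max is the smooth max
  clean <- gen_displacement_frames(seed = 10)
  s0 <- explant_summary(clean$frames)
  expect_equal(s$median$max_displacement_m, s0$median$max_displacement_m,
               tolerance = 1e-10)
})

test_that("trilinear interpolation reproduces values at original nodes", {
  fld <- gen_displacement_frames(nx = 4, ny = 4, nz = 3, spacing = 2e-5,
                                 seed = 3)
  fr <- fld$frames[fld$frames$frame == 0, ]
  fine <- interpolate_field(fr, element_size = 1e-5)
  merged <- dplyr::inner_join(fr, fine, by = c("x_m", "y_m", "z_m"),
                              suffix = c("", ".i"))
  expect_equal(merged$ux_m.i, merged$ux_m, tolerance = 1e-10)
  expect_gt(nrow(fine), nrow(fr))
})
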