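test_that("baseline fit recovers slope and offset of clean curves", {
  fc0 <- gen_hertz_curve(K_true = 432)
  bl0 <- fit_baseline(fc0)
  expect_lt(abs(bl0$slope), 1e-18 / 1e-6)  # N/m on a zero-baseline curve
  expect_lt(abs(bl0$offset), 1e-18)
  fc <- gen_hertz_curve(K_true = 432, baseline_slope = 5e-6,
                        baseline_offset = 2e-10)
  bl <- fit_baseline(fc)
  expect_equal(bl$slope, 5e-6, tolerance = 0.01)
  expect_equal(bl$offset, 2e-10, tolerance = 0.01)
  expect_true(bl$qc_pass)
})

test_that("noisy baselines beyond the residual threshold fail QC", {
  fc <- tissuemech:::.gen_noise_curve(seed = 1)
  bl <- fit_baseline(fc)
  expect_false(bl$qc_pass)
  expect_identical(bl$qc_reason, "baseline_unfittable")
})

test_that("contact detection lands within one sample of the true contact", {
  fc <- gen_hertz_curve(K_true = 432)
  bl <- fit_baseline(fc)
  cp <- find_contact_point(fc, bl)
  step <- 5e-6 / 1000
  expect_true(cp$qc_pass)
  expect_lt(abs(cp$z_c - 2e-6), 1.5 * step)
})

test_that("flat and spike-only curves give no_contact", {
  flat <- force_curve(
    data.frame(time_s = (0:199) / 1000, height_m = (0:199) * 5e-9,
               force_n = 0, segment = "extend"), 0.03, 1e-5, setpoint = 1e-8)
  bl <- fit_baseline(flat)
  expect_identical(find_contact_point(flat, bl)$qc_reason, "no_contact")
  # a single-sample spike must not count as sustained contact
  spike <- flat
  spike$force_n[150] <- 5e-9
  bls <- fit_baseline(spike)
  expect_identical(find_contact_point(spike, bls)$qc_reason, "no_contact")
})

test_that("tip-sample separation follows delta = (z - z_c) - F/k_c", {
  fc <- force_curve(
    data.frame(time_s = 0:2 / 1000, height_m = c(0, 1e-6, 2e-6),
               force_n = c(0, 0, 10e-9), segment = "extend"), 0.03, 1e-5)
  d <- tip_sample_separation(fc, z_c = 0, k_c = 0.03)
  expect_equal(d[2], 1e-6)                       # F = 0 -> z - z_c
  expect_equal(d[3], 2e-6 - 10e-9 / 0.03)        # ~1.667 um
  expect_equal(d[3], 1.667e-6, tolerance = 1e-3)
  expect_error(tip_sample_separation(fc, 0, k_c = -1),
               class = "tm_parameter_error")
  # monotone non-decreasing on a noiseless extend
  fc2 <- gen_hertz_curve(K_true = 300)
  d2 <- tip_sample_separation(fc2, z_c = 2e-6)
  expect_true(all(diff(d2) > -1e-15))
})

test_that("Hertz fits match a brute-force grid-search oracle", {
  fc <- gen_hertz_curve(K_true = 327)
  K_grid <- seq(250, 400, by = 0.5)
  K_oracle <- oracle_hertz_grid(fc, z_c = 2e-6, K_grid)
  fit <- fit_hertz(fc)
  expect_lt(abs(fit$K - K_oracle), 0.5)  # within one grid step
})

test_that("noiseless curves at the study moduli are recovered to 1e-4", {
  for (K in c(432, 231)) {
    fit <- fit_hertz(gen_hertz_curve(K_true = K))
    expect_true(fit$qc_pass)
    expect_lt(abs(fit$K - K) / K, 1e-4)
  }
})

test_that("pure-noise indentation data fail Hertz QC with one reason", {
  fc <- tissuemech:::.gen_noise_curve(seed = 2)
  fit <- fit_hertz(fc)
  expect_false(fit$qc_pass)
  expect_true(fit$qc_reason %in%
                c("baseline_unfittable", "no_contact", "poor_hertz_fit"))
})

test_that("every curve is classified exactly once (QC conservation)", {
  curves <- c(
    lapply(c(100, 432, 900), function(K) gen_hertz_curve(K_true = K)),
    lapply(1:3, function(s) tissuemech:::.gen_noise_curve(seed = s))
  )
  fits <- lapply(curves, fit_hertz)
  for (f in fits) {
    if (f$qc_pass) expect_identical(f$qc_reason, "pass")
    else expect_true(f$qc_reason %in%
                       c("baseline_unfittable", "no_contact",
                         "poor_hertz_fit"))
  }
})

test_that("recovered K is centred on truth under force noise", {
  n <- 60
  Ks <- vapply(seq_len(n), function(s) {
    fit_hertz(gen_hertz_curve(K_true = 350, noise_sd = 0.2e-9, seed = s))$K
  }, numeric(1))
  expect_lt(abs(median(Ks) - 350) / 350, 0.03)
  # sign test: recovered values scatter on both sides of truth
  n_above <- sum(Ks > 350)
  p_sign <- 2 * stats::pbinom(min(n_above, n - n_above), n, 0.5)
  expect_gt(p_sign, 0.01)
})

test_that("setpoint-deviation QC follows the strict 10 % rule", {
  base <- fit_hertz(gen_hertz_curve(K_true = 300, max_force = 2e-9,
                                    spring_constant = 0.06),
                    analysis_force = 2e-9)
  expect_true(base$qc_pass)
  f1 <- base; f1$F_max <- 2.3e-9
  expect_identical(apply_setpoint_qc(f1, 2e-9)$qc_reason,
                   "setpoint_deviation")  # 15 % > 10 %
  f2 <- base; f2$F_max <- 2.1e-9
  expect_true(apply_setpoint_qc(f2, 2e-9)$qc_pass)  # 5 %
  f3 <- base; f3$F_max <- 2.2e-9
  expect_true(apply_setpoint_qc(f3, 2e-9)$qc_pass)  # exactly 10 %: retained
  expect_error(apply_setpoint_qc(base, -1), class = "tm_parameter_error")
})

test_that("linear stiffness fit recovers an exact line to machine precision", {
  k_true <- 0.02; c_true <- 1e-10
  z <- seq(0, 5e-6, length.out = 200)
  f <- k_true * z + c_true
  # construct so that d = height - F/k_c equals z: height = z + F/k_c
  fc <- force_curve(
    data.frame(time_s = seq_along(z) / 1000, height_m = z + f / 0.03,
               force_n = f, segment = "extend"), 0.03, 1e-5)
  fit <- fit_linear_stiffness(fc, range(f))
  expect_equal(fit$k, k_true, tolerance = 1e-10)
  expect_equal(fit$c, c_true, tolerance = 1e-6)
})

test_that("window placement and modulus scaling behave as Hertz predicts", {
  fc <- gen_hertz_curve(K_true = 432, max_force = 30e-9)
  k_low <- fit_linear_stiffness(fc, c(2e-9, 10e-9))$k
  k_high <- fit_linear_stiffness(fc, c(22e-9, 30e-9))$k
  expect_lt(k_low, k_high)  # delta^(3/2) convexity
  # at a matched force window, Hertz contact predicts k ~ K^(2/3): the
  # local slope dF/dd = 2 K sqrt(R) delta^(1/2) evaluated at fixed force
  # gives K * (F/K)^(1/3); a doubling of K raises k by 2^(2/3)
  fc2 <- gen_hertz_curve(K_true = 864, max_force = 30e-9)
  k2 <- fit_linear_stiffness(fc2, c(2e-9, 10e-9))$k
  expect_equal(k2 / k_low, 2^(2 / 3), tolerance = 0.05)
  expect_error(fit_linear_stiffness(fc, c(2e-9, 2.01e-9)),
               class = "tm_window_error")
})

test_that("MAD outlier exclusion removes gross single-cell outliers only", {
  x <- c(seq(190, 210, length.out = 30), 2000)
  res <- exclude_outliers_mad(x)
  expect_identical(res$excluded, 2000)
  expect_identical(length(res$kept), 30L)
  # constant vectors are left untouched
  expect_identical(exclude_outliers_mad(rep(5, 4))$kept, rep(5, 4))
})
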