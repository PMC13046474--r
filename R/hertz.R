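# Per-curve Hertz analysis: baseline, contact point, indentation, modulus fit,
# quality control. QC is conservative and exhaustive: every curve is classified
# exactly once, either `pass` or with a single failure reason
# (`baseline_unfittable`, `no_contact`, `poor_hertz_fit`, `setpoint_deviation`).

#' Fit the pre-contact baseline of a force curve
#'
#' Ordinary least squares line through the leading fraction of the extend
#' segment. The residual standard deviation is reported for use in contact
#' detection and baseline quality control: a baseline whose residual spread
#' exceeds `max_residual_fraction` of the setpoint is flagged unfittable,
#' mirroring the exclusion of curves whose baseline region cannot be fit.
#'
#' @param curve A [force_curve()].
#' @param window_fraction Leading fraction of the extend segment to fit
#'   (default 0.3).
#' @param max_residual_fraction Baseline residual threshold as a fraction of
#'   the setpoint (default 0.15).
#' @return A list: `slope` (N/m), `offset` (N), `residual_sd` (N),
#'   `qc_pass`, `qc_reason`.
#' @export
fit_baseline <- function(curve, window_fraction = 0.3,
                         max_residual_fraction = 0.15) {
  ext <- curve_segment(curve, "extend")
  n <- max(20L, floor(nrow(ext) * window_fraction))
  if (nrow(ext) < 20 || n > nrow(ext)) {
    return(list(slope = NA_real_, offset = NA_real_, residual_sd = NA_real_,
                qc_pass = FALSE, qc_reason = "baseline_unfittable"))
  }
  z <- ext$height_m[1:n]
  f <- ext$force_n[1:n]
  zm <- mean(z); fm <- mean(f)
  slope <- sum((z - zm) * (f - fm)) / sum((z - zm)^2)
  offset <- fm - slope * zm
  res <- f - (offset + slope * z)
  residual_sd <- sqrt(sum(res^2) / max(n - 2, 1))
  setp <- curve_meta(curve)$setpoint
  ok <- TRUE
  if (is.finite(setp) && residual_sd > max_residual_fraction * setp) ok <- FALSE
  list(slope = slope, offset = offset, residual_sd = residual_sd,
       qc_pass = ok, qc_reason = if (ok) "pass" else "baseline_unfittable")
}

#' Locate the tip-sample contact point
#'
#' The contact point is the height at the start of the first run of at least
#' `min_run` consecutive samples whose baseline-subtracted force exceeds
#' `noise_mult` times the baseline residual spread. Expressing the threshold
#' in noise units lets the same rule serve setpoints from 500 pN to 10 nN;
#' requiring a sustained run rejects single-sample spikes.
#'
#' @param curve A [force_curve()].
#' @param baseline Result of [fit_baseline()].
#' @param noise_mult Detection threshold in units of baseline residual sd.
#' @param min_run Minimum consecutive above-threshold samples.
#' @return A list: `z_c` (m), `index` (sample index within extend),
#'   `qc_pass`, `qc_reason` (`no_contact` when no sustained crossing exists).
#' @export
find_contact_point <- function(curve, baseline, noise_mult = 3,
                               min_run = 10) {
  ext <- curve_segment(curve, "extend")
  if (!isTRUE(baseline$qc_pass)) {
    return(list(z_c = NA_real_, index = NA_integer_, qc_pass = FALSE,
                qc_reason = "no_contact"))
  }
  fs <- ext$force_n - (baseline$offset + baseline$slope * ext$height_m)
  thr <- noise_mult * baseline$residual_sd
  above <- fs > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  # sustained crossing: run of TRUE of length >= min_run reaching curve end,
  # or simply the first long-enough run
  cand <- which(r$values & r$lengths >= min_run)
  if (length(cand) == 0) {
    return(list(z_c = NA_real_, index = NA_integer_, qc_pass = FALSE,
                qc_reason = "no_contact"))
  }
  i <- starts[cand[1]]
  list(z_c = ext$height_m[i], index = i, qc_pass = TRUE, qc_reason = "pass")
}

#' Tip-sample separation (indentation) series
#'
#' Converts piezo height to indentation depth by subtracting the cantilever
#' deflection: \eqn{\delta = (z - z_c) - F / k_c}. Pre-contact samples give
#' \eqn{\delta \le 0}.
#'
#' @param curve A [force_curve()].
#' @param z_c Contact height (m).
#' @param k_c Cantilever spring constant (N/m), > 0; defaults to the curve's
#'   metadata.
#' @param baseline Optional [fit_baseline()] result; when given, the baseline
#'   is subtracted from the force before computing deflection.
#' @return Numeric vector of indentation depths (m), one per sample.
#' @export
tip_sample_separation <- function(curve, z_c, k_c = NULL, baseline = NULL) {
  if (is.null(k_c)) k_c <- curve_meta(curve)$spring_constant
  if (!is.numeric(k_c) || k_c <= 0) {
    stop_tm("k_c must be > 0", "tm_parameter_error")
  }
  f <- curve$force_n
  if (!is.null(baseline)) {
    f <- f - (baseline$offset + baseline$slope * curve$height_m)
  }
  (curve$height_m - z_c) - f / k_c
}

# Closed-form K for fixed z_c over a fixed sample set; returns K and SSE.
.hertz_ls <- function(z, f, z_c, k_c, R) {
  delta <- (z - z_c) - f / k_c
  ok <- delta > 0
  if (sum(ok) < 5) return(list(K = NA_real_, sse = Inf, n = sum(ok)))
  d32 <- delta[ok]^1.5
  ff <- f[ok]
  a <- (4 / 3) * sqrt(R)
  K <- sum(ff * d32) / (a * sum(d32^2))
  sse <- sum((ff - a * K * d32)^2)
  list(K = K, sse = sse, n = sum(ok), delta = delta)
}

#' Fit the Hertz spherical-contact model to a force curve
#'
#' Full per-curve pipeline: baseline fit, contact detection, then a
#' least-squares fit of \eqn{F = (4/3) K \sqrt{R}\,\delta^{3/2}} over the
#' baseline-subtracted post-contact extend data up to the analysis force.
#' The contact point is refined as a free nuisance parameter (bounded within
#' `refine_halfwidth` of the detected crossing); for each candidate contact
#' the optimal modulus has a closed form, so the refinement is a 1-D bounded
#' minimization of the residual sum of squares.
#'
#' @param curve A [force_curve()].
#' @param bead_radius Probe radius R (m); defaults to curve metadata.
#' @param analysis_force Fit data up to the first crossing of this force (N);
#'   default 10 nN.
#' @param refine_halfwidth Contact-point refinement half width (m).
#' @param window_fraction Passed to [fit_baseline()].
#' @param r2_min,rmse_max_fraction Fit-quality thresholds: the fit fails QC
#'   (`poor_hertz_fit`) when r-squared falls below `r2_min` or the residual
#'   rmse exceeds `rmse_max_fraction` of the maximum analysed force.
#' @return An object of class `hertz_fit`: `K` (Pa), `z_c` (m), baseline
#'   `slope`/`offset`, `delta_max` (m), `F_max` (N), `rmse` (N),
#'   `r_squared`, `n_points`, `qc_pass`, `qc_reason`.
#' @export
#' @examples
#' fc <- gen_hertz_curve(K_true = 432, seed = 7)
#' fit <- fit_hertz(fc)
#' fit$K
fit_hertz <- function(curve, bead_radius = NULL, analysis_force = 10e-9,
                      refine_halfwidth = 0.5e-6, window_fraction = 0.3,
                      r2_min = 0.85, rmse_max_fraction = 0.10) {
  meta <- curve_meta(curve)
  if (is.null(bead_radius)) bead_radius <- meta$bead_radius
  if (!is.numeric(bead_radius) || bead_radius <= 0) {
    stop_tm("bead_radius must be > 0", "tm_parameter_error")
  }
  k_c <- meta$spring_constant
  ext <- curve_segment(curve, "extend")
  F_max_raw <- if (nrow(ext) > 0) max(ext$force_n) else NA_real_

  fail <- function(reason, bl = NULL, z_c = NA_real_) {
    structure(list(K = NA_real_, z_c = z_c,
                   slope = if (is.null(bl)) NA_real_ else bl$slope,
                   offset = if (is.null(bl)) NA_real_ else bl$offset,
                   delta_max = NA_real_, F_max = F_max_raw,
                   rmse = NA_real_, r_squared = NA_real_,
                   n_points = 0L, qc_pass = FALSE, qc_reason = reason,
                   bead_radius = bead_radius, analysis_force = analysis_force),
              class = "hertz_fit")
  }

  bl <- fit_baseline(curve, window_fraction = window_fraction)
  if (!bl$qc_pass) return(fail("baseline_unfittable"))
  cp <- find_contact_point(curve, bl)
  if (!cp$qc_pass) return(fail("no_contact", bl))

  f <- ext$force_n - (bl$offset + bl$slope * ext$height_m)
  z <- ext$height_m
  # analysed data: post-detection samples up to first crossing of the
  # analysis force
  cross <- which(f >= analysis_force)
  last <- if (length(cross) > 0) cross[1] else nrow(ext)
  idx <- cp$index:last
  if (length(idx) < 5) return(fail("poor_hertz_fit", bl, cp$z_c))
  zz <- z[idx]; ff <- f[idx]

  sse_of <- function(zc) .hertz_ls(zz, ff, zc, k_c, bead_radius)$sse
  # the detected crossing sits where the force first clears the noise
  # threshold, i.e. deeper than the true contact by roughly the indentation
  # at threshold force; widen the downhill side of the refinement window by
  # a first-pass estimate of that offset
  K1 <- .hertz_ls(zz, ff, cp$z_c, k_c, bead_radius)$K
  thr <- 3 * bl$residual_sd
  det_offset <- if (is.finite(K1) && K1 > 0 && thr > 0) {
    (3 * thr / (4 * K1 * sqrt(bead_radius)))^(2 / 3)
  } else 0
  lo <- cp$z_c - max(refine_halfwidth, 3 * det_offset)
  hi <- cp$z_c + refine_halfwidth
  opt <- optimize(sse_of, c(lo, hi), tol = 1e-13)
  z_c <- opt$minimum
  ls <- .hertz_ls(zz, ff, z_c, k_c, bead_radius)
  if (!is.finite(ls$K) || ls$K <= 0) return(fail("poor_hertz_fit", bl, z_c))

  # final polish in the height domain: model the measured force as the
  # implicit Hertz + deflection response of piezo height, so measurement
  # noise sits purely in the ordinate (the indentation-domain fit has the
  # force noise on both axes through the deflection term, which biases K)
  fwd_sse <- function(p) {
    K <- p[1]; zc <- p[2]
    if (K <= 0) return(Inf)
    s <- zz - zc
    fm <- numeric(length(s))
    pos <- s > 0
    if (any(pos)) {
      d <- .solve_indentation(s[pos], K, bead_radius, k_c, iters = 40)
      fm[pos] <- .hertz_force(K, bead_radius, d)
    }
    sum((ff - fm)^2)
  }
  pol <- optim(c(ls$K, z_c), fwd_sse, method = "Nelder-Mead",
               control = list(maxit = 150, reltol = 1e-12,
                              parscale = c(max(ls$K, 1), 1e-7)))
  if (is.finite(pol$value) && pol$value <= fwd_sse(c(ls$K, z_c))) {
    z_c <- pol$par[2]
    ls <- .hertz_ls(zz, ff, z_c, k_c, bead_radius)
    ls$K <- pol$par[1]
    a <- (4 / 3) * sqrt(bead_radius)
    ls$sse <- sum((ff[ls$delta > 0] - a * ls$K * ls$delta[ls$delta > 0]^1.5)^2)
  }
  if (!is.finite(ls$K) || ls$K <= 0) return(fail("poor_hertz_fit", bl, z_c))

  F_fit_max <- max(ff)
  rmse <- sqrt(ls$sse / ls$n)
  ss_tot <- sum((ff[ls$delta > 0] - mean(ff[ls$delta > 0]))^2)
  r2 <- if (ss_tot > 0) 1 - ls$sse / ss_tot else NA_real_
  qc_ok <- is.finite(r2) && r2 >= r2_min && rmse <= rmse_max_fraction * F_fit_max
  structure(list(K = ls$K, z_c = z_c, slope = bl$slope, offset = bl$offset,
                 delta_max = max(ls$delta), F_max = F_max_raw,
                 rmse = rmse, r_squared = r2, n_points = ls$n,
                 qc_pass = qc_ok,
                 qc_reason = if (qc_ok) "pass" else "poor_hertz_fit",
                 bead_radius = bead_radius, analysis_force = analysis_force),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  if (x$qc_pass) {
    cat(sprintf("<hertz_fit> K = %.4g Pa (r2 = %.4f, rmse = %.3g nN, n = %d)\n",
                x$K, x$r_squared, x$rmse * 1e9, x$n_points))
  } else {
    cat(sprintf("<hertz_fit> QC fail: %s\n", x$qc_reason))
  }
  invisible(x)
}

#' Setpoint-deviation quality control
#'
#' Excludes a fit when its maximum applied force deviates from the nominal
#' setpoint by more than `tolerance_fraction` (strictly greater; exactly the
#' tolerance is retained). Used for skin measurements with a 2 nN setpoint
#' and 10 % tolerance.
#'
#' @param fit A `hertz_fit`.
#' @param setpoint Nominal setpoint (N), > 0.
#' @param tolerance_fraction Allowed relative deviation (default 0.10).
#' @return The fit, with `qc_pass`/`qc_reason` updated (`setpoint_deviation`)
#'   when excluded.
#' @export
apply_setpoint_qc <- function(fit, setpoint, tolerance_fraction = 0.10) {
  if (!is.numeric(setpoint) || setpoint <= 0) {
    stop_tm("setpoint must be > 0", "tm_parameter_error")
  }
  if (!isTRUE(fit$qc_pass)) return(fit)
  dev <- abs(fit$F_max - setpoint) / setpoint
  if (is.finite(dev) && dev > tolerance_fraction) {
    fit$qc_pass <- FALSE
    fit$qc_reason <- "setpoint_deviation"
  }
  fit
}

#' Linear stiffness fit over a force window
#'
#' Fits \eqn{F = k d + c} by ordinary least squares over the extend-segment
#' samples whose force lies inside `force_window`, where `d` is the
#' tip-sample distance (height minus cantilever deflection). Used where a
#' baseline for a Hertz fit is unavailable; the stiffness `k` scales
#' linearly with the apparent elastic modulus over a wide parameter range.
#'
#' @param curve A [force_curve()].
#' @param force_window Numeric length-2: lower and upper force bounds (N).
#' @param min_points Minimum samples required in the window (default 10).
#' @return An object of class `linear_stiffness_fit`: `k` (N/m), `c` (N),
#'   `force_window`, `n_points`, `rmse` (N).
#' @export
fit_linear_stiffness <- function(curve, force_window, min_points = 10) {
  if (length(force_window) != 2 || force_window[1] >= force_window[2]) {
    stop_tm("force_window must be (lower, upper) with lower < upper",
            "tm_parameter_error")
  }
  ext <- curve_segment(curve, "extend")
  k_c <- curve_meta(curve)$spring_constant
  inw <- ext$force_n >= force_window[1] & ext$force_n <= force_window[2]
  if (sum(inw) < min_points) {
    stop_tm("window_too_sparse: too few samples in force window",
            "tm_window_error")
  }
  d <- ext$height_m[inw] - ext$force_n[inw] / k_c
  f <- ext$force_n[inw]
  dm <- mean(d); fm <- mean(f)
  k <- sum((d - dm) * (f - fm)) / sum((d - dm)^2)
  c0 <- fm - k * dm
  res <- f - (k * d + c0)
  structure(list(k = k, c = c0, force_window = force_window,
                 n_points = sum(inw),
                 rmse = sqrt(mean(res^2))),
            class = "linear_stiffness_fit")
}

#' Median +/- MAD outlier exclusion
#'
#' Excludes values further than `k` median absolute deviations (scaled to be
#' consistent with the normal sd) from the median. This is the package's
#' outlier rule for single-cell modulus values; it replaces proprietary
#' regression-based outlier identification and is deliberately simple and
#' reproducible.
#'
#' @param x Numeric vector.
#' @param k Exclusion threshold in MAD units (default 3).
#' @return A list: `kept` (values), `excluded` (values), `keep` (logical).
#' @export
exclude_outliers_mad <- function(x, k = 3) {
  med <- median(x)
  m <- mad(x)
  keep <- if (m == 0) rep(TRUE, length(x)) else abs(x - med) <= k * m
  list(kept = x[keep], excluded = x[!keep], keep = keep)
}
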