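# Ramp-corrected standard-linear-solid (SLS) creep under a Hertzian contact.
#
# The model: a force ramp of shape parameter alpha (1 < alpha < 2) reaching
# the clamp force F_c after Delta t_a, followed by a force hold. During the
# hold the indentation is
#
#   delta(t) = [ (3/4) (F_c/sqrt(r)) alpha^(1-alpha) Dt_a^(alpha-1)
#                ( C0 + (C0 - C1) e^(-t C2) M(alpha, alpha+1, Dt_a C2) ) ]^(2/3)
#
# with C0 = 1/(k_l + k_a), C1 = 1/k_l, C2 = k_l k_a / (eta (k_l + k_a)) and
# M the confluent hypergeometric (Kummer) function: the three-argument
# hypergeometric factor arises analytically from the ramp convolution
# integral a * int_0^1 u^(a-1) e^(z u) du = M(a, a+1, z).

#' Confluent hypergeometric function M(a, b, z) (Kummer series)
#'
#' Power-series evaluation of \eqn{M(a,b,z) = \sum_n (a)_n z^n / ((b)_n n!)},
#' adequate for the moderate positive arguments arising in the ramp
#' correction (`z = ramp_time * C2`).
#'
#' @param a,b Parameters (`b` must not be a non-positive integer).
#' @param z Argument (vectorized); must satisfy `z < 700` to avoid overflow.
#' @return M(a, b, z), same length as `z`.
#' @export
kummer_m <- function(a, b, z) {
  if (any(z >= 700)) stop_tm("kummer_m argument too large", "tm_domain_error")
  vapply(z, function(zz) {
    term <- 1
    total <- 1
    for (n in 1:2000) {
      term <- term * (a + n - 1) / (b + n - 1) * zz / n
      total <- total + term
      if (abs(term) < 1e-16 * abs(total)) break
    }
    total
  }, numeric(1))
}

#' Standard-linear-solid creep coefficients
#'
#' Maps the model's two spring constants and viscosity to the creep
#' coefficients \eqn{C_0 = 1/(k_l + k_a)}, \eqn{C_1 = 1/k_l} and
#' \eqn{C_2 = k_l k_a / (\eta (k_l + k_a))} (an inverse retardation time).
#'
#' @param k_l,k_a Spring constants (model units, > 0).
#' @param eta Viscosity (model units, > 0).
#' @return A list `(C0, C1, C2)` with `C0 < C1` and `C2 > 0`.
#' @export
#' @examples
#' sls_coefficients(1, 1, 1)  # C0 = 0.5, C1 = 1, C2 = 0.5
sls_coefficients <- function(k_l, k_a, eta) {
  if (any(c(k_l, k_a, eta) <= 0)) {
    stop_tm("k_l, k_a, eta must be > 0", "tm_parameter_error")
  }
  list(C0 = 1 / (k_l + k_a),
       C1 = 1 / k_l,
       C2 = k_l * k_a / (eta * (k_l + k_a)))
}

# Closed form on the coefficient scale; t vectorized.
.sls_delta_coef <- function(t, C0, C1, C2, alpha, F_c, ramp_time, r) {
  z <- ramp_time * C2
  pref <- (3 / 4) * (F_c / sqrt(r)) * alpha^(1 - alpha) * ramp_time^(alpha - 1)
  bracket <- C0 + (C0 - C1) * exp(-t * C2) * kummer_m(alpha, alpha + 1, z)
  inner <- pref * bracket
  if (any(inner <= 0)) {
    stop_tm("SLS bracket non-positive: unphysical parameters for this t",
            "tm_domain_error")
  }
  inner^(2 / 3)
}

#' Ramp-corrected SLS creep indentation
#'
#' Evaluates the closed-form indentation \eqn{\delta(t)} of the
#' standard-linear-solid model under a finite force ramp followed by a force
#' hold (see the package vignette for the full expression). `t` is measured
#' from the start of the hold.
#'
#' @param t Time(s) since hold start (s), >= 0; vectorized.
#' @param k_l,k_a,eta SLS parameters (model units, > 0).
#' @param alpha Ramp-shape parameter in (1, 2).
#' @param clamp_force Clamp force F_c (N).
#' @param ramp_time Ramp duration \eqn{\Delta t_a} (s).
#' @param indenter_radius Probe radius r (m).
#' @param coefficients Optional override `list(C0, C1, C2)` bypassing
#'   `k_l`, `k_a`, `eta` (e.g. to construct the elastic limit `C0 == C1`).
#' @return Indentation depth(s) \eqn{\delta(t)} (model length units).
#' @export
sls_indentation <- function(t, k_l, k_a, eta, alpha = 1.5,
                            clamp_force = 30e-9, ramp_time = 1,
                            indenter_radius = 44.65e-6,
                            coefficients = NULL) {
  if (any(t < 0)) stop_tm("t must be >= 0", "tm_parameter_error")
  if (alpha <= 1 || alpha >= 2) {
    stop_tm("alpha must be in (1, 2)", "tm_parameter_error")
  }
  cf <- if (is.null(coefficients)) sls_coefficients(k_l, k_a, eta)
        else coefficients
  .sls_delta_coef(t, cf$C0, cf$C1, cf$C2, alpha, clamp_force, ramp_time,
                  indenter_radius)
}

#' Fit the ramp-corrected SLS creep model to a force-clamp record
#'
#' The controlled quantities are measured from the curve, not fitted: the
#' clamp force is the mean hold force, the ramp time runs from the detected
#' contact to the hold start, and the ramp-shape parameter `alpha` is the
#' log-log slope of the measured force ramp (on the hold segment alone,
#' `alpha` is structurally degenerate with the compliances: on the
#' \eqn{\delta^{3/2}} scale the model is `B0 + B1 exp(-t C2)` whatever
#' `alpha`, so only the ramp identifies it).
#'
#' The compliances are then fitted in two stages. First the model is
#' profiled on the \eqn{\delta^{3/2}} scale, where `B0` and `B1` are linear
#' for fixed `C2`, reducing the search to one dimension (coarse log grid in
#' `C2` plus golden-section refinement). The resulting `(k_l, k_a, eta)` then
#' seed a bounded Nelder-Mead polish minimizing the sum of squared
#' indentation residuals, with a small free contact offset absorbing the
#' one-sample uncertainty of contact detection. Multi-start fallbacks
#' (log-spaced initial viscosities) cover records the profile stage cannot
#' seed.
#'
#' @param curve A [force_curve()] with `extend` and `hold` segments.
#' @param indenter_radius Probe radius r (m).
#' @param window_s Fit window from hold start (s); default first 3 s.
#' @param n_starts Number of fallback multi-start optimizations.
#' @param baseline_fraction Leading fraction of the extend segment used for
#'   the baseline fit when detecting the contact point.
#' @return An object of class `sls_fit`: fitted parameters, derived
#'   coefficients, `rmse` (m), `n_points`, `window_s`, `converged`,
#'   `eta_identifiable` (FALSE when the exponential amplitude explains
#'   < 1 % of the signal range; `eta` is then reported as `NA`), plus the
#'   fitted series for plotting.
#' @export
fit_sls <- function(curve, indenter_radius = NULL, window_s = 3,
                    n_starts = 5, baseline_fraction = 0.3) {
  hold <- curve_segment(curve, "hold")
  if (nrow(hold) == 0) stop_tm("no hold segment", "tm_parameter_error")
  meta <- curve_meta(curve)
  if (is.null(indenter_radius)) indenter_radius <- meta$bead_radius
  k_c <- meta$spring_constant

  F_c <- mean(hold$force_n)
  bl <- fit_baseline(curve, window_fraction = baseline_fraction)
  if (!bl$qc_pass) stop_tm("baseline unfittable on extend segment",
                           "tm_fit_error")
  cp <- find_contact_point(curve, bl)
  if (!cp$qc_pass) stop_tm("no contact detected on extend segment",
                           "tm_fit_error")
  ext <- curve_segment(curve, "extend")
  # contact lies between the last below-threshold sample and the detected
  # crossing; take the midpoint convention of one sample step back
  i_det <- which(ext$height_m >= cp$z_c)[1]
  dt_s <- median(diff(ext$time_s))
  t_contact <- ext$time_s[i_det] - dt_s
  ramp_time <- hold$time_s[1] - t_contact
  if (!is.finite(ramp_time) || ramp_time <= 0) {
    stop_tm("could not measure ramp time", "tm_fit_error")
  }

  t <- hold$time_s - hold$time_s[1]
  keep <- t <= window_s
  if (sum(keep) < 8) stop_tm("fit window empty", "tm_parameter_error")
  t <- t[keep]
  bforce <- bl$offset + bl$slope * hold$height_m[keep]
  delta <- (hold$height_m[keep] - cp$z_c) -
    (hold$force_n[keep] - bforce) / k_c

  # alpha from the measured force ramp: log-log slope of F(t) over the ramp
  ramp_idx <- which(ext$time_s >= t_contact)
  tf <- ext$time_s[ramp_idx] - t_contact
  ff <- ext$force_n[ramp_idx] -
    (bl$offset + bl$slope * ext$height_m[ramp_idx])
  okr <- tf > 0 & ff > 0.01 * F_c & ff < 0.99 * F_c
  alpha <- if (sum(okr) >= 5) {
    lt <- log(tf[okr] / ramp_time)
    lf <- log(ff[okr] / F_c)
    min(max(sum((lt - mean(lt)) * (lf - mean(lf))) / sum((lt - mean(lt))^2),
            1.001), 1.999)
  } else 1.5

  pref <- (3 / 4) * (F_c / sqrt(indenter_radius)) * alpha^(1 - alpha) *
    ramp_time^(alpha - 1)
  dscale <- max(abs(delta))
  # contact mis-detection can shift the hold indentation by at most a few
  # samples of early-ramp indentation; cap the nuisance offset accordingly
  # so it cannot trade against the creep amplitudes
  i_off <- min(i_det + 3, nrow(ext))
  d_early <- (ext$height_m[i_off] - cp$z_c) -
    (ext$force_n[i_off] - (bl$offset + bl$slope * ext$height_m[i_off])) / k_c
  off_cap <- max(3 * abs(d_early), 1e-6 * dscale) / dscale
  obj <- function(p) {
    # p = log(k_l), log(k_a), log(eta), contact offset / dscale
    # (the offset absorbs the one-sample uncertainty of contact detection,
    # which shifts every hold indentation by a constant)
    if (abs(p[4]) > off_cap || max(p[1:3]) > log(1e3) ||
        min(p[1:3]) < log(1e-5)) {
      return(1e6 * sum(delta^2) + 1)
    }
    cf <- sls_coefficients(exp(p[1]), exp(p[2]), exp(p[3]))
    d <- tryCatch(
      .sls_delta_coef(t, cf$C0, cf$C1, cf$C2, alpha, F_c, ramp_time,
                      indenter_radius),
      error = function(e) NULL)
    if (is.null(d) || any(!is.finite(d))) return(1e6 * sum(delta^2) + 1)
    sum((d - p[4] * dscale - delta)^2)
  }

  # stage 1: profile fit on the delta^(3/2) scale, linear in (B0, B1) for
  # fixed C2
  y <- sign(delta) * abs(delta)^1.5
  e_of <- function(c2) exp(-t * c2)
  prof_sse <- function(c2) {
    X <- cbind(1, e_of(c2))
    b <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(b)) return(Inf)
    sum((y - X %*% b)^2)
  }
  c2_grid <- 10^seq(-3, 3, length.out = 80)
  sses <- vapply(c2_grid, prof_sse, numeric(1))
  i0 <- which.min(sses)
  o <- optimize(function(l) prof_sse(exp(l)),
                interval = c(log(c2_grid[max(1, i0 - 1)]),
                             log(c2_grid[min(length(c2_grid), i0 + 1)])),
                tol = 1e-12)
  C2_hat <- exp(o$minimum)
  Xh <- cbind(1, e_of(C2_hat))
  bh <- qr.solve(Xh, y)
  starts <- list()
  C0_hat <- bh[1] / pref
  M_hat <- kummer_m(alpha, alpha + 1, ramp_time * C2_hat)
  C1_hat <- C0_hat - bh[2] / (pref * M_hat)
  if (is.finite(C0_hat) && is.finite(C1_hat) &&
      C0_hat > 0 && C1_hat > C0_hat) {
    kl0 <- 1 / C1_hat
    ka0 <- 1 / C0_hat - kl0
    eta0 <- kl0 * ka0 / (C2_hat * (kl0 + ka0))
    clamp <- function(x, lo, hi) min(max(x, lo), hi)
    starts <- list(c(log(clamp(kl0, 2e-4, 9)), log(clamp(ka0, 2e-4, 9)),
                     log(clamp(eta0, 2e-4, 900)), 0))
  }
  # fallback multi-starts: long-time compliance sets the spring scale
  pref0 <- (3 / 4) * (F_c / sqrt(indenter_radius))
  Ctot <- max(tail(delta, 3))^(3 / 2) / pref0
  k_sum0 <- 1 / max(Ctot, 1e-8)
  for (eta_i in 10^seq(-2, 2, length.out = n_starts)) {
    starts <- c(starts, list(c(log(min(max(k_sum0 / 2, 2e-4), 9)),
                               log(min(max(k_sum0 / 2, 2e-4), 9)),
                               log(eta_i), 0)))
  }

  lb <- log(1e-4); ub_k <- log(10); ub_eta <- log(1e3)
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B",
            lower = c(lb, lb, lb, -off_cap),
            upper = c(ub_k, ub_k, ub_eta, off_cap),
            control = list(maxit = 500, factr = 1e3)),
      error = function(e) NULL)
    if (is.null(fit)) next
    fit <- tryCatch(
      optim(fit$par, obj, method = "Nelder-Mead",
            control = list(maxit = 4000, reltol = 1e-15)),
      error = function(e) fit)
    if (is.null(best) || fit$value < best$value * (1 - 1e-9) ||
        (abs(fit$value - best$value) <= 1e-9 * best$value &&
         exp(fit$par[3]) < exp(best$par[3]))) {
      best <- fit
    }
    if (best$value <= 1e-24 * sum(y^2)) break
  }
  if (is.null(best)) stop_tm("SLS fit did not converge", "tm_fit_error")

  k_l <- exp(best$par[1]); k_a <- exp(best$par[2]); eta <- exp(best$par[3])
  offset <- best$par[4] * dscale
  cf <- sls_coefficients(k_l, k_a, eta)
  fitted <- .sls_delta_coef(t, cf$C0, cf$C1, cf$C2, alpha, F_c, ramp_time,
                            indenter_radius) - offset
  rmse <- sqrt(mean((fitted - delta)^2))
  # identifiability of eta: does the exponential term move the signal?
  M <- kummer_m(alpha, alpha + 1, ramp_time * cf$C2)
  exp_range <- abs(cf$C0 - cf$C1) * M *
    (exp(-cf$C2 * min(t)) - exp(-cf$C2 * max(t)))
  sig_range <- diff(range(delta^(3 / 2)))
  pref <- (3 / 4) * (F_c / sqrt(indenter_radius)) * alpha^(1 - alpha) *
    ramp_time^(alpha - 1)
  eta_ok <- is.finite(exp_range) &&
    exp_range * pref > 0.01 * max(sig_range, 0.01 * cf$C0 * pref)

  structure(list(
    k_l = k_l, k_a = k_a, eta = if (eta_ok) eta else NA_real_,
    alpha = alpha, C0 = cf$C0, C1 = cf$C1,
    C2 = if (eta_ok) cf$C2 else NA_real_,
    eta_identifiable = eta_ok,
    clamp_force = F_c, ramp_time = ramp_time,
    indenter_radius = indenter_radius,
    contact_offset = offset,
    rmse = rmse, n_points = length(t), window_s = window_s,
    converged = TRUE,
    data = tibble(t_s = t, delta_m = delta, fitted_m = fitted)
  ), class = "sls_fit")
}

#' @export
print.sls_fit <- function(x, ...) {
  cat(sprintf(
    "<sls_fit> k_l = %.4g, k_a = %.4g, eta = %s, alpha = %.3f\n",
    x$k_l, x$k_a,
    if (x$eta_identifiable) sprintf("%.4g", x$eta) else "unidentifiable",
    x$alpha))
  cat(sprintf("  F_c = %.3g nN, ramp %.3g s, rmse = %.3g m over %d points\n",
              x$clamp_force * 1e9, x$ramp_time, x$rmse, x$n_points))
  invisible(x)
}

#' @export
autoplot.sls_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$delta_m * 1e6), alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_m * 1e6),
                       colour = "firebrick") +
    ggplot2::labs(x = "time since hold start (s)",
                  y = expression(paste("indentation (", mu, "m)")))
}
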