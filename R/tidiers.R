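# broom-style tidiers for fitted objects.

#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble(term = c("K", "z_c", "baseline_slope", "baseline_offset"),
         estimate = c(x$K, x$z_c, x$slope, x$offset),
         unit = c("Pa", "m", "N/m", "N"))
}

#' @export
glance.hertz_fit <- function(x, ...) {
  tibble(K_pa = x$K, r_squared = x$r_squared, rmse_n = x$rmse,
         delta_max_m = x$delta_max, F_max_n = x$F_max,
         n_points = x$n_points, qc_pass = x$qc_pass, qc_reason = x$qc_reason)
}

#' @export
tidy.sls_fit <- function(x, ...) {
  tibble(term = c("k_l", "k_a", "eta", "alpha", "C0", "C1", "C2"),
         estimate = c(x$k_l, x$k_a, x$eta, x$alpha, x$C0, x$C1, x$C2))
}

#' @export
glance.sls_fit <- function(x, ...) {
  tibble(rmse_m = x$rmse, n_points = x$n_points, window_s = x$window_s,
         clamp_force_n = x$clamp_force, ramp_time_s = x$ramp_time,
         converged = x$converged, eta_identifiable = x$eta_identifiable)
}

#' @export
tidy.linear_stiffness_fit <- function(x, ...) {
  tibble(term = c("k", "c"), estimate = c(x$k, x$c), unit = c("N/m", "N"))
}

#' @export
glance.linear_stiffness_fit <- function(x, ...) {
  tibble(k_n_per_m = x$k, intercept_n = x$c, n_points = x$n_points,
         rmse_n = x$rmse,
         window_low_n = x$force_window[1], window_high_n = x$force_window[2])
}

#' Fit Hertz models to a batch of curves
#'
#' Convenience wrapper mapping [fit_hertz()] over a list of curves and
#' returning one tidy row per curve.
#'
#' @param curves List of [force_curve()] objects (optionally named).
#' @param ... Passed to [fit_hertz()].
#' @return A tibble with one row per curve: `curve_id` plus the
#'   [glance.hertz_fit()] columns.
#' @export
fit_hertz_batch <- function(curves, ...) {
  ids <- names(curves)
  if (is.null(ids)) ids <- sprintf("curve%03d", seq_along(curves))
  purrr::map2(curves, ids, function(fc, id) {
    g <- glance(fit_hertz(fc, ...))
    dplyr::bind_cols(tibble(curve_id = id), g)
  }) |> dplyr::bind_rows()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
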