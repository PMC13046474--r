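#' Construct a force curve
#'
#' A force curve holds the sampled time, piezo height and cantilever force of a
#' single indentation, split into instrument segments (`extend`, `hold`,
#' `retract`), together with the acquisition metadata needed for analysis.
#' All quantities are SI: seconds, metres, newtons.
#'
#' @param data A data frame with columns `time_s`, `height_m`, `force_n` and
#'   `segment` (character; one of `"extend"`, `"hold"`, `"retract"`).
#' @param spring_constant Cantilever spring constant (N/m), must be positive.
#' @param bead_radius Radius of the spherical probe (m), must be positive.
#' @param setpoint Nominal force setpoint (N), or `NA`.
#' @param approach_speed Piezo approach speed (m/s), or `NA`.
#' @param data_rate Sampling rate (Hz), or `NA`.
#'
#' @return A tibble of class `force_curve` with acquisition metadata stored as
#'   attributes (retrieved with [curve_meta()]).
#' @export
#' @examples
#' fc <- force_curve(
#'   data.frame(time_s = 0:4 / 1000, height_m = 0:4 * 5e-9,
#'              force_n = 0, segment = "extend"),
#'   spring_constant = 0.03, bead_radius = 18.64e-6
#' )
#' curve_meta(fc)$spring_constant
force_curve <- function(data, spring_constant, bead_radius,
                        setpoint = NA_real_, approach_speed = NA_real_,
                        data_rate = NA_real_) {
  need <- c("time_s", "height_m", "force_n", "segment")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop_tm(paste0("missing column(s): ", paste(miss, collapse = ", ")),
            "tm_format_error")
  }
  if (!is.numeric(spring_constant) || spring_constant <= 0) {
    stop_tm("spring_constant must be > 0", "tm_parameter_error")
  }
  if (!is.numeric(bead_radius) || bead_radius <= 0) {
    stop_tm("bead_radius must be > 0", "tm_parameter_error")
  }
  out <- as_tibble(data[, need])
  # time must be strictly increasing within each segment
  for (seg in unique(out$segment)) {
    tt <- out$time_s[out$segment == seg]
    if (length(tt) > 1 && any(diff(tt) <= 0)) {
      stop_tm(sprintf("time not strictly increasing within segment '%s'", seg),
              "tm_format_error")
    }
  }
  structure(out,
            class = c("force_curve", class(out)),
            spring_constant = spring_constant,
            bead_radius = bead_radius,
            setpoint = setpoint,
            approach_speed = approach_speed,
            data_rate = data_rate)
}

#' Acquisition metadata of a force curve
#'
#' @param curve A [force_curve()].
#' @return A named list: `spring_constant`, `bead_radius`, `setpoint`,
#'   `approach_speed`, `data_rate`.
#' @export
curve_meta <- function(curve) {
  list(spring_constant = attr(curve, "spring_constant"),
       bead_radius = attr(curve, "bead_radius"),
       setpoint = attr(curve, "setpoint"),
       approach_speed = attr(curve, "approach_speed"),
       data_rate = attr(curve, "data_rate"))
}

#' Extract one segment of a force curve as a tibble
#'
#' @param curve A [force_curve()].
#' @param segment Segment name (`"extend"`, `"hold"` or `"retract"`).
#' @return A tibble with the segment's rows (possibly empty).
#' @export
curve_segment <- function(curve, segment) {
  as_tibble(curve)[curve$segment == segment, , drop = FALSE]
}

#' @export
print.force_curve <- function(x, ...) {
  m <- curve_meta(x)
  segs <- table(x$segment)
  cat(sprintf("<force_curve> %d samples (%s); k_c = %g N/m, R = %g m\n",
              nrow(x),
              paste(sprintf("%s: %d", names(segs), as.integer(segs)),
                    collapse = ", "),
              m$spring_constant, m$bead_radius))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Plot a force curve
#'
#' Force against piezo height, coloured by segment.
#'
#' @param object A [force_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.force_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$height_m * 1e6,
                               y = .data$force_n * 1e9,
                               colour = .data$segment)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = expression(paste("piezo height (", mu, "m)")),
                  y = "force (nN)", colour = "segment")
}
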