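# Synthetic 3D displacement/force fields: a smooth base field decaying away
# from a virtual explant boundary, with planted outliers at known indices.

#' Generate synthetic displacement frames with planted outliers
#'
#' Nodes on a regular 3D grid carry a smooth radial displacement field
#' decaying exponentially from a virtual explant boundary; the optional
#' force field is parallel to the displacement. Planted outliers have their
#' displacement magnitude multiplied by a known factor, giving exact ground
#' truth for filter-recovery tests. Frames differ by a deterministic
#' per-frame scale factor.
#'
#' @param nx,ny,nz Grid node counts per axis.
#' @param spacing Grid spacing (m).
#' @param amplitude Displacement amplitude at the explant boundary (m).
#' @param decay_length Exponential decay length (m).
#' @param explant_radius Virtual explant radius (m).
#' @param n_frames Number of frames.
#' @param outlier_idx Integer node indices (1-based, within one frame) whose
#'   displacement magnitude is multiplied by `outlier_multiplier`.
#' @param outlier_multiplier Magnitude multiplier for planted outliers.
#' @param with_force Include a force field (N) parallel to `u`.
#' @param force_per_disp Force magnitude per displacement magnitude (N/m).
#' @param seed Integer seed (drives small deterministic frame-to-frame
#'   scaling).
#' @return A list: `frames` (tibble with `frame` column),
#'   `truth` (list: `outlier_idx`, `multiplier`).
#' @export
gen_displacement_frames <- function(nx = 8, ny = 8, nz = 4,
                                    spacing = 15e-6, amplitude = 5e-6,
                                    decay_length = 60e-6,
                                    explant_radius = 30e-6,
                                    n_frames = 3,
                                    outlier_idx = integer(0),
                                    outlier_multiplier = 2,
                                    with_force = TRUE,
                                    force_per_disp = 1e-3,
                                    seed = 1) {
  if (spacing <= 0) stop_tm("spacing must be > 0", "tm_parameter_error")
  n <- nx * ny * nz
  if (any(outlier_idx < 1 | outlier_idx > n)) {
    stop_tm("outlier indices outside grid", "tm_parameter_error")
  }
  g <- tidyr::expand_grid(
    z_m = (seq_len(nz) - 1) * spacing,
    y_m = (seq_len(ny) - 1) * spacing,
    x_m = (seq_len(nx) - 1) * spacing
  )[, c("x_m", "y_m", "z_m")]
  ctr <- c(mean(range(g$x_m)), mean(range(g$y_m)), mean(range(g$z_m)))
  dx <- g$x_m - ctr[1]; dy <- g$y_m - ctr[2]; dz <- g$z_m - ctr[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  r[r == 0] <- spacing / 10
  mag <- amplitude * exp(-pmax(r - explant_radius, 0) / decay_length)
  set.seed(sub_seed(seed, 40))
  frame_scale <- 1 + 0.05 * (stats::runif(n_frames) - 0.5)
  frames <- purrr::map(seq_len(n_frames), function(fi) {
    m <- mag * frame_scale[fi]
    m[outlier_idx] <- m[outlier_idx] * outlier_multiplier
    out <- tibble(frame = fi - 1L,
                  x_m = g$x_m, y_m = g$y_m, z_m = g$z_m,
                  ux_m = m * dx / r, uy_m = m * dy / r, uz_m = m * dz / r)
    if (with_force) {
      out$fx_n <- force_per_disp * out$ux_m
      out$fy_n <- force_per_disp * out$uy_m
      out$fz_n <- force_per_disp * out$uz_m
    }
    out
  }) |> dplyr::bind_rows()
  list(frames = frames,
       truth = list(outlier_idx = sort(outlier_idx),
                    multiplier = outlier_multiplier))
}
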