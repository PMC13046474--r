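# Post-processing of reconstructed 3D traction fields. A frame is a tibble
# with one node per row: x_m, y_m, z_m, ux_m, uy_m, uz_m and optionally
# fx_n, fy_n, fz_n. Only norms and dot products are used, so every summary
# is invariant under rigid rotation of the coordinate frame.

.umag <- function(frame) sqrt(frame$ux_m^2 + frame$uy_m^2 + frame$uz_m^2)
.fmag <- function(frame) sqrt(frame$fx_n^2 + frame$fy_n^2 + frame$fz_n^2)
.has_force <- function(frame) all(c("fx_n", "fy_n", "fz_n") %in% names(frame))

# neighbour sets: axis-adjacent (up to 6) on a regular grid, else the
# 6 nearest nodes by Euclidean distance
.neighbor_sets <- function(frame, k = 6) {
  n <- nrow(frame)
  xs <- sort(unique(frame$x_m)); ys <- sort(unique(frame$y_m))
  zs <- sort(unique(frame$z_m))
  if (length(xs) * length(ys) * length(zs) == n) {
    ix <- match(frame$x_m, xs); iy <- match(frame$y_m, ys)
    iz <- match(frame$z_m, zs)
    key <- (ix - 1) + length(xs) * ((iy - 1) + length(ys) * (iz - 1))
    pos <- integer(length(xs) * length(ys) * length(zs))
    pos[key + 1] <- seq_len(n)
    lookup <- function(jx, jy, jz) {
      ok <- jx >= 1 & jx <= length(xs) & jy >= 1 & jy <= length(ys) &
        jz >= 1 & jz <= length(zs)
      out <- rep(0L, length(jx))
      out[ok] <- pos[(jx[ok] - 1) + length(xs) *
                       ((jy[ok] - 1) + length(ys) * (jz[ok] - 1)) + 1]
      out
    }
    lapply(seq_len(n), function(i) {
      cand <- c(lookup(ix[i] - 1, iy[i], iz[i]), lookup(ix[i] + 1, iy[i], iz[i]),
                lookup(ix[i], iy[i] - 1, iz[i]), lookup(ix[i], iy[i] + 1, iz[i]),
                lookup(ix[i], iy[i], iz[i] - 1), lookup(ix[i], iy[i], iz[i] + 1))
      cand[cand > 0]
    })
  } else {
    co <- cbind(frame$x_m, frame$y_m, frame$z_m)
    lapply(seq_len(n), function(i) {
      d2 <- colSums((t(co) - co[i, ])^2)
      order(d2)[2:min(k + 1, n)]
    })
  }
}

#' Remove displacement vectors much larger than their neighbours
#'
#' A vector is removed if its magnitude exceeds `(1 + factor)` times the
#' median magnitude of its nearest-neighbour set (strictly greater; exactly
#' the threshold is retained). Neighbours are the up-to-6 axis-adjacent grid
#' nodes for regular grids, otherwise the 6 nearest nodes. Decisions are
#' made on the original field in a single pass (no cascade).
#'
#' @param frame A node tibble (one frame).
#' @param factor Relative excess threshold (default 0.4, i.e. "40 % larger").
#' @param stat Neighbour statistic: `"median"` (default) or `"mean"`.
#' @return A list: `frame` (surviving rows), `removed` (removed rows),
#'   `removed_idx` (row indices in the input).
#' @export
filter_neighbor_outliers <- function(frame, factor = 0.4,
                                     stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (factor <= 0) stop_tm("factor must be > 0", "tm_parameter_error")
  if (nrow(frame) < 2) stop_tm("need >= 2 nodes", "tm_parameter_error")
  mags <- .umag(frame)
  nb <- .neighbor_sets(frame)
  sfun <- if (stat == "median") median else mean
  ref <- vapply(seq_len(nrow(frame)), function(i) {
    if (length(nb[[i]]) == 0) Inf else sfun(mags[nb[[i]]])
  }, numeric(1))
  out <- mags > (1 + factor) * ref
  list(frame = frame[!out, , drop = FALSE],
       removed = frame[out, , drop = FALSE],
       removed_idx = which(out))
}

#' z-score outlier filter on vector magnitudes
#'
#' Removes values whose magnitude deviates from the mean by more than
#' `z_max` standard deviations (`z = (x - mu) / sigma`); `mu` and `sigma`
#' are computed once on the unfiltered magnitudes. When `sigma` is zero
#' nothing is excluded.
#'
#' @param x A numeric vector of magnitudes, or a node tibble (then
#'   displacement magnitudes are used by default).
#' @param z_max Threshold (default 4, strictly greater).
#' @param on For tibbles: `"displacement"` (default) or `"force"`.
#' @return For vectors: list `kept`, `removed_idx`. For tibbles: list
#'   `frame`, `removed`, `removed_idx`.
#' @export
zscore_filter <- function(x, z_max = 4, on = c("displacement", "force")) {
  on <- match.arg(on)
  is_frame <- is.data.frame(x)
  mags <- if (is_frame) {
    if (on == "displacement") .umag(x) else .fmag(x)
  } else x
  if (length(mags) < 2) stop_tm("need >= 2 values", "tm_parameter_error")
  mu <- mean(mags); sigma <- sd(mags)
  out <- if (sigma == 0) rep(FALSE, length(mags))
         else abs(mags - mu) / sigma > z_max
  if (is_frame) {
    list(frame = x[!out, , drop = FALSE], removed = x[out, , drop = FALSE],
         removed_idx = which(out))
  } else {
    list(kept = mags[!out], removed_idx = which(out))
  }
}

#' Per-frame extrema of displacement and force magnitudes
#'
#' @param frame A node tibble, filters already applied.
#' @return A tibble: `max_displacement_m`, `max_force_n` (`NA` without
#'   force columns).
#' @export
frame_extrema <- function(frame) {
  if (nrow(frame) == 0) stop_tm("empty frame after filtering",
                                "tm_parameter_error")
  tibble(max_displacement_m = max(.umag(frame)),
         max_force_n = if (.has_force(frame)) max(.fmag(frame)) else NA_real_)
}

#' Strain energy of a frame
#'
#' Total work done to deform the matrix from the reference state, in the
#' linear-elastic (discrete) approximation \eqn{U = \frac12 \sum_i f_i
#' \cdot u_i}. A negative total (possible only for inconsistent inputs)
#' raises a warning, not an error.
#'
#' @param frame A node tibble with displacement and force columns.
#' @return Strain energy (J).
#' @export
strain_energy <- function(frame) {
  if (!.has_force(frame)) stop_tm("force vectors missing", "tm_parameter_error")
  u <- 0.5 * sum(frame$fx_n * frame$ux_m + frame$fy_n * frame$uy_m +
                   frame$fz_n * frame$uz_m)
  if (u < 0) warn("negative strain energy: inconsistent force/displacement input")
  u
}

#' Per-explant traction summary across frames
#'
#' Applies the neighbour and z-score filters to each frame, computes the
#' per-frame maximum displacement and force magnitudes and strain energy,
#' and reports the across-frame median of each (even-length medians are the
#' mean of the central pair).
#'
#' @param frames A node tibble covering one or more frames (`frame` column),
#'   or a list of single-frame tibbles.
#' @param neighbor_factor Neighbour-filter threshold; `NULL` skips it.
#' @param z_max z-score threshold; `NULL` skips it.
#' @return A list of class `traction_summary`: `per_frame` (tibble with one
#'   row per frame) and `median` (tibble: `max_displacement_m`,
#'   `max_force_n`, `strain_energy_j`).
#' @export
explant_summary <- function(frames, neighbor_factor = 0.4, z_max = 4) {
  if (is.data.frame(frames)) {
    frames <- split(frames, frames$frame)
  }
  if (length(frames) < 1) stop_tm("need >= 1 frame", "tm_parameter_error")
  per <- purrr::imap(frames, function(fr, nm) {
    if (!is.null(neighbor_factor)) {
      fr <- filter_neighbor_outliers(fr, neighbor_factor)$frame
    }
    if (!is.null(z_max)) fr <- zscore_filter(fr, z_max)$frame
    ex <- frame_extrema(fr)
    ex$strain_energy_j <- if (.has_force(fr)) strain_energy(fr) else NA_real_
    ex$frame <- nm
    ex
  }) |> dplyr::bind_rows()
  med <- tibble(
    max_displacement_m = median(per$max_displacement_m),
    max_force_n = median(per$max_force_n),
    strain_energy_j = median(per$strain_energy_j)
  )
  structure(list(per_frame = per, median = med),
            class = "traction_summary")
}

#' @export
print.traction_summary <- function(x, ...) {
  cat(sprintf(
    "<traction_summary> %d frame(s); median max |u| = %.3g um, max |f| = %.3g nN, U = %.3g pJ\n",
    nrow(x$per_frame), x$median$max_displacement_m * 1e6,
    x$median$max_force_n * 1e9, x$median$strain_energy_j * 1e12))
  invisible(x)
}

#' @export
tidy.traction_summary <- function(x, ...) x$per_frame

#' @export
glance.traction_summary <- function(x, ...) x$median

#' Trilinear resampling of a regular-grid vector field
#'
#' Convenience interpolation of the displacement (and force) components onto
#' a finer regular grid of the given element size. The field must lie on a
#' complete regular grid.
#'
#' @param frame A node tibble on a regular grid.
#' @param element_size Target spacing (m).
#' @return A node tibble on the finer grid.
#' @export
interpolate_field <- function(frame, element_size) {
  xs <- sort(unique(frame$x_m)); ys <- sort(unique(frame$y_m))
  zs <- sort(unique(frame$z_m))
  if (length(xs) * length(ys) * length(zs) != nrow(frame)) {
    stop_tm("field is not a complete regular grid", "tm_parameter_error")
  }
  comp_names <- intersect(c("ux_m", "uy_m", "uz_m", "fx_n", "fy_n", "fz_n"),
                          names(frame))
  arr_of <- function(v) {
    a <- array(NA_real_, c(length(xs), length(ys), length(zs)))
    a[cbind(match(frame$x_m, xs), match(frame$y_m, ys),
            match(frame$z_m, zs))] <- v
    a
  }
  nx <- seq(min(xs), max(xs), by = element_size)
  ny <- seq(min(ys), max(ys), by = element_size)
  nz <- seq(min(zs), max(zs), by = element_size)
  tgt <- tidyr::expand_grid(x_m = nx, y_m = ny, z_m = nz)
  lin1 <- function(grid, q) {
    # fractional index of q in grid
    i <- findInterval(q, grid, all.inside = TRUE)
    frac <- (q - grid[i]) / (grid[i + 1] - grid[i])
    list(i = i, f = frac)
  }
  gx <- lin1(xs, tgt$x_m); gy <- lin1(ys, tgt$y_m); gz <- lin1(zs, tgt$z_m)
  interp <- function(a) {
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) gx$f else 1 - gx$f) * (if (dy) gy$f else 1 - gy$f) *
        (if (dz) gz$f else 1 - gz$f)
      v <- v + w * a[cbind(gx$i + dx, gy$i + dy, gz$i + dz)]
    }
    v
  }
  for (cn in comp_names) tgt[[cn]] <- interp(arr_of(frame[[cn]]))
  tgt$frame <- frame$frame[1]
  tgt
}
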