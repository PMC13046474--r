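# Synthetic image fixtures with exact ground truth: puncta as hard discs
# placed by rejection sampling (so true covered areas are known by
# construction), elliptical masks from the implicit equation, nuclei images
# reusing the puncta machinery.

.disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- tidyr::expand_grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, ]
}

.draw_disc <- function(img, row, col, radius, value) {
  off <- .disc_offsets(radius)
  rr <- row + off$dy; cc <- col + off$dx
  ok <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
  img[cbind(rr[ok], cc[ok])] <- value
  img
}

.disc_mask <- function(size, center_row, center_col, radius) {
  m <- matrix(FALSE, size, size)
  .draw_disc(m, center_row, center_col, radius, TRUE)
}

# place n non-overlapping disc centres inside region_mask (discs fully inside)
.place_discs <- function(region_mask, n, radius, seed_k, seed, max_tries = 10000) {
  if (n == 0) return(cbind(integer(0), integer(0)))
  set.seed(sub_seed(seed, seed_k))
  cand <- which(region_mask, arr.ind = TRUE)
  centers <- matrix(0L, 0, 2)
  off <- .disc_offsets(radius)
  tries <- 0
  while (nrow(centers) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop_tm("infeasible packing: could not place puncta without overlap",
              "tm_parameter_error")
    }
    p <- cand[sample.int(nrow(cand), 1), ]
    rr <- p[1] + off$dy; cc <- p[2] + off$dx
    inside <- all(rr >= 1 & rr <= nrow(region_mask) &
                  cc >= 1 & cc <= ncol(region_mask)) &&
      all(region_mask[cbind(rr, cc)])
    if (!inside) next
    if (nrow(centers) > 0) {
      d2 <- (centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2
      if (any(d2 <= (2 * radius + 1)^2)) next
    }
    centers <- rbind(centers, p)
  }
  centers
}

#' Generate a synthetic puncta image with known area fractions
#'
#' Places non-overlapping bright discs ("puncta") inside a circular region
#' of interest and one or more circular background regions. Because discs
#' are hard and fully inside their regions, the ground-truth covered area of
#' each region is the exact pixel count of the placed discs.
#'
#' @param size Image side (px).
#' @param roi `c(row, col, radius)` of the circular ROI.
#' @param backgrounds List of `c(row, col, radius)` background regions
#'   (disjoint from the ROI, caller's responsibility).
#' @param n_roi,n_bg Puncta counts in the ROI and in each background region.
#' @param punctum_radius Disc radius (px).
#' @param punctum_intensity,background_intensity Intensities in `[0, 1]`.
#' @param noise_sd Additive Gaussian intensity noise.
#' @param seed Integer seed.
#' @return A list: `image`, `roi_mask`, `bg_masks` (list), `truth` (tibble
#'   with per-region `signal_area`, `region_area`, `area_fraction`).
#' @export
gen_puncta_image <- function(size = 200,
                             roi = c(60, 60, 40),
                             backgrounds = list(c(140, 140, 40)),
                             n_roi = 20, n_bg = 10, punctum_radius = 2.5,
                             punctum_intensity = 0.9,
                             background_intensity = 0.05,
                             noise_sd = 0, seed = 1) {
  regions <- c(list(roi = roi),
               setNames(backgrounds, paste0("bg", seq_along(backgrounds))))
  masks <- lapply(regions, function(r) .disc_mask(size, r[1], r[2], r[3]))
  img <- matrix(background_intensity, size, size)
  counts <- c(n_roi, rep(n_bg, length(backgrounds)))
  truth <- purrr::imap(masks, function(mask, nm) {
    i <- match(nm, names(masks))
    centers <- .place_discs(mask, counts[i], punctum_radius, 10 + i, seed)
    area <- 0
    for (j in seq_len(nrow(centers))) {
      img <<- .draw_disc(img, centers[j, 1], centers[j, 2], punctum_radius,
                         punctum_intensity)
      area <- area + nrow(.disc_offsets(punctum_radius))
    }
    tibble(region = nm, signal_area = area, region_area = sum(mask),
           area_fraction = area / sum(mask))
  }) |> dplyr::bind_rows()
  if (noise_sd > 0) {
    set.seed(sub_seed(seed, 20))
    img <- img + matrix(rnorm(size^2, 0, noise_sd), size, size)
  }
  list(image = img, roi_mask = masks$roi, bg_masks = masks[-1], truth = truth)
}

#' Generate an elliptical binary mask
#'
#' Pixels whose centres lie inside the ellipse with semi-axes `a >= b`,
#' rotated by `angle`, centred in a `size x size` frame.
#'
#' @param a,b Semi-axes (px), `a >= b > 0`.
#' @param angle Rotation (radians).
#' @param size Frame side (px).
#' @return Logical matrix.
#' @export
gen_ellipse_mask <- function(a, b, angle = 0, size = 2 * ceiling(a) + 21) {
  if (!(a >= b && b > 0)) stop_tm("need a >= b > 0", "tm_parameter_error")
  cx <- (size + 1) / 2
  if (a > cx - 1.5) {
    stop_tm("ellipse exceeds frame", "tm_parameter_error")
  }
  g <- tidyr::expand_grid(row = seq_len(size), col = seq_len(size))
  xr <- (g$col - cx) * cos(angle) + (g$row - cx) * sin(angle)
  yr <- -(g$col - cx) * sin(angle) + (g$row - cx) * cos(angle)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  matrix(inside, size, size, byrow = FALSE)
}

#' Generate a synthetic nuclei image for density analysis
#'
#' Non-overlapping bright discs ("nuclei") on a dark background inside a
#' rectangular region of interest; the ground-truth nuclear area fraction is
#' exact by construction.
#'
#' @param size Image side (px).
#' @param roi `c(row, col, height, width)` rectangle.
#' @param n_nuclei Nucleus count.
#' @param nucleus_radius Disc radius (px).
#' @param intensity,background_intensity Intensities in `[0, 1]`.
#' @param noise_sd Additive Gaussian intensity noise.
#' @param seed Integer seed.
#' @return A list: `image`, `roi`, `truth` (tibble: `nuclear_area`,
#'   `roi_area`, `area_fraction`).
#' @export
gen_nuclei_image <- function(size = 256, roi = c(29, 29, 200, 200),
                             n_nuclei = 10, nucleus_radius = 3.9,
                             intensity = 0.9, background_intensity = 0.05,
                             noise_sd = 0, seed = 1) {
  mask <- matrix(FALSE, size, size)
  mask[roi[1]:(roi[1] + roi[3] - 1), roi[2]:(roi[2] + roi[4] - 1)] <- TRUE
  # shrink by radius so discs stay inside the ROI
  inner <- matrix(FALSE, size, size)
  m <- ceiling(nucleus_radius)
  inner[(roi[1] + m):(roi[1] + roi[3] - 1 - m),
        (roi[2] + m):(roi[2] + roi[4] - 1 - m)] <- TRUE
  centers <- .place_discs(inner, n_nuclei, nucleus_radius, 30, seed)
  img <- matrix(background_intensity, size, size)
  for (j in seq_len(nrow(centers))) {
    img <- .draw_disc(img, centers[j, 1], centers[j, 2], nucleus_radius,
                      intensity)
  }
  area <- n_nuclei * nrow(.disc_offsets(nucleus_radius))
  if (noise_sd > 0) {
    set.seed(sub_seed(seed, 31))
    img <- img + matrix(rnorm(size^2, 0, noise_sd), size, size)
  }
  list(image = img, roi = roi,
       truth = tibble(nuclear_area = area, roi_area = roi[3] * roi[4],
                      area_fraction = area / (roi[3] * roi[4])))
}
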