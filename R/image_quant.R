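# Image-derived metrics. Images are numeric matrices (top-left origin,
# row-major raster convention); stacks are [row, col, slice] arrays.
#
# Particle analysis follows the common "analyse particles" convention:
# 8-connected components of the thresholded binary image, filtered on area
# and circularity 4*pi*A/P^2, with a Crofton-style perimeter estimate
# (axis-direction intercept counts, P = (pi/4) * (n_h + n_v)), which is
# unbiased for round particles; discrete values marginally above 1 are
# clamped to 1.

#' Particle filter specification
#'
#' @param min_size,max_size Area bounds (px^2; `Inf` allowed). Defaults
#'   1 to Inf.
#' @param circ_low,circ_high Circularity bounds in `[0, 1]`
#'   (circularity = 4*pi*area/perimeter^2, clamped to 1). Defaults 0.2-1.0.
#' @return A list of class `particle_filter`.
#' @export
particle_filter <- function(min_size = 1, max_size = Inf,
                            circ_low = 0.2, circ_high = 1.0) {
  if (circ_low < 0 || circ_high > 1 || circ_low > circ_high) {
    stop_tm("circularity bounds must satisfy 0 <= low <= high <= 1",
            "tm_parameter_error")
  }
  if (min_size > max_size) {
    stop_tm("min_size must be <= max_size", "tm_parameter_error")
  }
  structure(list(min_size = min_size, max_size = max_size,
                 circ_low = circ_low, circ_high = circ_high),
            class = "particle_filter")
}

# 8-connected component labelling by iterative minimum-label propagation.
label_components <- function(bw) {
  stopifnot(is.matrix(bw))
  lab <- matrix(0L, nrow(bw), ncol(bw))
  lab[bw] <- seq_len(sum(bw))
  if (!any(bw)) return(lab)
  nr <- nrow(bw); nc <- ncol(bw)
  pad <- function(m) {
    out <- matrix(Inf, nr + 2, nc + 2)
    out[2:(nr + 1), 2:(nc + 1)] <- ifelse(m == 0, Inf, m)
    out
  }
  repeat {
    p <- pad(lab)
    neigh <- pmin(
      p[1:nr, 1:nc],     p[1:nr, 2:(nc + 1)],     p[1:nr, 3:(nc + 2)],
      p[2:(nr + 1), 1:nc],                        p[2:(nr + 1), 3:(nc + 2)],
      p[3:(nr + 2), 1:nc], p[3:(nr + 2), 2:(nc + 1)], p[3:(nr + 2), 3:(nc + 2)]
    )
    new <- pmin(ifelse(lab == 0, Inf, lab), neigh)
    new[!bw | is.infinite(new)] <- 0
    new_lab <- new
    storage.mode(new_lab) <- "integer"
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  # compact labels to 1..k
  u <- sort(unique(lab[lab > 0]))
  lab[] <- match(lab, u, nomatch = 0L) |> as.integer()
  lab
}

# Crofton-style perimeter from axis-direction intercept counts.
perimeter_crofton <- function(bw) {
  b <- cbind(FALSE, bw, FALSE)
  n_h <- sum(b[, -1] != b[, -ncol(b)])
  b2 <- rbind(FALSE, bw, FALSE)
  n_v <- sum(b2[-1, ] != b2[-nrow(b2), ])
  (pi / 4) * (n_h + n_v)
}

#' Threshold an image and analyse particles
#'
#' Binarizes `image >= threshold`, labels 8-connected components, computes
#' per-particle area and circularity, and filters with a [particle_filter()].
#' An empty result is valid.
#'
#' @param image Numeric matrix.
#' @param threshold Intensity threshold; `"otsu"` picks Otsu's threshold.
#' @param filter A [particle_filter()].
#' @return A list: `labels` (matrix; surviving particles only, relabelled),
#'   `particles` (tibble: `label`, `area`, `perimeter`, `circularity`),
#'   `total_area` (px^2 over surviving particles), `threshold`.
#' @export
segment_particles <- function(image, threshold = "otsu",
                              filter = particle_filter()) {
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(image)
  bw <- image >= threshold
  lab <- label_components(bw)
  k <- max(lab)
  if (k == 0) {
    return(list(labels = lab, particles = tibble(
      label = integer(), area = numeric(), perimeter = numeric(),
      circularity = numeric()), total_area = 0, threshold = threshold))
  }
  areas <- tabulate(lab[lab > 0], nbins = k)
  per <- vapply(seq_len(k), function(i) perimeter_crofton(lab == i),
                numeric(1))
  circ <- pmin(4 * pi * areas / per^2, 1)
  keep <- areas >= filter$min_size & areas <= filter$max_size &
    circ >= filter$circ_low & circ <= filter$circ_high
  out_lab <- matrix(0L, nrow(lab), ncol(lab))
  kept_ids <- which(keep)
  for (j in seq_along(kept_ids)) out_lab[lab == kept_ids[j]] <- j
  list(labels = out_lab,
       particles = tibble(label = seq_along(kept_ids),
                          area = areas[kept_ids],
                          perimeter = per[kept_ids],
                          circularity = circ[kept_ids]),
       total_area = sum(areas[kept_ids]),
       threshold = threshold)
}

#' Otsu threshold of a numeric image
#'
#' @param image Numeric matrix with values in `[0, 1]` (values outside are
#'   clipped).
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(image) {
  x <- pmin(pmax(as.numeric(image), 0), 1)
  EBImage::otsu(matrix(x, nrow(image), ncol(image)), range = c(0, 1))
}

#' Project an image stack over a physical depth
#'
#' Projects `ceiling(depth_um / z_step_um)` slices starting at `start_slice`
#' using maximum- or sum-intensity projection. Sum projections are computed
#' in double precision, so they cannot overflow.
#'
#' @param stack 3D array `[row, col, slice]`.
#' @param mode `"max"` or `"sum"`.
#' @param depth_um Physical projection depth (um).
#' @param z_step_um Slice spacing (um).
#' @param start_slice First slice of the projection (default 1); see
#'   [find_start_slice()] for the data-driven rule.
#' @return Numeric matrix.
#' @export
project_stack <- function(stack, mode = c("max", "sum"), depth_um,
                          z_step_um, start_slice = 1) {
  mode <- match.arg(mode)
  n <- ceiling(depth_um / z_step_um)
  last <- start_slice + n - 1
  if (length(dim(stack)) != 3 || last > dim(stack)[3]) {
    stop_tm(sprintf("insufficient slices: need %d from %d, stack has %d",
                    n, start_slice, if (length(dim(stack)) == 3)
                      dim(stack)[3] else NA),
            "tm_parameter_error")
  }
  sub <- stack[, , start_slice:last, drop = FALSE]
  if (mode == "max") apply(sub, c(1, 2), max) else apply(sub, c(1, 2), sum)
}

#' Data-driven projection start slice
#'
#' Operationalizes "from the slice where the reference signal first appears"
#' as the first slice whose 99th-percentile intensity exceeds `fraction` of
#' the stack maximum.
#'
#' @param reference_stack 3D array of the reference channel (e.g. a nuclear
#'   stain).
#' @param fraction Appearance threshold as a fraction of the stack maximum
#'   (default 0.1).
#' @return Slice index (integer).
#' @export
find_start_slice <- function(reference_stack, fraction = 0.1) {
  mx <- max(reference_stack)
  p99 <- apply(reference_stack, 3, quantile, probs = 0.99, names = FALSE)
  i <- which(p99 > fraction * mx)[1]
  if (is.na(i)) stop_tm("no slice exceeds the appearance threshold",
                        "tm_parameter_error")
  i
}

#' Normalized expression from puncta-covered areas
#'
#' Two families of normalization are used for in situ hybridization puncta:
#' a ratio of the region-of-interest signal area to the mean background
#' signal area (`"ratio_to_background"`; variants `sema3a-ratio`,
#' `cs-ratio`) and a fraction of the region area covered by signal
#' (`"fraction_of_region"`; variants `slit1-fraction`, `lpa-fraction`).
#'
#' @param roi_signal_area Signal (puncta) area in the ROI (px^2).
#' @param bg_signal_areas Numeric vector of background signal areas (for the
#'   ratio variants).
#' @param region_area Total region area (for the fraction variants).
#' @param variant One of `"ratio_to_background"`, `"fraction_of_region"`,
#'   or the aliases `"sema3a-ratio"`, `"cs-ratio"`, `"slit1-fraction"`,
#'   `"lpa-fraction"`.
#' @return A tibble: `normalized_expression`, `variant`.
#' @export
normalized_expression <- function(roi_signal_area, bg_signal_areas = NULL,
                                  region_area = NULL,
                                  variant = "ratio_to_background") {
  fam <- switch(variant,
                "ratio_to_background" = ,
                "sema3a-ratio" = ,
                "cs-ratio" = "ratio_to_background",
                "fraction_of_region" = ,
                "slit1-fraction" = ,
                "lpa-fraction" = "fraction_of_region",
                stop_tm(sprintf("unknown variant '%s'", variant),
                        "tm_parameter_error"))
  value <- if (fam == "ratio_to_background") {
    if (is.null(bg_signal_areas) || length(bg_signal_areas) == 0 ||
        mean(bg_signal_areas) <= 0) {
      stop_tm("empty_background: no background signal", "tm_empty_background")
    }
    roi_signal_area / mean(bg_signal_areas)
  } else {
    if (is.null(region_area) || region_area <= 0) {
      stop_tm("empty_region: region area is zero", "tm_empty_region")
    }
    roi_signal_area / region_area
  }
  tibble(normalized_expression = value, variant = variant)
}

#' Relative nuclear area within a region of interest
#'
#' Gaussian blur, threshold, binarize, particle filter (defaults: size
#' 1-Inf px^2, circularity 0.2-1.0), then the ratio of surviving particle
#' area to total ROI area.
#'
#' @param image Numeric matrix.
#' @param roi Logical mask congruent with `image`, or `c(row, col, height,
#'   width)` of a rectangular ROI (e.g. a 50 x 50 um square in pixels).
#' @param blur_sigma Gaussian blur sigma in px (default 2).
#' @param threshold Intensity threshold, or `"otsu"`.
#' @param filter A [particle_filter()].
#' @return A tibble: `area_fraction`, `nuclear_area`, `roi_area`,
#'   `threshold`.
#' @export
nuclear_area_fraction <- function(image, roi, blur_sigma = 2,
                                  threshold = "otsu",
                                  filter = particle_filter()) {
  if (is.logical(roi) && is.matrix(roi)) {
    if (!all(dim(roi) == dim(image))) {
      stop_tm("roi mask not congruent with image", "tm_parameter_error")
    }
    rng <- range(which(roi, arr.ind = TRUE)[, 1])
    cng <- range(which(roi, arr.ind = TRUE)[, 2])
    sub <- image[rng[1]:rng[2], cng[1]:cng[2]]
    roi_area <- sum(roi)
  } else {
    r0 <- roi[1]; c0 <- roi[2]; h <- roi[3]; w <- roi[4]
    if (r0 < 1 || c0 < 1 || r0 + h - 1 > nrow(image) ||
        c0 + w - 1 > ncol(image)) {
      stop_tm("roi outside image", "tm_parameter_error")
    }
    sub <- image[r0:(r0 + h - 1), c0:(c0 + w - 1)]
    roi_area <- h * w
  }
  blurred <- if (blur_sigma > 0) {
    as.matrix(EBImage::gblur(sub, sigma = blur_sigma))
  } else sub
  seg <- segment_particles(blurred, threshold = threshold, filter = filter)
  tibble(area_fraction = seg$total_area / roi_area,
         nuclear_area = seg$total_area, roi_area = roi_area,
         threshold = seg$threshold)
}

#' Elongation of a binary mask
#'
#' Major-to-minor axis ratio of the ellipse with the same normalized second
#' central moments as the mask's pixel set: the ratio of the square roots of
#' the eigenvalues of the pixel covariance matrix (with the 1/12 per-pixel
#' spread term, so a single pixel has the moments of a unit square).
#'
#' @param mask Logical matrix.
#' @return Elongation ratio (>= 1).
#' @export
#' @examples
#' m <- gen_ellipse_mask(a = 40, b = 20, angle = 0.3, size = 121)
#' elongation(m)  # ~ 2
elongation <- function(mask) {
  if (!any(mask)) stop_tm("empty mask", "tm_parameter_error")
  pix <- which(mask, arr.ind = TRUE)
  x <- pix[, 2]; y <- pix[, 1]
  mu_xx <- mean((x - mean(x))^2)
  mu_yy <- mean((y - mean(y))^2)
  mu_xy <- mean((x - mean(x)) * (y - mean(y)))
  cov_raw <- matrix(c(mu_xx, mu_xy, mu_xy, mu_yy), 2, 2)
  ev_raw <- eigen(cov_raw, symmetric = TRUE, only.values = TRUE)$values
  if (ev_raw[2] <= 1e-9) {
    stop_tm("degenerate_mask: pixel set has no planar extent",
            "tm_degenerate_mask")
  }
  ev <- eigen(cov_raw + diag(1 / 12, 2), symmetric = TRUE,
              only.values = TRUE)$values
  sqrt(ev[1] / ev[2])
}
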