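# Stiffness maps: grids of reduced apparent elastic modulus K assembled from
# per-curve Hertz fits. Convention: matrix element [1, 1] is the lower-left
# (LL) corner of the physical map and the row index increases upward; this is
# the opposite of the raster (image) convention and is tested explicitly.

#' Construct a stiffness map
#'
#' @param k Numeric matrix of K values (Pa) with `NA` for missing cells;
#'   row 1 is the lower-left row.
#' @param spacing Grid spacing (m).
#' @param provenance Optional tibble with one row per grid cell
#'   (`row`, `col`, `curve_id`, `qc_reason`).
#' @return An object of class `stiffness_map`.
#' @export
stiffness_map <- function(k, spacing = NA_real_, provenance = NULL) {
  if (!is.matrix(k)) stop_tm("k must be a matrix", "tm_parameter_error")
  if (any(k[!is.na(k)] < 0)) stop_tm("K values must be >= 0",
                                     "tm_parameter_error")
  structure(list(k = k, spacing = spacing, origin = "lower-left",
                 provenance = provenance),
            class = "stiffness_map")
}

#' @export
print.stiffness_map <- function(x, ...) {
  cat(sprintf("<stiffness_map> %d x %d cells, %d missing, spacing %s m\n",
              nrow(x$k), ncol(x$k), sum(is.na(x$k)),
              format(x$spacing)))
  invisible(x)
}

#' Assemble per-curve Hertz fits into a stiffness map
#'
#' QC-failing fits become missing cells (rendered dark in heatmaps);
#' provenance (curve id and QC reason) is retained per cell. Input order is
#' irrelevant.
#'
#' @param fits A tibble with columns `row`, `col` (grid positions, 1-based,
#'   lower-left origin) and `fit` (list of `hertz_fit`), or columns `K`,
#'   `qc_pass`, `qc_reason` directly. An optional `curve_id` column is kept
#'   as provenance.
#' @param nrow,ncol Grid dimensions; defaults to the maxima of the positions.
#' @param spacing Grid spacing (m).
#' @return A [stiffness_map()].
#' @export
assemble_map <- function(fits, nrow = NULL, ncol = NULL, spacing = NA_real_) {
  if (is.null(fits) || base::nrow(fits) == 0) {
    stop_tm("empty fit list", "tm_parameter_error")
  }
  if ("fit" %in% names(fits)) {
    fits$K <- purrr::map_dbl(fits$fit, "K")
    fits$qc_pass <- purrr::map_lgl(fits$fit, "qc_pass")
    fits$qc_reason <- purrr::map_chr(fits$fit, "qc_reason")
  }
  if (anyDuplicated(fits[, c("row", "col")])) {
    stop_tm("duplicate grid position", "tm_parameter_error")
  }
  if (is.null(nrow)) nrow <- max(fits$row)
  if (is.null(ncol)) ncol <- max(fits$col)
  if (any(fits$row < 1 | fits$row > nrow | fits$col < 1 | fits$col > ncol)) {
    stop_tm("positions outside declared grid", "tm_parameter_error")
  }
  k <- matrix(NA_real_, nrow, ncol)
  ok <- fits$qc_pass
  k[cbind(fits$row[ok], fits$col[ok])] <- fits$K[ok]
  prov <- tibble(row = fits$row, col = fits$col,
                 curve_id = if ("curve_id" %in% names(fits)) fits$curve_id
                            else NA_character_,
                 qc_reason = fits$qc_reason)
  stiffness_map(k, spacing = spacing, provenance = prov)
}

#' Combine repeated ROI selections by voting
#'
#' A cell belongs to the region if it was selected in at least `min_votes`
#' of the supplied masks (default 3 of 4, the repeat-selection rule used for
#' manually drawn regions of interest). Generalized to n-of-m.
#'
#' @param masks List of logical matrices of identical dimensions.
#' @param min_votes Minimum selections for inclusion (default 3).
#' @param label Region label.
#' @return An object of class `region_mask`: `mask` (logical matrix),
#'   `vote_counts` (integer matrix), `label`, `min_votes`.
#' @export
vote_region <- function(masks, min_votes = 3, label = "roi") {
  if (length(masks) < 1) stop_tm("no masks given", "tm_parameter_error")
  dims <- lapply(masks, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop_tm("masks differ in shape", "tm_parameter_error")
  }
  votes <- Reduce(`+`, lapply(masks, function(m) {
    storage.mode(m) <- "integer"; m
  }))
  structure(list(mask = votes >= min_votes, vote_counts = votes,
                 label = label, min_votes = min_votes),
            class = "region_mask")
}

#' Regional median stiffness
#'
#' Median modulus over the present (non-missing) map cells inside the region.
#' Medians of even-length samples are the mean of the two central values.
#'
#' @param map A [stiffness_map()].
#' @param region A [vote_region()] result or a logical matrix congruent with
#'   the map.
#' @return A tibble: `median_pa`, `n`, `iqr_pa`.
#' @export
regional_median <- function(map, region) {
  mask <- if (inherits(region, "region_mask")) region$mask else region
  if (!all(dim(mask) == dim(map$k))) {
    stop_tm("region mask not congruent with map", "tm_parameter_error")
  }
  vals <- map$k[mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop_tm("empty_region: no present cells in region", "tm_empty_region")
  }
  tibble(median_pa = median(vals), n = length(vals),
         iqr_pa = stats::IQR(vals))
}

#' Compression-stiffening modulus ratio
#'
#' Compares the median modulus of three curves from the first hour of a
#' sustained-compression experiment with the median of three curves from the
#' last hour. When more than three QC-passing fits are available in a
#' window, the first/last three by timestamp are used.
#'
#' @param first_hour,last_hour Tibbles with columns `K`, `qc_pass` and
#'   `time` (any orderable timestamp), or lists of `hertz_fit` plus a
#'   `time` attribute-free ordering (rows are assumed time-ordered if no
#'   `time` column).
#' @param direction `"last_over_first"` (default: no change = 1, stiffening
#'   > 1) or `"first_over_last"`.
#' @return A tibble: `ratio`, `median_first_pa`, `median_last_pa`.
#' @export
cs_modulus_ratio <- function(first_hour, last_hour,
                             direction = c("last_over_first",
                                           "first_over_last")) {
  direction <- match.arg(direction)
  take <- function(df, side) {
    df <- as_tibble(df)
    if ("qc_pass" %in% names(df)) df <- df[df$qc_pass, , drop = FALSE]
    if (base::nrow(df) < 3) {
      stop_tm("insufficient_curves: need >= 3 qc-passing fits per window",
              "tm_insufficient_curves")
    }
    if ("time" %in% names(df)) df <- df[order(df$time), , drop = FALSE]
    if (side == "first") head(df$K, 3) else tail(df$K, 3)
  }
  m1 <- median(take(first_hour, "first"))
  m2 <- median(take(last_hour, "last"))
  ratio <- if (direction == "last_over_first") m2 / m1 else m1 / m2
  tm_log("INFO", "stiffness_maps",
         sprintf("cs_modulus_ratio direction = %s", direction))
  tibble(ratio = ratio, median_first_pa = m1, median_last_pa = m2)
}

#' Plot a stiffness map
#'
#' Heatmap of K with missing (non-analysable) cells shown dark grey.
#'
#' @param object A [stiffness_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stiffness_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$K)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey25", name = "K (Pa)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row (up)")
}

#' @export
tidy.stiffness_map <- function(x, ...) {
  k <- x$k
  tidyr::expand_grid(row = seq_len(nrow(k)), col = seq_len(ncol(k))) |>
    dplyr::mutate(K = k[cbind(.data$row, .data$col)],
                  missing = is.na(.data$K))
}

#' @export
glance.stiffness_map <- function(x, ...) {
  vals <- x$k[!is.na(x$k)]
  tibble(n_cells = length(x$k), n_missing = sum(is.na(x$k)),
         median_pa = if (length(vals)) median(vals) else NA_real_,
         iqr_pa = if (length(vals)) stats::IQR(vals) else NA_real_,
         spacing_m = x$spacing)
}
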