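# On-disk formats.
#
# Curves: tab-separated, header row, canonical columns `time_s`, `height_m`,
# `force_n`; a unit-suffix dialect (`time_ms`, `height_um`, `height_nm`,
# `force_nn`, `force_pn`) is accepted on read and canonicalized to SI.
# Metadata lives in a sibling `<path>.meta` file, one `key = value` per line.
# Maps: CSV matrix with `NA` as the missing token and spacing/origin in `#`
# header comments; row 1 of the in-memory matrix is the lower-left (LL) row,
# files are written top row first. Images (raster convention) use the top-left
# origin instead; the two conventions are deliberate and tested.
# Vector fields: TSV, one node per row, columns frame, x_m..uz_m [, fx_n..fz_n].

.unit_scale <- c(
  time_s = 1, time_ms = 1e-3,
  height_m = 1, height_um = 1e-6, height_nm = 1e-9,
  force_n = 1, force_nn = 1e-9, force_pn = 1e-12
)

.canon_col <- function(nm) sub("_(s|ms|m|um|nm|n|nn|pn)$", "", nm)

#' Write a force curve and its metadata sidecar
#'
#' @param curve A [force_curve()].
#' @param path Output path for the tab-separated curve file; metadata is
#'   written to `<path>.meta`.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  df <- as_tibble(curve)
  utils::write.table(df[, c("time_s", "height_m", "force_n", "segment")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- curve_meta(curve)
  segs <- rle(df$segment)
  ends <- cumsum(segs$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  seg_str <- paste(sprintf("%s:%d-%d", segs$values, starts, ends),
                   collapse = ",")
  lines <- c(
    sprintf("spring_constant_n_per_m = %.17g", m$spring_constant),
    sprintf("bead_radius_m = %.17g", m$bead_radius),
    sprintf("setpoint_n = %.17g", m$setpoint),
    sprintf("approach_speed_m_per_s = %.17g", m$approach_speed),
    sprintf("data_rate_hz = %.17g", m$data_rate),
    sprintf("segments = %s", seg_str)
  )
  writeLines(lines, paste0(path, ".meta"))
  invisible(path)
}

.read_meta <- function(path) {
  if (!file.exists(path)) {
    stop_tm(sprintf("metadata sidecar not found: %s", path), "tm_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")), "")
  setNames(as.list(vals), keys)
}

#' Read a force curve from disk
#'
#' Reads the canonical tab-separated curve format (plus its `<path>.meta`
#' sidecar) and canonicalizes any supported unit dialect to SI. Rows that fail
#' to parse are dropped with a logged count.
#'
#' @param path Path to a curve file written by [write_force_curve()] (or the
#'   same format exported in a supported unit dialect).
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path) {
  if (!file.exists(path)) {
    stop_tm(sprintf("file not found: %s", path), "tm_format_error")
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  canon <- .canon_col(names(df))
  for (req in c("time", "height", "force")) {
    if (!req %in% canon) {
      stop_tm(sprintf("missing column `%s_*`: expected one of the %s columns",
                      req, req), "tm_format_error")
    }
  }
  num_cols <- names(df)[canon %in% c("time", "height", "force")]
  unknown <- num_cols[!num_cols %in% names(.unit_scale)]
  if (length(unknown) > 0) {
    stop_tm(sprintf("unsupported unit dialect: %s",
                    paste(unknown, collapse = ", ")), "tm_format_error")
  }
  parsed <- lapply(num_cols, function(cn) {
    suppressWarnings(as.numeric(df[[cn]]) * .unit_scale[[cn]])
  })
  names(parsed) <- .canon_col(num_cols)
  seg <- if ("segment" %in% names(df)) df$segment else NULL
  bad <- Reduce(`|`, lapply(parsed, is.na))
  if (any(bad)) {
    tm_log("WARN", "data_io",
           sprintf("%d unparseable row(s) rejected in %s", sum(bad), path))
  }
  keep <- !bad
  out <- tibble(time_s = parsed$time[keep],
                height_m = parsed$height[keep],
                force_n = parsed$force[keep],
                segment = if (is.null(seg)) "extend" else seg[keep])
  meta <- .read_meta(paste0(path, ".meta"))
  getn <- function(key) {
    v <- meta[[key]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  if (is.null(seg) && !is.null(meta$segments)) {
    out$segment <- "extend"
    for (part in strsplit(meta$segments, ",", fixed = TRUE)[[1]]) {
      mt <- regmatches(part, regexec("^([a-z]+):([0-9]+)-([0-9]+)$", part))[[1]]
      if (length(mt) == 4) {
        idx <- as.integer(mt[3]):as.integer(mt[4])
        out$segment[idx[idx <= nrow(out)]] <- mt[2]
      }
    }
  }
  force_curve(out,
              spring_constant = getn("spring_constant_n_per_m"),
              bead_radius = getn("bead_radius_m"),
              setpoint = getn("setpoint_n"),
              approach_speed = getn("approach_speed_m_per_s"),
              data_rate = getn("data_rate_hz"))
}

#' Write a stiffness map to CSV
#'
#' @param map A [stiffness_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stiffness_map <- function(map, path) {
  stopifnot(inherits(map, "stiffness_map"))
  k <- map$k
  header <- c(sprintf("# spacing_m = %.17g", map$spacing),
              "# origin = lower-left",
              "# rows = top-to-bottom")
  # file rows from top (highest row index) down; matrix row 1 is lower-left
  body <- apply(k[rev(seq_len(nrow(k))), , drop = FALSE], 1, function(r) {
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = ",")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a stiffness map from CSV
#'
#' @param path Path written by [write_stiffness_map()].
#' @return A [stiffness_map()].
#' @export
read_stiffness_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  spacing <- NA_real_
  sp <- grep("spacing_m", hdr, value = TRUE)
  if (length(sp) == 1) {
    spacing <- suppressWarnings(as.numeric(sub(".*=", "", sp)))
  }
  rows <- strsplit(body, ",", fixed = TRUE)
  if (length(rows) == 0) stop_tm("empty map file", "tm_format_error")
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1) {
    stop_tm("ragged rows in map file", "tm_format_error")
  }
  mat <- do.call(rbind, lapply(rows, function(r) {
    suppressWarnings(as.numeric(ifelse(trimws(r) == "NA", NA, r)))
  }))
  mat <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]  # back to LL-origin
  if (any(mat[!is.na(mat)] < 0)) {
    stop_tm("negative K in map file", "tm_format_error")
  }
  stiffness_map(mat, spacing = spacing)
}

#' Write a vector field to TSV
#'
#' @param field A tibble of node records, one row per node per frame, with
#'   columns `frame`, `x_m`, `y_m`, `z_m`, `ux_m`, `uy_m`, `uz_m` and
#'   optionally `fx_n`, `fy_n`, `fz_n`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_vector_field <- function(field, path) {
  utils::write.table(field, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 3D vector field from TSV
#'
#' @param path TSV path with columns `frame`, `x_m`, `y_m`, `z_m`,
#'   `ux_m`, `uy_m`, `uz_m` and optionally `fx_n`, `fy_n`, `fz_n`.
#' @return A tibble ordered by frame index; frame gaps are allowed.
#' @export
read_vector_field <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  need <- c("frame", "x_m", "y_m", "z_m", "ux_m", "uy_m", "uz_m")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_tm(paste0("missing column(s): ", paste(miss, collapse = ", ")),
            "tm_format_error")
  }
  coord_bad <- !is.finite(df$x_m) | !is.finite(df$y_m) | !is.finite(df$z_m)
  if (any(coord_bad)) {
    tm_log("WARN", "data_io",
           sprintf("%d row(s) with non-finite coordinates", sum(coord_bad)))
    stop_tm("non-finite coordinates in vector field", "tm_format_error")
  }
  key <- paste(df$frame, df$x_m, df$y_m, df$z_m)
  if (anyDuplicated(key)) {
    stop_tm("duplicate node within a frame", "tm_format_error")
  }
  as_tibble(df[order(df$frame), , drop = FALSE])
}

#' Read a grayscale image or image stack from TIFF
#'
#' Single-page TIFFs are returned as a numeric matrix (top-left origin,
#' row-major); multi-page TIFFs as a 3D array `[row, col, slice]`. Intensities
#' are the values stored in the file (tiff scales integer data to `[0, 1]`).
#'
#' @param path TIFF path (8- or 16-bit grayscale, single or multi page).
#' @return Matrix or 3D array.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # first channel of multi-channel
    p
  })
  if (length(pages) == 1) return(pages[[1]])
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write a grayscale image or stack to TIFF
#'
#' @param img Matrix or 3D array with values in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(img, path) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  if (length(dim(img)) == 3) {
    pages <- lapply(seq_len(dim(img)[3]), function(i) img[, , i])
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 16)
  }
  invisible(path)
}
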