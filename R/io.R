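#' Read an Esri-style ASCII grid as a binary landscape
#'
#' Parses the standard headered ASCII grid format (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `nodata_value`, then rows of
#' values from north to south). Values must be 0/1 (or heights if
#' `threshold` is given); nodata cells become outside (`NA`). The grid must be
#' in a projected, meter-unit reference; this reader performs no reprojection.
#'
#' @param path Path to the `.asc` file.
#' @param threshold If supplied, values are treated as canopy heights in
#'   meters and thresholded via [binarize_forest()].
#' @return A [binary_landscape()].
#' @export
read_asc <- function(path, threshold = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid header must define ncols, nrows and cellsize", call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)),
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  xll <- hdr$xllcorner %||% 0
  yll <- hdr$yllcorner %||% 0
  if (is.null(threshold)) {
    binary_landscape(m, cell_size = hdr$cellsize, xll = xll, yll = yll)
  } else {
    binarize_forest(m, cell_size = hdr$cellsize, threshold = threshold,
                    xll = xll, yll = yll)
  }
}

#' Write a binary landscape as an Esri-style ASCII grid
#'
#' Outside cells are written as the nodata value (-9999). The file round-trips
#' through [read_asc()].
#'
#' @param ls A [binary_landscape()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(ls, path) {
  stopifnot(inherits(ls, "binary_landscape"))
  m <- ls$cells
  m[is.na(m)] <- -9999L
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", ls$xll),
           sprintf("yllcorner %.10g", ls$yll),
           sprintf("cellsize %.10g", ls$cell_size),
           "NODATA_value -9999")
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a single-band TIFF as a binary landscape
#'
#' Reads pixel values from a single-band TIFF (via the `tiff` package). Only
#' the raster values are read; the geotransform — cell size and lower-left
#' corner in a projected, meter-unit reference — must be supplied by the
#' caller. Values must be 0/1, or canopy heights if `threshold` is given.
#'
#' @param path Path to the TIFF file.
#' @param cell_size Cell side in meters.
#' @param xll,yll Lower-left corner coordinates, meters.
#' @param threshold Optional height threshold, as in [read_asc()].
#' @param nodata Optional value to treat as outside.
#' @return A [binary_landscape()].
#' @export
read_landscape_tif <- function(path, cell_size, xll = 0, yll = 0,
                               threshold = NULL, nodata = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF requires the `tiff` package", call. = FALSE)
  }
  m <- tiff::readTIFF(path, info = TRUE)
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L) stop("expected a single-band TIFF", call. = FALSE)
    m <- m[, , 1]
  }
  # integer TIFFs come back scaled to [0,1]; undo that. 32-bit floats are as stored.
  bps <- attr(m, "bits.per.sample")
  if (!is.null(bps) && bps %in% c(8L, 16L)) m <- round(m * (2^bps - 1))
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  if (!is.null(nodata)) m[m == nodata] <- NA
  if (is.null(threshold)) {
    binary_landscape(m, cell_size = cell_size, xll = xll, yll = yll)
  } else {
    binarize_forest(m, cell_size = cell_size, threshold = threshold,
                    xll = xll, yll = yll)
  }
}

#' Read a sample-point table
#'
#' CSV with columns `id`, `x`, `y` and optional `biome` (coordinates in the
#' same projected meter-unit reference as the rasters).
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `id`, `x`, `y`, `biome`.
#' @export
read_points_csv <- function(path) {
  pts <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("id", "x", "y") %in% names(pts))) {
    stop("points CSV must have columns id, x, y", call. = FALSE)
  }
  if (!"biome" %in% names(pts)) pts$biome <- NA_character_
  pts[, c("id", "x", "y", "biome")]
}

# write a CSV plus a YAML sidecar echoing the configuration and seed,
# so any output file can be reproduced from its sidecar alone
write_output_csv <- function(df, path, config_echo = NULL) {
  readr::write_csv(df, path)
  if (!is.null(config_echo)) {
    yaml::write_yaml(config_echo, paste0(path, ".run.yml"))
  }
  invisible(path)
}
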