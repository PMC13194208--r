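#' Construct a binary landscape
#'
#' A `binary_landscape` is the unit of measurement: a rectangular grid of cells
#' in one of three states — habitat (`1`), non-habitat (`0`), or outside the
#' analysis window (`NA`) — together with the cell size in meters and the
#' coordinates of the grid's lower-left corner in a projected, meter-unit
#' reference. Row 1 is the northernmost row, matching raster conventions.
#'
#' @param cells Integer (or logical) matrix; `1`/`TRUE` = habitat, `0`/`FALSE` =
#'   non-habitat, `NA` = outside the landscape.
#' @param cell_size Side length of a cell in meters (> 0).
#' @param xll,yll Coordinates of the lower-left corner of the grid, in meters.
#' @param radius_m Radius of the circular landscape in meters, if the grid has
#'   been delineated; `NULL` otherwise.
#' @return An object of class `binary_landscape`.
#' @examples
#' ls <- binary_landscape(matrix(c(1, 0, 0, 1), 2, 2), cell_size = 30)
#' proportion_habitat(ls)
#' @export
binary_landscape <- function(cells, cell_size, xll = 0, yll = 0, radius_m = NULL) {
  if (is.logical(cells)) {
    storage.mode(cells) <- "integer"
  }
  if (!is.matrix(cells) || !is.numeric(cells)) {
    stop("`cells` must be a numeric or logical matrix", call. = FALSE)
  }
  storage.mode(cells) <- "integer"
  vals <- cells[!is.na(cells)]
  if (length(vals) == 0L) {
    stop("landscape must contain at least one cell that is not outside", call. = FALSE)
  }
  if (!all(vals %in% c(0L, 1L))) {
    stop("`cells` values must be 0, 1 or NA", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number (meters)", call. = FALSE)
  }
  structure(
    list(cells = cells, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll),
         radius_m = if (is.null(radius_m)) NULL else as.numeric(radius_m)),
    class = "binary_landscape"
  )
}

#' @export
print.binary_landscape <- function(x, ...) {
  d <- dim(x$cells)
  n_in <- sum(!is.na(x$cells))
  cat(sprintf("<binary_landscape> %d x %d cells @ %g m", d[1], d[2], x$cell_size))
  if (!is.null(x$radius_m)) cat(sprintf(", radius %g m", x$radius_m))
  cat(sprintf("\n  inside: %d cells (%.4g ha), habitat: %.3f\n",
              n_in, landscape_area_ha(x), proportion_habitat(x)))
  invisible(x)
}

n_inside <- function(ls) sum(!is.na(ls$cells))

n_habitat <- function(ls) sum(ls$cells == 1L, na.rm = TRUE)

#' Landscape area in hectares
#'
#' Area of the analysis window: inside (non-outside) cell count times the cell
#' area, \eqn{cell\_size^2 / 10^4} ha.
#'
#' @param ls A [binary_landscape()].
#' @return Area in hectares.
#' @export
landscape_area_ha <- function(ls) {
  stopifnot(inherits(ls, "binary_landscape"))
  n_inside(ls) * ls$cell_size^2 / 1e4
}

# Cell-center coordinate helpers (row 1 = top)
cell_center_x <- function(ls) ls$xll + (seq_len(ncol(ls$cells)) - 0.5) * ls$cell_size
cell_center_y <- function(ls) ls$yll + (nrow(ls$cells) - seq_len(nrow(ls$cells)) + 0.5) * ls$cell_size

#' Classify a tree-height grid into habitat and non-habitat
#'
#' Cells with height greater than or equal to `threshold` (inclusive) and not
#' excluded by `nonforest_mask` become habitat; everything else — shorter
#' vegetation, cropland, built-up land, water and other masked covers — becomes
#' non-habitat. The default 5 m threshold follows the FAO forest definition.
#'
#' @param height_grid Numeric matrix of canopy heights in meters.
#' @param cell_size Cell side in meters.
#' @param threshold Height threshold in meters (> 0, default 5; `>=` is
#'   inclusive).
#' @param nonforest_mask Optional logical matrix, same shape; `TRUE` cells are
#'   forced to non-habitat regardless of height.
#' @param xll,yll Lower-left corner coordinates, meters.
#' @return A [binary_landscape()].
#' @examples
#' binarize_forest(matrix(c(6, 5, 4, 0), 2, 2), cell_size = 30)
#' @export
binarize_forest <- function(height_grid, cell_size, threshold = 5,
                            nonforest_mask = NULL, xll = 0, yll = 0) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number (meters)", call. = FALSE)
  }
  if (!is.matrix(height_grid)) stop("`height_grid` must be a matrix", call. = FALSE)
  if (is.null(nonforest_mask)) {
    nonforest_mask <- matrix(FALSE, nrow(height_grid), ncol(height_grid))
  }
  if (!identical(dim(nonforest_mask), dim(height_grid))) {
    stop("`nonforest_mask` shape does not match `height_grid`", call. = FALSE)
  }
  if (any(!is.finite(height_grid[!nonforest_mask]))) {
    stop("`height_grid` must be finite wherever unmasked", call. = FALSE)
  }
  cells <- (height_grid >= threshold) & !nonforest_mask
  binary_landscape(cells, cell_size = cell_size, xll = xll, yll = yll)
}

#' Extract a circular landscape around a point
#'
#' Cells whose centers lie within `radius_m` of `center` (inclusive) keep their
#' state; all other cells become outside (`NA`). The grid is cropped to the
#' circle's bounding box. By default the full circle must fit inside the source
#' grid extent; an out-of-extent circle is an error rather than a silent
#' truncation, unless `partial = TRUE`.
#'
#' @param ls A [binary_landscape()] covering the region.
#' @param center Numeric length-2, the `(x, y)` center in meters.
#' @param radius_m Landscape radius in meters.
#' @param partial If `TRUE`, allow the circle to extend beyond the grid and
#'   clip it to the available cells.
#' @return A [binary_landscape()] with `radius_m` recorded.
#' @export
delineate_landscape <- function(ls, center, radius_m, partial = FALSE) {
  stopifnot(inherits(ls, "binary_landscape"), length(center) == 2L)
  if (!is.numeric(radius_m) || length(radius_m) != 1L || radius_m <= 0) {
    stop("`radius_m` must be a single positive number", call. = FALSE)
  }
  cs <- ls$cell_size
  xmax <- ls$xll + ncol(ls$cells) * cs
  ymax <- ls$yll + nrow(ls$cells) * cs
  if (!partial &&
      (center[1] - radius_m < ls$xll || center[1] + radius_m > xmax ||
       center[2] - radius_m < ls$yll || center[2] + radius_m > ymax)) {
    stop(sprintf(paste0("circle of radius %g m around (%g, %g) exceeds the grid",
                        " extent [%g, %g] x [%g, %g]"),
                 radius_m, center[1], center[2], ls$xll, xmax, ls$yll, ymax),
         call. = FALSE)
  }
  cx <- cell_center_x(ls)
  cy <- cell_center_y(ls)
  keep_c <- which(cx >= center[1] - radius_m & cx <= center[1] + radius_m)
  keep_r <- which(cy >= center[2] - radius_m & cy <= center[2] + radius_m)
  if (length(keep_c) == 0L || length(keep_r) == 0L) {
    stop("no cell centers fall within the requested circle", call. = FALSE)
  }
  cells <- ls$cells[keep_r, keep_c, drop = FALSE]
  d2 <- outer((cy[keep_r] - center[2])^2, (cx[keep_c] - center[1])^2, "+")
  cells[d2 > radius_m^2] <- NA_integer_
  if (all(is.na(cells))) {
    stop("no cell centers fall within the requested circle", call. = FALSE)
  }
  binary_landscape(cells, cell_size = cs,
                   xll = ls$xll + (min(keep_c) - 1) * cs,
                   yll = ls$yll + (nrow(ls$cells) - max(keep_r)) * cs,
                   radius_m = radius_m)
}

#' Plot a binary landscape
#'
#' @param object A [binary_landscape()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.binary_landscape <- function(object, ...) {
  cx <- cell_center_x(object)
  cy <- cell_center_y(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(object$cells)),
                           col = seq_len(ncol(object$cells)))
  df$x <- cx[df$col]
  df$y <- cy[df$row]
  df$state <- factor(
    ifelse(is.na(object$cells[cbind(df$row, df$col)]), "outside",
           ifelse(object$cells[cbind(df$row, df$col)] == 1L, "habitat", "non-habitat")),
    levels = c("habitat", "non-habitat", "outside")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(habitat = "#1b7837",
                                          `non-habitat` = "#f7f7f7",
                                          outside = "grey70"),
                               drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = NULL)
}

#' @export
plot.binary_landscape <- function(x, ...) print(autoplot(x, ...))
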