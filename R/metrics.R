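#' Label habitat patches
#'
#' Connected-component labeling of habitat cells. Two habitat cells share a
#' label iff they are connected through habitat cells under the chosen
#' adjacency; non-habitat and outside cells get label 0. Labels are contiguous
#' `1..n_patches`, assigned in row-major first-encounter order.
#'
#' @param ls A [binary_landscape()].
#' @param connectivity Cell adjacency: `8` (queen, the common FRAGSTATS
#'   convention; default) or `4` (rook).
#' @return A `patch_labeling`: list with `labels` (integer matrix), `n_patches`,
#'   and `patch_sizes` (cells per patch, indexed by label).
#' @examples
#' ls <- binary_landscape(diag(2), cell_size = 30)
#' label_patches(ls, connectivity = 8)$n_patches # 1
#' label_patches(ls, connectivity = 4)$n_patches # 2
#' @export
label_patches <- function(ls, connectivity = 8) {
  stopifnot(inherits(ls, "binary_landscape"))
  connectivity <- check_connectivity(connectivity)
  out <- label_patches_cpp(ls$cells, connectivity)
  structure(list(labels = out$labels, n_patches = out$n_patches,
                 patch_sizes = as.integer(out$patch_sizes)),
            class = "patch_labeling")
}

check_connectivity <- function(connectivity) {
  if (!length(connectivity) == 1L || !connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  as.integer(connectivity)
}

#' Remove small habitat patches
#'
#' Converts every habitat patch of at most `max_cells` cells to non-habitat,
#' leaving larger patches untouched. Used as a sensitivity filter against
#' single, isolated pixels that are more likely to be classification errors
#' than real forest. `max_cells = 0` (the default) is a no-op.
#'
#' @inheritParams label_patches
#' @param max_cells Patches of this many cells or fewer are removed (>= 0).
#' @return A [binary_landscape()].
#' @export
remove_small_patches <- function(ls, max_cells = 0, connectivity = 8) {
  stopifnot(inherits(ls, "binary_landscape"))
  if (!is.numeric(max_cells) || length(max_cells) != 1L || max_cells < 0) {
    stop("`max_cells` must be a single non-negative number", call. = FALSE)
  }
  if (max_cells == 0) return(ls)
  lab <- label_patches(ls, connectivity)
  drop <- which(lab$patch_sizes <= max_cells)
  if (length(drop)) {
    ls$cells[lab$labels %in% drop] <- 0L
  }
  ls
}

#' Proportion of the landscape in habitat
#'
#' Habitat cells divided by all non-outside cells, in `[0, 1]`.
#'
#' @inheritParams label_patches
#' @return A fraction in `[0, 1]`.
#' @export
proportion_habitat <- function(ls) {
  stopifnot(inherits(ls, "binary_landscape"))
  n_habitat(ls) / n_inside(ls)
}

#' Edge density of the habitat / non-habitat boundary
#'
#' Total length of shared boundaries between rook-adjacent habitat and
#' non-habitat cell pairs, in meters per hectare of landscape. Both cells of a
#' pair must lie inside the landscape: the circular landscape boundary itself
#' contributes no edge, so a fully forested window has edge density zero.
#'
#' @inheritParams label_patches
#' @return Meters of edge per hectare (>= 0).
#' @export
edge_density <- function(ls) {
  stopifnot(inherits(ls, "binary_landscape"))
  n_edges <- count_edge_pairs(ls$cells)
  n_edges * ls$cell_size / landscape_area_ha(ls)
}

# unordered rook-adjacent {habitat, non-habitat} pairs, both inside
count_edge_pairs <- function(m) {
  h <- !is.na(m) & m == 1L
  n <- !is.na(m) & m == 0L
  nr <- nrow(m); nc <- ncol(m)
  horiz <- if (nc > 1) sum((h[, -1] & n[, -nc]) | (n[, -1] & h[, -nc])) else 0L
  vert <- if (nr > 1) sum((h[-1, ] & n[-nr, ]) | (n[-1, ] & h[-nr, ])) else 0L
  horiz + vert
}

#' Mean patch size in hectares
#'
#' Total habitat area divided by patch count. Defined as 0 ha when there are no
#' patches, so the conservation identity
#' `n_patches * mean_patch_size == p_habitat * landscape_area_ha` holds for
#' every landscape including those that lost all habitat.
#'
#' @param labeling A `patch_labeling` from [label_patches()].
#' @param cell_size Cell side in meters.
#' @return Hectares (>= 0).
#' @export
mean_patch_size <- function(labeling, cell_size) {
  stopifnot(inherits(labeling, "patch_labeling"))
  if (labeling$n_patches == 0L) return(0)
  (sum(labeling$patch_sizes) / labeling$n_patches) * cell_size^2 / 1e4
}

#' Compute the four fragmentation measures for one landscape
#'
#' Bundles proportion of habitat, patch number, edge density (m/ha) and mean
#' patch size (ha) — all derived from a single labeling pass — plus the
#' landscape area in hectares.
#'
#' @inheritParams label_patches
#' @return A one-row tibble with columns `p_habitat`, `n_patches`,
#'   `edge_density`, `mean_patch_size`, `landscape_area_ha`.
#' @examples
#' ls <- binary_landscape(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3),
#'                        cell_size = 30)
#' compute_metrics(ls)
#' @export
compute_metrics <- function(ls, connectivity = 8) {
  stopifnot(inherits(ls, "binary_landscape"))
  lab <- label_patches(ls, connectivity)
  tibble::tibble(
    p_habitat = proportion_habitat(ls),
    n_patches = lab$n_patches,
    edge_density = edge_density(ls),
    mean_patch_size = mean_patch_size(lab, ls$cell_size),
    landscape_area_ha = landscape_area_ha(ls)
  )
}
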