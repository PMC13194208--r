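#' The seven forested biomes used as grouping strata
#'
#' @format Character vector of length 7.
#' @export
forest_biomes <- c(
  "Tropical & Subtropical Moist Broadleaf Forests",
  "Tropical & Subtropical Dry Broadleaf Forests",
  "Tropical & Subtropical Coniferous Forests",
  "Temperate Broadleaf & Mixed Forests",
  "Temperate Conifer Forests",
  "Boreal Forests/Taiga",
  "Mediterranean Forests, Woodlands & Scrub"
)

#' Generate a spatially autocorrelated binary landscape
#'
#' Neutral landscape model by spectral synthesis: Gaussian white noise is
#' filtered in the Fourier domain so the power spectrum decays as
#' \eqn{f^{-roughness}}, then the surface is thresholded at its empirical
#' `(1 - p)` quantile (rank thresholding), so the realized habitat proportion
#' equals `p` to within half a cell in `n^2`. `roughness = 0` gives white
#' noise (many small patches); larger values give smoother, more aggregated
#' habitat. Deterministic given `(n, p, roughness, seed)`.
#'
#' @param n Cells per side (>= 8).
#' @param cell_size Cell side in meters (default 30, Landsat-like).
#' @param p Target habitat proportion in (0, 1).
#' @param roughness Spectral exponent (>= 0) controlling spatial
#'   autocorrelation.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG state.
#' @param xll,yll Lower-left corner coordinates, meters.
#' @return A [binary_landscape()].
#' @examples
#' ls <- gen_fractal_landscape(32, p = 0.5, roughness = 2, seed = 1)
#' proportion_habitat(ls)
#' @export
gen_fractal_landscape <- function(n, cell_size = 30, p = 0.5, roughness = 2,
                                  seed = NULL, xll = 0, yll = 0) {
  if (n < 8) stop("`n` must be at least 8", call. = FALSE)
  if (p <= 0 || p >= 1) stop("`p` must lie strictly in (0, 1)", call. = FALSE)
  if (roughness < 0) stop("`roughness` must be non-negative", call. = FALSE)
  gen <- function() {
    white <- matrix(stats::rnorm(n * n), n, n)
    kk <- 0:(n - 1)
    kk[kk > n / 2] <- kk[kk > n / 2] - n
    fr <- kk / n
    f <- sqrt(outer(fr^2, fr^2, "+"))
    filt <- ifelse(f == 0, 0, f^(-roughness / 2))
    surf <- Re(stats::fft(stats::fft(white) * filt, inverse = TRUE)) / (n * n)
    k <- round(p * n * n)
    cells <- matrix(0L, n, n)
    cells[order(surf, decreasing = TRUE)[seq_len(k)]] <- 1L
    binary_landscape(cells, cell_size = cell_size, xll = xll, yll = yll)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Define a habitat-loss scenario
#'
#' A named, parameterized process that removes habitat between the two time
#' points. The five kinds reproduce qualitatively distinct spatial patterns of
#' loss:
#' \describe{
#'   \item{random}{removes `ceiling(f * H)` habitat cells uniformly without
#'     replacement (`H` = habitat cells at t0, `f` = `target_fraction`).}
#'   \item{erosion}{repeatedly removes the habitat cell with the most rook
#'     non-habitat neighbors (edge-inward attrition; ties broken in row-major
#'     order) until the target is met.}
#'   \item{patch_removal}{removes whole patches in increasing size order (ties
#'     by lowest label) while the cumulative removal stays within the target;
#'     never splits a patch.}
#'   \item{dissection}{removes a randomly placed full row or column strip of
#'     width `max(1, round(f * H / n))`, clipped to the target cell count —
#'     a road-like cut.}
#'   \item{perforation}{removes cells only from patch interiors (habitat cells
#'     whose four rook neighbors are all habitat), one at a time uniformly at
#'     random, until the target is met or no interior cells remain.}
#' }
#'
#' @param kind One of `"random"`, `"erosion"`, `"patch_removal"`,
#'   `"dissection"`, `"perforation"`.
#' @param target_fraction Fraction of t0 habitat cells to remove, in (0, 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `loss_scenario` object.
#' @export
loss_scenario <- function(kind = c("random", "erosion", "patch_removal",
                                   "dissection", "perforation"),
                          target_fraction, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      target_fraction <= 0 || target_fraction >= 1) {
    stop("`target_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(kind = kind, target_fraction = target_fraction, seed = seed),
            class = "loss_scenario")
}

#' Apply a habitat-loss scenario to a landscape
#'
#' Removes habitat according to the scenario (habitat is only ever removed,
#' never created). Returns the modified landscape together with the realized
#' removal fraction (removed cells / t0 habitat cells), which can fall short of
#' the target for `patch_removal` (whole patches only) and `perforation`
#' (interior cells can run out).
#'
#' @param ls A [binary_landscape()] with at least one habitat cell.
#' @param scenario A [loss_scenario()].
#' @param connectivity Patch adjacency for `patch_removal` (default 8).
#' @return List with `landscape` (a [binary_landscape()]),
#'   `realized_fraction`, and `removed_cells`.
#' @export
apply_loss <- function(ls, scenario, connectivity = 8) {
  stopifnot(inherits(ls, "binary_landscape"), inherits(scenario, "loss_scenario"))
  H <- n_habitat(ls)
  if (H == 0L) stop("landscape has no habitat to remove", call. = FALSE)
  run <- function() {
    f <- scenario$target_fraction
    removed <- switch(scenario$kind,
      random = loss_random(ls$cells, f, H),
      erosion = loss_erosion(ls$cells, f, H),
      patch_removal = loss_patch_removal(ls, f, H, connectivity),
      dissection = loss_dissection(ls$cells, f, H),
      perforation = loss_perforation(ls$cells, f, H)
    )
    out <- ls
    out$cells[removed] <- 0L
    list(landscape = out, realized_fraction = length(removed) / H,
         removed_cells = length(removed))
  }
  if (is.null(scenario$seed)) run() else withr::with_seed(scenario$seed, run())
}

# -- loss kinds: each returns linear indices of cells to remove ---------------

resample <- function(x, k) x[sample.int(length(x), k)]

loss_random <- function(m, f, H) {
  resample(which(!is.na(m) & m == 1L), ceiling(f * H))
}

# row-major rank of a column-major linear index, for deterministic tie-breaks
row_major_rank <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr
  c <- (idx - 1L) %/% nr
  r * nc + c
}

pad_shift <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rd <- seq_len(nr)[seq_len(nr) + dr >= 1 & seq_len(nr) + dr <= nr]
  cd <- seq_len(nc)[seq_len(nc) + dc >= 1 & seq_len(nc) + dc <= nc]
  out[rd, cd] <- m[rd + dr, cd + dc]
  out
}

rook_neighbor_count <- function(mask) {
  pad_shift(mask, -1, 0) + pad_shift(mask, 1, 0) +
    pad_shift(mask, 0, -1) + pad_shift(mask, 0, 1)
}

loss_erosion <- function(m, f, H) {
  target <- ceiling(f * H)
  nr <- nrow(m); nc <- ncol(m)
  removed <- integer(target)
  for (i in seq_len(target)) {
    hab_idx <- which(!is.na(m) & m == 1L)
    if (length(hab_idx) == 0L) { removed <- removed[seq_len(i - 1L)]; break }
    score <- rook_neighbor_count(!is.na(m) & m == 0L)[hab_idx]
    cand <- hab_idx[score == max(score)]
    pick <- cand[which.min(row_major_rank(cand, nr, nc))]
    m[pick] <- 0L
    removed[i] <- pick
  }
  removed
}

loss_patch_removal <- function(ls, f, H, connectivity) {
  lab <- label_patches(ls, connectivity)
  ord <- order(lab$patch_sizes, seq_along(lab$patch_sizes))
  target_cells <- f * H
  cum <- 0
  take <- integer(0)
  for (p in ord) {
    if (cum + lab$patch_sizes[p] > target_cells) break
    cum <- cum + lab$patch_sizes[p]
    take <- c(take, p)
  }
  if (length(take) == 0L) {
    warning("smallest patch exceeds the removal target; nothing removed",
            call. = FALSE)
    return(integer(0))
  }
  which(lab$labels %in% take)
}

loss_dissection <- function(m, f, H) {
  target <- ceiling(f * H)
  by_row <- sample(c(TRUE, FALSE), 1)
  nlines <- if (by_row) nrow(m) else ncol(m)
  linelen <- if (by_row) ncol(m) else nrow(m)
  w <- max(1L, as.integer(round(f * H / linelen)))
  w <- min(w, nlines)
  start <- sample.int(nlines - w + 1L, 1)
  strip <- matrix(FALSE, nrow(m), ncol(m))
  if (by_row) strip[start:(start + w - 1L), ] <- TRUE
  else strip[, start:(start + w - 1L)] <- TRUE
  cand <- which(strip & !is.na(m) & m == 1L)
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[order(row_major_rank(cand, nrow(m), ncol(m)))]
  cand[seq_len(min(target, length(cand)))]
}

loss_perforation <- function(m, f, H) {
  target <- ceiling(f * H)
  removed <- integer(0)
  for (i in seq_len(target)) {
    hab <- !is.na(m) & m == 1L
    interior <- which(hab & rook_neighbor_count(hab) == 4L)
    if (length(interior) == 0L) break
    pick <- resample(interior, 1L)
    m[pick] <- 0L
    removed <- c(removed, pick)
  }
  removed
}

#' Configure a synthetic two-year landscape cohort
#'
#' Defines the conditions for a simulated study: how many landscapes, the grid
#' and cell geometry, the ranges that per-landscape habitat proportion,
#' autocorrelation and loss magnitude are drawn from, the mixture of loss
#' scenarios, the landscape radii, and the biome strata. Defaults give a
#' Landsat-like 30 m grid, habitat cover between 0.15 and 0.85, per-landscape
#' loss between 0.02 and 0.30 (large losses are rare in observed forest
#' change), an equal mixture of the five loss kinds, and radii of 250 and
#' 500 m that fit inside the default 64-cell grid.
#'
#' @param n_landscapes Number of landscapes.
#' @param grid_cells Cells per grid side.
#' @param cell_size Cell side in meters.
#' @param p_range Range habitat proportion is drawn from (uniform), in (0, 1).
#' @param roughness_range Range the spectral exponent is drawn from (uniform).
#' @param scenario_weights Named mixture weights over the five loss kinds;
#'   must sum to 1.
#' @param loss_range Range the target loss fraction is drawn from (uniform),
#'   in (0, 1).
#' @param radii Landscape radii in meters, positive and strictly increasing;
#'   every circle must fit inside the grid.
#' @param biomes Biome labels landscapes are assigned to (uniformly).
#' @param connectivity Patch adjacency used throughout.
#' @param seed Master seed; per-landscape seed = master seed + landscape index.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_landscapes = 500, grid_cells = 64, cell_size = 30,
                          p_range = c(0.15, 0.85),
                          roughness_range = c(0.5, 3),
                          scenario_weights = c(random = 0.2, erosion = 0.2,
                                               patch_removal = 0.2,
                                               dissection = 0.2,
                                               perforation = 0.2),
                          loss_range = c(0.02, 0.3),
                          radii = c(250, 500),
                          biomes = forest_biomes,
                          connectivity = 8,
                          seed = 1) {
  stopifnot(n_landscapes >= 1, grid_cells >= 8, cell_size > 0,
            length(p_range) == 2, all(p_range > 0 & p_range < 1),
            length(roughness_range) == 2, all(roughness_range >= 0),
            length(loss_range) == 2, all(loss_range > 0 & loss_range < 1),
            length(radii) >= 1, all(radii > 0), !is.unsorted(radii, strictly = TRUE),
            length(biomes) >= 1)
  kinds <- c("random", "erosion", "patch_removal", "dissection", "perforation")
  if (is.null(names(scenario_weights)) ||
      !all(names(scenario_weights) %in% kinds)) {
    stop("`scenario_weights` must be named with loss-scenario kinds", call. = FALSE)
  }
  if (abs(sum(scenario_weights) - 1) > 1e-8) {
    stop("`scenario_weights` must sum to 1", call. = FALSE)
  }
  extent <- grid_cells * cell_size
  if (2 * max(radii) + cell_size > extent) {
    stop(sprintf("largest radius (%g m) does not fit in a %g m grid",
                 max(radii), extent), call. = FALSE)
  }
  structure(list(n_landscapes = as.integer(n_landscapes),
                 grid_cells = as.integer(grid_cells), cell_size = cell_size,
                 p_range = p_range, roughness_range = roughness_range,
                 scenario_weights = scenario_weights, loss_range = loss_range,
                 radii = radii, biomes = biomes,
                 connectivity = check_connectivity(connectivity),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a paired-year synthetic cohort
#'
#' For each landscape: draw habitat proportion, roughness, loss scenario, loss
#' magnitude and biome from the config; synthesize the t0 landscape; apply the
#' loss to produce t1; delineate circular landscapes at every radius around
#' the grid center; and compute the four fragmentation measures for both
#' years. All randomness for landscape `i` runs under seed
#' `config$seed + i`, so the cohort is reproducible cell-for-cell from the
#' master seed alone.
#'
#' @param config A [cohort_config()].
#' @param keep_landscapes If `TRUE`, attach the full-grid t0/t1 landscapes as
#'   attribute `"landscapes"` (a list of pairs) for plotting or export.
#' @return A tibble with one row per landscape x radius: identifiers and draw
#'   parameters (`id`, `seed`, `biome`, `scenario`, `p_target`, `roughness`,
#'   `target_fraction`, `realized_fraction`), `radius_m`, and the paired
#'   metric columns `p_habitat_t0/t1`, `n_patches_t0/t1`,
#'   `edge_density_t0/t1`, `mean_patch_size_t0/t1`, `landscape_area_ha`.
#' @export
gen_cohort <- function(config, keep_landscapes = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  center <- rep(config$grid_cells * config$cell_size / 2, 2)
  kinds <- names(config$scenario_weights)
  landscapes <- if (keep_landscapes) vector("list", config$n_landscapes)
  rows <- purrr::map(seq_len(config$n_landscapes), function(i) {
    seed_i <- config$seed + i
    withr::with_seed(seed_i, {
      p <- stats::runif(1, config$p_range[1], config$p_range[2])
      rough <- stats::runif(1, config$roughness_range[1], config$roughness_range[2])
      kind <- sample(kinds, 1, prob = config$scenario_weights)
      f <- stats::runif(1, config$loss_range[1], config$loss_range[2])
      biome <- sample(config$biomes, 1)
      ls0 <- gen_fractal_landscape(config$grid_cells, config$cell_size,
                                   p = p, roughness = rough, seed = NULL)
      loss <- suppressWarnings(
        apply_loss(ls0, loss_scenario(kind, f, seed = NULL),
                   connectivity = config$connectivity)
      )
      if (keep_landscapes) {
        landscapes[[i]] <<- list(t0 = ls0, t1 = loss$landscape)
      }
      purrr::map(config$radii, function(r) {
        d0 <- delineate_landscape(ls0, center, r)
        d1 <- delineate_landscape(loss$landscape, center, r)
        m0 <- compute_metrics(d0, config$connectivity)
        m1 <- compute_metrics(d1, config$connectivity)
        dplyr::bind_cols(
          tibble::tibble(id = sprintf("L%04d", i), seed = seed_i,
                         biome = biome, scenario = kind, p_target = p,
                         roughness = rough, target_fraction = f,
                         realized_fraction = loss$realized_fraction,
                         radius_m = r),
          dplyr::rename_with(m0[, 1:4], ~ paste0(.x, "_t0")),
          dplyr::rename_with(m1[, 1:4], ~ paste0(.x, "_t1")),
          m0[, "landscape_area_ha"]
        )
      }) |> purrr::list_rbind()
    })
  }) |> purrr::list_rbind()
  if (keep_landscapes) attr(rows, "landscapes") <- landscapes
  rows
}
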