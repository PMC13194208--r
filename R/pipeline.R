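#' Per-landscape fragmentation measurements for sampled points
#'
#' For every sample point, radius and year: delineate the circular landscape
#' and compute the four fragmentation measures. Points whose circle does not
#' fit inside a raster's extent are refused (with a logged reason), not
#' silently truncated.
#'
#' @param rasters Named list of [binary_landscape()] region grids, one per
#'   year (e.g. `list(t0 = ..., t1 = ...)`; names become the `year` column,
#'   earliest first by name order as given).
#' @param points Tibble with columns `id`, `x`, `y`, optional `biome` (see
#'   [read_points_csv()]).
#' @param radii Landscape radii in meters, positive and strictly increasing.
#' @param connectivity Patch adjacency (default 8).
#' @param min_patch_cells Isolated-patch filter: habitat patches of at most
#'   this many cells are removed before measurement (0 = off).
#' @param verbose Print per-stage counts.
#' @return A tibble with one row per id x radius x year (`id`, `biome`,
#'   `radius_m`, `year`, the four measures, `landscape_area_ha`); refused
#'   combinations are attached as attribute `"refused"`.
#' @export
pipeline_metrics <- function(rasters, points, radii = c(250, 500, 1000, 2500,
                                                        5000, 10000),
                             connectivity = 8, min_patch_cells = 0,
                             verbose = TRUE) {
  stopifnot(is.list(rasters), length(rasters) >= 1,
            all(vapply(rasters, inherits, TRUE, "binary_landscape")))
  if (is.null(names(rasters)) || any(names(rasters) == "")) {
    stop("`rasters` must be a named list (one name per year)", call. = FALSE)
  }
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE)) {
    stop("`radii` must be positive and strictly increasing", call. = FALSE)
  }
  if (!"biome" %in% names(points)) points$biome <- NA_character_
  refused <- list()
  rows <- purrr::map(names(rasters), function(yr) {
    grid <- rasters[[yr]]
    if (min_patch_cells > 0) {
      grid <- remove_small_patches(grid, min_patch_cells, connectivity)
    }
    purrr::map(seq_len(nrow(points)), function(i) {
      purrr::map(radii, function(r) {
        d <- tryCatch(
          delineate_landscape(grid, c(points$x[i], points$y[i]), r),
          error = function(e) e
        )
        if (inherits(d, "error")) {
          refused[[length(refused) + 1L]] <<- tibble::tibble(
            id = points$id[i], radius_m = r, year = yr,
            reason = conditionMessage(d))
          return(NULL)
        }
        dplyr::bind_cols(
          tibble::tibble(id = points$id[i], biome = points$biome[i],
                         radius_m = r, year = yr),
          compute_metrics(d, connectivity)
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  refused <- if (length(refused)) purrr::list_rbind(refused) else
    tibble::tibble(id = character(), radius_m = numeric(), year = character(),
                   reason = character())
  if (verbose) {
    message(sprintf("measured %d landscape-years (%d points x %d radii x %d years), refused %d",
                    nrow(rows), nrow(points), length(radii), length(rasters),
                    nrow(refused)))
    for (j in seq_len(nrow(refused))) {
      message(sprintf("  refused id=%s radius=%g year=%s: %s", refused$id[j],
                      refused$radius_m[j], refused$year[j], refused$reason[j]))
    }
  }
  attr(rows, "refused") <- refused
  rows
}

#' Change analysis on paired-year metrics
#'
#' Takes a long metrics table (as produced by [pipeline_metrics()], two years)
#' or a wide paired-year record table (as produced by [gen_cohort()]), and
#' runs the change analysis: loss and per-metric deltas, retention of losing
#' landscapes, fragmentation-index fitting per radius on the retained cohort,
#' classification, and outcome summaries for every requested grouping.
#'
#' @param metrics Long table with a `year` column (exactly two distinct
#'   values; the earlier sorts first), or a wide `*_t0`/`*_t1` record table.
#' @param groupings Which outcome groupings to tabulate.
#' @param eps No-change tolerance for continuous metrics.
#' @param fence_k,capped,lower_fence_sign,norm Passed to [add_ffi()].
#' @param verbose Print per-stage counts.
#' @return List with `records` (classified, retained records), `summaries`
#'   (bound rows of [summarize_outcomes()] for each grouping), and
#'   `ffi_params` (per-radius fits).
#' @export
pipeline_change <- function(metrics,
                            groupings = c("radius", "cover_bin", "loss_bin",
                                          "biome"),
                            eps = 1e-9, fence_k = 1.5, capped = TRUE,
                            lower_fence_sign = c("minus", "plus"),
                            norm = c("per_year", "pooled"), verbose = TRUE) {
  lower_fence_sign <- match.arg(lower_fence_sign)
  norm <- match.arg(norm)
  groupings <- match.arg(groupings, several.ok = TRUE)
  records <- if ("year" %in% names(metrics)) widen_metrics(metrics) else metrics
  n_candidate <- nrow(records)
  records <- records |> add_change(eps = eps) |> retain_losing()
  if (nrow(records) == 0L) {
    stop("no landscapes lost habitat; nothing to analyze", call. = FALSE)
  }
  records <- add_ffi(records, fence_k = fence_k, capped = capped,
                     lower_fence_sign = lower_fence_sign, norm = norm,
                     eps = eps)
  if (verbose) {
    message(sprintf("candidate %d, retained (lost habitat) %d, refused %d",
                    n_candidate, nrow(records), n_candidate - nrow(records)))
  }
  # biome grouping only when biome labels exist
  if (!"biome" %in% names(records) || all(is.na(records$biome))) {
    groupings <- setdiff(groupings, "biome")
  }
  summaries <- purrr::map(groupings,
                          ~ summarize_outcomes(records, group_by = .x)) |>
    purrr::list_rbind()
  list(records = records, summaries = summaries,
       ffi_params = attr(records, "ffi_params"))
}

# long (id, radius_m, year, metrics) -> wide (*_t0 / *_t1) paired records
widen_metrics <- function(metrics) {
  years <- sort(unique(metrics$year))
  if (length(years) != 2L) {
    stop("change analysis needs exactly two years of metrics", call. = FALSE)
  }
  vals <- c("p_habitat", "n_patches", "edge_density", "mean_patch_size")
  metrics |>
    dplyr::mutate(year = ifelse(.data$year == years[1], "t0", "t1")) |>
    tidyr::pivot_wider(names_from = "year",
                       values_from = dplyr::all_of(vals),
                       names_sep = "_") |>
    dplyr::filter(stats::complete.cases(
      dplyr::pick(dplyr::ends_with("_t0"), dplyr::ends_with("_t1"))))
}

#' Simulate a cohort and run the full change analysis
#'
#' End-to-end driver: [gen_cohort()] then [pipeline_change()], optionally
#' writing the record and summary CSVs, a manifest of per-landscape draws, a
#' YAML sidecar echoing the configuration and seed, and (optionally) the
#' generated landscapes as ASCII grids. A single master seed reproduces every
#' output byte-for-byte.
#'
#' @param config A [cohort_config()].
#' @param out_dir If non-`NULL`, write `records.csv`, `summaries.csv`,
#'   `manifest.csv` and `run.yml` there.
#' @param write_rasters Also write each landscape's t0/t1 grids as `.asc`
#'   files under `out_dir/rasters/`.
#' @inheritParams pipeline_change
#' @return As [pipeline_change()], plus `manifest` (one row per landscape).
#' @export
pipeline_simulate <- function(config, out_dir = NULL, write_rasters = FALSE,
                              groupings = c("radius", "cover_bin", "loss_bin",
                                            "biome"),
                              eps = 1e-9, fence_k = 1.5, capped = TRUE,
                              lower_fence_sign = c("minus", "plus"),
                              norm = c("per_year", "pooled"), verbose = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- gen_cohort(config, keep_landscapes = write_rasters)
  manifest <- cohort |>
    dplyr::distinct(.data$id, .data$seed, .data$biome, .data$scenario,
                    .data$p_target, .data$roughness, .data$target_fraction,
                    .data$realized_fraction)
  res <- pipeline_change(cohort, groupings = groupings, eps = eps,
                         fence_k = fence_k, capped = capped,
                         lower_fence_sign = lower_fence_sign, norm = norm,
                         verbose = verbose)
  res$manifest <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    echo <- c(unclass(config),
              list(eps = eps, fence_k = fence_k, capped = capped,
                   lower_fence_sign = lower_fence_sign, norm = norm))
    echo$scenario_weights <- as.list(echo$scenario_weights)
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    readr::write_csv(res$records, file.path(out_dir, "records.csv"))
    readr::write_csv(res$summaries, file.path(out_dir, "summaries.csv"))
    yaml::write_yaml(echo, file.path(out_dir, "run.yml"))
    if (write_rasters) {
      rdir <- file.path(out_dir, "rasters")
      dir.create(rdir, showWarnings = FALSE)
      lss <- attr(cohort, "landscapes")
      for (i in seq_along(lss)) {
        write_asc(lss[[i]]$t0, file.path(rdir, sprintf("L%04d_t0.asc", i)))
        write_asc(lss[[i]]$t1, file.path(rdir, sprintf("L%04d_t1.asc", i)))
      }
    }
  }
  res
}
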