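#' Net habitat loss between two time points
#'
#' Proportion of the landscape in habitat at the first time point minus the
#' proportion at the second; positive values mean net loss.
#'
#' @param p_t0,p_t1 Habitat proportions in `[0, 1]` (vectorized).
#' @return Loss fractions in `[-1, 1]`.
#' @export
forest_loss <- function(p_t0, p_t1) {
  if (any(p_t0 < 0 | p_t0 > 1 | p_t1 < 0 | p_t1 > 1, na.rm = TRUE)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  p_t0 - p_t1
}

#' Classify a per-metric change in fragmentation terms
#'
#' Orients the raw change `value_t1 - value_t0` so that positive means more
#' fragmented — patch number, edge density and the composite index count as-is;
#' mean patch size is reversed (smaller mean patch size = more fragmented) —
#' then takes its sign. Oriented changes within `eps` of zero are `no_change`.
#' Patch number is an integer count, so its tolerance is forced to exact zero.
#'
#' @param delta Raw change(s), `value_t1 - value_t0`.
#' @param metric One of `"patch_number"`, `"edge_density"`,
#'   `"mean_patch_size"`, `"ffi"`.
#' @param eps Absolute no-change tolerance (>= 0) for the continuous metrics.
#' @return Factor with levels `increase`, `decrease`, `no_change`.
#' @examples
#' classify_change(-2, "patch_number")            # decrease
#' classify_change(0.4, "mean_patch_size")        # decrease (reversed sign)
#' classify_change(1e-15, "edge_density", 1e-9)   # no_change
#' @export
classify_change <- function(delta, metric, eps = 1e-9) {
  metric <- match.arg(metric, c("patch_number", "edge_density",
                                "mean_patch_size", "ffi"))
  if (!is.numeric(eps) || length(eps) != 1L || eps < 0) {
    stop("`eps` must be a single non-negative number", call. = FALSE)
  }
  if (metric == "patch_number") eps <- 0
  oriented <- if (metric == "mean_patch_size") -delta else delta
  factor(ifelse(abs(oriented) <= eps, "no_change",
                ifelse(oriented > 0, "increase", "decrease")),
         levels = c("increase", "decrease", "no_change"))
}

#' Bin habitat cover into fixed-width intervals
#'
#' Half-open bins `[0, w), [w, 2w), ...`; the top bin is closed so `p = 1` is
#' included.
#'
#' @param p Proportions in `[0, 1]`.
#' @param width Bin width (default 0.2).
#' @return Factor of bin labels such as `"[0.2,0.4)"`.
#' @examples
#' bin_cover(c(0.35, 0.2, 1))
#' @export
bin_cover <- function(p, width = 0.2) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  nb <- ceiling(1 / width)
  idx <- pmin(floor(p / width), nb - 1)
  lo <- idx * width
  hi <- pmin(lo + width, 1)
  labs_all <- {
    l <- (0:(nb - 1)) * width
    h <- pmin(l + width, 1)
    sprintf("[%g,%g%s", l, h, c(rep(")", nb - 1), "]"))
  }
  factor(sprintf("[%g,%g%s", lo, hi, ifelse(idx == nb - 1, "]", ")")),
         levels = labs_all)
}

#' Bin loss magnitude into fixed-width intervals
#'
#' Right-closed bins `(0, w], (w, 2w], ...` on `(0, 1]`; zero or negative loss
#' (no loss, or gain) maps to `NA`.
#'
#' @param loss Loss fractions.
#' @param width Bin width (default 0.1).
#' @return Factor of bin labels such as `"(0.1,0.2]"`.
#' @export
bin_loss <- function(loss, width = 0.1) {
  nb <- ceiling(1 / width)
  idx <- ifelse(loss > 0, pmin(ceiling(loss / width) - 1, nb - 1), NA)
  labs_all <- sprintf("(%g,%g]", (0:(nb - 1)) * width,
                      pmin((1:nb) * width, 1))
  factor(labs_all[idx + 1], levels = labs_all)
}

#' Derive loss, changes and classifications for paired-year records
#'
#' Adds to a paired-year record table: `forest_loss`
#' (`p_habitat_t0 - p_habitat_t1`), the raw per-metric changes
#' `delta_patch_number`, `delta_edge_density`, `delta_mean_patch_size`
#' (`value_t1 - value_t0`), their fragmentation-change classifications
#' `class_*` (via [classify_change()]), and the grouping bins `cover_bin`
#' (initial cover, width 0.2) and `loss_bin` (loss magnitude, width 0.1).
#'
#' @param records Tibble with columns `p_habitat_t0`, `p_habitat_t1`,
#'   `n_patches_t0`, `n_patches_t1`, `edge_density_*`, `mean_patch_size_*`.
#' @param eps Absolute no-change tolerance for the continuous metrics.
#' @param cover_width,loss_width Bin widths for the cover and loss groupings.
#' @return `records` with the derived columns appended.
#' @export
add_change <- function(records, eps = 1e-9, cover_width = 0.2, loss_width = 0.1) {
  records |>
    dplyr::mutate(
      forest_loss = forest_loss(.data$p_habitat_t0, .data$p_habitat_t1),
      delta_patch_number = .data$n_patches_t1 - .data$n_patches_t0,
      delta_edge_density = .data$edge_density_t1 - .data$edge_density_t0,
      delta_mean_patch_size = .data$mean_patch_size_t1 - .data$mean_patch_size_t0,
      class_patch_number = classify_change(.data$delta_patch_number,
                                           "patch_number", eps),
      class_edge_density = classify_change(.data$delta_edge_density,
                                           "edge_density", eps),
      class_mean_patch_size = classify_change(.data$delta_mean_patch_size,
                                              "mean_patch_size", eps),
      cover_bin = bin_cover(.data$p_habitat_t0, cover_width),
      loss_bin = bin_loss(.data$forest_loss, loss_width)
    )
}

#' Keep only landscapes that lost habitat
#'
#' Subsets to records with strictly positive `forest_loss`, preserving the
#' original order. Landscapes that gained habitat or did not change are
#' excluded from all change summaries.
#'
#' @param records Tibble with a `forest_loss` column (see [add_change()]).
#' @return The losing subset.
#' @export
retain_losing <- function(records) {
  if (!"forest_loss" %in% names(records)) {
    stop("`records` must have a `forest_loss` column; run add_change() first",
         call. = FALSE)
  }
  dplyr::filter(records, .data$forest_loss > 0)
}

group_cols <- c(radius = "radius_m", cover_bin = "cover_bin",
                loss_bin = "loss_bin", biome = "biome")

#' Summarize fragmentation-change outcomes by group
#'
#' For each group and fragmentation measure, the percentage of landscapes whose
#' fragmentation increased, decreased, or did not change. Groups with no
#' records are omitted; percentages sum to 100 within each row.
#'
#' @param records Classified records (after [add_change()], [retain_losing()],
#'   and optionally [add_ffi()]).
#' @param group_by One of `"radius"`, `"cover_bin"`, `"loss_bin"`, `"biome"`.
#' @param metrics Which measures to tabulate; defaults to every `class_*`
#'   column present.
#' @return Tibble with columns `group_var`, `group`, `metric`, `n`,
#'   `pct_increase`, `pct_decrease`, `pct_no_change`.
#' @export
summarize_outcomes <- function(records,
                               group_by = c("radius", "cover_bin", "loss_bin",
                                            "biome"),
                               metrics = NULL) {
  group_by <- match.arg(group_by)
  if (nrow(records) == 0L) {
    stop("no records to summarize (did every landscape gain habitat?)",
         call. = FALSE)
  }
  gcol <- group_cols[[group_by]]
  if (!gcol %in% names(records)) {
    stop(sprintf("records have no `%s` column", gcol), call. = FALSE)
  }
  class_cols <- grep("^class_", names(records), value = TRUE)
  if (!is.null(metrics)) class_cols <- paste0("class_", metrics)
  if (length(class_cols) == 0L || !all(class_cols %in% names(records))) {
    stop("requested classification columns are missing", call. = FALSE)
  }
  records |>
    dplyr::select(group = dplyr::all_of(gcol), dplyr::all_of(class_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(class_cols), names_to = "metric",
                        names_prefix = "class_", values_to = "class") |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::count(.data$group, .data$metric, .data$class, .drop = FALSE) |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::mutate(total = sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$total > 0) |>
    dplyr::mutate(pct = 100 * .data$n / .data$total) |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "class", values_from = "pct",
                       names_prefix = "pct_", values_fill = 0) |>
    dplyr::mutate(group_var = group_by, .before = 1) |>
    dplyr::rename(n = "total") |>
    dplyr::select("group_var", "group", "metric", "n", "pct_increase",
                  "pct_decrease", "pct_no_change") |>
    dplyr::arrange(.data$group, .data$metric) |>
    dplyr::mutate(group = as.character(.data$group))
}

#' Stacked-bar plot of outcome frequencies
#'
#' One bar per group and fragmentation measure, stacked by outcome
#' (increase / decrease / no change in fragmentation).
#'
#' @param summaries Output of [summarize_outcomes()].
#' @return A ggplot object.
#' @export
plot_outcomes <- function(summaries) {
  long <- summaries |>
    tidyr::pivot_longer(dplyr::starts_with("pct_"), names_to = "outcome",
                        names_prefix = "pct_", values_to = "pct") |>
    dplyr::mutate(outcome = factor(.data$outcome,
                                   levels = c("increase", "no_change", "decrease")))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$group), y = .data$pct,
                                     fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_manual(values = c(increase = "#d6604d",
                                          no_change = "grey80",
                                          decrease = "#4393c3")) +
    ggplot2::labs(x = unique(summaries$group_var),
                  y = "% of landscapes", fill = "fragmentation")
}

#' Scatter plot of fragmentation change against initial cover
#'
#' Oriented per-metric changes (positive = more fragmented; mean patch size is
#' reversed) against the initial habitat proportion, one panel per measure.
#'
#' @param records Classified records (after [add_change()]; include
#'   [add_ffi()] output to get the index panel).
#' @return A ggplot object.
#' @export
plot_change <- function(records) {
  delta_cols <- intersect(c("delta_patch_number", "delta_edge_density",
                            "delta_mean_patch_size", "delta_ffi"),
                          names(records))
  long <- records |>
    dplyr::select("p_habitat_t0", dplyr::all_of(delta_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(delta_cols), names_to = "metric",
                        names_prefix = "delta_", values_to = "delta") |>
    dplyr::mutate(oriented = ifelse(.data$metric == "mean_patch_size",
                                    -.data$delta, .data$delta))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$p_habitat_t0, y = .data$oriented)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "initial habitat proportion",
                  y = "change (positive = more fragmented)")
}
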