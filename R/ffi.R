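#' Tukey fences for outlier capping
#'
#' First and third quartiles (linear interpolation between order statistics,
#' `stats::quantile()` type 7), the interquartile range, and the fences used to
#' cap extreme values before normalization. The standard lower fence is
#' `Q1 - k * IQR`; `lower_fence_sign = "plus"` selects the `Q1 + k * IQR`
#' variant for literal fidelity to some published formulations.
#'
#' @param values Numeric vector, at least 2 finite values.
#' @param fence_k Fence multiplier (default 1.5).
#' @param lower_fence_sign `"minus"` (standard Tukey fence, default) or
#'   `"plus"`.
#' @param quantile_type Quantile estimator passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return List with `q1`, `q3`, `iqr`, `q_lower`, `q_upper`.
#' @examples
#' tukey_fences(c(1, 2, 3, 4, 5, 100)) # fences -1.5 and 8.5
#' @export
tukey_fences <- function(values, fence_k = 1.5,
                         lower_fence_sign = c("minus", "plus"),
                         quantile_type = 7) {
  lower_fence_sign <- match.arg(lower_fence_sign)
  if (length(values) < 2L) stop("need at least 2 values to fit fences", call. = FALSE)
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.75), type = quantile_type))
  iqr <- q[2] - q[1]
  sgn <- if (lower_fence_sign == "minus") -1 else 1
  list(q1 = q[1], q3 = q[2], iqr = iqr,
       q_lower = q[1] + sgn * fence_k * iqr,
       q_upper = q[2] + fence_k * iqr,
       fence_k = fence_k, lower_fence_sign = lower_fence_sign)
}

#' Winsorize values against fences
#'
#' Clamps each value into `[q_lower, q_upper]`; element order is preserved.
#'
#' @param values Numeric vector.
#' @param fences A list with `q_lower` and `q_upper`, as from [tukey_fences()].
#' @return Numeric vector, same length and order.
#' @export
winsorize <- function(values, fences) {
  pmin(pmax(values, fences$q_lower), fences$q_upper)
}

#' Min-max normalization to [0, 1]
#'
#' `(v - lo) / (hi - lo)`. When `hi == lo` the metric carries no information
#' and every value maps to the neutral 0.5, so a constant metric neither
#' inflates nor deflates a composite index built from it.
#'
#' @param values Numeric vector.
#' @param lo,hi Normalization bounds, `lo <= hi`.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values, lo, hi) {
  if (lo > hi) stop("`lo` must not exceed `hi`", call. = FALSE)
  if (hi == lo) return(rep(0.5, length(values)))
  (values - lo) / (hi - lo)
}

ffi_metrics <- c("patch_number", "edge_density", "mean_patch_size")
ffi_cols <- c(patch_number = "n_patches", edge_density = "edge_density",
              mean_patch_size = "mean_patch_size")

#' Fit fragmentation-index parameters on a two-year cohort
#'
#' Fits the capping and normalization parameters of the composite fragmentation
#' index for one landscape size. Tukey fences for patch number, edge density
#' and mean patch size are estimated from the later year's measurements only;
#' the same fences then cap both years' values (outlier influence is limited
#' without letting the earlier year move the thresholds). Normalization bounds
#' default to the min/max of each year's capped values (`norm = "per_year"`);
#' `norm = "pooled"` shares one set of bounds across years for strict
#' cross-year comparability. With `capped = FALSE` no fences are applied and
#' bounds are the raw per-year (or pooled) min/max.
#'
#' @param metrics_t1 Data frame of later-year measurements with columns
#'   `n_patches`, `edge_density`, `mean_patch_size` (one row per landscape).
#' @param metrics_t0 Data frame of earlier-year measurements, same columns.
#' @inheritParams tukey_fences
#' @param capped Apply Tukey-fence capping before normalization (default TRUE).
#' @param norm `"per_year"` (default) or `"pooled"` normalization bounds.
#' @return An object of class `ffi_params`.
#' @export
fit_ffi_params <- function(metrics_t1, metrics_t0, fence_k = 1.5, capped = TRUE,
                           lower_fence_sign = c("minus", "plus"),
                           norm = c("per_year", "pooled"), quantile_type = 7) {
  lower_fence_sign <- match.arg(lower_fence_sign)
  norm <- match.arg(norm)
  if (nrow(metrics_t1) == 0L || nrow(metrics_t0) == 0L) {
    stop("both cohorts must be non-empty", call. = FALSE)
  }
  per_metric <- lapply(ffi_metrics, function(m) {
    col <- ffi_cols[[m]]
    v1 <- metrics_t1[[col]]
    v0 <- metrics_t0[[col]]
    fences <- if (capped) {
      tukey_fences(v1, fence_k = fence_k, lower_fence_sign = lower_fence_sign,
                   quantile_type = quantile_type)
    } else NULL
    c1 <- if (capped) winsorize(v1, fences) else v1
    c0 <- if (capped) winsorize(v0, fences) else v0
    if (norm == "pooled") {
      lo <- min(c0, c1); hi <- max(c0, c1)
      bounds <- list(t0 = c(lo, hi), t1 = c(lo, hi))
    } else {
      bounds <- list(t0 = range(c0), t1 = range(c1))
    }
    list(fences = fences, bounds = bounds)
  })
  names(per_metric) <- ffi_metrics
  structure(list(metrics = per_metric, fence_k = fence_k, capped = capped,
                 lower_fence_sign = lower_fence_sign, norm = norm,
                 n_t0 = nrow(metrics_t0), n_t1 = nrow(metrics_t1)),
            class = "ffi_params")
}

#' @export
print.ffi_params <- function(x, ...) {
  cat(sprintf("<ffi_params> capped=%s, fence_k=%g, norm=%s (n_t0=%d, n_t1=%d)\n",
              x$capped, x$fence_k, x$norm, x$n_t0, x$n_t1))
  print(tidy(x))
  invisible(x)
}

# cap (if configured) and normalize one metric for one year
normalize_metric <- function(params, metric, values, year = c("t1", "t0")) {
  year <- match.arg(year)
  pm <- params$metrics[[metric]]
  if (is.null(pm)) stop("unknown metric: ", metric, call. = FALSE)
  v <- if (params$capped) winsorize(values, pm$fences) else values
  b <- pm$bounds[[year]]
  out <- minmax_normalize(v, b[1], b[2])
  # new data may fall outside the fitting cohort's bounds; keep components in [0,1]
  pmin(pmax(out, 0), 1)
}

#' Composite fragmentation index from normalized components
#'
#' `(PN + ED + (1 - MPA)) / 3` where PN, ED and MPA are the normalized patch
#' number, edge density and mean patch area. Mean patch area enters reversed:
#' smaller patches mean more fragmentation. The index lies in `[0, 1]`, higher
#' = more fragmented.
#'
#' @param pn_norm,ed_norm,mpa_norm Normalized components, each in `[0, 1]`.
#' @return Index values in `[0, 1]`.
#' @examples
#' ffi(1, 1, 0)       # 1, maximal fragmentation
#' ffi(0.2, 0.5, 0.8) # 0.3
#' @export
ffi <- function(pn_norm, ed_norm, mpa_norm) {
  comps <- cbind(pn_norm, ed_norm, mpa_norm)
  if (any(!is.finite(comps)) || any(comps < 0) || any(comps > 1)) {
    stop("all components must be finite and in [0, 1]", call. = FALSE)
  }
  unname((pn_norm + ed_norm + (1 - mpa_norm)) / 3)
}

#' Add fragmentation-index columns to a paired-year record table
#'
#' Fits [fit_ffi_params()] separately for each landscape size (`radius_m`) on
#' the supplied records, then appends normalized components and the composite
#' index for both years, its change `delta_ffi = ffi_t1 - ffi_t0`, and the
#' fragmentation-change classification `class_ffi`.
#'
#' @param records Tibble with paired-year metric columns (`n_patches_t0`,
#'   `n_patches_t1`, ...) and `radius_m`, typically from [gen_cohort()] after
#'   [retain_losing()].
#' @inheritParams fit_ffi_params
#' @param eps Absolute no-change tolerance for `class_ffi` (default 1e-9).
#' @return `records` with columns `pn_norm_*`, `ed_norm_*`, `mpa_norm_*`,
#'   `ffi_t0`, `ffi_t1`, `delta_ffi`, `class_ffi` added; the fitted
#'   `ffi_params` (one per radius) are attached as attribute `"ffi_params"`.
#' @export
add_ffi <- function(records, fence_k = 1.5, capped = TRUE,
                    lower_fence_sign = c("minus", "plus"),
                    norm = c("per_year", "pooled"), eps = 1e-9) {
  lower_fence_sign <- match.arg(lower_fence_sign)
  norm <- match.arg(norm)
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)
  params_by_radius <- list()
  out <- records |>
    dplyr::group_by(.data$radius_m) |>
    dplyr::group_modify(function(df, key) {
      p <- fit_ffi_params(
        metrics_t1 = dplyr::rename_with(df, ~ sub("_t1$", "", .x),
                                        dplyr::ends_with("_t1")),
        metrics_t0 = dplyr::rename_with(df, ~ sub("_t0$", "", .x),
                                        dplyr::ends_with("_t0")),
        fence_k = fence_k, capped = capped,
        lower_fence_sign = lower_fence_sign, norm = norm
      )
      params_by_radius[[as.character(key$radius_m)]] <<- p
      for (yr in c("t0", "t1")) {
        df[[paste0("pn_norm_", yr)]] <-
          normalize_metric(p, "patch_number", df[[paste0("n_patches_", yr)]], yr)
        df[[paste0("ed_norm_", yr)]] <-
          normalize_metric(p, "edge_density", df[[paste0("edge_density_", yr)]], yr)
        df[[paste0("mpa_norm_", yr)]] <-
          normalize_metric(p, "mean_patch_size", df[[paste0("mean_patch_size_", yr)]], yr)
        df[[paste0("ffi_", yr)]] <- ffi(df[[paste0("pn_norm_", yr)]],
                                        df[[paste0("ed_norm_", yr)]],
                                        df[[paste0("mpa_norm_", yr)]])
      }
      df$delta_ffi <- df$ffi_t1 - df$ffi_t0
      df$class_ffi <- classify_change(df$delta_ffi, "ffi", eps = eps)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("radius_m", .after = dplyr::last_col())
  # keep the caller's column order for the untouched columns
  out <- out[, c(intersect(names(records), names(out)),
                 setdiff(names(out), names(records)))]
  attr(out, "ffi_params") <- params_by_radius
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted fragmentation-index parameters
#'
#' @param x An `ffi_params` object.
#' @param ... Unused.
#' @return One row per metric: quartiles, IQR, fences (NA when uncapped) and
#'   per-year normalization bounds.
#' @export
tidy.ffi_params <- function(x, ...) {
  purrr::imap_dfr(x$metrics, function(pm, name) {
    f <- pm$fences
    tibble::tibble(
      metric = name,
      q1 = f$q1 %||% NA_real_, q3 = f$q3 %||% NA_real_,
      iqr = f$iqr %||% NA_real_,
      q_lower = f$q_lower %||% NA_real_, q_upper = f$q_upper %||% NA_real_,
      norm_lo_t0 = pm$bounds$t0[1], norm_hi_t0 = pm$bounds$t0[2],
      norm_lo_t1 = pm$bounds$t1[1], norm_hi_t1 = pm$bounds$t1[2]
    )
  })
}

#' One-row summary of a fragmentation-index fit
#'
#' @param x An `ffi_params` object.
#' @param ... Unused.
#' @return A one-row tibble with the fit configuration and cohort sizes.
#' @export
glance.ffi_params <- function(x, ...) {
  tibble::tibble(fence_k = x$fence_k, capped = x$capped,
                 lower_fence_sign = x$lower_fence_sign, norm = x$norm,
                 n_t0 = x$n_t0, n_t1 = x$n_t1)
}
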