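#' Box-counting fractal dimension of a release curve
#'
#' Estimates the "fractality degree" of a cumulative release curve: the
#' curve is min-max normalized to the unit square (so the estimate is
#' invariant to affine rescaling of either axis), linearly interpolated, and
#' the number of grid boxes `N(eps)` its graph occupies is counted for a
#' geometric ladder of box sizes. The dimension is the slope of
#' `log N(eps)` against `log(1/eps)`; the linear fit's R^2 is reported as a
#' scaling-quality diagnostic. A smooth curve gives a value near 1, a noisy
#' one pushes towards 2; the estimate is clamped to the planar-curve range
#' `[1, 2]`.
#'
#' @param curve A [release_curve()] or data frame with `time_min` and
#'   `mean_release`; at least 16 points.
#' @param box_sizes Box side lengths (unit-square fractions), at least 5
#'   scales. Default: 9 sizes geometrically spanning 1/4 to 1/64.
#' @return A one-row tibble: `drug`, `estimator`, `dimension`,
#'   `r_squared_loglog`, `scale_lo`, `scale_hi`, `n_scales`.
#' @seealso [higuchi_dimension()] for the curve-length cross-check,
#'   [drug_ordering()] for ranking drugs by fractality.
#' @export
box_counting_dimension <- function(curve,
                                   box_sizes = 1 / round(4 * 4^(seq(0, 2, length.out = 9)))) {
  curve <- as_release_curve(curve)
  if (nrow(curve) < 16) {
    abort("Need at least 16 points for a box-counting estimate.",
          class = "ocurel_domain_error")
  }
  if (length(box_sizes) < 5) {
    abort("Need at least 5 box sizes.", class = "ocurel_domain_error")
  }
  x <- curve$time_min
  y <- curve$mean_release
  x <- (x - min(x)) / diff(range(x))
  if (diff(range(y)) == 0) {
    abort("Cannot estimate the dimension of a constant curve.",
          class = "ocurel_domain_error")
  }
  y <- (y - min(y)) / diff(range(y))
  counts <- purrr::map_dbl(box_sizes, function(eps) {
    k <- max(1L, round(1 / eps))
    # columns of width 1/k; count the vertical box span of the
    # interpolated graph inside each column
    edges <- seq(0, 1, length.out = k + 1)
    xs <- sort(unique(c(x, edges)))
    ys <- approx(x, y, xout = xs, ties = "ordered")$y
    col <- pmin(pmax(ceiling(xs * k), 1L), k)
    # interior column-boundary points belong to both adjacent columns
    boundary <- xs %in% edges[c(-1, -(k + 1))]
    col2 <- c(col, col[boundary] + 1L)
    ys2 <- c(ys, ys[boundary])
    lo <- tapply(ys2, col2, min)
    hi <- tapply(ys2, col2, max)
    sum(floor(hi / eps - 1e-12) - floor(lo / eps + 1e-12) + 1)
  })
  fit <- lm(log(counts) ~ log(1 / box_sizes))
  slope <- coef(fit)[[2]]
  r2 <- suppressWarnings(summary(fit))$r.squared
  tibble(drug = attr(curve, "drug") %||% "drug",
         estimator = "boxcount",
         dimension = min(max(slope, 1), 2),
         r_squared_loglog = r2,
         scale_lo = min(box_sizes), scale_hi = max(box_sizes),
         n_scales = length(box_sizes))
}

#' Higuchi curve-length fractal dimension
#'
#' The classical curve-length estimator for a series sampled on a uniform
#' grid: for each delay `k = 1..k_max` the normalized mean curve length
#' `L(k)` is computed over the `k` decimated sub-series, and the dimension
#' is the slope of `log L(k)` versus `log(1/k)`. Brownian paths give ~1.5,
#' smooth curves ~1.
#'
#' @param series Numeric vector of release values on a uniform time grid,
#'   or a [release_curve()] whose `time_min` grid is uniform (checked).
#' @param k_max Maximum delay, `>= 4`. Default 8.
#' @return A one-row tibble in the same layout as
#'   [box_counting_dimension()] (`estimator = "higuchi"`; `scale_lo`,
#'   `scale_hi` are the delays used).
#' @export
higuchi_dimension <- function(series, k_max = 8L) {
  drug <- "series"
  if (is.data.frame(series)) {
    curve <- as_release_curve(series)
    dt <- diff(curve$time_min)
    if (max(dt) - min(dt) > 1e-8 * max(dt)) {
      abort("Time grid is not uniform; resample the curve first.",
            class = "ocurel_domain_error")
    }
    drug <- attr(curve, "drug") %||% "series"
    series <- curve$mean_release
  }
  n <- length(series)
  if (k_max < 4) {
    abort("`k_max` must be >= 4.", class = "ocurel_domain_error")
  }
  if (n < 4 * k_max) {
    abort("Series too short for the requested `k_max`.",
          class = "ocurel_domain_error")
  }
  ks <- seq_len(k_max)
  lk <- purrr::map_dbl(ks, function(k) {
    lengths_m <- purrr::map_dbl(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      nm <- length(idx)
      if (nm < 2) return(NA_real_)
      # normalization factor restores the full-series length scale
      sum(abs(diff(series[idx]))) * (n - 1) / ((nm - 1) * k)
    })
    mean(lengths_m, na.rm = TRUE) / k
  })
  fit <- lm(log(lk) ~ log(1 / ks))
  slope <- coef(fit)[[2]]
  tibble(drug = drug, estimator = "higuchi",
         dimension = min(max(slope, 1), 2),
         r_squared_loglog = suppressWarnings(summary(fit))$r.squared,
         scale_lo = 1, scale_hi = k_max, n_scales = k_max)
}

#' Estimate release-curve fractality with one or both estimators
#'
#' @param curve A [release_curve()] on a uniform time grid.
#' @param estimator `"boxcount"`, `"higuchi"` or `"both"`.
#' @param k_max Passed to [higuchi_dimension()].
#' @return A tibble with one row per estimator.
#' @export
estimate_fractality <- function(curve, estimator = c("both", "boxcount",
                                                     "higuchi"),
                                k_max = 8L) {
  estimator <- match.arg(estimator)
  out <- list()
  if (estimator %in% c("both", "boxcount")) {
    out <- c(out, list(box_counting_dimension(curve)))
  }
  if (estimator %in% c("both", "higuchi")) {
    out <- c(out, list(higuchi_dimension(curve, k_max = k_max)))
  }
  dplyr::bind_rows(out)
}

#' Order drugs by estimated fractality degree
#'
#' Sorts fractality estimates (all from the same estimator and scale range)
#' in descending dimension order -- the ordering used to rank the
#' complexity of drug-polymer interaction across formulations. Ties (equal
#' to 8 decimal places) are flagged.
#'
#' @param results A tibble of rows from [box_counting_dimension()] /
#'   [higuchi_dimension()], at least 2 rows, single estimator.
#' @return The input sorted by descending `dimension`, with a `rank` column
#'   and a `tied` logical column.
#' @export
drug_ordering <- function(results) {
  results <- as_tibble(results)
  if (nrow(results) < 2) {
    if (nrow(results) == 1) {
      return(dplyr::mutate(results, rank = 1L, tied = FALSE))
    }
    abort("Need at least one fractality result.",
          class = "ocurel_domain_error")
  }
  if (dplyr::n_distinct(results$estimator) != 1 ||
      dplyr::n_distinct(results$scale_lo) != 1 ||
      dplyr::n_distinct(results$scale_hi) != 1) {
    abort("All results must share one estimator and scale range.",
          class = "ocurel_domain_error")
  }
  out <- dplyr::arrange(results, dplyr::desc(.data$dimension), .data$drug)
  d <- round(out$dimension, 8)
  dplyr::mutate(out, rank = dplyr::row_number(),
                tied = duplicated(d) | duplicated(d, fromLast = TRUE))
}
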