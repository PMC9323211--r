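#' Construct a cumulative release curve
#'
#' A release curve is the replicate-averaged cumulative amount (or fraction)
#' of drug released into the bath versus time, the standard output of a
#' dialysis-bag release study. It is stored as a tibble with columns
#' `time_min`, `mean_release`, `sd_release` plus `drug`, `units` and
#' `n_replicates` attributes.
#'
#' @param times_min Strictly increasing, nonnegative sampling times
#'   (minutes).
#' @param mean_release Replicate-mean cumulative release at each time.
#'   Nonnegative; when `units = "fraction"` values must lie in `[0, 1.05]`
#'   (small overshoot from replicate noise is tolerated).
#' @param sd_release Replicate standard deviation at each time (same units);
#'   nonnegative. Default all zero.
#' @param drug Drug/formulation identifier.
#' @param units `"fraction"` of dose or a concentration/mass unit such as
#'   `"ug"` or `"ug/mL"`.
#' @param n_replicates Number of replicates behind the mean (default 3).
#' @return A tibble of class `release_curve`.
#' @export
release_curve <- function(times_min, mean_release, sd_release = NULL,
                          drug = "drug", units = "fraction",
                          n_replicates = 3L) {
  if (is.null(sd_release)) sd_release <- rep(0, length(times_min))
  if (length(times_min) != length(mean_release) ||
      length(times_min) != length(sd_release)) {
    abort("`times_min`, `mean_release`, `sd_release` must have equal length.",
          class = "ocurel_format_error")
  }
  if (any(!is.finite(times_min)) || any(times_min < 0) ||
      any(diff(times_min) <= 0)) {
    abort("`times_min` must be nonnegative and strictly increasing.",
          class = "ocurel_domain_error")
  }
  if (any(!is.finite(mean_release)) || any(mean_release < -1e-12)) {
    abort("`mean_release` must be nonnegative.",
          class = "ocurel_domain_error")
  }
  if (identical(units, "fraction") && any(mean_release > 1.05)) {
    abort("Fractional release must lie in [0, 1.05].",
          class = "ocurel_domain_error")
  }
  if (any(!is.finite(sd_release)) || any(sd_release < 0)) {
    abort("`sd_release` must be nonnegative.", class = "ocurel_domain_error")
  }
  if (n_replicates < 1) {
    abort("`n_replicates` must be a positive integer.",
          class = "ocurel_domain_error")
  }
  out <- tibble(time_min = as.double(times_min),
                mean_release = as.double(mean_release),
                sd_release = as.double(sd_release))
  attr(out, "drug") <- drug
  attr(out, "units") <- units
  attr(out, "n_replicates") <- as.integer(n_replicates)
  class(out) <- c("release_curve", class(out))
  out
}

as_release_curve <- function(x, drug = NULL, units = NULL,
                             n_replicates = NULL) {
  if (inherits(x, "release_curve") && is.null(drug) && is.null(units) &&
      is.null(n_replicates)) {
    return(x)
  }
  x <- as_tibble(x)
  if (!all(c("time_min", "mean_release") %in% names(x))) {
    abort("Need columns `time_min` and `mean_release`.",
          class = "ocurel_format_error")
  }
  release_curve(
    x$time_min, x$mean_release,
    sd_release = if ("sd_release" %in% names(x)) x$sd_release else NULL,
    drug = drug %||% attr(x, "drug") %||% "drug",
    units = units %||% attr(x, "units") %||% "fraction",
    n_replicates = n_replicates %||% attr(x, "n_replicates") %||% 3L
  )
}

#' Read / write release curves as CSV
#'
#' The on-disk dialect is a plain CSV with columns `time_min,mean,sd[,n]`,
#' preceded by optional comment lines `# drug: <name>` and
#' `# units: <units>`.
#'
#' @param path File path.
#' @return `read_release_csv()` returns a [release_curve()];
#'   `write_release_csv()` returns `path` invisibly.
#' @export
read_release_csv <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0 || all(!nzchar(lines))) {
    abort("Empty release-curve file.", class = "ocurel_format_error")
  }
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) == 0) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[[1]]))
  }
  df <- readr::read_csv(I(lines), comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("time_min", "mean") %in% names(df))) {
    abort("Release CSV needs columns `time_min,mean[,sd][,n]`.",
          class = "ocurel_format_error")
  }
  release_curve(
    df$time_min, df$mean,
    sd_release = if ("sd" %in% names(df)) df$sd else NULL,
    drug = get_meta("drug", "drug"),
    units = get_meta("units", "fraction"),
    n_replicates = if ("n" %in% names(df)) df$n[[1]] else 3L
  )
}

#' @param curve A [release_curve()].
#' @rdname read_release_csv
#' @export
write_release_csv <- function(curve, path) {
  curve <- as_release_curve(curve)
  hdr <- c(paste0("# drug: ", attr(curve, "drug")),
           paste0("# units: ", attr(curve, "units")))
  body <- tibble(time_min = curve$time_min, mean = curve$mean_release,
                 sd = curve$sd_release,
                 n = attr(curve, "n_replicates"))
  readr::write_lines(hdr, path)
  readr::write_csv(body, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf("<release_curve: %s, %d points, units = %s, n = %d>\n",
              attr(x, "drug"), nrow(x), attr(x, "units"),
              attr(x, "n_replicates")))
  NextMethod()
}

#' Time to reach a fraction of the release plateau
#'
#' Estimates the plateau level of a cumulative release curve (mean of the
#' last three points, which must agree with the curve maximum to within 2%)
#' and returns the first time at which the mean release reaches
#' `frac * plateau`, linearly interpolating between samples. The
#' formulations studied here reach their plateau within 200-360 min.
#'
#' @param curve A [release_curve()] or data frame with `time_min`,
#'   `mean_release`.
#' @param frac Plateau fraction defining "reached", in (0, 1). Default 0.95.
#' @return Time in minutes (single number).
#' @export
plateau_time <- function(curve, frac = 0.95) {
  curve <- as_release_curve(curve)
  if (frac <= 0 || frac >= 1) {
    abort("`frac` must lie in (0, 1).", class = "ocurel_domain_error")
  }
  y <- curve$mean_release
  t <- curve$time_min
  if (length(y) < 4) {
    abort("Need at least 4 points to detect a plateau.",
          class = "ocurel_domain_error")
  }
  tail3 <- tail(y, 3)
  # plateau criterion: last three points within 2% of the curve maximum,
  # widened by 3 standard errors of the replicate mean so measurement noise
  # does not mask a genuine plateau
  noise_allow <- 3 * median(curve$sd_release) /
    sqrt(attr(curve, "n_replicates") %||% 1)
  if (any(abs(tail3 - max(y)) > 0.02 * max(y) + noise_allow)) {
    abort("No plateau: last three points differ from the maximum by > 2%.",
          class = "ocurel_no_plateau_error")
  }
  plateau <- mean(tail3)
  target <- frac * plateau
  idx <- which(y >= target)
  if (length(idx) == 0) {
    abort("Curve never reaches the requested plateau fraction.",
          class = "ocurel_no_plateau_error")
  }
  i <- idx[[1]]
  if (i == 1 || y[[i]] == target) return(t[[i]])
  # linear interpolation on the rising segment
  t[[i - 1]] + (target - y[[i - 1]]) / (y[[i]] - y[[i - 1]]) *
    (t[[i]] - t[[i - 1]])
}

#' Cumulative release from UV-Vis absorbances
#'
#' Converts bath absorbances sampled during a dialysis release study into a
#' cumulative-mass release curve. Concentration follows the calibration line
#' `conc = (absorbance - intercept)/slope` (clipped at zero when an
#' absorbance falls below the intercept); the cumulative mass corrects for
#' the drug removed in earlier withdrawn-and-replaced aliquots:
#' `M_i = conc_i * V_bath + V_sample * sum_{j<i} conc_j`.
#'
#' @param absorbances A data frame with columns `time_min` and `absorbance`.
#' @param calibration A list with `slope` (absorbance per concentration
#'   unit, positive), `intercept` (absorbance) and optionally
#'   `wavelength_nm`.
#' @param bath_volume_mL Receptor volume in mL, positive.
#' @param sample_volume_mL Withdrawn-and-replaced aliquot volume in mL,
#'   nonnegative and smaller than the bath volume.
#' @param drug Identifier carried into the result.
#' @return A [release_curve()] in mass units (`units = "ug"` when the
#'   calibration slope is per ug/mL).
#' @export
release_from_absorbance <- function(absorbances, calibration,
                                    bath_volume_mL, sample_volume_mL = 0,
                                    drug = "drug") {
  absorbances <- as_tibble(absorbances)
  if (!all(c("time_min", "absorbance") %in% names(absorbances))) {
    abort("`absorbances` needs columns time_min, absorbance.",
          class = "ocurel_format_error")
  }
  slope <- calibration$slope
  intercept <- calibration$intercept %||% 0
  if (!is.numeric(slope) || slope <= 0) {
    abort("Calibration slope must be positive.",
          class = "ocurel_domain_error")
  }
  if (bath_volume_mL <= 0 || sample_volume_mL < 0 ||
      sample_volume_mL >= bath_volume_mL) {
    abort("Need 0 <= sample_volume_mL < bath_volume_mL, bath volume > 0.",
          class = "ocurel_domain_error")
  }
  conc <- (absorbances$absorbance - intercept) / slope
  n_clipped <- sum(conc < 0)
  if (n_clipped > 0) {
    warn(sprintf("%d absorbance(s) below the calibration intercept; %s",
                 n_clipped, "clipped to zero concentration."))
    conc <- pmax(conc, 0)
  }
  withdrawn <- sample_volume_mL * dplyr::lag(cumsum(conc), default = 0)
  mass <- conc * bath_volume_mL + withdrawn
  release_curve(absorbances$time_min, mass, drug = drug, units = "ug")
}
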