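#' The Kink (bounded tanh) release law
#'
#' Cumulative release predicted by the bounded solution of the Riccati-type
#' multifractal release equation:
#'
#' `M(t) = B + a * tanh(a * (t - t0) / A_scale)`
#'
#' `B` is the release offset at the inflection, `a > 0` the amplitude (the
#' plateau is `B + a`), `A_scale > 0` a time-scaling constant (units of
#' release x minutes; the initial slope at `t0` is `a^2 / A_scale`) and `t0`
#' a lag time locating the inflection. The curve is antisymmetric about
#' `(t0, B)`: `M(t0 + d) + M(t0 - d) = 2B`.
#'
#' @param t Time(s) in minutes; vectorised.
#' @param B,a,A_scale,t0 Kink parameters (see Description); `a` and
#'   `A_scale` must be positive.
#' @return Release value(s), same units as `B` and `a`.
#' @examples
#' kink_mass(1, B = 0, a = 1, A_scale = 1, t0 = 0) # tanh(1)
#' @export
kink_mass <- function(t, B, a, A_scale, t0 = 0) {
  if (a <= 0 || A_scale <= 0) {
    abort("`a` and `A_scale` must be positive.",
          class = "ocurel_domain_error")
  }
  B + a * tanh(a * (t - t0) / A_scale)
}

#' Classical dissolution model curves
#'
#' Evaluates one of the four classical cumulative-release baselines:
#' * `korsmeyer-peppas`: `M = k * t^n`
#' * `higuchi`: `M = kH * sqrt(t)` (Korsmeyer-Peppas with `n = 1/2`)
#' * `hixson-crowell`: `M = M0 * (1 - (1 - kHC * t)^3)`, clipped at `M0`
#'   once dissolution completes at `t = 1/kHC`
#' * `weibull`: `M = Minf * (1 - exp(-(t/lambda)^b))`
#'
#' @param name Model name (see above; `"kink"` is also accepted and
#'   dispatches to [kink_mass()]).
#' @param t Time(s) in minutes.
#' @param params Named list of parameters: `k, n` (Korsmeyer-Peppas); `kH`
#'   (Higuchi); `M0, kHC` (Hixson-Crowell); `Minf, lambda, b` (Weibull);
#'   `B, a, A_scale, t0` (kink).
#' @return Release value(s).
#' @examples
#' classical_release("higuchi", 4, list(kH = 0.1)) # 0.2
#' @export
classical_release <- function(name, t, params) {
  name <- match.arg(name, release_model_names)
  p <- params
  switch(name,
    "korsmeyer-peppas" = p$k * t^p$n,
    "higuchi" = p$kH * sqrt(t),
    "hixson-crowell" = p$M0 * (1 - pmax(1 - p$kHC * t, 0)^3),
    "weibull" = p$Minf * (1 - exp(-(t / p$lambda)^p$b)),
    "kink" = kink_mass(t, p$B, p$a, p$A_scale, p$t0 %||% 0)
  )
}

release_model_names <- c("kink", "korsmeyer-peppas", "higuchi",
                         "hixson-crowell", "weibull")

release_model_npar <- c("kink" = 4L, "korsmeyer-peppas" = 2L,
                        "higuchi" = 1L, "hixson-crowell" = 2L,
                        "weibull" = 3L)

# Weighted least-squares weights from replicate SDs. With few replicates a
# raw per-point 1/sd^2 is extremely noisy (a lucky near-zero SD dominates
# the fit), so per-point variances are shrunk halfway toward the pooled
# variance before inverting. All-zero or absent SDs give uniform weights.
fit_weights <- function(curve) {
  s <- curve$sd_release
  if (is.null(s) || all(!is.finite(s)) || all(s <= 0)) {
    return(rep(1, nrow(curve)))
  }
  pooled <- mean(s^2)
  1 / (0.5 * s^2 + 0.5 * pooled)
}

fit_stats <- function(y, yhat, w, npar) {
  res <- y - yhat
  n <- length(y)
  rss <- sum(res^2)
  wrss <- sum(w * res^2) / mean(w)
  r2 <- 1 - rss / sum((y - mean(y))^2)
  k <- npar + 1 # + residual variance
  aicc <- if (n - k - 1 > 0) {
    n * log(wrss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  } else {
    Inf
  }
  list(rss = rss, r_squared = r2, aicc = aicc)
}

new_release_fit <- function(model_name, params, stats, converged, curve) {
  structure(
    list(model_name = model_name, params = params, rss = stats$rss,
         r_squared = stats$r_squared, aicc = stats$aicc,
         converged = converged, n_obs = nrow(curve),
         drug = attr(curve, "drug"), units = attr(curve, "units")),
    class = c(paste0(gsub("-", "_", model_name), "_fit"), "release_fit")
  )
}

failed_release_fit <- function(model_name, curve) {
  structure(
    list(model_name = model_name,
         params = setNames(
           rep(NA_real_, release_model_npar[[model_name]]),
           release_model_param_names(model_name)),
         rss = NA_real_, r_squared = NA_real_, aicc = Inf,
         converged = FALSE, n_obs = nrow(curve),
         drug = attr(curve, "drug"), units = attr(curve, "units")),
    class = c(paste0(gsub("-", "_", model_name), "_fit"), "release_fit")
  )
}

release_model_param_names <- function(name) {
  switch(name,
    "kink" = c("B", "a", "A_scale", "t0"),
    "korsmeyer-peppas" = c("k", "n"),
    "higuchi" = "kH",
    "hixson-crowell" = c("M0", "kHC"),
    "weibull" = c("Minf", "lambda", "b")
  )
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf("<release_fit: %s on %s (%d points)%s>\n", x$model_name,
              x$drug, x$n_obs, if (x$converged) "" else " [not converged]"))
  cat("  params:",
      paste(names(x$params), signif(unlist(x$params), 5), sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("  RSS %.4g | R^2 %.4f | AICc %.2f\n", x$rss, x$r_squared,
              x$aicc))
  invisible(x)
}

nls_fit <- function(curve, formula, start, lower, upper, w) {
  df <- data.frame(t = curve$time_min, y = curve$mean_release)
  tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(formula, data = df, start = start, lower = lower,
                        upper = upper, weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    ),
    error = function(e) NULL
  )
}

#' Fit the Kink release law to a cumulative release curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) fit of
#' [kink_mass()] to a release curve. Weights are `1/sd^2` from the replicate
#' SDs (with a small floor on near-zero SDs); uniform weights are used, with
#' a message, when SDs are absent. Starting values: `B` from the first
#' observation, `a` from the observed rise, `t0` from the time of half-rise
#' and `A_scale` from the maximum finite-difference slope. Bounds enforce
#' `a > 0`, `A_scale > 0`, `B >= 0`. Non-convergence is reported through the
#' `converged` flag rather than an error.
#'
#' @param curve A [release_curve()] (or data frame with `time_min`,
#'   `mean_release`, optionally `sd_release`) with at least 5 points and a
#'   nonconstant mean.
#' @return An object of class `c("kink_fit", "release_fit")` with elements
#'   `model_name`, `params`, `rss`, `r_squared`, `aicc`, `converged`; see
#'   [tidy.release_fit()] and [glance.release_fit()].
#' @export
fit_kink <- function(curve) {
  curve <- as_release_curve(curve)
  check_fittable(curve)
  y <- curve$mean_release
  t <- curve$time_min
  w <- fit_weights(curve)
  if (all(w == w[[1]]) && !all(curve$sd_release > 0)) {
    rlang::inform("No usable replicate SDs; using uniform weights.",
                  class = "ocurel_uniform_weights")
  }
  B0 <- max(min(y), 1e-8)
  a0 <- max(max(y) - min(y), 1e-8)
  half <- min(y) + a0 / 2
  t0_0 <- approx(y, t, xout = half, ties = "ordered")$y
  if (!is.finite(t0_0)) t0_0 <- median(t)
  slope_max <- max(diff(y) / diff(t))
  A0 <- if (is.finite(slope_max) && slope_max > 0) a0^2 / slope_max else
    a0 * diff(range(t)) / 4
  fit <- nls_fit(curve, y ~ B + a * tanh(a * (t - t0) / A_scale),
                 start = list(B = B0, a = a0, A_scale = A0, t0 = t0_0),
                 lower = c(B = 0, a = 1e-10, A_scale = 1e-10,
                           t0 = min(t) - 2 * diff(range(t))),
                 upper = c(B = Inf, a = Inf, A_scale = Inf,
                           t0 = max(t) + 2 * diff(range(t))),
                 w = w)
  if (is.null(fit)) return(failed_release_fit("kink", curve))
  p <- as.list(coef(fit))
  yhat <- kink_mass(t, p$B, p$a, p$A_scale, p$t0)
  new_release_fit("kink", p, fit_stats(y, yhat, w, 4L), TRUE, curve)
}

check_fittable <- function(curve, min_points = 5L) {
  if (nrow(curve) < min_points) {
    abort(sprintf("Need at least %d time points to fit.", min_points),
          class = "ocurel_domain_error")
  }
  if (diff(range(curve$mean_release)) <= 0) {
    abort("Cannot fit a constant release curve.",
          class = "ocurel_domain_error")
  }
  invisible(curve)
}

fit_classical <- function(curve, name) {
  curve <- as_release_curve(curve)
  check_fittable(curve)
  y <- curve$mean_release
  t <- curve$time_min
  w <- fit_weights(curve)
  ymax <- max(y)
  tmax <- max(t)
  if (name == "higuchi") {
    # single linear parameter: exact weighted least squares
    kH <- sum(w * y * sqrt(t)) / sum(w * t)
    yhat <- kH * sqrt(t)
    return(new_release_fit("higuchi", list(kH = kH),
                           fit_stats(y, yhat, w, 1L), TRUE, curve))
  }
  fit <- switch(name,
    "korsmeyer-peppas" = {
      pos <- y > 0 & t > 0
      init <- if (sum(pos) >= 2) {
        cf <- coef(lm(log(y[pos]) ~ log(t[pos])))
        list(k = exp(cf[[1]]), n = min(max(cf[[2]], 0.05), 2.5))
      } else {
        list(k = ymax / sqrt(tmax), n = 0.5)
      }
      nls_fit(curve, y ~ k * t^n, start = init,
              lower = c(k = 1e-12, n = 0.01), upper = c(k = Inf, n = 3),
              w = w)
    },
    "hixson-crowell" = {
      nls_fit(curve, y ~ M0 * (1 - pmax(1 - kHC * t, 0)^3),
              start = list(M0 = ymax, kHC = 1 / (1.5 * tmax)),
              lower = c(M0 = 1e-10, kHC = 1e-10),
              upper = c(M0 = Inf, kHC = Inf), w = w)
    },
    "weibull" = {
      t_half <- approx(y, t, xout = ymax / 2, ties = "ordered")$y
      if (!is.finite(t_half) || t_half <= 0) t_half <- tmax / 3
      nls_fit(curve, y ~ Minf * (1 - exp(-(t / lambda)^b)),
              start = list(Minf = ymax, lambda = t_half / 0.693, b = 1),
              lower = c(Minf = 1e-10, lambda = 1e-6, b = 0.05),
              upper = c(Minf = Inf, lambda = Inf, b = 10), w = w)
    }
  )
  if (is.null(fit)) return(failed_release_fit(name, curve))
  p <- as.list(coef(fit))
  yhat <- classical_release(name, t, p)
  new_release_fit(name, p, fit_stats(y, yhat, w, release_model_npar[[name]]),
                  TRUE, curve)
}

#' Fit and rank all release models on one curve
#'
#' Fits the Kink law and the four classical baselines to the same curve with
#' the same weights and ranks them by small-sample-corrected AICc
#' (ascending). A model that fails to converge is kept in the table with
#' `converged = FALSE` and `AICc = Inf`; a single failure never aborts the
#' comparison.
#'
#' @inheritParams fit_kink
#' @param models Character vector of models to fit (default all five).
#' @return An object of class `release_model_set`: a list with `fits` (named
#'   list of `release_fit` objects) and `comparison` (tibble ranked by AICc
#'   with columns `rank, model, rss, r_squared, aicc, delta_aicc,
#'   converged`).
#' @examples
#' curve <- synth_release_curve(seed = 1)
#' fits <- fit_release_models(curve)
#' fits$comparison
#' @export
fit_release_models <- function(curve, models = release_model_names) {
  curve <- as_release_curve(curve)
  models <- match.arg(models, release_model_names, several.ok = TRUE)
  fits <- purrr::map(setNames(models, models), function(m) {
    tryCatch(
      if (m == "kink") {
        suppressMessages(fit_kink(curve))
      } else {
        fit_classical(curve, m)
      },
      error = function(e) failed_release_fit(m, curve)
    )
  })
  comparison <- purrr::map_dfr(fits, function(f) {
    tibble(model = f$model_name, rss = f$rss, r_squared = f$r_squared,
           aicc = f$aicc, converged = f$converged)
  })
  comparison <- dplyr::arrange(comparison, .data$aicc)
  comparison <- dplyr::mutate(
    comparison,
    rank = dplyr::row_number(),
    delta_aicc = .data$aicc - .data$aicc[[1]],
    .before = 1
  )
  structure(list(fits = fits, comparison = comparison,
                 drug = attr(curve, "drug")),
            class = "release_model_set")
}

#' @export
print.release_model_set <- function(x, ...) {
  cat(sprintf("<release_model_set: %s, %d models>\n", x$drug,
              length(x$fits)))
  print(x$comparison)
  invisible(x)
}
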