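#' Parameters of the closed-form Riccati release solution
#'
#' The multifractal release model reduces drug-release dynamics at the
#' non-differentiable scale to a Riccati-type ordinary differential equation
#' whose bounded oscillatory solution is, in real terms,
#'
#' `z(t) = B + A*Omega * (2*r*sin(phi) + i*(1 - r^2)) / (1 + r^2 + 2*r*cos(phi))`
#'
#' with phase `phi = 2*Omega*(t - t0)`. `A` and `B` are amplitude and offset
#' constants, `Omega > 0` the angular frequency, `0 <= r < 1` and `t0`
#' integration constants. The `A*Omega` factor scales both the real and the
#' imaginary part (the symmetric reading of the closed form). The solution is
#' periodic with period `pi/Omega`.
#'
#' @param omega Angular frequency `Omega > 0` (1/time).
#' @param r Modulation constant in `[0, 1)`. `r = 0` gives the constant
#'   solution `B + i*A*Omega`; `r -> 1` gives increasingly spiked dynamics.
#' @param A Amplitude constant, nonzero. Default 1.
#' @param B Offset constant. Default 0.
#' @param t0 Time origin. Default 0.
#' @return A list of class `riccati_params`.
#' @seealso [riccati_from_coefficients()], [riccati_z()], [riccati_sweep()]
#' @export
riccati_params <- function(omega, r, A = 1, B = 0, t0 = 0) {
  stopifnot(is.numeric(omega), is.numeric(r), is.numeric(A), is.numeric(B),
            is.numeric(t0))
  if (length(omega) != 1L || !is.finite(omega) || omega <= 0) {
    abort("`omega` must be a single positive number.",
          class = "ocurel_domain_error")
  }
  if (length(r) != 1L || !is.finite(r) || r < 0 || r >= 1) {
    abort("`r` must lie in [0, 1).", class = "ocurel_domain_error")
  }
  if (length(A) != 1L || !is.finite(A) || A == 0) {
    abort("`A` must be a single nonzero number.",
          class = "ocurel_domain_error")
  }
  structure(list(omega = omega, r = r, A = A, B = B, t0 = t0),
            class = "riccati_params")
}

#' Riccati solution parameters from the raw equation coefficients
#'
#' The Riccati equation `d(eps)/d(tau) = a1*eps^2 + 2*a2*eps + a3` is brought
#' to the normal form with `A = 1/a1`, `B = -2*a2/a1 / 2 = -a2/a1` (so that
#' the quadratic `P(eps) = eps^2 + 2*B*eps - A*C` has roots `B +/- i*A*Omega`)
#' and `A*C = -a3/a1`; the oscillatory regime requires
#' `Omega^2 = C/A - (B/A)^2 > 0`. Coefficients in the real-root regime are
#' rejected: the bounded closed form only exists in the oscillatory case.
#'
#' @param a1,a2,a3 Riccati coefficients; `a1` must be nonzero.
#' @param r,t0 Integration constants passed through to [riccati_params()].
#' @return A `riccati_params` object.
#' @examples
#' riccati_from_coefficients(1, 0, -1) # A = 1, B = 0, Omega = 1
#' @export
riccati_from_coefficients <- function(a1, a2, a3, r = 0.1, t0 = 0) {
  if (!is.numeric(a1) || length(a1) != 1L || !is.finite(a1) || a1 == 0) {
    abort("`a1` must be a single nonzero number.",
          class = "ocurel_domain_error")
  }
  A <- 1 / a1
  B <- -a2 / a1
  AC <- -a3 / a1
  C <- AC / A
  omega2 <- C / A - (B / A)^2
  if (!is.finite(omega2) || omega2 <= 0) {
    abort(paste0("Omega^2 = C/A - (B/A)^2 = ", format(omega2),
                 " <= 0: real-root (non-oscillatory) regime; the bounded ",
                 "closed-form solution does not apply."),
          class = "ocurel_nonoscillatory_error")
  }
  riccati_params(omega = sqrt(omega2), r = r, A = A, B = B, t0 = t0)
}

#' Evaluate the closed-form Riccati solution
#'
#' @param t Time(s) at which to evaluate; vectorised.
#' @param params A [riccati_params()] object.
#' @return Complex value(s) `z(t)`.
#' @examples
#' p <- riccati_params(omega = 1, r = 0.5)
#' riccati_z(pi / 2, p) # 0 + 3i
#' @export
riccati_z <- function(t, params) {
  stopifnot(inherits(params, "riccati_params"))
  phi <- 2 * params$omega * (t - params$t0)
  d <- 1 + params$r^2 + 2 * params$r * cos(phi)
  params$B + params$A * params$omega *
    (2 * params$r * sin(phi) + 1i * (1 - params$r^2)) / d
}

#' Deterministic parameter sweep of the Riccati release regimes
#'
#' Evaluates the closed-form solution on a time grid for every combination
#' of `omega` and `r`, producing the tidy series from which the model's
#' release-dynamics regimes (near-harmonic modulation through spike-train
#' "intermittent" release) are plotted and classified.
#'
#' @param omega Vector of angular frequencies, all positive.
#' @param r Vector of modulation constants, all in `[0, 1)`.
#' @param times Time grid (numeric vector).
#' @param A,B,t0 Shared solution constants; defaults `A = 1`, `B = 0`,
#'   `t0 = 0` match how the regime figures are usually parameterized when
#'   only `(omega, r)` are quoted.
#' @return A tibble with columns `omega, r, t, re_z, im_z`, one row per
#'   `(omega, r, t)` combination; `length(omega) * length(r)` series.
#' @examples
#' sweep <- riccati_sweep(omega = c(1.1, 1.5), r = c(0.1, 0.5),
#'                        times = seq(0, 20, by = 0.01))
#' dplyr::count(sweep, omega, r)
#' @export
riccati_sweep <- function(omega, r, times, A = 1, B = 0, t0 = 0) {
  if (length(omega) == 0 || length(r) == 0 || length(times) == 0) {
    abort("`omega`, `r` and `times` must be nonempty.",
          class = "ocurel_domain_error")
  }
  if (any(r >= 1) || any(r < 0)) {
    abort("All `r` must lie in [0, 1).", class = "ocurel_domain_error")
  }
  grid <- tidyr::expand_grid(omega = omega, r = r)
  purrr::pmap_dfr(grid, function(omega, r) {
    p <- riccati_params(omega = omega, r = r, A = A, B = B, t0 = t0)
    z <- riccati_z(times, p)
    tibble(omega = omega, r = r, t = times, re_z = Re(z), im_z = Im(z))
  })
}

#' Residual of the Riccati solution under the Möbius-transform oracle
#'
#' Independent correctness check of the closed form: the Möbius transform
#' `w = (z - z1)/(z - z2)` with `z1 = B + i*A*Omega`, `z2 = B - i*A*Omega`
#' linearises the Riccati dynamics to `dw/dt = 2i*Omega*w`. This function
#' evaluates `z` on the grid, applies the transform, differentiates `w`
#' numerically by central differences, and returns the maximum absolute
#' residual `|dw/dt - 2i*Omega*w|` over the interior grid points. For the
#' exact solution the residual is pure finite-differencing error and decays
#' at second order in the step.
#'
#' @param params A [riccati_params()] object.
#' @param times Uniform time grid with at least 8 points per period
#'   `pi/Omega`; denser grids give smaller residuals.
#' @return The maximum absolute residual (single number).
#' @export
riccati_ode_residual <- function(params, times) {
  stopifnot(inherits(params, "riccati_params"))
  n <- length(times)
  if (n < 5) {
    abort("Need at least 5 grid points.", class = "ocurel_resolution_error")
  }
  h <- diff(times)
  if (max(h) - min(h) > 1e-9 * max(abs(h))) {
    abort("`times` must be a uniform grid.", class = "ocurel_domain_error")
  }
  step <- h[[1]]
  period <- pi / params$omega
  if (period / step < 8) {
    abort("Grid too coarse: need >= 8 points per period pi/Omega.",
          class = "ocurel_resolution_error")
  }
  if (params$r == 0) return(0)
  z <- riccati_z(times, params)
  z1 <- params$B + 1i * params$A * params$omega
  z2 <- params$B - 1i * params$A * params$omega
  w <- (z - z1) / (z - z2)
  dw <- (w[3:n] - w[1:(n - 2)]) / (2 * step)
  resid <- dw - 2i * params$omega * w[2:(n - 1)]
  max(Mod(resid))
}

#' Classify the oscillatory regime of a Riccati release series
#'
#' Operational classification of one `(omega, r)` series from
#' [riccati_sweep()] by peak-shape statistics of `Re z` over whole periods:
#' the duty cycle (fraction of the period during which `|Re z - B|` exceeds
#' half its maximum) and the ratio of consecutive local-maximum amplitudes.
#' A sinusoid has duty cycle 2/3; as `r` grows the crests sharpen into
#' spikes. Labels, by duty cycle `D`:
#' `near-harmonic` (`D >= duty_harmonic`), `double-peaked`
#' (`duty_spike < D < duty_harmonic`), `spike-train` (`D <= duty_spike`).
#' These operational labels track the qualitative regime vocabulary used for
#' such dynamics (period doubling, quasi-periodicity, damped oscillation,
#' intermittency), which is defined only visually; both are reported.
#'
#' @param series A data frame with columns `t`, `re_z` and `omega` (a single
#'   series, e.g. one group of a [riccati_sweep()] result). Must span at
#'   least 5 periods `pi/omega`.
#' @param B Offset constant of the series; if `NULL`, estimated as the mean
#'   of `re_z` over the analysed whole periods (exact for the closed form).
#' @param duty_harmonic,duty_spike Classification thresholds on the duty
#'   cycle. Defaults 0.5 and 0.25.
#' @return A one-row tibble: `label`, `duty_cycle`, `peak_ratio`,
#'   `n_periods`, `annotation` (the visual-vocabulary note).
#' @export
classify_regime <- function(series, B = NULL, duty_harmonic = 0.5,
                            duty_spike = 0.25) {
  series <- as_tibble(series)
  if (!all(c("t", "re_z", "omega") %in% names(series))) {
    abort("`series` needs columns t, re_z, omega.",
          class = "ocurel_format_error")
  }
  omega <- unique(series$omega)
  if (length(omega) != 1L) {
    abort("`series` must contain a single omega value.",
          class = "ocurel_domain_error")
  }
  period <- pi / omega
  span <- max(series$t) - min(series$t)
  n_periods <- floor(span / period)
  if (n_periods < 5) {
    abort("Series must span at least 5 periods pi/omega.",
          class = "ocurel_domain_error")
  }
  keep <- series$t <= min(series$t) + n_periods * period
  t <- series$t[keep]
  y <- series$re_z[keep]
  if (is.null(B)) B <- mean(y)
  dev <- abs(y - B)
  amp <- max(dev)
  duty <- mean(dev > amp / 2)
  # consecutive local-maximum amplitude ratio (min/max of adjacent peaks)
  n <- length(dev)
  is_peak <- c(FALSE, dev[2:(n - 1)] > dev[1:(n - 2)] &
                 dev[2:(n - 1)] >= dev[3:n], FALSE)
  peaks <- dev[is_peak & dev > amp / 4]
  peak_ratio <- if (length(peaks) >= 2) {
    pairs <- cbind(head(peaks, -1), tail(peaks, -1))
    mean(apply(pairs, 1, min) / apply(pairs, 1, max))
  } else {
    NA_real_
  }
  label <- if (duty <= duty_spike) {
    "spike-train"
  } else if (duty >= duty_harmonic) {
    "near-harmonic"
  } else {
    "double-peaked"
  }
  annotation <- switch(label,
    "near-harmonic" = "quasi-periodic / period-doubling modulation",
    "double-peaked" = "damped-oscillation-like modulation",
    "spike-train" = "intermittency-like release bursts"
  )
  tibble(label = label, duty_cycle = duty, peak_ratio = peak_ratio,
         n_periods = n_periods, annotation = annotation)
}
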