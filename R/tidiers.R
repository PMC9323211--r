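#' Tidy a fitted release model
#'
#' @param x A `release_fit` from [fit_kink()] or [fit_release_models()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @export
tidy.release_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unlist(x$params, use.names = FALSE))
}

#' @rdname tidy.release_fit
#' @return For `glance()`: a one-row tibble `model, rss, r_squared, aicc,
#'   converged, n_obs`.
#' @export
glance.release_fit <- function(x, ...) {
  tibble(model = x$model_name, rss = x$rss, r_squared = x$r_squared,
         aicc = x$aicc, converged = x$converged, n_obs = x$n_obs)
}

#' @rdname tidy.release_fit
#' @export
tidy.release_model_set <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    dplyr::mutate(tidy(f), model = f$model_name, .before = 1)
  })
}

#' @rdname tidy.release_fit
#' @export
glance.release_model_set <- function(x, ...) {
  x$comparison
}
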